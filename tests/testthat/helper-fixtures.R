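# Shared fixtures, all built in code.

# -- hand-planted NHX topologies ---------------------------------------------

# Usable topology: duplication directly preceded by a speciation node whose
# sister clade is a clean singleton.
nhx_usable <- function() {
  paste0("((pA_1[&&NHX:S=spA:GT=paralog]:0.2,",
         "pA_2[&&NHX:S=spA:GT=paralog]:0.2)[&&NHX:D=Y]:0.2,",
         "oB[&&NHX:S=spB:GT=true_singleton]:0.4)[&&NHX:D=N];")
}

# Nested duplications: the inner duplication must be discarded, the
# outermost kept.
nhx_nested <- function() {
  paste0("(((pA_1a[&&NHX:S=spA:GT=paralog]:0.1,",
         "pA_1b[&&NHX:S=spA:GT=paralog]:0.1)[&&NHX:D=Y]:0.1,",
         "pA_2[&&NHX:S=spA:GT=paralog]:0.2)[&&NHX:D=Y]:0.2,",
         "oB[&&NHX:S=spB:GT=true_singleton]:0.4)[&&NHX:D=N];")
}

# Outgroup clade descending from a lost duplication: its leaves are
# remaining paralogs, so the candidate duplication must be rejected.
nhx_lost_outgroup <- function() {
  paste0("((pA_1[&&NHX:S=spA:GT=paralog]:0.2,",
         "pA_2[&&NHX:S=spA:GT=paralog]:0.2)[&&NHX:D=Y]:0.2,",
         "(rB[&&NHX:S=spB:GT=remaining_paralog]:0.2,",
         "rC[&&NHX:S=spC:GT=remaining_paralog]:0.2)[&&NHX:D=Y]:0.2)[&&NHX:D=N];")
}

# Family with uniform dummy sequences for topology-only tests.
topology_family <- function(nhx, id = "fx", n_col = 30) {
  parsed <- dupasym:::read_nhx(nhx)
  seqs <- setNames(rep(strrep("A", n_col), length(parsed$tree$tip.label)),
                   parsed$tree$tip.label)
  fam <- reconciled_family(id, seqs, parsed$tree, parsed$node_type,
                           parsed$gene_type, parsed$leaf_species)
  fam$node_depth <- rep(0.3, length(parsed$tree$tip.label) + parsed$tree$Nnode)
  fam$node_depth[seq_along(parsed$tree$tip.label)] <- 0
  fam
}

# -- depth-matrix fixtures ---------------------------------------------------

# Single-bin matrices with hand-set off-diagonal frequencies; unspecified
# cells share the remaining mass uniformly.
fake_matrices <- function(freqs = NULL, max_depth = 1) {
  aa <- amino_acids()
  m <- matrix(1, 20, 20, dimnames = list(aa, aa))
  diag(m) <- 0
  if (!is.null(freqs)) {
    for (i in seq_len(nrow(freqs))) {
      m[freqs$from[[i]], freqs$to[[i]]] <- freqs$w[[i]]
    }
  }
  m <- m / sum(m)
  structure(list(breaks = c(0, max_depth), matrices = list(m), pooled = m,
                 n_events = sum(!is.na(m))),
            class = "depth_matrices")
}

# -- small simulated cohorts (cached across test files) ----------------------

tiny_species_tree <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_species_tree(4, 0.6, seed = 400)
    cache
  }
})

# Many small families for generator-level statistics: duplication on the
# focal species' terminal edge so every family yields a focal paralog pair.
tiny_pair_families <- local({
  cache <- NULL
  function(n = 300, rate_ratio = 1, seed = 500) {
    key <- sprintf("%d_%g_%d", n, rate_ratio, seed)
    if (is.null(cache[[key]])) {
      st <- tiny_species_tree()
      focal <- match("s01", st$tree$tip.label)
      fams <- lapply(seq_len(n), function(i) {
        generate_family(st, sim_family_spec(
          id = sprintf("f%04d", i), length = 60, gamma_shape = 5,
          dup_edge = focal, rate_ratio = rate_ratio, ka_ks = 0.5,
          seed = seed + i))
      })
      names(fams) <- vapply(fams, function(f) f$family$id, "")
      cache[[key]] <<- fams
    }
    cache[[key]]
  }
})

# One shared mid-size analysed cohort for the join/battery/pipeline tests.
shared_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- simulate_cohort(n_families = 14, n_taxa = 6, root_depth = 0.8,
                                length = 150, gamma_shape = 5, rate_ratio = 2,
                                expr_coupling = -1, kaks_coupling = 1,
                                seed = 77)
      analysis <- analyze_cohort(cohort)
      pairs <- build_pair_records(analysis, cohort$expression,
                                  snp = cohort$snp,
                                  locations = cohort$locations)
      cache <<- list(cohort = cohort, analysis = analysis, pairs = pairs)
    }
    cache
  }
})
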