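#' Simulate a cohort of reconciled families with companion tables
#'
#' Draws a species tree, then one family per replicate with the
#' duplication placed on a random non-root species-tree edge, plus
#' focal-species expression, SNP and location tables.  Defaults emulate
#' the statistical structure of a drosophilid-style input: 12 species,
#' 300-residue proteins, moderate site-rate heterogeneity (gamma shape
#' 2), substitutions at the Ks clock, 26 expression tissues.
#'
#' @param n_families Number of families.
#' @param n_taxa Species count (default 12).
#' @param root_depth Species-tree root age in Ks units (default 1.5).
#' @param length Alignment length in residues (default 300).
#' @param gamma_shape Site-rate gamma shape (default 2).
#' @param rate_ratio Imposed paralog-1/paralog-2 rate ratio (default 1 =
#'   symmetric).
#' @param ka_ks Constraint factor (expected relKa) for every clade
#'   (default 0.2).
#' @param expr_coupling,kaks_coupling Couplings passed to the table
#'   generators (defaults 0).
#' @param n_tissues Expression tissue count (default 26).
#' @param indel_rate Per-column indel probability (default 0).
#' @param seed Integer master seed; every stage seed derives from it.
#' @return List of class \code{asym_cohort}: \code{species_tree},
#'   \code{families} (named list of \code{generate_family} results),
#'   \code{expression}, \code{snp}, \code{locations}, and the arguments
#'   in \code{params}.
#' @export
simulate_cohort <- function(n_families, n_taxa = 12, root_depth = 1.5,
                            length = 300, gamma_shape = 2, rate_ratio = 1,
                            ka_ks = 0.2, expr_coupling = 0, kaks_coupling = 0,
                            n_tissues = 26, indel_rate = 0, seed = 1) {
  seed <- as.integer(seed)
  stree <- generate_species_tree(n_taxa, root_depth, seed = seed)
  st <- stree$tree
  candidates <- setdiff(seq_len(n_tips(st) + st$Nnode), root_node(st))
  edges <- withr::with_seed(seed + 1L, {
    sample(candidates, n_families, replace = TRUE)
  })
  families <- lapply(seq_len(n_families), function(i) {
    spec <- sim_family_spec(id = sprintf("f%04d", i), length = length,
                            gamma_shape = gamma_shape, dup_edge = edges[[i]],
                            rate_ratio = rate_ratio, ka_ks = ka_ks,
                            indel_rate = indel_rate,
                            seed = seed + 100L + i)
    generate_family(stree, spec)
  })
  names(families) <- vapply(families, function(f) f$family$id, "")
  structure(list(
    species_tree = stree,
    families = families,
    expression = generate_expression_table(families, coupling = expr_coupling,
                                           n_tissues = n_tissues,
                                           seed = seed + 2L),
    snp = generate_snp_table(families, kaks_coupling = kaks_coupling,
                             seed = seed + 3L),
    locations = generate_location_table(families, seed = seed + 4L),
    params = list(n_families = n_families, n_taxa = n_taxa,
                  root_depth = root_depth, length = length,
                  gamma_shape = gamma_shape, rate_ratio = rate_ratio,
                  ka_ks = ka_ks,
                  expr_coupling = expr_coupling, kaks_coupling = kaks_coupling,
                  seed = seed)),
    class = "asym_cohort")
}

#' @export
print.asym_cohort <- function(x, ...) {
  cat(sprintf("<asym_cohort> %d families on %d species (seed %d)\n",
              length(x$families), n_tips(x$species_tree$tree),
              x$params$seed))
  invisible(x)
}

#' Run the full asymmetry analysis over a family cohort
#'
#' End-to-end deterministic pipeline: mask indels, build depth-binned
#' substitution matrices from the corpus, reconstruct posterior-weighted
#' substitution events per family, select eligible duplications, compute
#' per-clade rates and radicality, assemble asymmetry records and apply
#' multiple-testing adjustment, and record the funnel counts.
#'
#' @param families Either an \code{asym_cohort} or a named list of
#'   \code{generate_family}-style elements (each with \code{$family}).
#' @param species_tree Required when \code{families} is a plain list.
#' @param max_indel,flank Masking parameters (defaults 1 and 5).
#' @param n_bins Depth bins for the substitution matrices (default 10).
#' @param young_ks Young/mid age boundary in Ks (default 0.051); the
#'   mid/old boundary is the cohort tertile.
#' @param alpha Bonferroni level (default 0.05).
#' @param q Benjamini-Yekutieli FDR level (default 0.1).
#' @param max_alternatives Parsimony enumeration cap (default 64).
#' @param polarity,ex Radicality property tables.
#' @return Object of class \code{asym_analysis}: \code{triplets},
#'   \code{rates}, \code{asymmetry}, \code{matrices}, \code{manifest},
#'   plus the masked \code{families}.
#' @export
analyze_cohort <- function(families, species_tree = NULL, max_indel = 1,
                           flank = 5, n_bins = 10, young_ks = 0.051,
                           alpha = 0.05, q = 0.1, max_alternatives = 64,
                           polarity = grantham_polarity(),
                           ex = default_ex_matrix()) {
  if (inherits(families, "asym_cohort")) {
    species_tree <- families$species_tree
    families <- families$families
  }
  stopifnot(!is.null(species_tree))
  fams <- lapply(families, function(fg) {
    f <- mask_family(fg$family, max_indel, flank)
    if (is.null(f$node_depth)) f <- annotate_depths(f, species_tree)
    fg$family <- f
    fg
  })
  masked <- lapply(fams, `[[`, "family")
  matrices <- build_matrices(masked, n_bins = n_bins,
                             max_alternatives = max_alternatives)

  trip_list <- list(); rate_list <- list()
  for (fam in masked) {
    trips <- select_duplications(fam)
    if (nrow(trips) == 0) next
    events <- reconstruct_events(fam, matrices, max_alternatives)
    for (i in seq_len(nrow(trips))) {
      rate_list[[length(rate_list) + 1L]] <-
        triplet_rates(fam, events, trips[i, ], polarity, ex)
    }
    trip_list[[length(trip_list) + 1L]] <- trips
  }
  triplets <- dplyr::bind_rows(trip_list)
  rates <- dplyr::bind_rows(rate_list)
  if (nrow(triplets)) {
    triplets$age_class <- assign_age_class(
      triplets$ks_depth, age_boundaries(triplets$ks_depth, young = young_ks))
    records <- adjust_asymmetry(asymmetry_records(rates), alpha = alpha, q = q)
  } else {
    records <- adjust_asymmetry(
      tibble::tibble(family = character(), dup_node = integer(),
                     n1 = double(), l1 = double(), n2 = double(),
                     l2 = double(), p1 = double(), p2 = double(),
                     p = double(), z2 = double(), a = double(),
                     p_value = double()),
      alpha = alpha, q = q)
  }
  manifest <- list(
    n_families = length(masked),
    n_triplets = nrow(triplets),
    n_bonferroni_sig = sum(records$bonferroni_sig),
    n_fdr_sig = sum(records$fdr_sig),
    params = list(max_indel = max_indel, flank = flank, n_bins = n_bins,
                  young_ks = young_ks, alpha = alpha, q = q,
                  max_alternatives = max_alternatives))
  structure(list(triplets = triplets, rates = rates, asymmetry = records,
                 matrices = matrices, manifest = manifest, families = fams),
            class = "asym_analysis")
}

#' @export
print.asym_analysis <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<asym_analysis> %d families -> %d triplets; ",
                     "%d Bonferroni-significant, %d FDR-significant\n"),
              m$n_families, m$n_triplets, m$n_bonferroni_sig, m$n_fdr_sig))
  invisible(x)
}

#' Run the whole pipeline from a configuration
#'
#' Thin orchestration over \code{\link{simulate_cohort}},
#' \code{\link{analyze_cohort}}, \code{\link{build_pair_records}} and
#' \code{\link{analysis_battery}}: synthesize (or the caller may supply a
#' cohort), analyze, join, test, and write all stage outputs as TSV plus
#' a JSON manifest with the seed and funnel counts to \code{outdir}.
#'
#' @param config A named list or path to a YAML file.  Recognized fields
#'   (defaults in parentheses): \code{n_families} (50), \code{n_taxa}
#'   (12), \code{root_depth} (1.5), \code{length} (300),
#'   \code{gamma_shape} (2), \code{rate_ratio} (1), \code{expr_coupling}
#'   (0), \code{kaks_coupling} (0), \code{n_tissues} (26),
#'   \code{max_indel} (1), \code{flank} (5), \code{n_bins} (10),
#'   \code{young_ks} (0.051), \code{alpha} (0.05), \code{q} (0.1),
#'   \code{tandem_threshold} (5000), \code{seed} (1), \code{with_snp}
#'   (TRUE).
#' @param outdir Output directory (created if needed); \code{NULL} skips
#'   writing.
#' @param cohort Optional pre-built \code{asym_cohort} (overrides the
#'   synthesis fields).
#' @return List with \code{cohort}, \code{analysis}, \code{pairs},
#'   \code{battery}, \code{manifest} (invisibly if writing).
#' @export
run_pipeline <- function(config = list(), outdir = NULL, cohort = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(n_families = 50, n_taxa = 12, root_depth = 1.5,
                   length = 300, gamma_shape = 2, rate_ratio = 1, ka_ks = 0.2,
                   expr_coupling = 0, kaks_coupling = 0, n_tissues = 26,
                   max_indel = 1, flank = 5, n_bins = 10, young_ks = 0.051,
                   alpha = 0.05, q = 0.1, tandem_threshold = 5000,
                   seed = 1, with_snp = TRUE)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cohort)) {
    cohort <- simulate_cohort(
      n_families = cfg$n_families, n_taxa = cfg$n_taxa,
      root_depth = cfg$root_depth, length = cfg$length,
      gamma_shape = cfg$gamma_shape, rate_ratio = cfg$rate_ratio,
      ka_ks = cfg$ka_ks,
      expr_coupling = cfg$expr_coupling, kaks_coupling = cfg$kaks_coupling,
      n_tissues = cfg$n_tissues, seed = cfg$seed)
  }
  analysis <- analyze_cohort(cohort, max_indel = cfg$max_indel,
                             flank = cfg$flank, n_bins = cfg$n_bins,
                             young_ks = cfg$young_ks, alpha = cfg$alpha,
                             q = cfg$q)
  pairs <- build_pair_records(analysis, cohort$expression,
                              snp = if (isTRUE(cfg$with_snp)) cohort$snp else NULL,
                              locations = cohort$locations,
                              tandem_threshold = cfg$tandem_threshold)
  battery <- if (nrow(pairs) >= 3) analysis_battery(pairs, alpha = cfg$alpha)
             else NULL
  manifest <- c(analysis$manifest,
                list(n_pairs_expression = nrow(pairs),
                     n_pairs_snp_eligible =
                       if (nrow(pairs)) sum(pairs$snp_eligible, na.rm = TRUE) else 0L,
                     seed = cfg$seed, config = cfg))
  out <- list(cohort = cohort, analysis = analysis, pairs = pairs,
              battery = battery, manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv <- function(df, name) {
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    write_tsv(analysis$triplets, "triplets.tsv")
    write_tsv(analysis$rates, "clade_rates.tsv")
    write_tsv(analysis$asymmetry, "asymmetry_records.tsv")
    if (nrow(pairs)) write_tsv(pairs, "pair_records.tsv")
    if (!is.null(battery)) {
      write_tsv(battery$tests, "battery_tests.tsv")
      if (!is.null(battery$anova)) write_tsv(battery$anova, "battery_anova.tsv")
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(out)
}
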