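#' Specification for one simulated gene family
#'
#' Describes how a family evolves on the species tree: a single gene at the
#' root, one duplication placed on a chosen species-tree edge, amino-acid
#' substitutions accruing at the Ks clock (so relKa is 1 in expectation for
#' neutral families) under a uniform 20-state exchange model with per-site
#' gamma rate multipliers.
#'
#' @param id Family id used to prefix gene names.
#' @param length Alignment length in residues (> 0).
#' @param gamma_shape Shape of the gamma site-rate distribution (> 0);
#'   large values (e.g. 20) give nearly uniform rates, values below 1 a
#'   strongly leptokurtic distribution.
#' @param dup_edge Species-tree node id at the child end of the edge that
#'   receives the duplication.  Must not be the root (a duplication above
#'   the root speciation would leave no singleton outgroup).
#' @param rate_ratio Imposed rate ratio paralog-1 / paralog-2 (>= 1);
#'   1 gives symmetric evolution.
#' @param ka_ks Selective-constraint factor scaling amino-acid branch
#'   lengths relative to the Ks spans (expected relKa; default 0.2, a
#'   typical protein constraint level; 1 = neutral, the Ks clock).
#' @param concerted_until Ka span below the duplication over which the two
#'   copies are homogenized (share one substitution stream), emulating
#'   concerted evolution; 0 disables.
#' @param indel_rate Per-column probability of punching a multi-residue gap
#'   (length 2-6) into one randomly chosen extant sequence.
#' @param dup_at Relative position of the duplication on its edge (0 =
#'   at the child node, 1 = at the parent speciation); default midpoint.
#' @param loss Optional list \code{list(copy =, species =)} deleting the
#'   named species' leaves from one paralog copy (plants
#'   remaining-paralog leaves for filter tests).
#' @param seed Integer seed.
#' @return A \code{sim_family_spec} list.
#' @export
sim_family_spec <- function(id = "f001", length = 300, gamma_shape = 2,
                            dup_edge = NULL, rate_ratio = 1, ka_ks = 0.2,
                            concerted_until = 0, indel_rate = 0,
                            dup_at = 0.5, loss = NULL, seed = 1) {
  stopifnot(length > 0, gamma_shape > 0, concerted_until >= 0,
            dup_at > 0, dup_at < 1, ka_ks > 0)
  if (rate_ratio < 1) stop("rate_ratio must be >= 1 (copy 1 is the fast copy)",
                           call. = FALSE)
  structure(list(id = id, length = as.integer(length), gamma_shape = gamma_shape,
                 dup_edge = dup_edge, rate_ratio = rate_ratio, ka_ks = ka_ks,
                 concerted_until = concerted_until, indel_rate = indel_rate,
                 dup_at = dup_at, loss = loss, seed = as.integer(seed)),
            class = "sim_family_spec")
}

#' Simulate one reconciled gene family with known ground truth
#'
#' Builds the reconciled gene tree implied by placing a duplication on
#' \code{spec$dup_edge} of the species tree (with optional paralog loss),
#' then simulates amino-acid evolution along it: per-site rates are gamma
#' distributed, exchanges are uniform over the 19 alternative residues, and
#' branch lengths are the Ks spans of the species tree so that substitution
#' counts accrue at the Ks clock.  Copy 1 edges run \code{rate_ratio} times
#' faster than copy 2.
#'
#' @param species_tree A \code{species_tree}.
#' @param spec A \code{sim_family_spec}.
#' @return A list with elements \code{family} (a \code{reconciled_family},
#'   depth-annotated) and \code{truth}: per-edge simulated event counts,
#'   per-clade path-summed counts \code{n1}, \code{n2}, \code{n_out} taken
#'   from the pre-duplication speciation ancestor, total event count, the
#'   planted node ids and the identity of the faster copy.
#' @export
generate_family <- function(species_tree, spec) {
  stopifnot(inherits(species_tree, "species_tree"),
            inherits(spec, "sim_family_spec"))
  st <- species_tree$tree
  v <- spec$dup_edge
  if (is.null(v) || is.na(match(v, seq_len(n_tips(st) + st$Nnode)))) {
    stop("dup_edge must name a node of the species tree", call. = FALSE)
  }
  if (v == root_node(st)) {
    stop("dup_edge is the root edge: a duplication ancestral to all species has no singleton outgroup",
         call. = FALSE)
  }
  depth <- species_tree$node_depth
  d_v <- depth[v]
  d_p <- depth[parent_of(st, v)]
  d_dup <- d_v + spec$dup_at * (d_p - d_v)

  sp_under <- st$tip.label[descendant_tips(st, v)]
  lost <- list(`1` = character(0), `2` = character(0))
  if (!is.null(spec$loss)) {
    lost[[as.character(spec$loss$copy)]] <- intersect(spec$loss$species, sp_under)
  }
  surv <- list(setdiff(sp_under, lost[["1"]]), setdiff(sp_under, lost[["2"]]))
  if (!length(surv[[1]]) && !length(surv[[2]])) {
    stop("loss removes both paralog copies entirely", call. = FALSE)
  }

  gene_id <- function(sp, copy) sprintf("%s_%s_%d", spec$id, sp, copy)
  leaf_tag <- function(sp, copy) {
    gt <- if (copy == 0L) "true_singleton"
          else if (sp %in% surv[[3L - copy]]) "paralog" else "remaining_paralog"
    nhx_tag(list(S = sp, GT = gt))
  }

  # recursive Newick assembly; emit() returns list(str, len) or NULL
  emit_copy <- function(node, stem_len, copy) {
    if (is_tip(st, node)) {
      sp <- st$tip.label[[node]]
      if (!(sp %in% surv[[copy]])) return(NULL)
      return(list(str = paste0(gene_id(sp, copy), leaf_tag(sp, copy)), len = stem_len))
    }
    ch <- children_of(st, node)
    parts <- lapply(ch, function(c2) {
      emit_copy(c2, depth[node] - depth[c2], copy)
    })
    parts <- parts[!vapply(parts, is.null, TRUE)]
    if (!length(parts)) return(NULL)
    if (length(parts) == 1L) {
      p <- parts[[1]]
      return(list(str = p$str, len = p$len + stem_len))
    }
    inner <- paste(vapply(parts, function(p) sprintf("%s:%.10g", p$str, p$len), ""),
                   collapse = ",")
    list(str = paste0("(", inner, ")", nhx_tag(list(D = "N"))), len = stem_len)
  }

  emit_dup <- function(stem_len_total) {
    stem <- d_dup - d_v
    c1 <- emit_copy(v, stem, 1L)
    c2 <- emit_copy(v, stem, 2L)
    above <- d_p - d_dup
    if (!is.null(c1) && !is.null(c2)) {
      inner <- sprintf("%s:%.10g,%s:%.10g", c1$str, c1$len, c2$str, c2$len)
      list(str = paste0("(", inner, ")", nhx_tag(list(D = "Y"))), len = above)
    } else {
      p <- if (is.null(c1)) c2 else c1
      list(str = p$str, len = p$len + above)
    }
  }

  emit_top <- function(node, stem_len) {
    if (node == v) return(emit_dup(stem_len))
    if (is_tip(st, node)) {
      sp <- st$tip.label[[node]]
      return(list(str = paste0(gene_id(sp, 0L), leaf_tag(sp, 0L)), len = stem_len))
    }
    ch <- children_of(st, node)
    parts <- lapply(ch, function(c2) emit_top(c2, depth[node] - depth[c2]))
    inner <- paste(vapply(parts, function(p) sprintf("%s:%.10g", p$str, p$len), ""),
                   collapse = ",")
    list(str = paste0("(", inner, ")", nhx_tag(list(D = "N"))), len = stem_len)
  }

  top <- emit_top(root_node(st), 0)
  nhx <- paste0(top$str, ";")
  parsed <- read_nhx(nhx)
  gt <- parsed$tree

  sim <- withr::with_seed(spec$seed, simulate_on_tree(gt, parsed, spec, d_dup - d_v))

  fam <- reconciled_family(id = spec$id, aln = sim$aln, tree = gt,
                           node_type = parsed$node_type,
                           gene_type = parsed$gene_type,
                           leaf_species = parsed$leaf_species)
  fam <- annotate_depths(fam, species_tree)

  truth <- family_truth(fam, sim, rate_ratio = spec$rate_ratio)
  list(family = fam, truth = truth)
}

# Evolve sequences along the parsed gene tree.  Returns alignment matrix,
# per-edge event counts (named by child node id) and shared (concerted)
# event count.
simulate_on_tree <- function(gt, parsed, spec, stem_len) {
  L <- spec$length
  nt <- n_tips(gt)
  n_nodes <- nt + gt$Nnode
  g <- stats::rgamma(L, shape = spec$gamma_shape, rate = spec$gamma_shape)

  dup_nodes <- which(parsed$node_type == "duplication") + nt
  dup <- if (length(dup_nodes)) dup_nodes[[1L]] else NA_integer_
  copy1_nodes <- integer(0)
  stem_children <- integer(0)
  if (!is.na(dup)) {
    ch <- children_of(gt, dup)
    stem_children <- ch
    copy1_nodes <- descendant_nodes(gt, ch[[1L]])
  }

  shared_span <- 0
  if (!is.na(dup) && spec$concerted_until > 0) {
    shared_span <- min(spec$concerted_until, stem_len * spec$ka_ks)
  }

  states <- matrix(0L, nrow = n_nodes, ncol = L)
  states[root_node(gt), ] <- sample.int(20L, L, replace = TRUE)
  per_edge <- stats::setNames(numeric(n_nodes), seq_len(n_nodes))
  shared_events <- 0
  shared_start <- NULL

  ord <- ape::reorder.phylo(gt, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1L]; chl <- ord$edge[i, 2L]
    t_e <- ord$edge.length[i] * spec$ka_ks
    mult <- if (chl %in% copy1_nodes) spec$rate_ratio else 1
    start <- states[par, ]
    if (shared_span > 0 && chl %in% stem_children) {
      if (is.null(shared_start)) {
        ev <- evolve_segment(states[dup, ], shared_span * g)
        shared_start <- ev$seq
        shared_events <- ev$n_events
      }
      start <- shared_start
      t_e <- t_e - shared_span
    }
    ev <- evolve_segment(start, t_e * mult * g)
    states[chl, ] <- ev$seq
    per_edge[[chl]] <- ev$n_events
  }

  aa <- amino_acids()
  aln <- matrix(aa[states[seq_len(nt), , drop = FALSE]], nrow = nt)
  rownames(aln) <- gt$tip.label

  if (spec$indel_rate > 0) {
    hit <- which(stats::runif(L) < spec$indel_rate)
    for (j in hit) {
      row <- sample.int(nt, 1L)
      len <- sample(2:6, 1L)
      aln[row, j:min(j + len - 1L, L)] <- "-"
    }
  }
  list(aln = aln, per_edge = per_edge, shared_events = shared_events,
       dup_node = dup)
}

# One branch segment: per-site Poisson event counts at the given expected
# substitutions/site, chained uniform exchanges among the other 19 residues.
evolve_segment <- function(seq, lambda) {
  k <- stats::rpois(length(seq), pmax(lambda, 0))
  one <- which(k == 1L)
  if (length(one)) {
    r <- sample.int(19L, length(one), replace = TRUE)
    seq[one] <- r + (r >= seq[one])
  }
  for (j in which(k > 1L)) {
    for (m in seq_len(k[[j]])) {
      r <- sample.int(19L, 1L)
      seq[[j]] <- r + (r >= seq[[j]])
    }
  }
  list(seq = seq, n_events = sum(k))
}

# Ground-truth summary: path-summed event counts per clade, measured from
# the speciation node directly preceding the planted duplication, matching
# what the reconstruction pipeline estimates.
family_truth <- function(fam, sim, rate_ratio) {
  tree <- fam$tree
  per_edge <- sim$per_edge
  dup <- sim$dup_node
  out <- list(per_edge = per_edge, shared_events = sim$shared_events,
              total_events = sum(per_edge) + sim$shared_events,
              dup_node = dup, spec_node = NA_integer_,
              n1 = NA_real_, n2 = NA_real_, n_out = NA_real_,
              faster_copy = if (rate_ratio > 1) 1L else NA_integer_,
              rate_ratio = rate_ratio)
  if (is.na(dup)) return(out)
  spec_node <- parent_of(tree, dup)
  if (is.na(spec_node)) return(out)
  out$spec_node <- spec_node
  ch <- children_of(tree, dup)
  path_sum <- function(clade_root, leaves) {
    if (!length(leaves)) return(NA_real_)
    sum(vapply(leaves, function(lf) {
      sum(per_edge[as.character(path_below(tree, spec_node, lf))])
    }, 0)) + sim$shared_events * length(leaves)
  }
  paralog_leaves <- function(clade_root) {
    tips <- descendant_tips(tree, clade_root)
    tips[fam$gene_type[tree$tip.label[tips]] == "paralog"]
  }
  sib <- setdiff(children_of(tree, spec_node), dup)
  out_leaves <- if (length(sib)) descendant_tips(tree, sib[[1L]]) else integer(0)
  out$n1 <- path_sum(ch[[1L]], paralog_leaves(ch[[1L]]))
  out$n2 <- path_sum(ch[[2L]], paralog_leaves(ch[[2L]]))
  out$n_out <- if (length(out_leaves)) {
    sum(vapply(out_leaves, function(lf) {
      sum(per_edge[as.character(path_below(tree, spec_node, lf))])
    }, 0))
  } else NA_real_
  out
}
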