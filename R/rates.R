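#' Posterior-weighted substitution rate of a clade
#'
#' Ka of a clade relative to the reconstruction reference node: the sum of
#' posterior probabilities of all hypothesised substitutions lying on the
#' paths from \code{anc_node} down to each eligible leaf, divided by the
#' summed usable alignment lengths of those ancestor-to-leaf comparisons.
#' Substitutions on the edge between the speciation ancestor and the
#' duplication node lie on every such path and are therefore counted for
#' both paralog clades (this is what lets concerted evolution show up as
#' parallel divergence).  Remaining paralogs are excluded by the caller
#' through \code{leaves}.
#'
#' @param events Event tibble from \code{\link{reconstruct_events}}.
#' @param family Masked \code{reconciled_family}.
#' @param anc_node Reference (speciation ancestor) node id.
#' @param leaves Tip ids of the eligible leaves of the clade.
#' @return List with \code{ka}, \code{n_events} (posterior path sum) and
#'   \code{total_length}.
#' @export
clade_ka <- function(events, family, anc_node, leaves) {
  if (!length(leaves)) stop("clade has no eligible leaves", call. = FALSE)
  tree <- family$tree
  num <- 0
  for (lf in leaves) {
    path <- path_below(tree, anc_node, lf)
    num <- num + sum(events$posterior[events$node %in% path])
  }
  len <- sum(usable_length(family, tree$tip.label[leaves]))
  if (len == 0) stop("total usable length is zero for the clade", call. = FALSE)
  list(ka = num / len, n_events = num, total_length = len)
}

#' Relative substitution rate
#'
#' Ka normalized by the Ks depth of the reference node (the upper-bound
#' age of the duplication), so that a neutrally evolving clade has
#' expectation near 1.
#'
#' @param ka Substitutions per site.
#' @param ks_depth Ks depth (> 0).
#' @return \code{ka / ks_depth}.
#' @export
rel_ka <- function(ka, ks_depth) {
  if (any(ks_depth <= 0)) stop("ks_depth must be > 0", call. = FALSE)
  ka / ks_depth
}

#' Radicality of a clade's substitutions
#'
#' Posterior-weighted mean absolute polarity difference and directional
#' exchangeability over the substitutions assigned to a clade.  The
#' exchangeability is looked up as EX\[ancestral, derived\], i.e. polarized
#' by the reconstructed ancestral state.  An empty event set yields
#' \code{NA} (flagged missing, not 0).
#'
#' @param events Event tibble restricted to the clade (see
#'   \code{\link{clade_events}}).
#' @param polarity Named polarity vector (default
#'   \code{\link{grantham_polarity}}).
#' @param ex 20x20 directional exchangeability matrix (default
#'   \code{\link{default_ex_matrix}}).
#' @return List with \code{d_polarity} and \code{ex}.
#' @export
clade_radicality <- function(events, polarity = grantham_polarity(),
                             ex = default_ex_matrix()) {
  if (nrow(events) == 0 || sum(events$posterior) == 0) {
    return(list(d_polarity = NA_real_, ex = NA_real_))
  }
  w <- events$posterior
  dp <- abs(polarity[events$from] - polarity[events$to])
  exv <- ex[cbind(events$from, events$to)]
  list(d_polarity = sum(w * dp) / sum(w), ex = sum(w * exv) / sum(w))
}

#' Events on the paths of a clade
#'
#' Restricts an event tibble to the union of edges on the paths from the
#' reference ancestor to the given leaves (each event once, regardless of
#' how many leaf paths share its edge).
#'
#' @inheritParams clade_ka
#' @return Filtered event tibble.
#' @export
clade_events <- function(events, family, anc_node, leaves) {
  tree <- family$tree
  edge_set <- unique(unlist(lapply(leaves, function(lf)
    path_below(tree, anc_node, lf))))
  events[events$node %in% edge_set, , drop = FALSE]
}

# Per-triplet rates for paralog1 / paralog2 / outgroup clades.
triplet_rates <- function(family, events, triplet, polarity = grantham_polarity(),
                          ex = default_ex_matrix()) {
  tree <- family$tree
  genes <- classify_genes(family)
  gtype <- stats::setNames(genes$type, genes$gene)
  one <- function(clade_node, role) {
    tips <- descendant_tips(tree, clade_node)
    if (role != "singleton") {
      tips <- tips[gtype[tree$tip.label[tips]] == "paralog"]
    }
    ck <- clade_ka(events, family, triplet$spec_node, tips)
    rad <- clade_radicality(
      clade_events(events, family, triplet$spec_node, tips), polarity, ex)
    tibble::tibble(family = family$id, dup_node = triplet$dup_node, role = role,
                   ka = ck$ka, rel_ka = rel_ka(ck$ka, triplet$ks_depth),
                   n_events = ck$n_events, total_length = ck$total_length,
                   d_polarity = rad$d_polarity, ex = rad$ex)
  }
  dplyr::bind_rows(
    one(triplet$clade1, "paralog1"),
    one(triplet$clade2, "paralog2"),
    one(triplet$outgroup, "singleton")
  )
}
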