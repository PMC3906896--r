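#' Reconstruct posterior-weighted substitution events for a family
#'
#' For every unmasked divergent site, enumerates the equally parsimonious
#' ancestral reconstructions and assigns each a posterior probability: the
#' weight of a reconstruction is the product, over its implied
#' substitutions, of the depth-binned matrix frequency for that
#' (ancestral, derived) pair at the substitution's node depth, normalized
#' over the alternatives.  A single most parsimonious reconstruction gets
#' posterior 1; sites whose enumeration exceeds the cap get uniform
#' posteriors over the enumerated alternatives.  Per site, posteriors over
#' alternatives sum to 1.
#'
#' @param family Masked, depth-annotated \code{reconciled_family}.
#' @param matrices A \code{depth_matrices} object.
#' @param max_alternatives Enumeration cap (default 64).
#' @return Tibble of substitution events with columns \code{family},
#'   \code{site}, \code{alt} (reconstruction index), \code{n_alt},
#'   \code{node} (child end of the edge carrying the event), \code{from},
#'   \code{to}, \code{posterior}.
#' @export
reconstruct_events <- function(family, matrices, max_alternatives = 64) {
  check_ready(family)
  stopifnot(inherits(matrices, "depth_matrices"))
  prep <- prep_parsimony(family$tree)
  codes <- aln_codes(family)
  aa <- amino_acids()
  out <- vector("list", sum(!family$mask))
  k <- 0L
  for (site in which(!family$mask)) {
    col <- codes[, site]
    if (length(unique(col[!is.na(col)])) < 2L) next
    res <- site_enumerate(prep, col, as.integer(max_alternatives))
    n_alt <- length(res$labelings)
    if (!n_alt) next
    evs <- lapply(res$labelings, function(lb) labeling_events(prep, lb, res$obs))
    if (n_alt == 1L) {
      post <- 1
    } else if (res$capped) {
      post <- rep(1 / n_alt, n_alt)
    } else {
      w <- vapply(evs, function(ev) {
        if (!length(ev$child)) return(1)
        prod(vapply(seq_along(ev$child), function(i) {
          m <- matrix_at_depth(matrices, family$node_depth[ev$child[[i]]])
          m[ev$from[[i]], ev$to[[i]]]
        }, 0))
      }, 0)
      post <- w / sum(w)
    }
    rows <- lapply(seq_len(n_alt), function(j) {
      ev <- evs[[j]]
      if (!length(ev$child)) return(NULL)
      tibble::tibble(site = site, alt = j, n_alt = n_alt, node = ev$child,
                     from = aa[ev$from], to = aa[ev$to],
                     posterior = post[[j]])
    })
    k <- k + 1L
    out[[k]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out[seq_len(k)])
  if (nrow(res) == 0) {
    res <- tibble::tibble(site = integer(), alt = integer(), n_alt = integer(),
                          node = integer(), from = character(),
                          to = character(), posterior = double())
  }
  dplyr::mutate(res, family = family$id, .before = 1L)
}

#' Posterior assignment for a pre-enumerated reconstruction set
#'
#' Lower-level interface matching \code{\link{enumerate_parsimonious}}
#' output: given the alternative reconstructions of one site, returns
#' their posterior probabilities under the depth-binned matrices.
#'
#' @param ps A \code{parsimony_set}.
#' @param matrices A \code{depth_matrices}.
#' @param node_depths Numeric vector of Ks depths indexed by node id.
#' @return Numeric vector of posteriors (sums to 1), one per alternative;
#'   \code{numeric(0)} for invariant sites.
#' @export
assign_posteriors <- function(ps, matrices, node_depths) {
  stopifnot(inherits(ps, "parsimony_set"))
  n_alt <- length(ps$alternatives)
  if (!n_alt) return(numeric(0))
  if (n_alt == 1L) return(1)
  if (ps$capped) return(rep(1 / n_alt, n_alt))
  w <- vapply(ps$alternatives, function(tb) {
    if (!nrow(tb)) return(1)
    prod(vapply(seq_len(nrow(tb)), function(i) {
      m <- matrix_at_depth(matrices, node_depths[[tb$node[[i]]]])
      m[tb$from[[i]], tb$to[[i]]]
    }, 0))
  }, 0)
  w / sum(w)
}
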