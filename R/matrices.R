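#' Depth-binned empirical substitution matrices
#'
#' Builds, from the non-ambiguous substitutions of a masked family corpus,
#' per-depth-bin 20x20 relative-frequency matrices of (ancestral, derived)
#' residue pairs.  Only sites with a single most parsimonious
#' reconstruction contribute; each contributing substitution is binned by
#' the Ks depth of the child node of the edge it lies on (tips at depth
#' 0).  Bins partition \[0, max depth\] uniformly.  A pseudo-count is added
#' to every off-diagonal cell before normalization so that posterior
#' weighting never divides by zero; bins with no observed events fall back
#' to the pooled (all-depth) matrix.
#'
#' @param families List of masked, depth-annotated
#'   \code{reconciled_family} objects.
#' @param n_bins Number of depth bins (default 10).
#' @param pseudo_count Pseudo-count added per cell (default 0.5).
#' @param max_alternatives Parsimony enumeration cap.
#' @return Object of class \code{depth_matrices}: \code{breaks} (length
#'   \code{n_bins + 1}), \code{matrices} (list of 20x20 matrices, each
#'   summing to 1 over off-diagonal cells), \code{pooled}, and the raw
#'   event count per bin.
#' @export
build_matrices <- function(families, n_bins = 10, pseudo_count = 0.5,
                           max_alternatives = 64) {
  stopifnot(length(families) > 0)
  aa <- amino_acids()
  counts <- array(0, dim = c(20L, 20L, n_bins))
  max_depth <- max(vapply(families, function(f) max(f$node_depth), 0))
  if (max_depth <= 0) stop("families carry no positive node depths", call. = FALSE)
  breaks <- seq(0, max_depth, length.out = n_bins + 1L)

  for (fam in families) {
    check_ready(fam)
    prep <- prep_parsimony(fam$tree)
    codes <- aln_codes(fam)
    for (site in which(!fam$mask)) {
      col <- codes[, site]
      if (length(unique(col[!is.na(col)])) < 2L) next
      res <- site_enumerate(prep, col, as.integer(max_alternatives))
      if (length(res$labelings) != 1L || res$capped) next
      ev <- labeling_events(prep, res$labelings[[1L]], res$obs)
      if (!length(ev$child)) next
      d <- fam$node_depth[ev$child]
      b <- pmin(pmax(findInterval(d, breaks, rightmost.closed = TRUE), 1L), n_bins)
      for (k in seq_along(ev$child)) {
        counts[ev$from[[k]], ev$to[[k]], b[[k]]] <-
          counts[ev$from[[k]], ev$to[[k]], b[[k]]] + 1
      }
    }
  }
  n_events <- apply(counts, 3L, sum)
  if (sum(n_events) == 0) {
    stop("no unambiguous substitutions found in the corpus", call. = FALSE)
  }
  normalize <- function(m) {
    m <- m + pseudo_count
    diag(m) <- 0
    m / sum(m)
  }
  pooled_raw <- apply(counts, c(1L, 2L), sum)
  pooled <- normalize(pooled_raw)
  dimnames(pooled) <- list(aa, aa)
  mats <- lapply(seq_len(n_bins), function(b) {
    if (n_events[[b]] == 0) return(pooled)
    m <- normalize(counts[, , b])
    dimnames(m) <- list(aa, aa)
    m
  })
  structure(list(breaks = breaks, matrices = mats, pooled = pooled,
                 n_events = n_events),
            class = "depth_matrices")
}

#' @export
print.depth_matrices <- function(x, ...) {
  cat(sprintf("<depth_matrices> %d bins over [0, %.4g] Ks; events per bin: %s\n",
              length(x$matrices), max(x$breaks),
              paste(x$n_events, collapse = ", ")))
  invisible(x)
}

# Matrix for a given depth.
matrix_at_depth <- function(matrices, depth) {
  n_bins <- length(matrices$matrices)
  b <- pmin(pmax(findInterval(depth, matrices$breaks, rightmost.closed = TRUE), 1L),
            n_bins)
  matrices$matrices[[b]]
}

# Integer residue codes of the alignment (NA for gaps/X), genes x columns,
# rows in tip order.
aln_codes <- function(family) {
  m <- match(family$aln, amino_acids())
  dim(m) <- dim(family$aln)
  rownames(m) <- rownames(family$aln)
  m[family$tree$tip.label, , drop = FALSE]
}

check_ready <- function(family) {
  if (is.null(family$mask)) stop("family ", family$id, " is not masked", call. = FALSE)
  if (is.null(family$node_depth)) stop("family ", family$id,
                                       " has no node depths; call annotate_depths()",
                                       call. = FALSE)
  invisible(family)
}
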