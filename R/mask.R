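#' Mask low-quality alignment regions around indels
#'
#' Excludes alignment columns belonging to any gap run longer than
#' \code{max_indel} residues in any sequence, together with \code{flank}
#' columns on each side of the run (clipped at the alignment bounds).
#' Gap runs of length \code{<= max_indel} are left untouched.  Masking is
#' column-wise: a qualifying indel in one sequence removes the column for
#' the whole family.  Terminal gap runs are treated like internal ones
#' (one-sided flank).
#'
#' @param aln Character matrix of aligned residues (or a named character
#'   vector of equal-length strings); gap character \code{"-"}.
#' @param max_indel Longest gap run that is tolerated (default 1).
#' @param flank Columns excluded on each side of a qualifying run
#'   (default 5).
#' @return An object of class \code{masked_alignment}: list with the
#'   alignment matrix \code{aln} and a logical \code{mask} per column
#'   (\code{TRUE} = excluded).
#' @examples
#' a <- c(g1 = "AAAAAAAAAA---AAAAAAA", g2 = "AAAAAAAAAAAAAAAAAAAA")
#' sum(mask_indels(a)$mask)  # 3 + 2*5 = 13
#' @export
mask_indels <- function(aln, max_indel = 1, flank = 5) {
  if (is.character(aln) && is.null(dim(aln))) aln <- strings_to_matrix(aln)
  stopifnot(is.matrix(aln))
  nc <- ncol(aln)
  mask <- rep(FALSE, nc)
  for (i in seq_len(nrow(aln))) {
    r <- rle(aln[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long <- which(r$values & r$lengths > max_indel)
    for (j in long) {
      lo <- max(1L, starts[[j]] - flank)
      hi <- min(nc, ends[[j]] + flank)
      mask[lo:hi] <- TRUE
    }
  }
  structure(list(aln = aln, mask = mask), class = "masked_alignment")
}

#' @export
print.masked_alignment <- function(x, ...) {
  cat(sprintf("<masked_alignment> %d x %d, %d columns masked\n",
              nrow(x$aln), ncol(x$aln), sum(x$mask)))
  invisible(x)
}

#' Apply indel masking to a reconciled family
#'
#' @param family A \code{reconciled_family}.
#' @inheritParams mask_indels
#' @return The family with its \code{mask} slot set.
#' @export
mask_family <- function(family, max_indel = 1, flank = 5) {
  stopifnot(inherits(family, "reconciled_family"))
  family$mask <- mask_indels(family$aln, max_indel, flank)$mask
  family
}

#' Usable ancestor-to-leaf alignment length per sequence
#'
#' Number of columns that are unmasked and carry a residue (not a gap) in
#' the given sequence: the per-leaf denominator for clade Ka.
#'
#' @param family A masked \code{reconciled_family}.
#' @param genes Gene ids (default all).
#' @return Named integer vector.
#' @export
usable_length <- function(family, genes = rownames(family$aln)) {
  if (is.null(family$mask)) stop("family is not masked; call mask_family() first",
                                 call. = FALSE)
  vapply(genes, function(g) {
    sum(!family$mask & family$aln[g, ] != "-")
  }, integer(1))
}
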