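#' The 20-letter amino-acid alphabet used throughout the package
#'
#' One-letter codes in the conventional order Ala..Val.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Amino-acid polarity values (Grantham scale)
#'
#' Per-residue polarity on the scale of Grantham (1974), used for the
#' \code{|dPolarity|} radicality measure: the posterior-weighted mean
#' absolute polarity difference between ancestral and derived residues.
#' Any named numeric vector over the 20 amino acids may be substituted.
#'
#' @return Named numeric vector of length 20 (polarity units).
#' @export
grantham_polarity <- function() {
  c(A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5, E = 12.3,
    G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3, M = 5.7, F = 5.2,
    P = 8.0, S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9)
}

#' Read a directional 20x20 exchangeability matrix from TSV
#'
#' The matrix gives, for each ordered (ancestral, derived) residue pair, the
#' expected tolerance of the exchange (higher = more conservative).  It is
#' directional: \code{EX[i, j]} need not equal \code{EX[j, i]}, which is why
#' it pairs naturally with phylogenetically polarized substitutions.
#'
#' @param path Path to a TSV with a header row and a first column of
#'   one-letter row names; rows are ancestral, columns derived residues.
#' @return 20x20 numeric matrix with \code{NA} on the diagonal, values in
#'   \[0, 1\].
#' @export
read_ex_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  aa <- amino_acids()
  if (!setequal(rownames(m), aa) || !setequal(colnames(m), aa)) {
    stop("exchangeability matrix must have the 20 amino acids as rows and columns",
         call. = FALSE)
  }
  m <- m[aa, aa]
  diag(m) <- NA_real_
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("exchangeability values must lie in [0, 1]", call. = FALSE)
  }
  m
}

#' Default (synthetic) exchangeability matrix
#'
#' Loads the synthetic directional exchangeability matrix shipped with the
#' package (\code{inst/extdata/ex_matrix_synthetic.tsv}).  The shipped
#' values are a synthetic stand-in constructed from polarity-distance
#' structure with mild directional perturbation; they have the right
#' statistical shape (bounded, directional, distance-correlated) but are
#' not measured exchangeabilities.  Replace with a measured matrix via
#' \code{\link{read_ex_matrix}} for substantive radicality analyses.
#'
#' @return 20x20 numeric matrix, diagonal \code{NA}.
#' @export
default_ex_matrix <- function() {
  path <- system.file("extdata", "ex_matrix_synthetic.tsv", package = "dupasym")
  read_ex_matrix(path)
}

# Deterministic constructor for the shipped synthetic matrix (kept in the
# package so the fixture can be regenerated; not exported).
build_synthetic_ex_matrix <- function() {
  aa <- amino_acids()
  pol <- grantham_polarity()[aa]
  d <- abs(outer(pol, pol, "-"))
  base <- 0.08 + 0.84 * exp(-d / 4)
  # fixed directional skew: exchanges toward more polar residues slightly
  # more tolerated, so EX[i,j] != EX[j,i]
  skew <- outer(pol, pol, function(from, to) 1 + 0.10 * sign(to - from))
  m <- pmin(pmax(base * skew, 0), 1)
  dimnames(m) <- list(aa, aa)
  diag(m) <- NA_real_
  round(m, 4)
}
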