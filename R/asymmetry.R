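#' Z-squared substitution-rate asymmetry statistic
#'
#' The squared normal deviate of the two-proportion comparison of
#' substituted-site frequencies between two clades:
#' \deqn{Z^2 = \frac{(p_1 - p_2)^2}{p(1-p)(1/L_1 + 1/L_2)}}
#' with \eqn{p_i = N_i / L_i} and \eqn{p = (N_1 + N_2)/(L_1 + L_2)}.
#' Under equal rates and uniform sites its expectation is 1 (a 1-df
#' chi-square), independent of divergence and of unequal lengths, which is
#' what makes it comparable across pairs.  Degenerate cases
#' (\eqn{N_1 + N_2 = 0} or \eqn{p = 1}) return 0 by convention.
#' Posterior-weighted (non-integer) counts are accepted as-is.
#'
#' @param n1,n2 Substituted-site counts (or posterior-weighted sums) in
#'   the two clades.
#' @param l1,l2 Usable sequence lengths (> 0).
#' @return Numeric vector of Z-squared values (>= 0).
#' @examples
#' z_squared(15, 500, 5, 500)  # 5.102...
#' @export
z_squared <- function(n1, l1, n2, l2) {
  if (any(l1 <= 0 | l2 <= 0)) stop("lengths must be positive", call. = FALSE)
  if (any(n1 > l1 | n2 > l2 | n1 < 0 | n2 < 0)) {
    stop("counts must lie in [0, length]", call. = FALSE)
  }
  p1 <- n1 / l1
  p2 <- n2 / l2
  p <- (n1 + n2) / (l1 + l2)
  denom <- p * (1 - p) * (1 / l1 + 1 / l2)
  out <- ifelse(denom <= 0, 0, (p1 - p2)^2 / denom)
  unname(out)
}

#' Count-based asymmetry statistic A
#'
#' \eqn{A = (N_1 - N_2)^2 / (N_1 + N_2)}.  Related to Z-squared by
#' \eqn{Z^2 = A/(1-p)} when \eqn{L_1 = L_2}.  Undefined (NA) when both
#' counts are zero.
#'
#' @param n1,n2 Substitution counts.
#' @return Numeric vector.
#' @export
a_statistic <- function(n1, n2) {
  tot <- n1 + n2
  ifelse(tot > 0, (n1 - n2)^2 / tot, NA_real_)
}

#' Significance of rate asymmetry (Yates-corrected chi-square)
#'
#' Upper-tail probability of a 1-df chi-square at the Yates-corrected
#' statistic of the 2x2 table of sites with/without substitutions in the
#' two lineages.  The continuity correction is defined on counts, so
#' posterior-weighted counts are rounded half-to-even before forming the
#' table.  Degenerate tables (a zero margin) return p = 1.
#'
#' @inheritParams z_squared
#' @return Vector of p-values in \[0, 1\].
#' @export
asymmetry_pvalue <- function(n1, l1, n2, l2) {
  if (any(l1 <= 0 | l2 <= 0)) stop("lengths must be positive", call. = FALSE)
  n1 <- round(n1); n2 <- round(n2); l1 <- round(l1); l2 <- round(l2)
  if (any(n1 > l1 | n2 > l2)) stop("counts exceed lengths", call. = FALSE)
  mapply(function(a, la, b, lb) {
    tab <- matrix(c(a, la - a, b, lb - b), nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum(pmax(abs(tab - e) - 0.5, 0)^2 / e)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }, n1, l1, n2, l2)
}

#' Build asymmetry records for selected duplications
#'
#' Combines per-clade posterior-weighted counts into one record per
#' duplication: counts and lengths for the two paralog clades, Z-squared,
#' A, and the Yates-corrected p-value.
#'
#' @param rates Per-clade rate tibble from the pipeline (roles
#'   \code{paralog1}, \code{paralog2} present per duplication).
#' @return Tibble, one row per duplication.
#' @export
asymmetry_records <- function(rates) {
  wide <- tidyr::pivot_wider(
    dplyr::select(rates, "family", "dup_node", "role", "n_events", "total_length"),
    names_from = "role", values_from = c("n_events", "total_length"))
  dplyr::transmute(wide,
    family = .data$family, dup_node = .data$dup_node,
    n1 = .data$n_events_paralog1, l1 = .data$total_length_paralog1,
    n2 = .data$n_events_paralog2, l2 = .data$total_length_paralog2,
    p1 = .data$n1 / .data$l1, p2 = .data$n2 / .data$l2,
    p = (.data$n1 + .data$n2) / (.data$l1 + .data$l2),
    z2 = z_squared(.data$n1, .data$l1, .data$n2, .data$l2),
    a = a_statistic(.data$n1, .data$n2),
    p_value = asymmetry_pvalue(.data$n1, .data$l1, .data$n2, .data$l2))
}

#' Multiple-testing adjustment across duplications
#'
#' Annotates asymmetry records with Bonferroni significance at
#' \code{alpha} and Benjamini-Yekutieli false-discovery-rate adjusted
#' q-values (valid under arbitrary dependence) thresholded at \code{q}.
#'
#' @param records Tibble with a \code{p_value} column.
#' @param alpha Family-wise error level for Bonferroni (default 0.05).
#' @param q FDR level for Benjamini-Yekutieli (default 0.1).
#' @return Records with \code{bonferroni_sig}, \code{fdr_q},
#'   \code{fdr_sig} added.
#' @export
adjust_asymmetry <- function(records, alpha = 0.05, q = 0.1) {
  if (nrow(records) == 0) {
    return(dplyr::mutate(records, bonferroni_sig = logical(0),
                         fdr_q = double(0), fdr_sig = logical(0)))
  }
  dplyr::mutate(records,
    bonferroni_sig = stats::p.adjust(.data$p_value, "bonferroni") < alpha,
    fdr_q = stats::p.adjust(.data$p_value, "BY"),
    fdr_sig = .data$fdr_q < q)
}

#' Log-transform Z-squared values, dropping exact zeros
#'
#' Pairs with exactly equal substitution counts (Z-squared = 0) cannot be
#' log-transformed and are removed before regression analyses; the number
#' removed is reported as a warning.
#'
#' @param z2 Numeric vector of Z-squared values.
#' @return Base-10 logarithms of the nonzero values.
#' @export
log_z2 <- function(z2) {
  zero <- z2 == 0
  if (any(zero)) {
    warning(sum(zero), " value(s) with Z^2 = 0 removed before log-transform",
            call. = FALSE)
  }
  log10(z2[!zero])
}
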