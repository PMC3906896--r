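#' Summaries of a tissue expression profile
#'
#' For a per-tissue expression vector: \code{log_mean} = log10 of the mean
#' across tissues (expression rate), \code{cv} = SD/mean across tissues
#' (non-uniformity of expression), and \code{evenness} = Shannon-entropy
#' evenness of the tissue shares, H(shares)/ln(n), in \[0, 1\] and equal
#' to 1 for a perfectly uniform profile (an alternative ubiquity measure
#' that mirrors CV with the opposite sign).
#'
#' @param values Non-negative expression values over >= 2 tissues, not
#'   all zero.
#' @return Tibble with \code{log_mean}, \code{cv}, \code{evenness}.
#' @export
expression_summary <- function(values) {
  stopifnot(length(values) >= 2)
  if (any(values < 0)) stop("negative expression values", call. = FALSE)
  if (all(values == 0)) {
    return(tibble::tibble(log_mean = NA_real_, cv = NA_real_,
                          evenness = NA_real_))
  }
  m <- mean(values)
  shares <- values / sum(values)
  nz <- shares[shares > 0]
  tibble::tibble(
    log_mean = log10(m),
    cv = stats::sd(values) / m,
    evenness = -sum(nz * log(nz)) / log(length(values)))
}

#' Polarize a signed paralog difference by divergence
#'
#' Returns (value in the faster-evolving paralog) minus (value in the
#' slower one): \code{v1 - v2} if \code{ka1 > ka2}, \code{v2 - v1} if
#' \code{ka2 > ka1}.  Pairs with exactly equal Ka have no polarization and
#' return \code{NA} (they are excluded, consistently with the removal of
#' Z-squared = 0 pairs).
#'
#' @param value1,value2 Per-paralog values (expression summary, Ka/Ks...).
#' @param ka1,ka2 Per-paralog divergence Ka.
#' @return Signed difference (vectorized).
#' @export
polarize <- function(value1, value2, ka1, ka2) {
  dplyr::case_when(
    ka1 > ka2 ~ value1 - value2,
    ka2 > ka1 ~ value2 - value1,
    .default = NA_real_)
}

#' Correlation of two tissue expression profiles
#'
#' Product-moment correlation across tissues; profiles must cover the
#' same tissue set.  Zero variance in either profile yields \code{NA}.
#'
#' @param profile1,profile2 Numeric vectors over the same >= 3 tissues.
#' @return Correlation coefficient or \code{NA}.
#' @export
tissue_correlation <- function(profile1, profile2) {
  stopifnot(length(profile1) == length(profile2), length(profile1) >= 3)
  if (stats::sd(profile1) == 0 || stats::sd(profile2) == 0) return(NA_real_)
  stats::cor(profile1, profile2)
}

#' Polymorphism Ka/Ks from SNP counts
#'
#' Per-gene ratio of non-synonymous to synonymous SNP density:
#' \code{(n_nonsyn/sites_nonsyn) / (n_syn/sites_syn)}.  A gene is eligible
#' for polymorphism analysis only with at least 3 synonymous and at least
#' 3 non-synonymous SNPs; below that the ratio estimate is dominated by
#' sampling noise and the record is flagged ineligible.
#'
#' @param n_nonsyn,n_syn SNP counts (>= 0).
#' @param sites_nonsyn,sites_syn Site counts (> 0).
#' @param min_snps Eligibility threshold (default 3, applied to both
#'   categories).
#' @return Tibble with \code{kaks} and \code{eligible} (vectorized).
#' @export
snp_kaks <- function(n_nonsyn, n_syn, sites_nonsyn, sites_syn, min_snps = 3) {
  stopifnot(all(sites_nonsyn > 0), all(sites_syn > 0))
  eligible <- n_nonsyn >= min_snps & n_syn >= min_snps
  kaks <- ifelse(n_syn > 0,
                 (n_nonsyn / sites_nonsyn) / (n_syn / sites_syn), NA_real_)
  tibble::tibble(kaks = kaks, eligible = eligible)
}

#' Relative chromosomal location of a paralog pair
#'
#' Four-level classification: \code{different_arms}; same arm with the
#' gap between the gene spans over the tandem threshold
#' (\code{same_arm_distant}); within the threshold with equal strands
#' (\code{tandem_collinear}) or opposite strands (\code{tandem_inverted}).
#' Overlapping spans count as distance 0 (tandem, split by orientation).
#'
#' @param loc1,loc2 Lists or one-row data frames with \code{arm},
#'   \code{start}, \code{end}, \code{strand}.
#' @param tandem_threshold Gap threshold in bp (default 5000).
#' @return Factor level as character.
#' @export
classify_location <- function(loc1, loc2, tandem_threshold = 5000) {
  if (loc1$arm != loc2$arm) return("different_arms")
  gap <- max(0, max(loc1$start, loc2$start) - min(loc1$end, loc2$end))
  if (gap > tandem_threshold) return("same_arm_distant")
  if (loc1$strand == loc2$strand) "tandem_collinear" else "tandem_inverted"
}

location_levels <- function() {
  c("different_arms", "same_arm_distant", "tandem_collinear", "tandem_inverted")
}
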