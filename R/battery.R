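#' Join asymmetry records with expression, SNP and location data
#'
#' Builds one record per duplication whose two paralogs are both present
#' in the focal species: per-paralog expression summaries, tissue
#' correlation, polarized signed differences (faster minus slower copy,
#' polarized by the reconstruction-estimated clade Ka), per-paralog SNP
#' Ka/Ks with the >= 3 / >= 3 eligibility filter, and the relative
#' chromosomal location category.  Pairs whose two paralogs map to the
#' same expression record are dropped (the duplicate-identifier collapse
#' rule), as are pairs with exactly equal Ka (no polarization).
#'
#' @param analysis Result of \code{\link{analyze_cohort}}.
#' @param expression Expression table
#'   (\code{\link{generate_expression_table}} format).
#' @param snp Optional SNP table (\code{\link{generate_snp_table}}
#'   format).
#' @param locations Optional location table
#'   (\code{\link{generate_location_table}} format).
#' @param focal_species Species that must carry both paralogs.
#' @param tandem_threshold Gap threshold for the tandem categories (bp).
#' @param min_snps SNP eligibility threshold per category (default 3).
#' @return Tibble of pair records (kept pairs only; polarized columns
#'   \code{d_me}, \code{d_cve}, \code{d_evenness}, \code{d_kaks}).
#' @export
build_pair_records <- function(analysis, expression, snp = NULL,
                               locations = NULL, focal_species = "s01",
                               tandem_threshold = 5000, min_snps = 3) {
  stopifnot(inherits(analysis, "asym_analysis"))
  fams <- analysis$families
  tissue_cols <- grep("^tissue_", names(expression), value = TRUE)
  expr_sum <- dplyr::bind_cols(
    expression["gene_id"],
    dplyr::bind_rows(lapply(seq_len(nrow(expression)), function(i) {
      expression_summary(as.numeric(expression[i, tissue_cols]))
    })))

  ka_wide <- tidyr::pivot_wider(
    dplyr::select(analysis$rates, "family", "dup_node", "role", "ka"),
    names_from = "role", values_from = "ka")

  rows <- lapply(seq_len(nrow(analysis$triplets)), function(i) {
    tr <- analysis$triplets[i, ]
    fam <- fams[[tr$family]]$family
    tree <- fam$tree
    focal_paralog <- function(clade) {
      tips <- descendant_tips(tree, clade)
      labs <- tree$tip.label[tips]
      labs[fam$leaf_species[labs] == focal_species &
             fam$gene_type[labs] == "paralog"]
    }
    g1 <- focal_paralog(tr$clade1); g2 <- focal_paralog(tr$clade2)
    if (length(g1) != 1L || length(g2) != 1L) return(NULL)
    if (g1 == g2) return(NULL)
    if (!(g1 %in% expr_sum$gene_id) || !(g2 %in% expr_sum$gene_id)) return(NULL)
    tibble::tibble(family = tr$family, dup_node = tr$dup_node,
                   gene1 = g1, gene2 = g2)
  })
  pairs <- dplyr::bind_rows(rows)
  if (nrow(pairs) == 0) return(pairs)

  pairs <- dplyr::left_join(pairs, ka_wide, by = c("family", "dup_node"))
  pairs <- dplyr::rename(pairs, ka1 = "paralog1", ka2 = "paralog2")
  pairs <- dplyr::left_join(
    pairs,
    dplyr::select(analysis$asymmetry, "family", "dup_node", "z2", "p_value",
                  "bonferroni_sig", "fdr_q", "fdr_sig"),
    by = c("family", "dup_node"))

  add_gene <- function(pairs, which) {
    gcol <- paste0("gene", which)
    sfx <- paste0(which)
    tb <- stats::setNames(expr_sum,
                          c("gene_id", paste0(c("log_mean", "cv", "evenness"), sfx)))
    dplyr::left_join(pairs, tb, by = stats::setNames("gene_id", gcol))
  }
  pairs <- add_gene(add_gene(pairs, 1), 2)

  em <- as.matrix(expression[, tissue_cols])
  rownames(em) <- expression$gene_id
  pairs$r_tissue <- vapply(seq_len(nrow(pairs)), function(i) {
    tissue_correlation(em[pairs$gene1[[i]], ], em[pairs$gene2[[i]], ])
  }, 0)

  pairs <- dplyr::mutate(pairs,
    d_me = polarize(.data$log_mean1, .data$log_mean2, .data$ka1, .data$ka2),
    d_cve = polarize(.data$cv1, .data$cv2, .data$ka1, .data$ka2),
    d_evenness = polarize(.data$evenness1, .data$evenness2, .data$ka1, .data$ka2),
    pair_log_mean = (.data$log_mean1 + .data$log_mean2) / 2,
    pair_cv = (.data$cv1 + .data$cv2) / 2)

  if (!is.null(snp)) {
    sk <- dplyr::bind_cols(snp["gene_id"],
                           snp_kaks(snp$n_nonsyn, snp$n_syn,
                                    snp$sites_nonsyn, snp$sites_syn, min_snps))
    j1 <- stats::setNames(sk, c("gene_id", "kaks1", "eligible1"))
    j2 <- stats::setNames(sk, c("gene_id", "kaks2", "eligible2"))
    pairs <- dplyr::left_join(pairs, j1, by = c(gene1 = "gene_id"))
    pairs <- dplyr::left_join(pairs, j2, by = c(gene2 = "gene_id"))
    pairs <- dplyr::mutate(pairs,
      snp_eligible = !is.na(.data$eligible1) & !is.na(.data$eligible2) &
        .data$eligible1 & .data$eligible2,
      d_kaks = ifelse(.data$snp_eligible,
                      polarize(.data$kaks1, .data$kaks2, .data$ka1, .data$ka2),
                      NA_real_))
  } else {
    pairs$snp_eligible <- NA
    pairs$d_kaks <- NA_real_
  }

  if (!is.null(locations)) {
    loc <- as.data.frame(locations)
    rownames(loc) <- loc$gene_id
    pairs$location <- vapply(seq_len(nrow(pairs)), function(i) {
      if (!(pairs$gene1[[i]] %in% rownames(loc)) ||
          !(pairs$gene2[[i]] %in% rownames(loc))) return(NA_character_)
      classify_location(loc[pairs$gene1[[i]], ], loc[pairs$gene2[[i]], ],
                        tandem_threshold)
    }, "")
    pairs$location <- factor(pairs$location, levels = location_levels())
  } else {
    pairs$location <- factor(NA_character_, levels = location_levels())
  }
  pairs
}

#' Statistical battery over paralog pair records
#'
#' Runs the standard test set over polarized pair differences: one-sample
#' two-tailed t-tests and sign tests of \code{d_me}, \code{d_cve} and
#' \code{d_kaks} (all pairs, pairs with Z-squared > 1, FDR-significant
#' pairs), Fisher's exact test of the 2x2 faster/slower-by-higher/lower
#' expression table, linear regressions of the polarized differences and
#' of the tissue correlation on log10 Z-squared (Z-squared > 1 pairs),
#' regressions of log10 Z-squared on pair-mean expression summaries, a
#' sequential ANOVA of log10 Z-squared on mean expression, expression CV
#' and location, and binned means by half-log10-unit of Z-squared.  Tests
#' with fewer than \code{min_n} usable records are skipped with a reason.
#'
#' @param pairs Tibble from \code{\link{build_pair_records}}.
#' @param alpha Significance level annotation (default 0.05).
#' @param min_n Minimum records per test (default 3).
#' @return Object of class \code{asym_battery}.
#' @export
analysis_battery <- function(pairs, alpha = 0.05, min_n = 3) {
  subsets <- list(
    all = rep(TRUE, nrow(pairs)),
    z2_gt_1 = !is.na(pairs$z2) & pairs$z2 > 1,
    fdr_sig = !is.na(pairs$fdr_sig) & pairs$fdr_sig)
  measures <- c(d_me = "d_me", d_cve = "d_cve", d_kaks = "d_kaks")

  tests <- list(); skipped <- list()
  skip <- function(test, why) {
    skipped[[length(skipped) + 1L]] <<- tibble::tibble(test = test, reason = why)
  }
  for (mn in names(measures)) {
    for (sn in names(subsets)) {
      x <- pairs[[measures[[mn]]]][subsets[[sn]]]
      x <- x[!is.na(x)]
      lab <- sprintf("%s[%s]", mn, sn)
      if (length(x) < min_n) { skip(lab, sprintf("n = %d < %d", length(x), min_n)); next }
      tt <- stats::t.test(x)
      nz <- x[x != 0]
      sp <- if (length(nz)) stats::binom.test(sum(nz > 0), length(nz))$p.value
            else NA_real_
      tests[[length(tests) + 1L]] <- tibble::tibble(
        measure = mn, subset = sn, n = length(x), mean = mean(x),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_t = tt$p.value, p_sign = sp,
        significant = tt$p.value < alpha)
    }
  }
  tests <- dplyr::bind_rows(tests)

  fisher <- list()
  for (sn in c("all", "z2_gt_1")) {
    x <- pairs$d_me[subsets[[sn]]]
    x <- x[!is.na(x) & x != 0]
    if (length(x) < min_n) { skip(sprintf("fisher[%s]", sn), "too few nonzero d_me"); next }
    a <- sum(x > 0); n <- length(x)
    ft <- stats::fisher.test(matrix(c(a, n - a, n - a, a), nrow = 2))
    fisher[[length(fisher) + 1L]] <- tibble::tibble(
      subset = sn, n = n, faster_higher = a, p = ft$p.value)
  }
  fisher <- dplyr::bind_rows(fisher)

  reg_rows <- list()
  run_reg <- function(label, df, formula) {
    if (nrow(df) < min_n) { skip(label, sprintf("n = %d < %d", nrow(df), min_n)); return() }
    fit <- stats::lm(formula, data = df)
    sm <- summary(fit)
    reg_rows[[length(reg_rows) + 1L]] <<- tibble::tibble(
      regression = label, n = nrow(df),
      slope = unname(stats::coef(fit)[2]),
      p = sm$coefficients[2, 4], r_squared = sm$r.squared)
  }
  asym <- dplyr::filter(pairs, !is.na(.data$z2) & .data$z2 > 1)
  run_reg("d_me ~ log10(z2)", dplyr::filter(asym, !is.na(.data$d_me)),
          d_me ~ log10(z2))
  run_reg("d_cve ~ log10(z2)", dplyr::filter(asym, !is.na(.data$d_cve)),
          d_cve ~ log10(z2))
  run_reg("d_kaks ~ log10(z2)", dplyr::filter(asym, !is.na(.data$d_kaks)),
          d_kaks ~ log10(z2))
  run_reg("r_tissue ~ log10(z2)", dplyr::filter(asym, !is.na(.data$r_tissue)),
          r_tissue ~ log10(z2))
  pos <- dplyr::filter(pairs, !is.na(.data$z2) & .data$z2 > 0)
  run_reg("log10(z2) ~ pair_log_mean",
          dplyr::filter(pos, !is.na(.data$pair_log_mean)),
          log10(z2) ~ pair_log_mean)
  run_reg("log10(z2) ~ pair_cv", dplyr::filter(pos, !is.na(.data$pair_cv)),
          log10(z2) ~ pair_cv)
  regressions <- dplyr::bind_rows(reg_rows)

  anova_tab <- NULL
  av <- dplyr::filter(pos, !is.na(.data$location) & !is.na(.data$pair_log_mean) &
                        !is.na(.data$pair_cv))
  av$location <- droplevels(av$location)
  n_par <- 2L + max(0L, nlevels(av$location) - 1L)   # slopes + location dummies
  if (nlevels(av$location) >= 2 && nrow(av) - n_par - 1L >= 2L) {
    fit <- stats::lm(log10(z2) ~ pair_log_mean + pair_cv + location, data = av)
    at <- stats::anova(fit)
    anova_tab <- tibble::tibble(
      source = rownames(at), df = at$Df, mean_sq = at$`Mean Sq`,
      f = at$`F value`, p = at$`Pr(>F)`)
  } else {
    skip("anova", "insufficient records or location levels")
  }

  binned <- NULL
  bz <- dplyr::filter(pairs, !is.na(.data$z2) & .data$z2 > 0)
  if (nrow(bz) >= min_n) {
    bz$bin <- floor(log10(bz$z2) / 0.5) * 0.5
    binned <- dplyr::summarise(
      dplyr::group_by(bz, .data$bin),
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(c("d_me", "d_cve", "d_kaks", "r_tissue")),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         se = ~stats::sd(.x, na.rm = TRUE) /
                           sqrt(max(1, sum(!is.na(.x)))))),
      .groups = "drop")
  }

  structure(list(tests = tests, fisher = fisher, regressions = regressions,
                 anova = anova_tab, binned = binned,
                 skipped = dplyr::bind_rows(skipped),
                 n_pairs = nrow(pairs), alpha = alpha),
            class = "asym_battery")
}

#' @export
print.asym_battery <- function(x, ...) {
  cat(sprintf("<asym_battery> %d pair records\n", x$n_pairs))
  if (nrow(x$tests)) {
    cat("Polarized-difference tests:\n")
    print(as.data.frame(x$tests), digits = 3)
  }
  if (!is.null(x$anova)) {
    cat("ANOVA of log10 Z^2:\n")
    print(as.data.frame(x$anova), digits = 3)
  }
  if (nrow(x$skipped)) {
    cat(sprintf("%d test(s) skipped.\n", nrow(x$skipped)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the test table of an analysis battery
#'
#' @param x An \code{asym_battery}.
#' @param ... Unused.
#' @return Tibble of the polarized-difference tests.
#' @export
tidy.asym_battery <- function(x, ...) x$tests

#' One-row summary of an analysis battery
#'
#' @param x An \code{asym_battery}.
#' @param ... Unused.
#' @return One-row tibble: record and test counts.
#' @export
glance.asym_battery <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    n_tests = nrow(x$tests),
    n_significant = sum(x$tests$significant),
    n_skipped = nrow(x$skipped))
}
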