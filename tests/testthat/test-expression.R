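test_that("expression summaries behave on degenerate profiles", {
  uni <- expression_summary(rep(10, 26))
  expect_equal(uni$cv, 0)
  expect_equal(uni$evenness, 1)
  expect_equal(uni$log_mean, 1)

  single <- expression_summary(c(5, rep(0, 25)))
  expect_equal(single$evenness, 0)   # minimal evenness on that support

  allzero <- expression_summary(rep(0, 26))
  expect_true(is.na(allzero$log_mean))

  expect_error(expression_summary(c(-1, 2)), "negative")
})

test_that("expression summaries match direct computation on random profiles", {
  withr::with_seed(3, {
    for (i in 1:20) {
      v <- stats::rlnorm(26)
      s <- expression_summary(v)
      expect_equal(s$cv, stats::sd(v) / mean(v))
      expect_equal(s$log_mean, log10(mean(v)))
      p <- v / sum(v)
      expect_equal(s$evenness, -sum(p * log(p)) / log(26))
      expect_true(s$evenness >= 0 && s$evenness <= 1)
    }
  })
})

test_that("polarization orients by Ka and ignores input order", {
  expect_equal(polarize(2, 5, 0.3, 0.1), -3)
  expect_equal(polarize(5, 2, 0.1, 0.3), -3)
  expect_true(is.na(polarize(2, 5, 0.2, 0.2)))
})

test_that("tissue correlation handles exact and degenerate cases", {
  v <- c(1, 4, 2, 8, 5)
  expect_equal(tissue_correlation(v, v), 1)
  expect_equal(tissue_correlation(v, 2 * mean(v) - v), -1)
  expect_true(is.na(tissue_correlation(v, rep(3, 5))))
  w <- c(2, 1, 7, 3, 6)
  num <- sum((v - mean(v)) * (w - mean(w)))
  den <- sqrt(sum((v - mean(v))^2) * sum((w - mean(w))^2))
  expect_equal(tissue_correlation(v, w), num / den)
})

test_that("SNP Ka/Ks applies the three-SNP eligibility filter", {
  r <- snp_kaks(3, 3, 900, 900)
  expect_equal(r$kaks, 1)
  expect_true(r$eligible)
  expect_false(snp_kaks(10, 2, 900, 300)$eligible)
  expect_false(snp_kaks(2, 10, 900, 300)$eligible)
  r2 <- snp_kaks(6, 4, 600, 300)
  expect_equal(r2$kaks, (6 / 600) / (4 / 300))
})

test_that("location classification follows the four-level scheme", {
  mk <- function(arm, start, end, strand) list(arm = arm, start = start,
                                               end = end, strand = strand)
  expect_equal(classify_location(mk("2L", 1e5, 1.01e5, "+"),
                                 mk("2R", 2e5, 2.01e5, "+")), "different_arms")
  expect_equal(classify_location(mk("3R", 1e5, 1.01e5, "+"),
                                 mk("3R", 1.04e5, 1.05e5, "+")), "tandem_collinear")
  expect_equal(classify_location(mk("3R", 1e5, 1.01e5, "+"),
                                 mk("3R", 1.04e5, 1.05e5, "-")), "tandem_inverted")
  expect_equal(classify_location(mk("3R", 1e5, 1.01e5, "+"),
                                 mk("3R", 1.2e5, 1.21e5, "+")), "same_arm_distant")
  # overlapping spans are tandem at distance zero
  expect_equal(classify_location(mk("X", 1e5, 1.1e5, "+"),
                                 mk("X", 1.05e5, 1.15e5, "+")), "tandem_collinear")
  # a gap of exactly the threshold is still tandem (over-threshold rule)
  expect_equal(classify_location(mk("X", 1e5, 1.1e5, "+"),
                                 mk("X", 1.1e5 + 5000, 1.2e5, "+")),
               "tandem_collinear")
})

test_that("expression generator recovers imposed coupling signs", {
  fams <- tiny_pair_families(300, seed = 500)
  polarized_dme <- function(tbl) {
    tc <- grep("^tissue_", names(tbl))
    vapply(fams, function(fg) {
      faster <- fg$truth$n1 > fg$truth$n2
      if (fg$truth$n1 == fg$truth$n2) return(NA_real_)
      g1 <- sprintf("%s_s01_1", fg$family$id)
      g2 <- sprintf("%s_s01_2", fg$family$id)
      lm1 <- log10(mean(as.numeric(tbl[tbl$gene_id == g1, tc])))
      lm2 <- log10(mean(as.numeric(tbl[tbl$gene_id == g2, tc])))
      if (faster) lm1 - lm2 else lm2 - lm1
    }, 0)
  }
  neg <- generate_expression_table(fams, coupling = -1, seed = 81)
  d_neg <- polarized_dme(neg)
  expect_lt(mean(d_neg, na.rm = TRUE), 0)
  expect_lt(stats::t.test(d_neg)$p.value, 0.01)

  none <- generate_expression_table(fams, coupling = 0, seed = 82)
  d0 <- polarized_dme(none)
  se <- stats::sd(d0, na.rm = TRUE) / sqrt(sum(!is.na(d0)))
  expect_lt(abs(mean(d0, na.rm = TRUE)), 2 * se)

  expect_equal(sum(grepl("^tissue_", names(neg))), 26)
  tall <- generate_expression_table(fams[1:5], n_tissues = 8, seed = 3)
  expect_equal(sum(grepl("^tissue_", names(tall))), 8)
})

test_that("SNP generator recovers imposed Ka/Ks coupling", {
  fams <- tiny_pair_families(300, seed = 500)
  polarized_dkaks <- function(tbl) {
    vapply(fams, function(fg) {
      if (fg$truth$n1 == fg$truth$n2) return(NA_real_)
      faster <- fg$truth$n1 > fg$truth$n2
      g1 <- tbl[tbl$gene_id == sprintf("%s_s01_1", fg$family$id), ]
      g2 <- tbl[tbl$gene_id == sprintf("%s_s01_2", fg$family$id), ]
      k1 <- (g1$n_nonsyn / g1$sites_nonsyn) / max(g1$n_syn, 0.5) * g1$sites_syn
      k2 <- (g2$n_nonsyn / g2$sites_nonsyn) / max(g2$n_syn, 0.5) * g2$sites_syn
      if (faster) k1 - k2 else k2 - k1
    }, 0)
  }
  pos <- generate_snp_table(fams, kaks_coupling = 1, seed = 91)
  d_pos <- polarized_dkaks(pos)
  expect_gt(mean(d_pos, na.rm = TRUE), 0)
  expect_lt(stats::t.test(d_pos)$p.value, 0.01)

  none <- generate_snp_table(fams, kaks_coupling = 0, seed = 92)
  d0 <- polarized_dkaks(none)
  se <- stats::sd(d0, na.rm = TRUE) / sqrt(sum(!is.na(d0)))
  expect_lt(abs(mean(d0, na.rm = TRUE)), 2 * se)

  # a gene with two synonymous SNPs fails the downstream filter
  low <- snp_kaks(5, 2, 600, 200)
  expect_false(low$eligible)
})
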