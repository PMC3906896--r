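test_that("z-squared matches its closed form and symmetry properties", {
  expect_equal(z_squared(10, 500, 10, 500), 0)
  expect_equal(z_squared(15, 500, 5, 500), 5 / (1 - 0.02), tolerance = 1e-12)
  expect_equal(z_squared(15, 500, 5, 500), z_squared(5, 500, 15, 500))
  expect_equal(z_squared(0, 500, 0, 500), 0)    # degenerate: no events
  expect_equal(z_squared(500, 500, 500, 500), 0) # degenerate: saturated
  expect_error(z_squared(501, 500, 5, 500), "counts")
  expect_error(z_squared(5, 0, 5, 500), "positive")
})

test_that("z-squared increases with count imbalance at fixed totals", {
  tot <- 40
  z <- vapply(0:20, function(d) z_squared(tot / 2 + d, 300, tot / 2 - d, 300), 0)
  expect_true(all(diff(z) > 0))
})

test_that("z-squared equals the uncorrected Pearson chi-square", {
  withr::with_seed(11, {
    for (i in 1:300) {
      l1 <- sample(50:800, 1); l2 <- sample(50:800, 1)
      n1 <- sample.int(l1 %/% 2, 1); n2 <- sample.int(l2 %/% 2, 1)
      tab <- matrix(c(n1, l1 - n1, n2, l2 - n2), nrow = 2, byrow = TRUE)
      oracle <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(z_squared(n1, l1, n2, l2), unname(oracle$statistic),
                   tolerance = 1e-9)
    }
  })
})

test_that("A relates to z-squared by the equal-length identity", {
  expect_equal(a_statistic(15, 5), 5)
  expect_equal(a_statistic(10, 10), 0)
  expect_true(is.na(a_statistic(0, 0)))
  withr::with_seed(13, {
    for (i in 1:100) {
      l <- sample(100:1000, 1)
      n1 <- sample.int(l %/% 3, 1); n2 <- sample.int(l %/% 3, 1)
      p <- (n1 + n2) / (2 * l)
      expect_equal(z_squared(n1, l, n2, l), a_statistic(n1, n2) / (1 - p),
                   tolerance = 1e-9)
    }
  })
})

test_that("asymmetry p-values match the Yates-corrected oracle", {
  expect_equal(asymmetry_pvalue(7, 300, 7, 300), 1)
  expect_equal(asymmetry_pvalue(0, 500, 0, 500), 1)
  withr::with_seed(19, {
    for (i in 1:200) {
      l1 <- sample(50:600, 1); l2 <- sample(50:600, 1)
      n1 <- sample.int(l1 %/% 2, 1); n2 <- sample.int(l2 %/% 2, 1)
      tab <- matrix(c(n1, l1 - n1, n2, l2 - n2), nrow = 2, byrow = TRUE)
      oracle <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
      expect_equal(asymmetry_pvalue(n1, l1, n2, l2), oracle$p.value,
                   tolerance = 1e-9)
    }
  })
})

test_that("fractional posterior counts are rounded half-to-even for the table", {
  expect_equal(asymmetry_pvalue(10.5, 500, 5.5, 500),
               asymmetry_pvalue(10, 500, 6, 500))
})

test_that("multiple-testing adjustment matches step-up brute force", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  rec <- tibble::tibble(p_value = p)
  adj <- adjust_asymmetry(rec, alpha = 0.05, q = 0.1)
  # Benjamini-Yekutieli step-up by definition
  m <- length(p); cm <- sum(1 / seq_len(m))
  ord <- order(p)
  thresh <- seq_len(m) * 0.1 / (m * cm)
  passing <- which(p[ord] <= thresh)
  expected_sig <- logical(m)
  if (length(passing)) expected_sig[ord[seq_len(max(passing))]] <- TRUE
  expect_equal(adj$fdr_sig, expected_sig)
  expect_equal(adj$fdr_q, stats::p.adjust(p, "BY"))
  expect_equal(adj$bonferroni_sig, p * m < 0.05)

  none <- adjust_asymmetry(tibble::tibble(p_value = rep(1, 5)))
  expect_false(any(none$bonferroni_sig) || any(none$fdr_sig))
  one <- adjust_asymmetry(tibble::tibble(p_value = 0.04))
  expect_true(one$bonferroni_sig)
  empty <- adjust_asymmetry(tibble::tibble(p_value = double()))
  expect_equal(nrow(empty), 0)
})

test_that("log transform removes exactly the zero values with a warning", {
  expect_warning(out <- log_z2(c(0, 1, 10)), "1 value")
  expect_equal(out, c(0, 1))
  expect_warning(all0 <- log_z2(c(0, 0)), "2 value")
  expect_length(all0, 0)
  expect_silent(log_z2(c(1, 10)))
})
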