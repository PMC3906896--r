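test_that("posteriors over alternatives sum to one and honour frequencies", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ep <- enumerate_parsimonious(tr, c(a = "A", b = "A", c = "V", d = "V"))
  depths <- c(0, 0, 0, 0, 0.5, 0.2, 0.2)

  uniform <- fake_matrices()
  post_u <- assign_posteriors(ep, uniform, depths)
  expect_equal(sum(post_u), 1, tolerance = 1e-12)
  expect_equal(post_u, c(0.5, 0.5))

  skewed <- fake_matrices(data.frame(from = c("A", "V"), to = c("V", "A"),
                                     w = c(0.3, 0.1) * 378))
  post_s <- assign_posteriors(ep, skewed, depths)
  ord <- vapply(ep$alternatives, function(x) paste0(x$from, x$to), "")
  expect_equal(sum(post_s), 1, tolerance = 1e-12)
  expect_equal(unname(post_s[ord == "AV"]), 0.75, tolerance = 1e-9)
  expect_equal(unname(post_s[ord == "VA"]), 0.25, tolerance = 1e-9)
})

test_that("a single most parsimonious reconstruction gets posterior one", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ep <- enumerate_parsimonious(tr, c(a = "A", b = "A", c = "A", d = "V"))
  expect_length(ep$alternatives, 1)
  expect_equal(assign_posteriors(ep, fake_matrices(), rep(0.1, 7)), 1)
})

test_that("depth-binned matrices normalize per bin and fall back when empty", {
  fams <- lapply(tiny_pair_families(30, seed = 2200), `[[`, "family")
  fams <- lapply(fams, mask_family)
  dm <- build_matrices(fams, n_bins = 5)
  expect_length(dm$matrices, 5)
  for (m in dm$matrices) {
    expect_true(all(m >= 0))
    expect_equal(sum(m), 1, tolerance = 1e-12)
    expect_true(all(diag(m) == 0))
  }
  # duplication depths concentrate events in few bins; empty bins must
  # equal the pooled matrix
  empty <- which(dm$n_events == 0)
  for (b in empty) expect_identical(dm$matrices[[b]], dm$pooled)
  expect_equal(dm$breaks[1], 0)
})

test_that("a corpus generated by uniform exchange is recovered as near-uniform", {
  fams <- lapply(tiny_pair_families(60, seed = 2200)[1:60], `[[`, "family")
  fams <- lapply(fams, mask_family)
  dm <- build_matrices(fams, n_bins = 1)
  m <- dm$pooled
  off <- m[row(m) != col(m)]
  # uniform generator: no off-diagonal cell should dominate
  expect_lt(max(off), 6 * mean(off))
})

test_that("event posteriors per site always sum to one across a family", {
  fams <- tiny_pair_families(30, seed = 2200)
  fam <- mask_family(fams[[1]]$family)
  dm <- build_matrices(lapply(tiny_pair_families(30, seed = 2200)[1:10],
                              function(f) mask_family(f$family)), n_bins = 3)
  ev <- reconstruct_events(fam, dm)
  per_site <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(ev, site, alt, posterior), site),
    total = sum(posterior), .groups = "drop")
  expect_true(all(abs(per_site$total - 1) < 1e-9))
})

test_that("expected event totals are invariant to enumeration order", {
  fams <- tiny_pair_families(30, seed = 2200)
  fam <- mask_family(fams[[2]]$family)
  dm <- build_matrices(list(fam), n_bins = 2)
  ev1 <- reconstruct_events(fam, dm, max_alternatives = 64)
  # a rotated tree enumerates reconstructions in a different order
  fam2 <- fam
  fam2$tree <- ape::rotate(fam$tree, dupasym:::root_node(fam$tree))
  ev2 <- reconstruct_events(fam2, dm, max_alternatives = 64)
  expect_equal(sum(ev1$posterior), sum(ev2$posterior), tolerance = 1e-9)
})

test_that("a corpus without substitutions is rejected", {
  fam <- topology_family(nhx_usable(), n_col = 20)
  fam <- mask_family(fam)
  expect_error(build_matrices(list(fam)), "no unambiguous substitutions")
})
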