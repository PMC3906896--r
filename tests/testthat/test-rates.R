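test_that("clade Ka is the posterior path sum over the usable length", {
  fam <- topology_family(nhx_usable(), n_col = 500)
  fam <- mask_family(fam)
  tip <- match("pA_1", fam$tree$tip.label)
  anc <- dupasym:::root_node(fam$tree)
  events <- tibble::tibble(site = 1:5, alt = 1L, n_alt = 1L,
                           node = tip, from = "A", to = "V", posterior = 1)
  ck <- clade_ka(events, fam, anc, tip)
  expect_equal(ck$ka, 5 / 500)
  expect_equal(ck$n_events, 5)
  expect_equal(ck$total_length, 500)
})

test_that("multi-leaf clades pool path sums and lengths", {
  fam <- topology_family(nhx_usable(), n_col = 500)
  # give pA_2 100 single-residue gaps so its usable length is 400
  gap_cols <- seq(2, 400, by = 4)
  fam$aln["pA_2", gap_cols] <- "-"
  fam <- mask_family(fam)
  t1 <- match("pA_1", fam$tree$tip.label)
  t2 <- match("pA_2", fam$tree$tip.label)
  anc <- dupasym:::root_node(fam$tree)
  events <- tibble::tibble(
    site = 1:9, alt = 1L, n_alt = 1L,
    node = c(rep(t1, 4), rep(t2, 5)), from = "A", to = "V", posterior = 1)
  ck <- clade_ka(events, fam, anc, c(t1, t2))
  expect_equal(ck$total_length, 900)
  expect_equal(ck$ka, 9 / 900)
})

test_that("shared stem events count for both paralog clades", {
  fam <- topology_family(nhx_usable(), n_col = 100)
  fam <- mask_family(fam)
  dup <- which(fam$node_type == "duplication") + length(fam$tree$tip.label)
  anc <- dupasym:::root_node(fam$tree)
  t1 <- match("pA_1", fam$tree$tip.label)
  t2 <- match("pA_2", fam$tree$tip.label)
  events <- tibble::tibble(site = 1L, alt = 1L, n_alt = 1L,
                           node = dup, from = "A", to = "V", posterior = 1)
  expect_equal(clade_ka(events, fam, anc, t1)$n_events, 1)
  expect_equal(clade_ka(events, fam, anc, t2)$n_events, 1)
})

test_that("relative rate normalizes by Ks depth", {
  expect_equal(rel_ka(0.02, 0.1), 0.2)
  expect_equal(rel_ka(0, 0.5), 0)
  expect_error(rel_ka(0.1, 0), "ks_depth")
})

test_that("radicality is the posterior-weighted mean of property changes", {
  pol <- grantham_polarity()
  ex <- default_ex_matrix()
  ev1 <- tibble::tibble(from = "A", to = "V", posterior = 1)
  r1 <- clade_radicality(ev1, pol, ex)
  expect_equal(r1$d_polarity, abs(pol[["A"]] - pol[["V"]]))
  expect_equal(r1$ex, ex["A", "V"])

  # two events with equal weight average the properties
  ev2 <- tibble::tibble(from = c("A", "L"), to = c("V", "K"),
                        posterior = c(0.5, 0.5))
  r2 <- clade_radicality(ev2, pol, ex)
  expect_equal(r2$ex, mean(c(ex["A", "V"], ex["L", "K"])))

  # brute-force oracle on random event sets
  withr::with_seed(77, {
    for (i in 1:20) {
      n <- sample(2:10, 1)
      ev <- tibble::tibble(from = sample(amino_acids(), n, replace = TRUE),
                           to = sample(amino_acids(), n, replace = TRUE),
                           posterior = stats::runif(n))
      ev <- ev[ev$from != ev$to, ]
      if (!nrow(ev)) next
      r <- clade_radicality(ev, pol, ex)
      w <- ev$posterior
      expect_equal(r$d_polarity,
                   sum(w * abs(pol[ev$from] - pol[ev$to])) / sum(w))
      expect_equal(r$ex, sum(w * ex[cbind(ev$from, ev$to)]) / sum(w))
      expect_gte(r$ex, min(ex[cbind(ev$from, ev$to)]))
      expect_lte(r$ex, max(ex[cbind(ev$from, ev$to)]))
    }
  })
})

test_that("empty event sets are flagged missing, not zero", {
  r <- clade_radicality(tibble::tibble(from = character(), to = character(),
                                       posterior = double()))
  expect_true(is.na(r$d_polarity) && is.na(r$ex))
})

test_that("directional exchangeability is genuinely asymmetric", {
  ex <- default_ex_matrix()
  expect_false(isTRUE(all.equal(ex, t(ex))))
})

test_that("reconstruction recovers ground-truth counts at low divergence", {
  st <- tiny_species_tree()
  focal <- match("s01", st$tree$tip.label)
  fg <- generate_family(st, sim_family_spec(
    id = "flo", length = 200, gamma_shape = 20, dup_edge = focal,
    ka_ks = 0.05, seed = 60))
  fam <- mask_family(fg$family)
  dm <- build_matrices(list(fam), n_bins = 2)
  ev <- reconstruct_events(fam, dm)
  trip <- select_duplications(fam)
  expect_equal(nrow(trip), 1)
  rates <- dupasym:::triplet_rates(fam, ev, trip[1, ])
  n1 <- rates$n_events[rates$role == "paralog1"]
  n2 <- rates$n_events[rates$role == "paralog2"]
  expect_lt(abs(n1 - fg$truth$n1), 2 + 1e-9)
  expect_lt(abs(n2 - fg$truth$n2), 2 + 1e-9)
})

test_that("neutral families calibrate relKa near one", {
  st <- generate_species_tree(6, 0.25, seed = 610)
  fams <- lapply(1:10, function(i) {
    generate_family(st, sim_family_spec(
      id = sprintf("fn%02d", i), length = 200, gamma_shape = 20,
      dup_edge = 8 + (i %% 3), ka_ks = 1, seed = 700 + i))
  })
  names(fams) <- vapply(fams, function(f) f$family$id, "")
  an <- analyze_cohort(fams, st)
  expect_gt(nrow(an$rates), 0)
  expect_gt(mean(an$rates$rel_ka), 0.75)
  expect_lt(mean(an$rates$rel_ka), 1.2)
})

test_that("paralog clades outpace singletons under relaxed constraint", {
  # impose a rate ratio so the paralog mean exceeds the singleton rate
  fams <- tiny_pair_families(40, rate_ratio = 3, seed = 3600)
  st <- tiny_species_tree()
  an <- analyze_cohort(fams, st)
  wide <- tidyr::pivot_wider(
    dplyr::select(an$rates, family, dup_node, role, ka),
    names_from = role, values_from = ka)
  expect_gt(mean((wide$paralog1 + wide$paralog2) / 2 > wide$singleton), 0.6)
})
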