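test_that("family simulation is deterministic given the seed", {
  st <- tiny_species_tree()
  spec <- sim_family_spec(id = "fd", length = 80, dup_edge = 6, seed = 9)
  a <- generate_family(st, spec)
  b <- generate_family(st, spec)
  expect_identical(a$family$aln, b$family$aln)
  expect_identical(a$truth, b$truth)
  expect_identical(ape::write.tree(a$family$tree), ape::write.tree(b$family$tree))
})

test_that("ground-truth counts conserve the simulated event total", {
  st <- tiny_species_tree()
  fg <- generate_family(st, sim_family_spec(id = "fc", length = 100,
                                            dup_edge = 6, ka_ks = 0.5,
                                            seed = 31))
  tr <- fg$truth
  expect_equal(tr$total_events, sum(tr$per_edge) + tr$shared_events)
  expect_true(all(tr$per_edge >= 0))
  expect_true(tr$n1 >= 0 && tr$n2 >= 0)
})

test_that("symmetric families show no systematic count asymmetry", {
  fams <- tiny_pair_families(200, rate_ratio = 1, seed = 1500)
  d <- vapply(fams, function(f) f$truth$n1 - f$truth$n2, 0)
  nz <- d[d != 0]
  frac_pos <- mean(nz > 0)
  expect_gt(frac_pos, 0.4)
  expect_lt(frac_pos, 0.6)
})

test_that("an imposed rate ratio of 4 makes copy 1 accumulate more events", {
  st <- tiny_species_tree()
  focal <- match("s01", st$tree$tip.label)
  wins <- vapply(seq_len(200), function(i) {
    fg <- generate_family(st, sim_family_spec(
      id = "fr", length = 60, gamma_shape = 20, dup_edge = focal,
      rate_ratio = 4, ka_ks = 0.5, seed = 7000 + i))
    fg$truth$n1 > fg$truth$n2
  }, TRUE)
  expect_gt(mean(wins), 0.9)
})

test_that("indel handling matches the switch", {
  st <- tiny_species_tree()
  clean <- generate_family(st, sim_family_spec(id = "fi0", length = 120,
                                               dup_edge = 6, indel_rate = 0,
                                               seed = 5))
  expect_false(any(clean$family$aln == "-"))
  gappy <- generate_family(st, sim_family_spec(id = "fi1", length = 120,
                                               dup_edge = 6, indel_rate = 0.05,
                                               seed = 5))
  expect_true(any(gappy$family$aln == "-"))
  runs <- rle(gappy$family$aln[which.max(rowSums(gappy$family$aln == "-")), ] == "-")
  expect_gte(max(runs$lengths[runs$values]), 2)
})

test_that("a planted loss yields remaining-paralog survivors", {
  st <- generate_species_tree(5, 0.8, seed = 21)
  # duplicate above an internal clade, then delete copy 2 in one species
  internal <- which(tabulate(st$tree$edge[, 1]) > 0)
  v <- setdiff(internal, 6)[1]
  sp_under <- st$tree$tip.label[dupasym:::descendant_tips(st$tree, v)]
  fg <- generate_family(st, sim_family_spec(
    id = "fl", length = 80, dup_edge = v,
    loss = list(copy = 2, species = sp_under[1]), seed = 3))
  cls <- classify_genes(fg$family)
  lost_gene <- sprintf("fl_%s_1", sp_under[1])
  expect_equal(cls$type[cls$gene == lost_gene], "remaining_paralog")
  expect_equal(unname(fg$family$gene_type[lost_gene]), "remaining_paralog")
  # classification from topology agrees with the generator's labels
  expect_equal(cls$type, unname(fg$family$gene_type[cls$gene]))
})

test_that("a duplication on the root edge is rejected", {
  st <- tiny_species_tree()
  expect_error(
    generate_family(st, sim_family_spec(dup_edge = dupasym:::root_node(st$tree))),
    "outgroup")
})

test_that("concerted evolution keeps young copies identical", {
  st <- tiny_species_tree()
  focal <- match("s01", st$tree$tip.label)
  fg <- generate_family(st, sim_family_spec(
    id = "fce", length = 100, dup_edge = focal, ka_ks = 0.5,
    concerted_until = 10, seed = 12))   # homogenized for the whole stem
  g1 <- fg$family$aln[sprintf("fce_%s_1", "s01"), ]
  g2 <- fg$family$aln[sprintf("fce_%s_2", "s01"), ]
  expect_identical(g1, g2)
  free <- generate_family(st, sim_family_spec(
    id = "fce", length = 100, dup_edge = focal, ka_ks = 0.5,
    concerted_until = 0, seed = 12))
  expect_false(identical(free$family$aln["fce_s01_1", ],
                         free$family$aln["fce_s01_2", ]))
})
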