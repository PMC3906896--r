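test_that("the textbook four-leaf split has exactly two minimal reconstructions", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ep <- enumerate_parsimonious(tr, c(a = "A", b = "A", c = "V", d = "V"))
  expect_equal(ep$min_cost, 1)
  expect_length(ep$alternatives, 2)
  expect_true(all(vapply(ep$alternatives, nrow, 0L) == 1))
  pairs <- sort(vapply(ep$alternatives, function(x) paste0(x$from, x$to), ""))
  expect_equal(pairs, c("AV", "VA"))
})

test_that("invariant sites yield an empty event set", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ep <- enumerate_parsimonious(tr, c(a = "A", b = "A", c = "A", d = "A"))
  expect_equal(ep$min_cost, 0)
  expect_length(ep$alternatives, 0)
})

test_that("gaps are treated as missing and multifurcations are supported", {
  tr <- ape::read.tree(text = "(a:1,b:1,(c:1,d:1):1);")
  ep <- enumerate_parsimonious(tr, c(a = "A", b = "-", c = "V", d = "V"))
  expect_equal(ep$min_cost, 1)
  expect_gte(length(ep$alternatives), 1)
})

test_that("minimal cost matches the phangorn Fitch oracle on random trees", {
  withr::with_seed(91, {
    for (i in 1:200) {
      n <- sample(4:6, 1)
      tr <- ape::rtree(n)
      states <- sample(c("A", "V", "L", "S"), n, replace = TRUE)
      names(states) <- tr$tip.label
      if (length(unique(states)) < 2) next
      ep <- enumerate_parsimonious(tr, states)
      dat <- phangorn::phyDat(as.matrix(states), type = "AA")
      oracle <- phangorn::parsimony(tr, dat, method = "fitch")
      expect_equal(ep$min_cost, unname(oracle))
    }
  })
})

test_that("enumeration is exhaustive against a brute-force scan", {
  # enumerate every assignment of observed states to internal nodes and
  # count optimal ones directly
  brute <- function(tr, states) {
    nt <- length(tr$tip.label)
    obs <- sort(unique(states))
    parent <- rep(NA_integer_, nt + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    tipcode <- match(states[tr$tip.label], obs)
    grid <- expand.grid(rep(list(seq_along(obs)), tr$Nnode))
    cost <- apply(grid, 1, function(g) {
      lab <- c(tipcode, as.integer(g))
      sum(vapply(seq_along(lab), function(v) {
        p <- parent[v]
        !is.na(p) && lab[v] != lab[p]
      }, TRUE))
    })
    list(min = min(cost), n = sum(cost == min(cost)))
  }
  withr::with_seed(17, {
    for (i in 1:25) {
      n <- sample(4:5, 1)
      tr <- ape::rtree(n)
      states <- sample(c("A", "V", "L"), n, replace = TRUE)
      names(states) <- tr$tip.label
      if (length(unique(states)) < 2) next
      ep <- enumerate_parsimonious(tr, states)
      bf <- brute(tr, states)
      expect_equal(ep$min_cost, bf$min)
      expect_equal(length(ep$alternatives), bf$n)
    }
  })
})

test_that("every alternative implies exactly the minimal number of events", {
  withr::with_seed(23, {
    for (i in 1:20) {
      tr <- ape::rtree(6)
      states <- sample(c("A", "V", "L", "S", "G"), 6, replace = TRUE)
      names(states) <- tr$tip.label
      ep <- enumerate_parsimonious(tr, states)
      for (alt in ep$alternatives) expect_equal(nrow(alt), ep$min_cost)
    }
  })
})

test_that("the enumeration cap truncates and flags pathological sites", {
  # star-ish tree with many tied states explodes combinatorially
  tr <- ape::read.tree(text = "((((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1):1,(i:1,j:1):1);")
  states <- setNames(c("A", "V", "L", "S", "G", "T", "C", "M", "F", "W"),
                     letters[1:10])
  ep <- enumerate_parsimonious(tr, states, max_alternatives = 4)
  expect_true(ep$capped)
  expect_length(ep$alternatives, 4)
})
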