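# Sankoff parsimony with unit costs and exhaustive enumeration of
# equally parsimonious labelings.  With unit costs every optimal labeling
# uses only residues observed at the site's leaves (relabelling a maximal
# same-state component of an unobserved residue to a neighbouring state
# strictly lowers the cost), so the DP runs over the observed alphabet.

# Precompute traversal structure for repeated per-site calls.
prep_parsimony <- function(tree) {
  nt <- n_tips(tree)
  n_nodes <- nt + tree$Nnode
  parent <- rep(NA_integer_, n_nodes)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  children <- vector("list", n_nodes)
  for (v in (nt + 1L):n_nodes) children[[v]] <- tree$edge[tree$edge[, 1L] == v, 2L]
  internal <- (nt + 1L):n_nodes
  depth_of <- function(v) { d <- 0L; while (!is.na(parent[[v]])) { v <- parent[[v]]; d <- d + 1L }; d }
  ndepth <- vapply(internal, depth_of, 0L)
  list(nt = nt, n_nodes = n_nodes, parent = parent, children = children,
       root = root_node(tree),
       post = internal[order(ndepth, decreasing = TRUE)],
       pre = internal[order(ndepth)],
       tip_labels = tree$tip.label)
}

# Enumerate minimal labelings for one site.  leaf_states: integer codes
# (any alphabet) of length nt, NA = missing.  Returns min cost, a list of
# integer labelings over all nodes (observed-alphabet indices, NA at
# missing tips), the observed alphabet, and a capped flag.
site_enumerate <- function(prep, leaf_states, max_alternatives = 64L) {
  obs <- sort(unique(leaf_states[!is.na(leaf_states)]))
  m <- length(obs)
  if (m <= 1L) {
    return(list(min_cost = 0, labelings = list(), obs = obs, capped = FALSE))
  }
  tip_idx <- match(leaf_states, obs)
  big <- .Machine$integer.max %/% 4L
  cost <- matrix(0L, nrow = prep$n_nodes, ncol = m)
  for (i in seq_len(prep$nt)) {
    if (!is.na(tip_idx[[i]])) {
      cost[i, ] <- big
      cost[i, tip_idx[[i]]] <- 0L
    }
  }
  for (v in prep$post) {
    acc <- integer(m)
    for (ch in prep$children[[v]]) {
      acc <- acc + pmin(cost[ch, ], min(cost[ch, ]) + 1L)
    }
    cost[v, ] <- acc
  }
  min_cost <- min(cost[prep$root, ])

  labelings <- list()
  capped <- FALSE
  assign0 <- rep(NA_integer_, prep$n_nodes)
  assign0[seq_len(prep$nt)] <- tip_idx
  pre <- prep$pre
  np <- length(pre)

  rec <- function(k, assign) {
    if (capped) return()
    if (k > np) {
      if (length(labelings) >= max_alternatives) { capped <<- TRUE; return() }
      labelings[[length(labelings) + 1L]] <<- assign
      return()
    }
    v <- pre[[k]]
    if (v == prep$root) {
      vals <- cost[v, ]
    } else {
      s <- assign[[prep$parent[[v]]]]
      vals <- cost[v, ] + (seq_len(m) != s)
    }
    for (t in which(vals == min(vals))) {
      assign[[v]] <- t
      rec(k + 1L, assign)
      if (capped) return()
    }
  }
  rec(1L, assign0)
  list(min_cost = min_cost, labelings = labelings, obs = obs, capped = capped)
}

# Substitution events implied by one labeling: tibble(child, from, to)
# with `from` the parental (ancestral) and `to` the derived residue code.
labeling_events <- function(prep, labeling, obs) {
  childs <- integer(0); froms <- integer(0); tos <- integer(0)
  for (v in seq_len(prep$n_nodes)) {
    p <- prep$parent[[v]]
    if (is.na(p)) next
    sc <- labeling[[v]]
    if (is.na(sc)) next
    sp <- labeling[[p]]
    if (sc != sp) {
      childs <- c(childs, v); froms <- c(froms, obs[[sp]]); tos <- c(tos, obs[[sc]])
    }
  }
  list(child = childs, from = froms, to = tos)
}

#' Enumerate equally parsimonious ancestral reconstructions of one site
#'
#' Runs unit-cost Sankoff dynamic programming over the residues observed
#' at the leaves and enumerates every labeling of the internal nodes that
#' attains the minimal substitution count.  Gap (\code{"-"}) and \code{X}
#' leaves are treated as missing and constrain nothing.  Enumeration is
#' capped at \code{max_alternatives}; past the cap the set is truncated
#' and flagged, and downstream posteriors fall back to uniform weights.
#'
#' @param tree Rooted \code{ape} phylo (bifurcating or not).
#' @param states Named character vector of leaf residues (names = tip
#'   labels), or an unnamed vector in tip order.
#' @param max_alternatives Enumeration cap (default 64).
#' @return Object of class \code{parsimony_set}: \code{min_cost}, a list
#'   \code{alternatives} of tibbles (\code{node}, \code{from}, \code{to});
#'   one tibble per minimal reconstruction, empty list for invariant
#'   sites; \code{capped} flag.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
#' ep <- enumerate_parsimonious(tr, c(a = "A", b = "A", c = "V", d = "V"))
#' ep$min_cost  # 1
#' length(ep$alternatives)  # 2
#' @export
enumerate_parsimonious <- function(tree, states, max_alternatives = 64) {
  prep <- prep_parsimony(tree)
  if (!is.null(names(states))) states <- states[prep$tip_labels]
  states <- toupper(states)
  states[states %in% c("-", "X", "")] <- NA
  code <- match(states, amino_acids())
  if (any(!is.na(states) & is.na(code))) {
    stop("unknown residue(s): ",
         paste(unique(states[!is.na(states) & is.na(code)]), collapse = ", "),
         call. = FALSE)
  }
  res <- site_enumerate(prep, code, as.integer(max_alternatives))
  aa <- amino_acids()
  alternatives <- lapply(res$labelings, function(lb) {
    ev <- labeling_events(prep, lb, res$obs)
    tibble::tibble(node = ev$child, from = aa[ev$from], to = aa[ev$to])
  })
  structure(list(min_cost = res$min_cost, alternatives = alternatives,
                 capped = res$capped),
            class = "parsimony_set")
}

#' @export
print.parsimony_set <- function(x, ...) {
  cat(sprintf("<parsimony_set> min cost %d, %d alternative reconstruction(s)%s\n",
              x$min_cost, length(x$alternatives),
              if (x$capped) " (capped)" else ""))
  invisible(x)
}
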