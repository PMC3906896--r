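# Small helpers over ape's phylo edge matrix.  Node ids follow ape's
# convention: tips 1..Ntip, internal nodes (Ntip+1)..(Ntip+Nnode), root is
# Ntip+1 for rooted trees produced by read.tree/rcoal.

n_tips <- function(tree) length(tree$tip.label)

root_node <- function(tree) n_tips(tree) + 1L

parent_of <- function(tree, node) {
  i <- match(node, tree$edge[, 2L])
  if (is.na(i)) NA_integer_ else tree$edge[i, 1L]
}

children_of <- function(tree, node) {
  tree$edge[tree$edge[, 1L] == node, 2L]
}

#' @keywords internal
#' @noRd
is_tip <- function(tree, node) node <= n_tips(tree)

# All tip ids below a node (the node itself if it is a tip).
descendant_tips <- function(tree, node) {
  nt <- n_tips(tree)
  if (node <= nt) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ch <- children_of(tree, v)
    out <- c(out, ch[ch <= nt])
    stack <- c(stack, ch[ch > nt])
  }
  sort(out)
}

# All nodes (tips and internal) in the clade rooted at `node`, inclusive.
descendant_nodes <- function(tree, node) {
  out <- node
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ch <- children_of(tree, v)
    out <- c(out, ch)
    stack <- c(stack, ch[ch > n_tips(tree)])
  }
  sort(unique(out))
}

# Ancestor chain of `node` up to the root (node itself excluded).
ancestors_of <- function(tree, node) {
  out <- integer(0)
  p <- parent_of(tree, node)
  while (!is.na(p)) {
    out <- c(out, p)
    p <- parent_of(tree, p)
  }
  out
}

# Child-end node ids of the edges on the path from `anc` down to `node`
# (`node` included, `anc` excluded).  Errors if `anc` is not an ancestor.
path_below <- function(tree, anc, node) {
  out <- integer(0)
  v <- node
  while (v != anc) {
    out <- c(out, v)
    v <- parent_of(tree, v)
    if (is.na(v)) stop("`anc` is not an ancestor of `node`", call. = FALSE)
  }
  out
}

# Depth (height above the tips, in branch-length units) of every node of an
# ultrametric-by-construction tree; tips get exactly zero.
node_heights <- function(tree) {
  dist_root <- ape::node.depth.edgelength(tree)
  h <- max(dist_root[seq_len(n_tips(tree))]) - dist_root
  h[seq_len(n_tips(tree))] <- 0
  h
}
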