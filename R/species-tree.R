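#' Generate a random ultrametric species tree with Ks node depths
#'
#' Produces a rooted bifurcating species tree whose node depths are
#' interpreted in Ks units (synonymous substitutions per 4-fold degenerate
#' site), the age scale used to date duplications.  Topology and
#' coalescence times come from a standard coalescent draw, rescaled so the
#' root sits at \code{root_depth}; leaves sit at depth 0.
#'
#' @param n_taxa Number of species (>= 3, so that a duplication can have a
#'   singleton outgroup).
#' @param root_depth Root age in Ks units (> 0).
#' @param seed Integer seed; identical seeds give identical trees.
#' @return An object of class \code{species_tree}: an \code{ape} phylo with
#'   a \code{node_depth} numeric attribute over all nodes (tips first).
#' @examples
#' tr <- generate_species_tree(6, 1.5, seed = 1)
#' @export
generate_species_tree <- function(n_taxa, root_depth, seed) {
  stopifnot(length(n_taxa) == 1, length(root_depth) == 1)
  if (n_taxa < 3) {
    stop("n_taxa must be >= 3: with fewer species no duplication can have a singleton outgroup",
         call. = FALSE)
  }
  if (root_depth <= 0) stop("root_depth must be > 0", call. = FALSE)
  tree <- withr::with_seed(as.integer(seed), {
    ape::rcoal(n_taxa, tip.label = sprintf("s%02d", seq_len(n_taxa)))
  })
  h <- node_heights(tree)
  scale <- root_depth / h[root_node(tree)]
  tree$edge.length <- tree$edge.length * scale
  tree$node.label <- NULL
  structure(
    list(tree = tree, node_depth = node_heights(tree)),
    class = "species_tree"
  )
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("<species_tree> %d taxa, root depth %.4g Ks\n",
              n_tips(x$tree), x$node_depth[root_node(x$tree)]))
  invisible(x)
}

#' Write / read a species tree (Newick, ultrametric branch lengths in Ks)
#'
#' @param x A \code{species_tree}.
#' @param path File path.
#' @return \code{read_species_tree} returns a \code{species_tree}.
#' @export
write_species_tree <- function(x, path) {
  stopifnot(inherits(x, "species_tree"))
  ape::write.tree(x$tree, file = path)
  invisible(path)
}

#' @rdname write_species_tree
#' @export
read_species_tree <- function(path) {
  tree <- ape::read.tree(path)
  structure(list(tree = tree, node_depth = node_heights(tree)),
            class = "species_tree")
}

# Depth (Ks) of the species-tree MRCA of a set of species names.
species_mrca_depth <- function(stree, species) {
  tips <- match(unique(species), stree$tree$tip.label)
  if (anyNA(tips)) stop("unknown species: ",
                        paste(setdiff(species, stree$tree$tip.label), collapse = ", "),
                        call. = FALSE)
  if (length(tips) == 1L) return(0)
  m <- ape::getMRCA(stree$tree, tips)
  stree$node_depth[m]
}
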