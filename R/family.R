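#' Reconciled gene family objects
#'
#' A \code{reconciled_family} binds an amino-acid alignment to a reconciled
#' gene tree whose internal nodes are labelled speciation/duplication and
#' whose leaves carry a species and a gene type (\code{paralog},
#' \code{true_singleton} or \code{remaining_paralog}).  It is the unit of
#' input for masking, ancestral reconstruction and duplication selection.
#'
#' @param id Family identifier (character scalar).
#' @param aln Character matrix of aligned residues (rows = genes, one
#'   column per alignment column, gap = \code{"-"}), rownames = gene ids.
#' @param tree Rooted \code{ape} phylo whose tip labels are the gene ids.
#' @param node_type Character vector over internal nodes (in ape node
#'   order, i.e. element 1 is node Ntip+1), values \code{"speciation"} or
#'   \code{"duplication"}.
#' @param gene_type Named character vector over tips.
#' @param leaf_species Named character vector over tips (species id).
#' @return An object of class \code{reconciled_family}.
#' @export
reconciled_family <- function(id, aln, tree, node_type, gene_type, leaf_species) {
  if (is.character(aln) && is.null(dim(aln))) aln <- strings_to_matrix(aln)
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  tips <- tree$tip.label
  missing_seq <- setdiff(tips, rownames(aln))
  extra_seq <- setdiff(rownames(aln), tips)
  if (length(missing_seq) || length(extra_seq)) {
    stop("tree/alignment name mismatch; in tree only: [",
         paste(missing_seq, collapse = ", "), "]; in alignment only: [",
         paste(extra_seq, collapse = ", "), "]", call. = FALSE)
  }
  if (length(node_type) != tree$Nnode) {
    stop("node_type must have one entry per internal node", call. = FALSE)
  }
  if (!all(node_type %in% c("speciation", "duplication"))) {
    stop("every internal node must be labelled speciation or duplication",
         call. = FALSE)
  }
  aln <- toupper(aln[tips, , drop = FALSE])
  structure(
    list(id = id, aln = aln, tree = tree, node_type = node_type,
         gene_type = gene_type[tips], leaf_species = leaf_species[tips],
         node_depth = NULL, mask = NULL),
    class = "reconciled_family"
  )
}

#' @export
print.reconciled_family <- function(x, ...) {
  cat(sprintf("<reconciled_family> %s: %d genes x %d columns, %d duplication node(s)%s\n",
              x$id, nrow(x$aln), ncol(x$aln),
              sum(x$node_type == "duplication"),
              if (is.null(x$mask)) "" else sprintf(", %d columns masked", sum(x$mask))))
  invisible(x)
}

# Convert named character vector of equal-length strings to a char matrix.
strings_to_matrix <- function(seqs) {
  lens <- unique(nchar(seqs))
  if (length(lens) != 1) {
    stop("ragged alignment: sequences have lengths ",
         paste(sort(unique(nchar(seqs))), collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

matrix_to_strings <- function(aln) {
  stats::setNames(apply(aln, 1, paste, collapse = ""), rownames(aln))
}

# Type of internal node `node` ("speciation"/"duplication").
node_type_of <- function(family, node) {
  family$node_type[node - n_tips(family$tree)]
}

#' Annotate a gene tree with Ks node depths from the species tree
#'
#' Speciation nodes get the Ks depth of the species-tree MRCA of their
#' descendant species.  Duplication nodes are dated by the upper-bound
#' rule: the depth of the nearest ancestral speciation node (the species
#' phylogeny cannot date a duplication more precisely than the flanking
#' speciations).  Tips get depth 0.
#'
#' @param family A \code{reconciled_family}.
#' @param species_tree A \code{species_tree}.
#' @return The family with \code{node_depth} filled in.
#' @export
annotate_depths <- function(family, species_tree) {
  tree <- family$tree
  nt <- n_tips(tree)
  depth <- numeric(nt + tree$Nnode)
  # preorder so ancestors are dated before their descendants
  nodes <- (nt + 1L):(nt + tree$Nnode)
  ord <- nodes[order(vapply(nodes, function(v) length(ancestors_of(tree, v)), 1L))]
  for (v in ord) {
    if (node_type_of(family, v) == "speciation") {
      sp <- unique(family$leaf_species[tree$tip.label[descendant_tips(tree, v)]])
      depth[v] <- species_mrca_depth(species_tree, sp)
    } else {
      anc <- ancestors_of(tree, v)
      spec_anc <- anc[vapply(anc, function(a) node_type_of(family, a) == "speciation", TRUE)]
      depth[v] <- if (length(spec_anc)) depth[spec_anc[[1L]]] else
        species_tree$node_depth[root_node(species_tree$tree)]
    }
  }
  family$node_depth <- depth
  family
}
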