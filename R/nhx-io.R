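# Reading and writing reconciled families: aligned FASTA via ape, Newick
# via ape, with the reconciliation annotations carried in NHX-style
# comments ([&&NHX:D=Y] / [&&NHX:D=N] on internal nodes, S=<species> and
# GT=<type> on leaves).  ape drops square-bracket comments, so the tags
# are spliced in and out around ape's Newick engine.

nhx_tag <- function(fields) {
  paste0("[&&NHX:", paste(sprintf("%s=%s", names(fields), unlist(fields)),
                          collapse = ":"), "]")
}

parse_nhx_tag <- function(tag) {
  body <- sub("^\\[&&NHX:", "", sub("\\]$", "", tag))
  parts <- strsplit(body, ":", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}

#' Write a reconciled family to aligned FASTA + NHX Newick
#'
#' @param family A \code{reconciled_family}.
#' @param fasta_path,tree_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_family <- function(family, fasta_path, tree_path) {
  stopifnot(inherits(family, "reconciled_family"))
  bin <- ape::as.AAbin(family$aln)
  ape::write.FASTA(bin, fasta_path)

  tree <- family$tree
  nt <- n_tips(tree)
  ph <- tree
  ph$tip.label <- sprintf("%s__TIPTAG%04d", tree$tip.label, seq_len(nt))
  ph$node.label <- sprintf("NODETAG%04d", seq_len(tree$Nnode))
  s <- ape::write.tree(ph)
  for (i in seq_len(nt)) {
    lab <- tree$tip.label[[i]]
    tag <- nhx_tag(list(S = family$leaf_species[[lab]], GT = family$gene_type[[lab]]))
    s <- sub(sprintf("__TIPTAG%04d", i), tag, s, fixed = TRUE)
  }
  for (j in seq_len(tree$Nnode)) {
    tag <- nhx_tag(list(D = if (family$node_type[[j]] == "duplication") "Y" else "N"))
    s <- sub(sprintf("NODETAG%04d", j), tag, s, fixed = TRUE)
  }
  writeLines(s, tree_path)
  invisible(c(fasta_path, tree_path))
}

#' Read a reconciled family from aligned FASTA + NHX Newick
#'
#' Leaf names in the tree must match the FASTA headers exactly; lowercase
#' residues are accepted and uppercased.
#'
#' @param fasta_path Aligned amino-acid FASTA.
#' @param tree_path Newick with \code{[&&NHX:...]} tags (\code{D=Y/N} on
#'   internal nodes; \code{S=}, \code{GT=} on leaves).
#' @param id Family id; defaults to the FASTA file stem.
#' @return A \code{reconciled_family}.
#' @export
read_family <- function(fasta_path, tree_path, id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(fasta_path))
  bin <- ape::read.FASTA(fasta_path, type = "AA")
  seqs <- toupper(vapply(as.character(bin), paste, "", collapse = ""))
  parsed <- read_nhx(paste(readLines(tree_path), collapse = ""))
  reconciled_family(id = id, aln = strings_to_matrix(seqs), tree = parsed$tree,
                    node_type = parsed$node_type, gene_type = parsed$gene_type,
                    leaf_species = parsed$leaf_species)
}

# Parse an NHX Newick string into tree + annotations.
read_nhx <- function(s) {
  locs <- gregexpr("\\[&&NHX:[^]]*\\]", s)[[1]]
  if (locs[[1]] == -1) stop("no NHX tags found in tree", call. = FALSE)
  tags <- regmatches(s, gregexpr("\\[&&NHX:[^]]*\\]", s))[[1]]
  for (i in seq_along(tags)) {
    s <- sub(tags[[i]], sprintf("ZNXTAG%04dZ", i), s, fixed = TRUE)
  }
  tree <- ape::read.tree(text = s)
  if (is.null(tree)) stop("could not parse Newick", call. = FALSE)
  nt <- n_tips(tree)

  take_tag <- function(lab) {
    m <- regmatches(lab, regexpr("ZNXTAG(\\d{4})Z", lab))
    if (!length(m)) return(NULL)
    parse_nhx_tag(tags[[as.integer(sub("ZNXTAG(\\d{4})Z", "\\1", m))]])
  }

  leaf_species <- character(nt); gene_type <- character(nt)
  clean_tips <- sub("ZNXTAG\\d{4}Z", "", tree$tip.label)
  for (i in seq_len(nt)) {
    tg <- take_tag(tree$tip.label[[i]])
    if (is.null(tg)) stop("leaf without NHX tag: ", clean_tips[[i]], call. = FALSE)
    leaf_species[[i]] <- if ("S" %in% names(tg)) tg[["S"]] else NA_character_
    gene_type[[i]] <- if ("GT" %in% names(tg)) tg[["GT"]] else NA_character_
  }
  node_type <- character(tree$Nnode)
  if (is.null(tree$node.label)) stop("internal nodes lack D=Y/N tags", call. = FALSE)
  for (j in seq_len(tree$Nnode)) {
    tg <- take_tag(tree$node.label[[j]])
    if (is.null(tg) || !"D" %in% names(tg)) {
      stop("internal node ", j, " lacks a D=Y/N tag", call. = FALSE)
    }
    node_type[[j]] <- if (identical(tg[["D"]], "Y")) "duplication" else "speciation"
  }
  tree$tip.label <- clean_tips
  tree$node.label <- NULL
  names(leaf_species) <- clean_tips
  names(gene_type) <- clean_tips
  list(tree = tree, node_type = node_type, gene_type = gene_type,
       leaf_species = leaf_species)
}

# Build a family directly from an NHX string + named aligned sequences
# (used by tests and examples to plant exact topologies).
family_from_nhx <- function(id, nhx, seqs) {
  parsed <- read_nhx(nhx)
  reconciled_family(id = id, aln = strings_to_matrix(seqs), tree = parsed$tree,
                    node_type = parsed$node_type, gene_type = parsed$gene_type,
                    leaf_species = parsed$leaf_species)
}
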