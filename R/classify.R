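#' Classify extant genes of a reconciled family
#'
#' Every leaf is classified from the labelled tree alone: a leaf below a
#' duplication node whose species is represented on both sides of that
#' duplication is a \code{paralog}; a leaf below a duplication whose
#' sister copy was lost in its species (for every ancestral duplication)
#' is a \code{remaining_paralog}; a leaf with no duplication among its
#' ancestors is a \code{true_singleton}.
#'
#' @param family A \code{reconciled_family}.
#' @return Tibble with columns \code{gene}, \code{species}, \code{type}.
#' @export
classify_genes <- function(family) {
  stopifnot(inherits(family, "reconciled_family"))
  tree <- family$tree
  nt <- n_tips(tree)
  type <- character(nt)
  for (i in seq_len(nt)) {
    anc <- ancestors_of(tree, i)
    dups <- anc[vapply(anc, function(a) node_type_of(family, a) == "duplication", TRUE)]
    if (!length(dups)) {
      type[[i]] <- "true_singleton"
      next
    }
    sp <- family$leaf_species[[tree$tip.label[[i]]]]
    both_sided <- vapply(dups, function(d) {
      ch <- children_of(tree, d)
      side <- vapply(ch, function(c2) i %in% descendant_tips(tree, c2), TRUE)
      other <- ch[!side]
      any(vapply(other, function(o) {
        sp %in% family$leaf_species[tree$tip.label[descendant_tips(tree, o)]]
      }, TRUE))
    }, TRUE)
    type[[i]] <- if (any(both_sided)) "paralog" else "remaining_paralog"
  }
  tibble::tibble(gene = tree$tip.label, species = unname(family$leaf_species),
                 type = type)
}

#' Select eligible duplications (outgroup/paralog triplets)
#'
#' Applies the three topology filters for usable duplications: (i) the
#' duplication must be directly preceded by a speciation node (so a
#' singleton outgroup exists; duplications ancestral to the whole species
#' set are excluded), (ii) in nested duplications only the outermost is
#' retained, and (iii) a duplication whose nearest outgroup clade contains
#' a remaining paralog from a lost duplication (or any duplication node)
#' is excluded.  Multiple triplets per family are allowed when they occur
#' in parallel orthologous clades.
#'
#' @param family A \code{reconciled_family} (depth-annotated if Ks depths
#'   are wanted in the output).
#' @return Tibble with one row per eligible duplication: node ids of the
#'   duplication, its preceding speciation ancestor, the two paralog
#'   clades and the singleton outgroup clade, plus \code{ks_depth}.
#' @export
select_duplications <- function(family) {
  stopifnot(inherits(family, "reconciled_family"))
  tree <- family$tree
  nt <- n_tips(tree)
  genes <- classify_genes(family)
  gtype <- stats::setNames(genes$type, genes$gene)

  dup_nodes <- which(family$node_type == "duplication") + nt
  rows <- list()
  for (d in dup_nodes) {
    anc <- ancestors_of(tree, d)
    if (!length(anc)) next                       # duplication at the root
    has_outer_dup <- any(vapply(anc, function(a)
      node_type_of(family, a) == "duplication", TRUE))
    if (has_outer_dup) next                      # nested: keep outermost only
    spec_node <- anc[[1L]]
    if (node_type_of(family, spec_node) != "speciation") next
    sib <- setdiff(children_of(tree, spec_node), d)
    if (length(sib) != 1L) next
    out_nodes <- descendant_nodes(tree, sib)
    out_internal <- out_nodes[out_nodes > nt]
    if (any(vapply(out_internal, function(a)
      node_type_of(family, a) == "duplication", TRUE))) next
    out_tips <- tree$tip.label[descendant_tips(tree, sib)]
    if (any(gtype[out_tips] != "true_singleton")) next   # lost-duplication outgroup
    ch <- children_of(tree, d)
    n_para <- vapply(ch, function(c2) {
      sum(gtype[tree$tip.label[descendant_tips(tree, c2)]] == "paralog")
    }, 0L)
    if (any(n_para == 0L)) next
    ks <- if (is.null(family$node_depth)) NA_real_
          else family$node_depth[[spec_node]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      family = family$id, dup_node = d, spec_node = spec_node,
      clade1 = ch[[1L]], clade2 = ch[[2L]], outgroup = sib,
      ks_depth = ks
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(family = character(), dup_node = integer(),
                          spec_node = integer(), clade1 = integer(),
                          clade2 = integer(), outgroup = integer(),
                          ks_depth = double())
  }
  out
}

#' Assign duplication age classes from Ks depth
#'
#' Ages (Ks depth of the preceding speciation node) are split into three
#' classes with half-open intervals: \code{young} below the lower
#' boundary, \code{old} at or above the upper boundary, \code{mid}
#' between.  A depth exactly at a boundary falls in the upper class.
#'
#' @param ks_depth Numeric vector of Ks depths (>= 0).
#' @param boundaries Length-2 numeric, default \code{c(0.051, 0.5)}: the
#'   lower (young/mid) boundary is the published young-duplication cutoff;
#'   the upper is unspecified in the source analysis and defaults here to
#'   0.5, or use \code{\link{age_boundaries}} for cohort tertiles.
#' @return Factor with levels \code{young}, \code{mid}, \code{old}.
#' @export
assign_age_class <- function(ks_depth, boundaries = c(0.051, 0.5)) {
  if (any(ks_depth < 0, na.rm = TRUE)) stop("negative Ks depth", call. = FALSE)
  stopifnot(length(boundaries) == 2, boundaries[[1]] < boundaries[[2]])
  cls <- ifelse(ks_depth < boundaries[[1]], "young",
                ifelse(ks_depth < boundaries[[2]], "mid", "old"))
  factor(cls, levels = c("young", "mid", "old"))
}

#' Age-class boundaries from cohort tertiles
#'
#' @param ks_depth Numeric vector of cohort Ks depths.
#' @param young Optional override of the lower boundary (default
#'   \code{NULL} = first tertile); pass 0.051 to pin the published young
#'   cutoff.
#' @return Length-2 numeric boundary vector for
#'   \code{\link{assign_age_class}}.
#' @export
age_boundaries <- function(ks_depth, young = NULL) {
  qs <- stats::quantile(ks_depth, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
  lower <- if (is.null(young)) qs[[1]] else young
  upper <- qs[[2]]
  if (upper <= lower) upper <- lower + .Machine$double.eps * 100
  c(lower, upper)
}
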