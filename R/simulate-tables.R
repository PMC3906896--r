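# Synthetic per-gene data tables for the focal species: tissue expression,
# SNP counts, chromosomal locations.  Each generator takes the list
# returned by repeated generate_family() calls (elements with $family and
# $truth) and knows, through the ground truth, which paralog copy really
# evolved faster, so imposed couplings can later be recovered.

focal_genes <- function(families, focal_species) {
  dplyr::bind_rows(lapply(families, function(fg) {
    fam <- fg$family
    tips <- names(fam$leaf_species)[fam$leaf_species == focal_species]
    if (!length(tips)) return(NULL)
    copy <- as.integer(sub(".*_(\\d+)$", "\\1", tips))
    faster <- NA_integer_
    tr <- fg$truth
    if (!is.na(tr$n1) && !is.na(tr$n2) && tr$n1 != tr$n2) {
      faster <- if (tr$n1 > tr$n2) 1L else 2L
    }
    tibble::tibble(family = fam$id, gene_id = tips, copy = copy,
                   gene_type = unname(fam$gene_type[tips]),
                   length = ncol(fam$aln),
                   is_faster = ifelse(copy %in% 1:2, copy == faster, NA))
  }))
}

#' Generate a synthetic tissue expression table
#'
#' One row per extant focal-species gene.  Per-tissue values are
#' log-normal around a gene-level mean; \code{coupling} shifts the
#' log-means of a paralog pair apart, the truly faster-evolving copy
#' receiving \code{coupling * effect_size / 2} (so negative coupling gives
#' the faster paralog stochastically lower mean expression, the
#' unfinished-pseudogenization signature).
#'
#' @param families List of \code{generate_family} results.
#' @param coupling Signed coupling of expression to rate asymmetry
#'   (0 = none).
#' @param n_tissues Number of tissue columns (>= 2; default 26).
#' @param seed Integer seed.
#' @param focal_species Species whose genes get rows (default
#'   \code{"s01"}).
#' @param effect_size Log10 spread applied at |coupling| = 1
#'   (default 0.5).
#' @param tissue_sd Per-tissue log10 noise SD (default 0.3).
#' @return Tibble: \code{gene_id}, \code{tissue_01..}.
#' @export
generate_expression_table <- function(families, coupling = 0, n_tissues = 26,
                                      seed = 1, focal_species = "s01",
                                      effect_size = 0.5, tissue_sd = 0.3) {
  stopifnot(n_tissues >= 2)
  genes <- focal_genes(families, focal_species)
  withr::with_seed(as.integer(seed), {
    rows <- lapply(split(genes, genes$family), function(g) {
      mu_fam <- stats::rnorm(1, 1, 0.4)
      shift <- rep(0, nrow(g))
      shift[which(g$is_faster)] <- coupling * effect_size / 2
      shift[which(!g$is_faster)] <- -coupling * effect_size / 2
      vals <- lapply(seq_len(nrow(g)), function(i) {
        10^stats::rnorm(n_tissues, mu_fam + shift[[i]], tissue_sd)
      })
      m <- do.call(rbind, vals)
      colnames(m) <- sprintf("tissue_%02d", seq_len(n_tissues))
      dplyr::bind_cols(tibble::tibble(gene_id = g$gene_id),
                       tibble::as_tibble(m))
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a synthetic SNP count table
#'
#' One row per focal-species gene with synonymous / non-synonymous SNP
#' and site counts.  Site counts follow the usual codon budget
#' (about 1/4 of the 3L nucleotide sites synonymous); SNP counts are
#' Poisson at fixed per-site densities.  Positive \code{kaks_coupling}
#' multiplies the non-synonymous density of the truly faster paralog up
#' and its partner down, so the faster copy accumulates a higher
#' polymorphism Ka/Ks.
#'
#' @inheritParams generate_expression_table
#' @param kaks_coupling Signed coupling of SNP Ka/Ks to rate asymmetry.
#' @param theta_syn,theta_nonsyn Per-site SNP densities (defaults 0.045
#'   and 0.015: roughly five SNPs of each class on a 150-residue gene, a
#'   resequencing-panel-like density that leaves a realistic minority of
#'   genes below the three-SNP eligibility filter).
#' @param effect Log-scale multiplier strength at |coupling| = 1
#'   (default 0.35).
#' @return Tibble: \code{gene_id}, \code{n_syn}, \code{n_nonsyn},
#'   \code{sites_syn}, \code{sites_nonsyn}.
#' @export
generate_snp_table <- function(families, kaks_coupling = 0, seed = 1,
                               focal_species = "s01", theta_syn = 0.045,
                               theta_nonsyn = 0.015, effect = 0.35) {
  genes <- focal_genes(families, focal_species)
  withr::with_seed(as.integer(seed), {
    mult <- rep(1, nrow(genes))
    mult[which(genes$is_faster)] <- exp(kaks_coupling * effect)
    mult[which(!genes$is_faster)] <- exp(-kaks_coupling * effect)
    sites_syn <- round(0.75 * genes$length)
    sites_nonsyn <- round(2.25 * genes$length)
    tibble::tibble(
      gene_id = genes$gene_id,
      n_syn = stats::rpois(nrow(genes), theta_syn * sites_syn),
      n_nonsyn = stats::rpois(nrow(genes), theta_nonsyn * sites_nonsyn * mult),
      sites_syn = sites_syn,
      sites_nonsyn = sites_nonsyn)
  })
}

#' Generate a synthetic chromosomal location table
#'
#' Paralog pairs are placed in one of the four relative-location
#' categories (different arms; same arm, distant; tandem collinear;
#' tandem inverted) with fixed frequencies; other focal genes get random
#' positions.
#'
#' @inheritParams generate_expression_table
#' @param category_probs Sampling probabilities over the four categories.
#' @param tandem_threshold Gap in bp separating tandem from distant
#'   (default 5000).
#' @return Tibble: \code{gene_id}, \code{arm}, \code{start}, \code{end},
#'   \code{strand}.
#' @export
generate_location_table <- function(families, seed = 1, focal_species = "s01",
                                    category_probs = c(0.4, 0.3, 0.2, 0.1),
                                    tandem_threshold = 5000) {
  genes <- focal_genes(families, focal_species)
  arms <- c("X", "2L", "2R", "3L", "3R", "4")
  withr::with_seed(as.integer(seed), {
    rows <- lapply(split(genes, genes$family), function(g) {
      span <- g$length * 3L
      start <- sample.int(2e7, nrow(g))
      arm <- sample(arms, nrow(g), replace = TRUE)
      strand <- sample(c("+", "-"), nrow(g), replace = TRUE)
      pair <- which(g$copy %in% 1:2 & g$gene_type == "paralog")
      if (length(pair) == 2L) {
        cat4 <- sample(location_levels(), 1L, prob = category_probs)
        a <- pair[[1]]; b <- pair[[2]]
        if (cat4 == "different_arms") {
          arm[a] <- "2L"; arm[b] <- "2R"
        } else {
          arm[b] <- arm[a]
          gap <- if (cat4 == "same_arm_distant") {
            tandem_threshold + sample.int(1e6, 1L)
          } else sample.int(tandem_threshold - 1L, 1L)
          start[b] <- start[a] + span[[a]] + gap
          strand[b] <- if (cat4 == "tandem_inverted") {
            if (strand[a] == "+") "-" else "+"
          } else strand[a]
        }
      }
      tibble::tibble(gene_id = g$gene_id, arm = arm, start = start,
                     end = start + span, strand = strand)
    })
    dplyr::bind_rows(rows)
  })
}
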