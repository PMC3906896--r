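---
title: "Measuring substitution-rate asymmetry between paralogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring substitution-rate asymmetry between paralogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupasym)
```

## The question and the design

After a gene duplicates, the two copies need not evolve at the same rate:
relaxed purifying selection in one copy (up to unfinished
pseudogenization), neofunctionalization, or epistatic release can all make
one paralog accumulate amino-acid substitutions faster than its twin.
`dupasym` measures that asymmetry on reconciled gene families — an
amino-acid alignment plus a gene tree whose internal nodes are labelled as
speciation or duplication events — and relates it to expression and
polymorphism differences between the copies.

The design choice that anchors everything is the *reference point*: each
pair of paralog clades is compared not to each other directly but to the
ancestral sequence reconstructed at the **speciation node directly
preceding the duplication**, whose sister clade is the nearest singleton
ortholog.  This matches each duplication with its phylogenetically closest
non-duplicated control, and it lets concerted evolution show up (as
substitutions apparently occurring "in both copies" on the short edge
between the speciation and duplication nodes — these are deliberately
credited to both paralog clades).  The cost of the convention is
conservative: the paralogs spent an unknown time evolving as a single gene
before duplicating, which biases the measured paralog/singleton contrast
and the measured asymmetry downward, never upward.

Three topology filters define a usable duplication: the duplication must
be directly preceded by a speciation node (duplications ancestral to the
whole species set have no singleton outgroup); in nested duplications only
the outermost is kept; and the outgroup clade must be a clean singleton —
if it contains a surviving copy of a lost duplication (a *remaining
paralog*) or any duplication node, the triplet is discarded.  More than
one triplet per family is allowed in parallel orthologous clades.

## Ancestral reconstruction

Per divergent alignment column we enumerate **all** equally parsimonious
ancestral reconstructions (unit-cost Sankoff dynamic programming; with
unit costs every optimal labeling uses only residues observed at the
leaves, so the enumeration over the observed alphabet is exhaustive).
Ties are resolved probabilistically rather than arbitrarily: from the
unambiguous sites of the whole corpus we build 20×20 relative-frequency
matrices of (ancestral, derived) residue pairs in 10 bins of phylogeny
depth (Ks units), and the posterior of a reconstruction is the normalized
product of the bin-matrix frequencies of its implied substitutions.  A
site with a unique reconstruction gets posterior 1; per site the
posteriors sum to 1 by construction.

Numerical choices worth knowing:

* a pseudo-count of 0.5 per matrix cell avoids zero weights; bins with no
  observed events fall back to the pooled matrix;
* the depth of a substitution is the Ks depth of the child node of its
  edge; duplication nodes are dated by the upper-bound rule (depth of the
  nearest ancestral speciation node), the same convention used to
  normalize rates (relKa = Ka / Ks depth) and to assign age classes;
* tie enumeration is capped (default 64 alternatives per site); past the
  cap posteriors fall back to uniform over the enumerated set, bounding
  runtime on pathological columns;
* the posterior weight of a reconstruction is the per-substitution product
  of matrix frequencies — the simplest likelihood-flavoured use of the
  matrices; nothing downstream depends on more than the relative weights
  of alternatives at one site.

Alignment regions around indels are excluded before any of this: every
gap run longer than one residue is masked together with five flanking
columns on each side (clipped at the bounds), column-wise for the whole
family.  Masking family-wide (rather than per sequence pair) is the
conservative reading of quality filtering; terminal gap runs are treated
like internal ones.

## The asymmetry statistic

For one duplication let `N1`, `N2` be the posterior-weighted substitution
counts between the reference ancestor and the two paralog clades' leaves
(paths pooled over eligible leaves; remaining paralogs excluded), and
`L1`, `L2` the matching usable alignment lengths.  With
`p_i = N_i / L_i` and `p = (N1 + N2) / (L1 + L2)`,

```
Z^2 = (p1 - p2)^2 / [ p (1 - p) (1/L1 + 1/L2) ]
```

the squared normal deviate of the two-proportion comparison.  Its null
expectation is 1 under equal rates and uniform sites, independent of
divergence and of unequal lengths — which is what makes it comparable
across thousands of pairs, unlike the classical `A = (N1-N2)^2/(N1+N2)`
(related by `Z^2 = A/(1-p)` at equal lengths).  `z_squared()` implements
the plain statistic used as the *measure*; significance uses the
Yates-corrected chi-square of the 2×2 sites-by-lineage table
(`asymmetry_pvalue()`), with posterior-weighted counts rounded
half-to-even only for the continuity-corrected table (the correction is
defined on counts).  Multiple testing is controlled family-wise
(Bonferroni at α = 0.05) and by Benjamini–Yekutieli FDR at q = 0.1, the
step-up rule valid under arbitrary dependence.  For regression analyses
Z² is log10-transformed, which forces removal of Z² = 0 pairs (exactly
equal counts).

Radicality of the substitutions in a clade is summarized as the
posterior-weighted mean absolute polarity change (|dPolarity|, Grantham
polarity by default) and the posterior-weighted mean directional
exchangeability EX[ancestral → derived].  Only posterior weights enter
these means (no length weighting — they are per-substitution, not
per-site, quantities).  The EX matrix shipped with the package is a
clearly-labelled synthetic stand-in with the right structure (bounded,
directional, correlated with polarity distance); substantive radicality
claims should substitute a measured matrix via `read_ex_matrix()`.

## The null simulator

`simulate_pair()`/`null_curve()` characterize how Z² behaves when the
null of equal per-copy rates is true but sites are heterogeneous.  Events
are scheduled discretely — each event picks a (copy, site) with
probability proportional to current rates until the pair reaches a target
mean Ka — and `n_i` counts *distinct* substituted sites, matching the
"sites with substitutions" entering Z².

Two findings the simulator reproduces, and one modelling decision it
forced:

* with near-uniform rates (gamma shape 20) mean Z² stays at 1 across
  divergence, and a 500/400-length pair behaves exactly like 500/500;
* leptokurtic site rates (shape 0.5) pull the null expectation *below* 1
  as divergence grows — observed asymmetry must beat that depressed
  baseline, not 1;
* that depression only appears when the two copies **share** their
  per-site rate draws.  We checked both variants: with independent draws
  the copy-specific effective target sizes differ and the depression
  vanishes (mean Z² ≈ 1.02 at Ka = 0.3, shape 0.5, versus 0.71 with
  shared draws).  Since a site's rate is a property of the protein
  structure both fresh duplicates inherit, shared draws are the default
  and independent draws remain available as `shared_rates = FALSE`.

Epistasis is modelled as designated sites that, once substituted in a
copy, multiply all other rates in that copy by a factor; five such sites
at factor 2 push mean Z² well above 1 already at Ka = 0.1.  This is the
caveat attached to every significant asymmetry: it can reflect unequal
constraint *or* epistatic release under identical constraint; the two are
not distinguishable from counts alone.

## What the synthetic-data generator emulates — and what it does not

`generate_family()` plants one duplication on a chosen species-tree edge
(duplication time at the edge midpoint by default) and evolves sequences
by a uniform 20-state exchange model with per-site gamma rate multipliers
(shape 2 by default — the moderate heterogeneity level used as the
plausible upper line in the real-data comparison; shape 20 approximates
uniform rates).  Branch lengths are the species tree's Ks spans scaled by
a constraint factor `ka_ks` (default 0.2, a typical protein level;
`ka_ks = 1` is the neutral Ks clock under which relKa calibrates to ≈ 1).
Ground truth — per-edge event counts and per-clade path sums from the
pre-duplication ancestor — is recorded so every downstream stage has a
parameter-recovery surface.  Optional dials: an imposed rate ratio
(copy 1 faster), homogenization of the first `concerted_until` Ka below
the duplication (implemented on the stem edges only — a full
gene-conversion model across later branches is out of scope), programmed
paralog loss (to plant remaining-paralog leaves), and multi-residue
indels for the masking filter.

Companion tables emulate the statistical structure of tissue-expression,
polymorphism and location data: log-normal expression over 26 tissues
with a coupling that shifts the truly faster copy's log-mean (negative
coupling = faster copy less expressed); Poisson SNP counts at
resequencing-panel-like densities (≈ 5 synonymous and ≈ 5 non-synonymous
SNPs on a 150-residue gene, so a realistic minority of genes fails the
≥3/≥3 eligibility filter) with a Ka/Ks coupling; and paralog pairs placed
in the four relative-location categories (different arms / same arm
distant / tandem collinear / tandem inverted, 5 kb gap threshold).

What the generator does **not** emulate: codon-level evolution with
realistic dN/dS, exchange-matrix structure (uniform exchanges are enough
because no analysis stage depends on the generator's matrix), real tissue
correlation structure, gene birth–death across the tree, or alignment
error beyond clean indels.  Passing parameter-recovery tests therefore
demonstrates that the *pipeline* recovers what the model plants, not that
real data satisfy the model.

## Polarized expression and polymorphism differences

For focal-species pairs, per-gene profiles are summarized as log10 mean
expression, the coefficient of variation across tissues, and
Shannon-entropy evenness (H(shares)/ln n, in [0, 1]; the evenness formula
of the original ubiquity reference is not reproduced in the source
analysis, so this standard form is used and isolated behind
`expression_summary()` — by construction it mirrors CV with the opposite
sign).  Signed differences are polarized by divergence: `d_me`, `d_cve`,
`d_kaks` are (faster copy − slower copy), orientation decided by the
estimated clade Ka; pairs with exactly equal Ka carry no orientation and
are excluded, consistently with the Z² = 0 removal.  The 5 kb tandem rule
uses the *gap* between gene spans (not midpoints; overlapping spans count
as distance 0).  Pairs whose two paralogs map to one expression record
are dropped.  `analysis_battery()` then runs the standard test set:
one-sample t and sign tests per subset (all pairs, Z² > 1,
FDR-significant), Fisher's exact test of faster/slower × higher/lower
expression, regressions on log10 Z², the two-covariate-plus-location
ANOVA of log10 Z², and half-log-unit binned summaries.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one CPU: null-calibration batches
of 2000 simulated pairs (Monte-Carlo SE of mean Z² ≈ 0.03), null curves
at 500 replicates per grid point, reconstruction cohorts of 20–40
families of 150–300 residues on 4–12 species, and 100 replicate
expression cohorts of 300 pairs for the type-I control.  Every stochastic
stage takes an explicit integer seed and is reproducible bit-for-bit;
`run_pipeline()` records seeds and stage funnel counts in a JSON
manifest.

## Known limitations

* Parsimony undercounts multiple hits; at neutral depths (relKa ≈ 1 at
  Ks ≈ 0.25) the calibration tests tolerate ≈ 10–20% downward bias, and
  deep clades (Ks ≫ 0.5) should be interpreted through relKa, not raw Ka.
* Posterior tie-resolution uses corpus-level matrices; for tiny corpora
  the pseudo-count dominates and posteriors approach uniform.
* The duplication age is only ever an upper bound (the preceding
  speciation), so age classes are conservative for young duplications.
* The battery treats parallel triplets within a family as independent
  records, as the underlying design does; families contributing several
  duplications are correspondingly over-weighted.
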