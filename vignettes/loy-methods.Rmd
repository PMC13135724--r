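---
title: "Methods: LOY calling, trajectory enrichment and X-inactivation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LOY calling, trajectory enrichment and X-inactivation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models implemented in `loytraj`,
the assumptions behind them, the synthetic-cohort generator used to
validate every estimator, and the numerical choices made where the
underlying procedures leave room for interpretation.

## The LOY call

A male cell is classified as having lost chromosome Y when the summed UMI
count over genes of the male-specific region (MSY; GRCh38
chrY:2,781,480–56,887,902, 1-based inclusive) is zero in **both** of two
independent counting sources.  The rule is deliberately asymmetric:

* any stray MSY read — ambient RNA, barcode swapping — blocks the call, so
  contamination produces false negatives only;
* true LOY cells are recovered unless ambient reads land on them, and
  non-LOY cells can be misclassified only by sampling zeros (low depth and
  Poisson chance), which is why the UMI sensitivity filter
  (`umi_sensitivity_filter()`) exists.

MSY membership requires a gene to lie entirely inside the MSY span.  Genes
straddling a boundary are excluded — a conservative containment rule,
chosen because the source material defines the region by coordinates but
not the membership convention; containment favours specificity, in the same
spirit as the zero-read rule.  Cells with zero total UMI in both sources
are uninformative and flagged `NA` rather than called.  Female cells keep
their MSY totals (a useful contamination diagnostic) but receive no LOY
flag.

## Donor clonality and the age model

Per-donor LOY percentages are bounded in [0, 100] and include donors at
exactly 0%, so the donor-level age regression uses the empirical logit
`log((x + 0.5)/(n − x + 0.5))`.  A smoothing rule is mandatory here — a
plain logit is undefined for 0% donors — and the additive-half convention
is the standard minimally-informative choice.  Covariates are sequencing
pool and up to ten genotype principal components; constant or aliased
covariates are dropped with a flag rather than failing the fit.  *Expanded
clonality* is LOY in ≥ 10% of a donor's assayed cells, with the boundary
(exactly 10%) counted as expanded.

SNP-array concordance is the Pearson correlation between the single-cell
per-donor fraction and the array clonal fraction, with the Fisher-z
interval and Benjamini–Hochberg adjustment across cell types.  The
LOY-versus-mCA independence test is a Pearson chi-square without continuity
correction (so that the statistic matches the textbook formula exactly);
an empty margin falls back to Fisher's exact test, flagged in the output.

## Preprocessing

QC metrics (UMI total, genes detected, mitochondrial fraction) are mapped
to Z-scores through their ranks, `Z = Φ⁻¹((rank − ½)/n)` with average ranks
for ties.  Cells with any metric below Z = −3 are removed, plus cells at or
above Z = +2 on the mitochondrial fraction.  A rank-based rule is
self-calibrating but **not idempotent**: re-running the filter re-ranks the
survivors and the top ~2.3% of mitochondrial fractions will always exceed
+2 again.  The filter is therefore applied once, as in the original
workflow; the tests assert the tied-metric (no-removal) fixed point and the
single-pass contract.

Normalization is `log(1 + count/total × 10⁴)`; it depends only on
within-cell proportions.  Highly variable genes are ranked by the ratio of
observed to trend-expected variance, where the trend is a robust loess of
log variance on log mean computed on the de-logged (library-size-scaled)
values — overdispersion is much easier to see on that scale than after the
log transform.  Scaling regresses each gene on per-cell covariates
(mitochondrial fraction, pool), standardizes residuals and clips at ±10
before PCA (30 components by default).

Cluster validation takes any deterministic clustering as input (community
detection itself is a pluggable contract) and tests each cluster
one-vs-rest for upregulation of each candidate type's markers by one-sided
Wilcoxon rank-sum, Bonferroni-corrected within cluster at α = 0.05 — the
threshold the source procedure leaves unstated.  A cluster is labelled only
if all markers of the best-supported type are significant; clusters
expressing contamination markers (e.g. CD3 genes in a myeloid subset) are
excluded outright.

## Trajectories and quantile models

Pseudotime is fitted by an iterative principal-curve projection: bin cells
along the current ordering, average the embedding coordinates per bin into
a polyline, lightly smooth it, re-project all cells, and iterate.  Because
a symmetric manifold can make the first principal component orthogonal to
the true parameter, the iteration is started from PC1 *and* from each raw
coordinate, and the solution with the smallest total projection error wins;
all starts are deterministic, so the fit is reproducible and invariant to
row order.  The curve is oriented by the designated start/end clusters and
scaled to [0, 1].  Embeddings are pluggable: any low-dimensional
representation can be supplied.

Cells are split into six equal-count pseudotime quantiles.  Equal-count
bins are ill-defined under ties, so ties are broken by the stable
(pseudotime, barcode) lexicographic order, making the labelling
deterministic and invariant to monotone relabelling of pseudotime.

The LOY-versus-position models are logistic regressions with the quantile
entered as a single numeric slope — one odds ratio per quantile step —
because a single OR per trajectory is the reported quantity; an ordinal
coding would produce five.  Variants: univariate; multivariate (age, pool,
ten PCs); multivariate plus the rs2887399 additive dosage (G/G = 0,
G/T = 1, T/T = 2).  Confidence intervals are Wald; perfect separation is
detected and handled by a Firth-type (Jeffreys-prior) penalized fit,
flagged in the output.  Age-stratified refits split donors (not cells) at
the median donor age.

## Differential expression

The two-part hurdle model handles the zero inflation of UMI data: a
logistic regression of detection (count > 0) on the group indicator plus
the centred per-cell detection rate, and a Gaussian regression of the
log-normalized values over expressing cells on the same design.  The two
likelihood-ratio chi-squares are summed and referred to a chi-square with
the combined degrees of freedom; when fewer than two expressing cells per
group exist the continuous part is skipped and the discrete part stands
alone with one degree of freedom.  The detection-rate covariate is the
standard guard against cellular detection-efficiency confounding.  Filters:
detection in ≥ 1% of the cells of at least one group (the Seurat `min.pct`
convention, which the module contract adopts) and |average log2 FC| ≥ 0.1,
with `avg_log2fc = log2((mean(expm1 x)+1)₁/(mean(expm1 x)+1)₂)`.  Bonferroni
adjustment uses the number of genes actually tested in the run, recorded in
the output metadata.

The proportion-expressing pseudobulk test aggregates detection to one
proportion per (donor, group) and compares donor-level proportions with a
two-sided Wilcoxon rank-sum: exact by full enumeration of group assignments
when the smaller stratum has ≤ 8 donors (ties handled exactly), otherwise
the normal approximation with tie-corrected variance and continuity
correction.  The effect is the plain difference of donor-mean proportions
over donors contributing both strata; the minimum-effect filter (0.1)
operates on that difference, since the statistic is a proportion.  One
caveat worth knowing: with very few LOY cells per donor the LOY-stratum
proportions are coarse (multiples of 1/n), and rank-sum granularity can
slightly inflate the nominal level; the calibration experiments size donors
and cells so proportions are fine enough.

## X-inactivation analysis

X genes are classified as PAR (by GRCh38 PAR1/PAR2 coordinates —
X:10,001–2,781,479 and X:155,701,383–156,030,895, the assembly-standard
spans), or by the curated class (escape / inactive / variable) for non-PAR
genes, defaulting to unclassified.  A coordinate-based PAR assignment
overrides any curated class: the locus is a fact, the curated class a
tissue-derived inference.  The variable class is summarized but excluded
from the headline up-versus-down comparison, which covers the three named
groups.

Direction statistics count, per cell type and class, the members
significantly up or down (adjusted p < 0.05, sign of the fold change), roll
genes up across cell types (up-only / down-only / both), and compare %up
against %down across cell types by rank-sum.

### The dip test

Hartigan's dip — the smallest sup-norm distance between the empirical CDF
and any unimodal CDF — is implemented from scratch in C++ using the
classical modal-interval narrowing algorithm over the greatest convex
minorant and least concave majorant.  For distinct samples the statistic
lies in [1/(2n), ¼].  Two properties worth stating precisely:

* the dip is location-scale invariant, but **not** invariant under general
  monotone transforms — it cannot be, since a rank transform maps any
  sample to equally spaced values whose dip is the minimal 1/(2n); and
* significance is assessed against a uniform reference (the classical
  calibration: the uniform is the asymptotically least-favourable unimodal
  null), by drawing `n_boot` uniform samples of the same size and reporting
  the fraction whose dip exceeds the observed one, with a fixed seed for
  exact reproducibility.

Because single-cell expression is zero-inflated, the test runs on the full
vector and on the non-zero subset (default report includes both).  Constant
vectors are degenerate: dip 0, p 1, flagged.

## Dynamics

For each gene expressed (detected in ≥ 1% of cells — the per-quantile
expression criterion the source procedure leaves undefined) in at least
three of the six quantiles, a basic mixed model
`y ~ LOY + quantile (+ quantile²) + age + PCs + (1 | donor)` is compared by
likelihood ratio (maximum-likelihood fits) with an augmented model adding
`LOY × quantile` (and `LOY × quantile²` in the quadratic form).  The
response is the log-normalized expression, a continuous approximation
appropriate for a linear-model framing; a count-model variant is out of
scope.  Boundary (singular) random-effect fits are accepted — they are the
correct ML solution when the donor variance is estimated at zero — and only
hard failures fall back to a fixed donor-intercept model, flagged.  With a
handful of donors the chi-square reference for the LRT is known to be
slightly liberal; the calibration experiments quantify this and it stays
within two points of nominal at the default design.

## Overrepresentation

Selected genes (adjusted p below α and fold change beyond the cutoff, up
and down separately, cutoffs 0.25/0.5/0.75) are tested against each gene
set with the upper-tail hypergeometric probability — identical to the
one-tailed Fisher exact test, which the test suite verifies on random
tables.  The universe is the set of genes tested in the DE run (the
conservative standard), sets are intersected with it, and the overlap ratio
is overlap divided by the set's size within the universe.  BH adjustment is
applied within one (direction, cutoff) family.

## The synthetic cohort generator

`sim_truth()` fixes the generative parameters; they are the study
conditions, not tuning knobs:

* **Donors**: ages drawn from an elderly-cohort pyramid (bins 19–38, 39–58,
  59–78, 79–93 weighted 43:69:227:77; median ≈ 68); logit clonal fraction
  linear in age with slope 0.013/year, intercept −3.3 and donor SD 0.8,
  reproducing per-donor prevalences from about 1% to the mid-50s%; a noisy
  SNP-array fraction (Gaussian SD 0.05, censored below the 0.02 array
  detection floor); rs2887399 dosage at T-allele frequency 0.3; an mCA flag
  independent of LOY at rate 0.06.
* **Cells**: cell types drawn from the observed composition; within an
  active lineage (both member types present) the subtype label derives from
  pseudotime at the composition-matched threshold and the LOY offset uses
  the lineage-pooled base rate, so the per-quantile log-odds step — e.g.
  log(0.91) on the monocyte transition — is the *single* source of the
  within-lineage gradient and is exactly the estimand of the quantile
  logistic model.  Types without their lineage partner are standalone with
  their own base rate.
* **MSY counts**: non-LOY cells draw Poisson totals with depth-scaled mean
  5 per source; LOY cells draw only Poisson ambient reads (default rate
  0.2 per source — a free parameter, since no contamination estimate is
  available to copy) independently per source.
* **Expression**: negative binomial with gene-specific log-normal
  baselines, common dispersion 0.5 (a typical UMI-data value; no generative
  model is prescribed by the source), depth scaling, and planted log2
  effects in LOY cells of designated types.  XIST follows a two-component
  mixture in LOY cells (silent Poisson component, mean 0.02; active
  negative-binomial component, mean 40, weight 0.1), giving a bimodal
  non-zero distribution.  The active-component mean is set high enough that
  bimodality is resolvable at desk-scale cell counts on the normalized log
  scale.
* **Determinism**: one master seed; each stage derives an independent child
  stream, so adding a stage never perturbs earlier draws and identical
  seeds give byte-identical cohorts.

What the generator does **not** emulate: doublets, batch chemistry,
realistic full transcriptomes (a small gene panel suffices), branching
trajectories, and one inconsistency inherited from the observed numbers —
the Treg-versus-other-CD4 subtype contrast (OR ≈ 2.4) is far larger than a
six-quantile linear gradient of OR 1.04 can produce, so the generator's
realized Treg rate sits below the observed per-type table.  Passing tests
on this cohort therefore demonstrate estimator correctness under the stated
model, not robustness to everything real data can do.

## Validation experiment sizes

The `recovery_*()` and `calibration_*()` drivers use desk-scale designs
chosen analytically for coverage and level before any results were
inspected: slope recovery with 400 donors × 150 cells × 150 replicates;
per-quantile OR with 30 donors × 140 cells × 120 replicates (about 4,200
monocyte-lineage cells per replicate keeps the small marginalization
attenuation from donor heterogeneity well inside the Wald interval);
interaction recovery with 25 donors × 160 cells × 100 replicates; null
calibrations sized for ≥ 200 p-values per method with donor-level
proportions fine enough that rank-sum granularity does not distort the
level (e.g. 150 cells/donor for the pseudobulk null).  The acceptance
script (`scripts/acceptance.R`) re-runs all of these from scratch.

## Known limitations

* The percentile-Z QC rule is single-pass by construction (see above).
* The dip test's uniform-null bootstrap is the classical calibration, not a
  sample-specific null; heavily tied data (raw small counts) can look
  multimodal to any dip-type statistic, which is why the test is run on
  normalized values and on the non-zero subset.
* The mixed-model LRT is mildly liberal with very few donors.
* Separation in the logistic models is handled by a Firth-type fit with
  Wald intervals; profile-likelihood intervals are not implemented.
* The hurdle model uses a Gaussian continuous part on log-normalized
  values; a count-likelihood variant is out of scope.
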