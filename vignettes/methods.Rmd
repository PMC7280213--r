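---
title: "From spatial marker gradients to partitioned heritability: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spatial marker gradients to partitioned heritability: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradh2)
```

`gradh2` implements an analysis chain that asks three linked questions about
inhibitory interneuron biology and in-vivo brain function:

1. Are the transcripts of two interneuron marker genes (somatostatin, *SST*,
   and parvalbumin, *PVALB*) anti-correlated across the cortical sheet, and
   is that anti-correlation extreme relative to what any two genes show?
2. Do common genetic variants near genes that spatially co-express with a
   marker explain a disproportionate ("enriched") share of the heritable
   variance of a regional brain phenotype (resting-state fluctuation
   amplitude, RSFA), and does that share track the marker's own expression
   map across regions?
3. Is psychiatric (schizophrenia-like) polygenic risk concentrated in the
   marker-correlated gene sets, and do individual risk scores predict the
   regional phenotype preferentially where the marker is expressed?

Every statistic the package reports is exercised end to end on synthetic
data with known ground truth, because the original inputs (donor brain
microarrays, biobank imaging genetics, consortium GWAS) are restricted or
far beyond desk scale.  This vignette records the models, the defaults, the
numerical choices, and what passing the test-suite does and does not show.

## The spatial model and its statistics

Expression atlases are samples-by-genes matrices with donor, region and
3-D coordinate annotations.  Because microarray intensities are only
comparable within a probe, every analysis starts from within-region
z-scoring (`normalize_within_region()`): per gene and per anatomical
region, subtract the mean and divide by the sample SD (denominator
n&nbsp;&minus;&nbsp;1).  The sample-SD convention is used everywhere in the
package; the worked examples in the tests are chosen so the choice is
visible (`[1, 2, 3]` normalizes to `[-1, 0, 1]`).  Zero-variance genes
within a region are set to zero with a warning rather than dropped, so
matrix shapes survive.  Donor batch effects can be absorbed by per-donor
mean-centering (`center_donors = TRUE`), a deliberately minimal adjustment
that preserves spatial gradients; it is off by default because the
synthetic generator does not simulate donor batches.

The marker-difference map is the per-sample `z(SST) - z(PVALB)` contrast,
averaged within parcels of a fixed parcellation.  Samples are attached to
parcels by nearest-centroid assignment with a 4 length-unit exclusion
radius (`map_samples_to_parcels()`), mirroring the distance rule used when
projecting tissue samples to an imaging atlas; ties go to the lowest
parcel id so assignment is deterministic.

How unusual is an observed two-gene correlation?  `null_auc()` ranks it
within two reference distributions: the correlations of every other gene
with the anchor gene, and the correlations of all G(G-1)/2 two-gene
pairings.  The AUC is the fraction of reference correlations at or below
the observed one — small values mean "among the most negative pairs in the
transcriptome".  Two conventions needed fixing where the field's
descriptions are ambiguous, and both are decided (not configurable):

* the reference excludes the anchor's self-correlation but **includes** the
  partner gene, so a duplicated column attains AUC = 1 and the observed
  pair itself always contributes to the pair null;
* correlations within 1e-12 of the observed value count as ties and are
  included, so the AUC does not depend on whether a correlation was
  computed by `cor()` or by a blocked matrix product.

The pair null is enumerated in fixed-size column blocks (150&nbsp;million
pairs at full scale is a streaming problem, not a memory problem), and a
seeded random subsample of pairs can stand in for the full enumeration;
with `pair_subsample = Inf` the streamed result is bit-for-bit the
brute-force enumeration, which the tests verify on 50-gene fixtures.

`spatial_coupling()` is the package's single currency for "do two maps
agree": Pearson (default) or Spearman correlation over jointly valid
parcels, or, when a covariate map is supplied, the standardized
coefficient of the predictor map from a two-regressor OLS — used to show a
coupling survives controlling for total SNP heritability.  Outlier parcels
are removed jointly across a family of maps (`exclude_outliers()`, default
4 SD, moments computed once on pre-exclusion values; a zero-SD map excludes
nothing).

## Synthetic data: what it emulates, what it does not

`sim_config()` fixes the study conditions once; generators derive
fixed child seeds from the single global seed, so adding one generator
never perturbs another's draws, and every output is bitwise reproducible.

* **Expression** (`gen_expression_atlas()`): parcels sit on a 1-D
  anterior-posterior gradient (equally spaced scores on [-1.5, 1.5]);
  marker A loads `+gradient_strength` (default 0.8), marker B the
  negative, background genes load N(0, 0.3), and all values get N(0, 0.5)
  noise.  Under these defaults the marker correlation is about -0.6 to
  -0.7 and both AUC statistics fall well below 0.05 — the qualitative
  regime of the real atlases, not a numerical imitation of them.
* **Single-cell profiles** (`gen_single_cell_profiles()`): each type gets
  exclusive marker genes with a 4-fold elevated mean and log-normal
  within-type noise; the first two types carry the two atlas markers, so
  deconvolved fraction maps have a ground-truth spatial pattern.
* **Genotypes** (`gen_genotypes()`): dosages are binomial(2, p) with
  p ~ U(0.05, 0.5), LD-free by default so clumping is a no-op and REML and
  PRS ground truth are exact; an AR(1) latent block-LD option exists for
  clump testing (the latent correlation attenuates on the dosage scale).
  SNPs sit at 1 kb spacing on one synthetic chromosome so the bundled gene
  annotation (2 kb bodies every 4 kb) tiles them through ±5 kb windows.
* **Phenotypes** (`gen_phenotypes()`): per parcel,
  `y = sum_k Z_k u_k + X c + e` with per-SNP effects
  `u_k ~ N(0, h2_k / g_k)` on standardized dosages, age/sex covariates
  with small fixed effects, and (optionally) a subtracted, parcel-weighted
  polygenic liability shared with the summary-statistic generator — the
  mechanism that creates a spatially patterned PRS association.  The
  realized genetic variance per partition is returned as ground truth.
* **Summary statistics** (`gen_summary_stats()`): a continuous liability
  in an independent cohort drawn from the same frequency spectrum, per-SNP
  effect variance multiplied by the enrichment factor inside the causal
  set, then one OLS per SNP.  A continuous liability (not case/control) is
  used because the downstream consumers only need betas, SEs and p-values.

What the generator does **not** emulate: microarray probe chemistry,
imputation quality scores, LD beyond the toy AR(1) blocks, cryptic
relatedness, donor batches, and vascular or motion structure in the
amplitude phenotype.  Passing tests therefore demonstrate that the
estimators recover the truth under their own assumptions at desk scale;
they do not certify performance on biobank data.

## Deconvolution

`build_signature()` reduces labeled single-cell profiles to per-type mean
profiles restricted to the union of top marker genes; the marker score is
log2 fold-change times -log10 of a Wilcoxon rank-sum p-value, with ties
broken by gene id.  `estimate_fractions()` fits each bulk sample by
non-negative least squares on the signature columns and renormalizes to
the unit simplex, recording the residual norm.  This deliberately replaces
the reference tool's unpublished support-vector machinery with a fully
specifiable estimator that satisfies the same simplex contract and is
exact on noiseless mixtures.  One scaling subtlety matters: each bulk
sample is library-size scaled, but the signature matrix is scaled by a
*single global factor* — a per-column scaling would silently distort the
recovered mixture weights.  Fractions from samples aggregate to per-type
parcel maps, and all type-pair difference maps can be ranked by absolute
coupling against a target map (the analysis that asks "which cell-type
contrast best explains the amplitude map?").

## Gene sets, SNP partitions, and the competitive test

Gene sets are nominated by guilt-by-association: genes ranked by spatial
correlation to a marker (the marker itself ranks first — the field leaves
this unstated; including it is the decision here), cut into consecutive
bins of `top_k` (default 500).  SNPs map to a set when they fall within
±5 kb (closed interval, 1-based inclusive) of a member gene or appear in
an eQTL link table.  Named partitions are made disjoint by removing SNPs
shared between them from *all* named sets (the conservative reading of
"non-overlapping"); together with the remainder partition the outputs tile
the genotyped SNP set exactly, which the tests assert as a conservation
law.  Coordinates are 1-based inclusive internally; the BED writer
converts to 0-based half-open at the file boundary only.

The competitive gene-set test assigns each gene the mean chi-square
(squared z = beta/se) of its window SNPs and regresses gene statistics on
bin membership with log(SNP count) and gene length as covariates,
one-sided for positive coefficients; the trend statistic is the Spearman
correlation between bin index and bin coefficient.  Mean chi-square (not a
PCA-based multi-SNP model) is appropriate here because the synthetic
genotypes are LD-free; the covariate pair mirrors the size correction of
standard competitive tests.  Degenerate inputs are defined away: identical
gene statistics give beta 0 and p 1; bins without analyzable genes are
dropped with a warning.

## Variance components: GRM, AI-REML, the mixture test, enrichment

The GRM is the standard allele-frequency-standardized cross-product,
`A = Z Z' / m` with `z_ij = (x_ij - 2 p_j) / sqrt(2 p_j (1 - p_j))`,
using sample allele frequencies and per-SNP mean imputation; QC removes
samples above 10% missingness and SNPs below 5% MAF (both configurable),
and skips monomorphic SNPs.

`reml_fit()` maximizes the restricted likelihood of
`y = X b + sum_k g_k + e`, `g_k ~ N(0, A_k sigma2_k)`, by
average-information updates.  Numerical choices, all visible in the code:

* the first step is an EM step (always feasible); afterwards the AI system
  is solved directly and any component pushed below `1e-6 * Vp` is clamped
  to that floor and flagged as a boundary hit.  An EM fallback for
  infeasible steps was tried and rejected: EM's multiplicative shrinkage
  creeps toward the zero boundary so slowly that the log-likelihood
  criterion fires while the component is still visibly positive, which
  inflates null estimates and mis-calibrates the boundary test;
* convergence is a log-likelihood change below 1e-6, at most 100
  iterations; non-convergence returns the last iterate with a warning and
  a flag (the parcel sweep masks such parcels);
* standard errors come from the inverse AI matrix at convergence;
  heritability fractions divide by the summed components
  (`Vp = sum sigma2`), and `se(h2_total)` sums the AI covariance of the
  genetic block;
* traces use the identity `tr(P A) = sum(P * A)` for symmetric matrices,
  so each iteration costs one Cholesky factorization plus O(K n^2) — this
  is what makes a 40-parcel sweep at n = 600 take seconds, not minutes;
* a GRM numerically equal to the identity is reported as a
  non-identifiability warning (genetic and residual variance are then
  confounded);
* the parcel sweep shares the GRMs and warm-starts each parcel's fit from
  the previous parcel's estimates rescaled to the new phenotypic variance;
  the tests check warm-started results equal independent cold fits.

A variance component sits on the boundary of its parameter space under
the null, so the Wald statistic `W = (sigma2 / se)^2` is referred to a
50:50 mixture of a point mass at zero and chi-square(1):
`p = 0.5 * Pr(chisq_1 > W)`, hence p = 0.5 at W = 0 and p ~ 0.050 at
W = 2.706.  The test-suite verifies empirical type-I error within
[0.03, 0.07] at nominal 0.05 over 500 null REML fits at n = 800 with 300
SNPs — sized so the Wald statistic is in its asymptotic regime; at
n = 400 the boundary makes the test visibly conservative (empirical rate
near 3%), which is a property of the test itself, not of the solver.

Partition enrichment is the ratio of ratios

```
enrich = (h2_part / h2_total) / (g_part / g_total)
```

with the partition's SE scaled by the same genome-fraction denominator
(`se_scaled = se(h2_part) / (g_part / g_total)`) — the scaling that
reproduces the printed standard errors of the reference analysis; note it
does not divide by `h2_total`.  On printed prefrontal inputs
(h2_part 0.022, h2_total 0.33, 9,571 of 337,501 SNPs) the package computes
`r round(enrichment_from_components(0.022, 0.33, 9571, 337501)$enrich, 4)`,
which rounds to the published 2.35–2.36 (the printed 2.36 came from
unrounded inputs).  Some published cluster enrichments (e.g. visual, 8.10)
are *not* recoverable from their printed rounded components; the ratio is
extremely sensitive to the rounding of a small `h2_part`, so the package
treats only the prefrontal worked example as a numerical anchor.

## Amplitude phenotypes, residualization, clustering

Amplitude is the sample SD of a linearly detrended parcel time series —
the desk-scale core of RSFA, with the fMRI preprocessing chain out of
scope.  An optional frequency-band mask is deliberately absent: detrending
plus SD is the definitional core, and anything more belongs to an imaging
pipeline.  Residualization builds its design from R formula terms (so
`I(age^2)` and `age:sex` work), applies row-wise deletion for missing
covariates with a logged count, refuses collinear designs by name, and
returns exact OLS residuals (orthogonality to the design is asserted to
1e-8 in tests).  Parcels are clustered by Ward linkage (`ward.D2`) on
Euclidean distances between their across-individual residual profiles —
the published analysis says only "hierarchical clustering", so Ward on
Euclidean is this package's choice, made for its variance-minimizing
interpretation and determinism; cluster phenotypes are means of *raw*
(non-residualized) amplitudes over member parcels, matching the downstream
heritability contract.

## Polygenic scores and their regional associations

`compute_prs()` matches SNPs by id and alleles, flips dosages when effect
and other alleles are swapped, drops strand-ambiguous (A/T, C/G) SNPs —
the field's standard practice where the source analysis is silent — keeps
only the most significant SNP inside the MHC interval, optionally performs
greedy p-ordered clumping against a supplied r² matrix (a no-op on LD-free
synthetic data by design), and accumulates `sum(beta * dosage)` per
p-value threshold, with `p <= threshold` so that a threshold of 1.0 uses
every post-clump SNP.  Scores are z-standardized before regression so
reported effects are per-SD; Benjamini-Hochberg correction runs separately
within each threshold across the phenotypes tested.  Per-parcel betas
assemble into a PRS-effect map for coupling against expression maps.

## The orchestrated pipeline and problem sizes

`run_pipeline()` chains the stages in dependency order with per-stage
error isolation (a failed stage skips its dependents; independent branches
continue), writes a headline-statistics TSV and hashes its outputs so
reruns with the same seed are verifiably identical.  The default
architecture makes the marker-B partition's per-parcel heritability track
the marker-B expression map (rescaled to [0.05, 0.45]) over flat 0.05 /
0.15 profiles for the other partitions, and subtracts a
marker-B-weighted schizophrenia-like liability — so the expected findings
are a positive h2-map coupling and a negative PRS-effect coupling.

Default problem sizes are chosen as the smallest at which the estimators
are comfortably powered, so the whole suite runs on a laptop core: 40
parcels x 6 samples, 600 genes, 600 individuals x 2,400 SNPs (three
partitions of roughly 470/470/1,450 SNPs), GWAS cohort 1,000.  With a few
hundred SNPs per partition, the sampling error of a partition
heritability at n = 600 is about `sqrt(2 * g_part) / n` (roughly 0.05),
which is why spatial couplings of the heritability maps are detectable
with 40 parcels.  Parameter-recovery checks use n = 2,000 at three
500-SNP partitions, where the 2-SE band is about ±0.04.

## Known limitations

* The REML solver is dense; n is limited by the O(n^3) Cholesky per
  iteration (thousands, not hundreds of thousands, of individuals).
* SEs of heritability ratios use the plug-in `Vp` rather than a full
  delta method over all components; at test scale the difference is well
  inside the Monte-Carlo noise the suite tolerates.
* The competitive test's mean-chi-square gene statistic assumes
  LD-free SNPs; with real LD a multi-SNP gene model would be needed.
* The deconvolution stand-in makes no claim of numerical equivalence to
  CIBERSORTx; it shares the contract (simplex fractions from a signature
  matrix), not the algorithm.
* An LD-score-regression replication arm is intentionally absent; the
  GREML path is the single source of truth here.
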