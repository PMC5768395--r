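---
title: "Screening DNA methylation biomarkers at CTCF-binding sites: methods and design"
author: "methylscreen"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Screening DNA methylation biomarkers at CTCF-binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscreen)
```

# The problem

CTCF-binding sites are short (~30 bp) genomic loci whose occupancy by the
CCCTC-binding factor is methylation-sensitive: in many tumors, occupancy is
lost and the site's CpGs gain (or, less often, lose) methylation. Because the
loci are short and genome-wide catalogued, their methylation state is an
attractive class of tissue biomarkers for early tumor detection, notably for
colorectal adenomas where established promoter-methylation markers are weak.

`methylscreen` implements the complete screening funnel that takes a large
pool of candidate sites down to a small diagnostic panel:

1. **Discovery** — from cell-line data, keep sites whose CTCF occupancy is
   specific to immortal (cancer-like) lines and negatively associated with
   methylation.
2. **MS-HRM triage** — a cheap semiquantitative melting assay bins each
   sample's methylation against a 0/1/10/100% dilution standard curve;
   matched tumor/normal pairs vote on whether a site is tumor-specific.
3. **Quantitative screening** — per-CpG-unit mass-spectrometry style data are
   QC-filtered; each site is represented by its best CpG unit; markers are
   ranked by ROC AUC and shortlisted.
4. **Panel evaluation** — the top markers are combined by an m-of-k voting
   rule and evaluated stage-stratified, alongside two-way hierarchical
   clustering as a global sanity check.

Because per-sample patient methylation values for this design are not
publicly deposited anywhere, the package ships a first-class synthetic-data
generator that reproduces the *statistical structure* the pipeline assumes,
so every stage is testable end-to-end.

# Statistical machinery

## AUC and its significance

For a marker with tumor values $x_1..x_m$ and normal values $y_1..y_n$
(after orientation, below), the AUC is the Mann–Whitney statistic

$$\widehat{A} = \frac{1}{mn}\sum_{i,j}\left[\mathbf 1(x_i > y_j) +
\tfrac12\,\mathbf 1(x_i = y_j)\right],$$

computed via midranks. Its variance uses the DeLong placement-value
estimator, and the p-value is a two-sided z-test of $A = 0.5$ (the
Hanley–McNeil variance is available via `method = "hanley"`). The test suite
checks $\widehat A$ against exhaustive pair counting on hundreds of random
small instances (including heavily tied ones) and the DeLong variance
against an independent implementation (pROC).

**Orientation.** A *hyper* marker is more tumor-like at larger values, a
*hypo* marker at smaller ones. With `direction = "auto"` the orientation
achieving AUC ≥ 0.5 is chosen; an exact tie breaks to hyper (and is
messaged). All downstream thresholds carry the orientation with them
(`">="` vs `"<="` positivity rules).

## Sensitivity at fixed specificity

Decision cutpoints live at midpoints between adjacent distinct observed
values (plus sentinels beyond the extremes). The reported threshold is the
cutpoint maximizing sensitivity subject to **empirical specificity ≥ the
requested level** — the conservative clinical convention: with 84 normals and
a 95% level, at most $\lfloor 0.05 \cdot 84\rfloor = 4$ normals may sit on
the positive side. Ties in sensitivity resolve to the more specific, then
the smaller cutpoint, making the scan a total order.

The confidence interval is the percentile interval over stratified bootstrap
replicates (default 1000): tumor and normal classes are resampled
independently — a pooled bootstrap would perturb prevalence — and the
threshold is re-derived *inside every replicate*, so the interval reflects
threshold-estimation uncertainty too. The point estimate comes from the full
data, not the bootstrap mean. Whether the original software re-derived
thresholds per replicate, and whether its intervals were percentile or
bias-corrected, is not documented anywhere; these are this package's stated
defaults. A dedicated test estimates the coverage of the 95% interval for
the analytic sensitivity of a known Beta model (500 replicates, 80 samples
per class) and requires it to land in [0.90, 0.99] — the generous band
acknowledges the bias introduced by in-sample threshold re-estimation.

## QC filters

CpG units producing data in fewer than 30% of samples, and samples missing
more than 30% of their data points, are unreliable and discarded. Both
comparisons are **strict** inequalities, so exact-30% boundary cases are
retained. The unit filter runs first and the sample filter is computed on
the surviving units; the order is not documented in the underlying protocol,
changes results, and is therefore fixed here and recorded in every pipeline
manifest. Both thresholds are arguments. No imputation is performed.

## MS-HRM triage

The melting assay is abstracted to a scalar melt-shift statistic per
sample × site, strictly monotone in methylation. Observations are binned
against the standards: [0–1%), [1–10%), [10–100%], left-closed intervals
(a statistic exactly at the 1% standard falls in the second bin), clamped at
both ends. Matched pairs vote by the sign of (tumor bin − normal bin); tied
pairs stay in the denominator because a tied pair is evidence *against*
tumor specificity. A site passes when one direction carries at least
`min_fraction` of its pairs — default 0.60, chosen just below the 64% floor
observed among sites kept in the original screen, since no exact pass
criterion was published. Both the fraction and the rule are configurable and
logged.

## Representative CpG unit and ranking

Each site is represented by the CpG unit with the highest oriented AUC; ties
break lexicographically by unit id (logged, deterministic). Ranking sorts by
AUC, then sensitivity at 95% specificity, then marker id — a total order.
The optional early-stage-weighted shortlist review used informally in the
original screen is not formalized there; here shortlisting is purely
AUC-based (`select$k`).

## Discovery screen

Step 1 keeps sites occupied in at least one immortal line and in no normal
line. Step 2 requires methylation in unoccupied lines to exceed that in
occupied lines by a one-sided Mann–Whitney test, **exact** p-values given
the tiny group sizes (6–7 lines). The exact test is conservative at
α = 0.05 because of its discrete support, which the type-I-error acceptance
test bounds within 3 binomial standard errors of α across 1000 null sites.
No multiplicity correction is applied by default (the original screen
reports a raw count), Benjamini–Hochberg is behind a flag; Spearman
correlation is an alternative test.

## Panel voting

Per-marker positivity cutpoints default to the 95%-specificity thresholds
derived on the same negative class (consistent with a panel specificity
observed *near*, not at, 95%); a calibration/evaluation split is available
by deriving thresholds on one experiment and sweeping another. A missing
marker value never counts positive (conservative toward specificity);
samples with no observed panel marker are excluded from denominators with a
warning. The sweep over m = 1..k is monotone by set containment —
sensitivities non-increasing, specificity non-decreasing — and every
reported proportion is kept alongside its numerator and denominator; the
pooled sensitivity is the count-weighted stage average by construction.
Under independent markers each at specificity $s$, panel specificity at
m = 2 has the closed form $P(\mathrm{Bin}(5, 1-s) \le 1)$, which the
acceptance suite verifies by simulation.

## Clustering

Values are transformed as $\log_{10}((v + c)/c)$ with pseudocount
$c = 0.005$ — half the 1% detection floor of the dilution curve — because
$\log_{10}(0)$ is undefined on unmethylated sites. The reference division by
$c$ makes the transform non-negative, which Bray–Curtis dissimilarity (the
vegan default, used when no metric is documented) requires; Euclidean
distances are invariant to that constant shift, so it costs nothing there.
Samples and sites are clustered by average linkage (UPGMA) and the sample
tree is cut at its top merge into two clusters; the cluster holding the
majority of normals is the `N-like` cluster. Merge heights are validated
against a hand-computed UPGMA on a 4-point configuration. Note the source
description of the two-cluster composition is internally inconsistent (20 vs
18 normals in the N cluster between text and figure caption); the package's
fixtures follow the Results-text composition (22 N-like / 18 T-like with two
tumor contaminants).

# The synthetic-data generator

Methylation proportions are drawn from class- and site-specific Beta
distributions — the natural bounded model for proportions; no generative
model was published. Defaults (frozen in `defaultSiteParams()`, chosen by
numerical calibration before any downstream testing):

* 84 normals; 295 tumors: 108 adenoma, 39 stage I, 101 stage II, 47 stage
  III; every normal matched to a tumor (`pairing_fraction = 1`).
* 23 informative sites: 16 hypermethylated (normal ≈ Beta(mean 0.02,
  concentration 10); tumor means 0.15–0.50, concentration 8) and 7
  hypomethylated (mirrored). Additional sites are null (both classes from
  the normal distribution).
* Analytic single-site AUCs — $P(X_T > X_N)$ by numerical integration,
  recorded per site in `truth` — span 0.92–0.998. A wider span reaching down
  to ~0.85 was considered but rejected: under the coarse 3-bin HRM readout,
  sites that weak fall under the 0.60 pair-direction fraction at 84 pairs,
  so the triage-recovery property the pipeline is specified to have would
  fail by construction. The trade-off is that shortlisted markers are
  near-perfect separators, so default panel sensitivities saturate near
  100% — stronger than a real cohort, where assay noise, tumor heterogeneity
  and inter-patient variation push single-marker AUCs down.
* CpG units share their sample's latent site value plus a fixed per-unit
  logit offset (σ = 0.2) and small per-observation logit noise (σ = 0.1), so
  representative-unit selection is exercised non-trivially while unit-level
  AUCs stay within ~0.01 of the site's analytic AUC at large n.
* Missingness is completely at random (default 5%) — no mechanism was
  published; the default survives the 30%/30% QC rules so fixtures stay
  intact.
* Optional per-stage logit shift (default 0, since stage-stratified
  performance was broadly flat in the motivating study).

The HRM statistic is $25\log_{10}(1 + 999m)$ — an arbitrary but fixed
strictly monotone map anchored at 0 for unmethylated input — plus Gaussian
noise; standards are emitted noiseless (the calibration curve is treated as
known). Cell-line tables plant candidates as immortal-only occupancy with
methylation low where occupied; null sites get occupancy-independent
methylation but the same immortal-only occupancy pattern so they reach the
step-2 test.

What the generator does **not** emulate: batch effects, spatially correlated
missingness, bisulfite-conversion artefacts, raw melt curves or mass
spectra, and realistic linkage disequilibrium between neighboring sites.
Passing tests therefore demonstrate the correctness of the statistical
machinery under the stated model, not field performance on clinical tissue.

# Reproducibility and problem sizes

Every stochastic function takes a seed and restores the caller's RNG state;
identical config + seed yields byte-identical studies and reports, which the
suite asserts. The test suite runs at deliberately modest sizes — e.g. AUC
recovery at 2000 samples per class, bootstrap coverage over 500 replicates
of 80 + 80 samples at 200 bootstrap runs, 1000 null sites for the discovery
type-I check — sizes at which the asserted tolerances (±0.02 AUC, [0.90,
0.99] coverage, 3 binomial SEs) are comfortably discriminating. The
acceptance script (`scripts/acceptance.R`) runs the full pipeline at the
reference scale (379 samples, 1000 bootstrap runs, 1236 discovery sites).

# Known limitations

* Acceptance is property-based: the original study's per-marker tables
  cannot be reproduced numerically because the underlying patient data are
  unpublished.
* The exact pass criterion of the historical HRM triage and the exact
  per-marker positivity cutoffs of the historical panel are unknown; the
  implemented defaults are documented choices, not reconstructions.
* `p = 0` is reported for perfectly separated markers (degenerate DeLong
  variance); small-sample exactness of that p-value is not claimed.
* The two-cluster cut assumes the top split is the tumor/normal split; on
  data dominated by another structure (e.g. batch), the labels answer the
  wrong question.
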