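---
title: "Methods: serum type I IFN stratification and single-cell qPCR analysis"
author: "ifnmono"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum type I IFN stratification and single-cell qPCR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnmono)
```

# Overview

Roughly a third of rheumatoid arthritis patients do not respond to TNF
inhibitors, and pre-treatment serum type I interferon (T1IFN) activity — in
particular the ratio of IFN-β to IFN-α activity — has been proposed as a
predictive biomarker: patients with an IFN-β/α activity ratio above 1.3, or
with no detectable T1IFN at all, are unlikely to respond. `ifnmono`
implements the analysis workflow for studies that probe the cellular
correlates of this stratification with single-cell qPCR of purified
classical (CL, CD14++CD16−) and non-classical (NC, CD14dim CD16+)
monocytes:

1. **Serum scoring** (`scoreSerum()`): reporter-assay Ct values are turned
   into a serum T1IFN activity score, decomposed into IFN-α and IFN-β
   activities by antibody blocking, and patients are grouped by the
   IFN-β/α ratio.
2. **Single-cell QC** (`qcPipeline()`): artifact wells and degraded cells
   are removed and the analyzable expression matrix is assembled into a
   `MonocyteExperiment` (a `SingleCellExperiment`).
3. **Per-gene group statistics** (`geneGroupStats()`): categorical
   expressed/not-expressed comparisons (odds ratio, Fisher exact test) and
   quantitative comparisons (Mann-Whitney U), with a correlation-adjusted
   Bonferroni correction.
4. **On/off transcript detection** (`onoffScreen()`): subject-level
   bimodal expression states, the pattern JAK1 exhibits in this setting.
5. **Multivariate summaries** (`runPCA()`, `hcluster()`,
   `multivariateModel()`, `rocAUC()`).

A seeded synthetic-cohort generator (`generateCohort()`,
`simulateSerum()`, `simulateCells()`) supplies data with the structure the
analysis assumes; raw data from the motivating study design are not
publicly deposited, so the generator is the package's test bed.

# Serum T1IFN scoring

## Model

Reporter cells incubated with patient serum upregulate three canonical
T1IFN-induced genes (MX1, PKR, IFIT1), read out by qPCR against a
housekeeping control. For each gene, `relativeExpression()` computes the
ΔCt versus housekeeping, the fold change relative to a healthy-donor
reference panel, and standardizes it in healthy-panel SD units:

score = (FC_sample − mean(FC_healthy)) / sd(FC_healthy).

`t1ifnActivity()` sums the three per-gene scores into the total serum
activity score.

**Standardization scale.** The fold change can be standardized on the
linear scale (default) or after log2 transformation (`scale = "log2"`).
We default to the linear scale because the downstream quantity of interest
is an activity *ratio*: only a readout linear in activity preserves
IFN-β/α as a ratio of activities. On the log scale the recovered ratio is
compressed toward 1 and the clinically meaningful 1.3 dichotomy is not
recoverable. The log2 option is retained because standardizing log fold
changes is also common laboratory practice for ΔΔCt data.

## Subtype decomposition

Serum aliquots pre-incubated with anti-IFN-α or anti-IFN-β antibodies give
two additional activity readouts. Under the **residual convention**
(default of `decomposeAlphaBeta()`), blocking one subtype leaves the
other's activity: the residual after anti-IFN-α quantifies IFN-β, and
vice versa. The alternative reading — the *drop* in activity caused by
blocking one subtype quantifies that subtype, so the other subtype is the
untreated total minus that drop — is available as `method =
"inhibition"`; for internally consistent data the two coincide. Both clip
at zero and report the consistency diagnostic |α + β − untreated|. The
estimator makes no attempt to correct for incomplete antibody
neutralization; blocking efficiency is a property of the simulator only.

## Not-detected rule and the ratio

Sera with very low total activity (below a 1 pg/mL-equivalent detection
level) are flagged not-detected (ND) **before** decomposition and receive
no ratio. `ndScoreThreshold()` converts the pg/mL detection limit into
score units; when given the healthy reference panel it calibrates
empirically — the threshold is the score a serum at the detection-limit
activity would receive under *that* panel's fold-change mean and SD. This
matters: with a dozen healthy donors the SD estimate has ~20% sampling
error that is shared by every score in the cohort, so a threshold fixed in
advance on the analytic scale would drift relative to the scores. The
analytic form (from the log-normal Ct measurement noise) is used when no
panel is available.

`ifnRatio()` returns β/α when α exceeds a detection floor ε. When α ≤ ε
but β is present the ratio is *undefined-high* (`Inf`) and the subject
falls in the above-1.3 group — the clinically conservative choice. Inside
`scoreSerum()`, ε is half the ND threshold: the two blocking residuals sum
to at least the untreated activity (up to noise), so for a detected serum
both residuals can only fall below ε if the apparent detection was itself
a noise artifact; such subjects are demoted to ND with a warning rather
than given a meaningless ratio.

## Grouping

`assignGroups()` implements both schemes with a strict inequality at 1.3
(a ratio of exactly 1.3 is in the "at most 1.3" group):

* three-way: ND / ratio ≤ 1.3 / ratio > 1.3;
* two-way: {ND or ratio > 1.3} ("non-response-like") versus
  {detected and ratio ≤ 1.3} ("response-like").

The two-way label is a deterministic function of the three-way label.

# Single-cell quality control

QC runs in a fixed order, and every exclusion is logged with its reason
(`qcLog()`):

1. **Well flags** (`filterWells()`): empty wells, wells that captured more
   than one cell, and wells whose amplification curves failed review are
   dropped. These flags are set upstream (in the laboratory, by visual
   inspection); the package consumes them as booleans.
2. **Failure score** (`filterFailures()`): the failure score of a cell is
   its total Ct over the full 87-gene panel with "no amplification"
   imputed at the maximum cycle (40), so degraded, low-complexity cells
   score high. Within each capture run, the mean and sample SD of the
   scores are computed **once** over all candidate cells, and cells more
   than 2 SD above the mean are removed in a single pass — the statistics
   are deliberately not recomputed after removals. Runs with fewer than 3
   cells are skipped with a warning. Per-run stratification matches
   plate-level failure modes; a pooled variant is available via
   `qcConfig(grouping = "pooled")`.
3. **Matrix construction** (`buildMatrix()`): surviving cells are joined
   with the serum-derived group labels and transformed to expression
   units, Et = max(0, LOD − Ct), with LOD defaulting to cycle 28; "no
   amplification" maps to Et 0 and a gene is *expressed* in a cell iff
   Et > 0.

A statistical note on the 2-SD rule: it is a Grubbs-type studentized
criterion, and the largest studentized deviation in a run of $n$ cells is
bounded by $(n-1)/\sqrt{n}$. Runs of five or fewer cells therefore can
never lose a cell to this filter, whereas in large runs of perfectly
healthy cells roughly 1–2% sit beyond 2 SD by chance — occasional
exclusions on clean data are the rule behaving as specified, not a defect.
The package's count-parity checks consequently use either small runs or
noise-free fixtures, where QC is deterministic.

# Per-gene group statistics

## Categorical analysis

For each gene and lineage, `expressedTable()` builds the 2×2 table of
expressed/not-expressed by group, with the non-response-like group first
so the odds ratio reads "odds of being expressed in the non-response-like
group". `fisherOR()` reports:

* the sample cross-product odds ratio $ad/bc$, with the Haldane–Anscombe
  +0.5 correction applied to all cells iff any cell is zero (an exact
  conditional estimate is available via `or_method = "conditional"`);
* Woolf's 95% CI, $\exp(\log OR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$;
* the two-sided Fisher exact p — the sum of hypergeometric probabilities
  of all tables with the observed margins no more likely than the observed
  table. The test suite verifies this against exhaustive enumeration for
  every table with a grand total up to 20.

## Quantitative analysis

`mannWhitneyGene()` compares Et values between groups with a two-sided
Mann-Whitney U test: exact permutation enumeration when both groups have
at most 8 cells, otherwise the tie-corrected normal approximation without
continuity correction (the p-value is checked against full permutation
enumeration and against the standard large-sample test in the suite).

## Correlation-adjusted multiple testing

Transcripts measured in the same cell are correlated, so a strict
Bonferroni correction over the 87 tests would be conservative.
`spearmanPairs()` computes the Spearman correlation over cells for all
87·86/2 = 3,741 unordered transcript pairs (pairs undefined because of a
constant gene are excluded and counted), and the corrected p-value is

p_corr = p_obs × m × (1 − mean |rho|),

equivalently a significance threshold of alpha / (m × (1 − mean |rho|))
on the raw p. At zero correlation this is exactly Bonferroni; the
correction is linear in p and never exceeds m × p. A mean absolute
correlation of about 0.28 over an 87-gene panel gives a raw-p threshold of
0.0008 at alpha 0.05. The mean |rho| is computed per lineage on the
QC-passed matrix by default; pooling is the caller's choice since either
convention is defensible.

## On/off transcript states

Some transcripts are expressed in most cells of some subjects and in no
cell of others — a subject-level bimodal state, exhibited by JAK1 in this
stratification. `onoffCalls()` classifies each subject: *non-expresser*
(zero expressing cells out of at least `min_cells`), *expresser* (at least
one expressing cell), *indeterminate* (too few cells). The pooled per-cell
expression rate among expressers gives the sampling-error bound
`miscategorizationProb(rate, n)` = (1 − rate)^n — the chance a true
expresser shows zero expressing cells. At the observed ~83% per-cell rate,
even five cells give a ~0.01% miscategorization chance, which motivates
the default `min_cells = 5`. `onoffScreen()` flags a gene when at least
one determinate subject is a non-expresser *and* at least one subject
expresses it in ≥ 80% of cells (`on_fraction`, exposed); ordinary
stochastic dropout produces intermediate per-subject fractions and is not
flagged.

# Multivariate summaries

* `runPCA()`: centered, optionally unit-variance PCA of cells in gene
  space; constant genes are dropped with a warning; each component's sign
  is fixed by making its largest-magnitude loading positive, so results
  are deterministic.
* `hcluster()`: hierarchical clustering of both genes and cells.
  Correlation distance (1 − Pearson r) with average linkage is the
  default — the common choice for expression heatmaps — but neither is
  canonical, so both are arguments. Degenerate distances (constant items
  under the correlation metric) raise an error naming the items.
* `multivariateModel()`: binomial GLM of group on candidate genes
  (pre-filtered by univariate significance), with backward elimination of
  the largest-p coefficient until all retained coefficients have p < 0.05.
  Backward elimination at 0.05 is our concrete reading of "retained as
  independent predictors"; genes causing (quasi-)complete separation have
  meaningless Wald p-values, so they are flagged, retained, and exempted
  from elimination.
* `rocAUC()`: AUC via the rank statistic (identical to U/(n₁n₀)), with
  Hanley–McNeil standard error and a truncated normal 95% CI.

# The synthetic-cohort generator

`cohortConfig()` defaults describe the emulated study design: 15 subjects
(3 ND, 6 with ratio ≤ 1.3, 6 with ratio > 1.3), CL and NC monocytes per
subject, an 87-gene innate-immunity panel.

* **Latent activities**: detected groups draw total activity log-normal
  (median 10 units, log-SD 0.3 — positive and right-skewed, as cytokine
  activities are); the ratio is uniform within the group's range (0.35–
  1.05 for the low group, 1.7–3.5 for the high group, leaving a margin on
  either side of 1.3 comparable to assay noise); ND subjects draw totals
  below half the detection level. 1 activity unit corresponds to 1 pg/mL
  (`pg_per_activity_unit`).
* **Reporter assay**: Ct = baseline − slope·log2(1 + activity) + noise,
  with slope 1 ΔCt per doubling, Gaussian cycle noise (SD 0.15), blocking
  efficiencies 0.95, and a 12-donor healthy panel.
* **Cells**: per-gene Bernoulli expression (baseline probability 0.7)
  with group-specific probability and mean-Ct offsets; amplified Ct
  Gaussian around 22 (SD 1.5); correlated transcript blocks realized by a
  shared per-cell Gaussian factor with Pearson loading 2·sin(π·rho/6),
  the exact bivariate-normal inverse of the target Spearman rho; degraded
  cells (rate 0.03) have all Ct values shifted up 12 cycles; artifact
  wells (empty 3%, doublet 2%, curve-fail 2%) are emitted in addition to
  the requested cells with their flags set at generation time.
* **JAK1**: subject-level on/off. Non-expresser probability by group
  (0.9/0.15/0.9 for ND/low/high) emulates a cohort in which nine of
  fifteen subjects lack JAK1 expression, concentrated outside the
  low-ratio group; expresser subjects detect JAK1 in 83% of CL and 99% of
  NC cells.

**What the generator does not emulate** — and therefore what passing
tests do *not* establish about real data: empirical Ct and dropout
distributions of any real instrument; plate/batch effects and cross-plate
drift; amplification-curve shapes (curve QC enters only as a boolean
flag); doublet expression mixtures beyond a one-cycle Ct shift; any
dose–response relationship for the blocking antibodies (their
concentrations are recorded as metadata only); and intermediate monocyte
phenotypes. The tests establish that the *machinery* is correct and that
planted structure of realistic magnitude is recovered; they cannot
validate biological conclusions.

# Numerical choices and problem sizes

All generation is seeded and deterministic (identical config and seed give
byte-identical fixtures; the pipeline embeds the seed and a config hash in
every output). Degenerate inputs fail loudly: zero healthy-panel SD, a
missing condition or gene, a subject without serum results, one-class
model labels. Ties in the Mann-Whitney test use midranks; clustering ties
break by input order via `stats::hclust`.

The verification suites use these sizes, chosen to give stable Monte-Carlo
estimates at interactive runtimes: exhaustive Fisher enumeration to grand
total 20; Mann-Whitney enumeration at n = (5, 5); 100 null-cohort
replicates for type-I error of the corrected threshold; planted
expression-probability differences of 0.25 at 200 cells/group for power
(≥ 80% observed); 200 subjects for serum regrouping (≥ 90% correct at
default noise); 500 subjects for decomposition error (< 10% of a
total-activity-10 serum, against a 200-donor healthy panel so reference
noise does not dominate); and a 2,000-cell run for correlation-block
calibration. Count-parity runs are noise-free by construction, as
discussed under QC.

# Limitations

* The standardization scale and the subtype-decomposition reading of the
  original laboratory pipeline are not published; both are exposed as
  arguments, with defaults chosen for ratio preservation and internal
  consistency as argued above.
* The corrected threshold treats the mean absolute pairwise correlation
  as a global discount; it is not a full dependence-aware procedure such
  as permutation-based FWER control.
* Backward elimination with Wald p-values is a pragmatic stand-in for an
  unspecified model-selection rule; retained gene sets should be read as
  descriptive, not inferential.
* `miscategorizationProb()` assumes exchangeable cells within subject;
  within-subject clustering of dropout would loosen the bound.

# Session info

```{r}
sessionInfo()
```
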