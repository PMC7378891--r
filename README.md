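# ifnmono

Type I interferon stratification and single-cell qPCR analysis of
monocytes in rheumatoid arthritis.

## The problem

Roughly a third of rheumatoid arthritis (RA) patients do not respond to
TNF inhibitors (TNFi). Pre-treatment serum type I interferon (T1IFN)
activity stratifies patients: those with an IFN-β/α activity ratio above
1.3, or with no detectable T1IFN, are unlikely to respond. Studies probing
the cellular correlates of this stratification profile purified classical
(CL, CD14++CD16−) and non-classical (NC, CD14dim CD16+) monocytes with
single-cell qPCR over a panel of 87 innate-immunity genes. `ifnmono` is a
tested, reusable implementation of that analysis for bioinformaticians and
rheumatology researchers working with reporter-assay serum data and
Ct-matrix single-cell qPCR.

## What it computes

**Serum scoring.** Reporter cells incubated with patient serum induce
MX1, PKR and IFIT1. Per gene, the ΔΔCt fold change versus a healthy-donor
panel is standardized to a score, (FC − mean FC<sub>healthy</sub>) /
sd(FC<sub>healthy</sub>), and the three scores are summed into the serum
T1IFN activity. Aliquots blocked with anti-IFN-α or anti-IFN-β antibodies
give the subtype decomposition (the residual after blocking one subtype
measures the other), the ratio β/α, a not-detected (ND) rule below a
1 pg/mL-equivalent threshold, and the patient groups: three-way
{ND, ≤ 1.3, > 1.3} and two-way {ND or > 1.3} vs {≤ 1.3}.

**Single-cell QC.** Flagged wells (empty/doublet/curve-fail) are dropped;
then each cell's *failure score* — total Ct over the panel, no
amplification imputed at cycle 40 — is screened per capture run: cells
more than 2 SD above the run mean are excluded in a single pass. Surviving
cells form a `MonocyteExperiment` (a `SingleCellExperiment`) on the
Et = max(0, LOD − Ct) scale with expressed ⇔ Et > 0.

**Per-gene statistics.** For each gene and lineage: the 2×2
expressed-by-group table, the odds ratio *ad/bc* (Haldane–Anscombe
correction when a cell is zero) with Woolf 95% CI and two-sided Fisher
exact p; a Mann-Whitney U test on the quantitative Et values (exact
enumeration at small n). Multiplicity uses a correlation-adjusted
Bonferroni correction: with m = 87 transcripts and the mean absolute
Spearman correlation ρ̄ over all m(m−1)/2 = 3,741 transcript pairs,

    p_corr = p_obs · m · (1 − ρ̄),

i.e. a raw-p threshold of α / (m·(1 − ρ̄)) — about 0.0008 at α = 0.05 when
ρ̄ ≈ 0.28.

**On/off transcripts.** A subject is a *non-expresser* of a gene when zero
of ≥ 5 cells express it; the sampling-error bound for a true expresser is
(1 − rate)^n (≈ 0.01% at the observed 83% per-cell rate and 5 cells).
`onoffScreen()` flags genes with both non-expresser subjects and subjects
expressing in ≥ 80% of cells — the bimodal pattern JAK1 shows.

**Multivariate.** PCA (deterministic sign convention), hierarchical
clustering (correlation distance, average linkage), logistic models with
backward elimination at p < 0.05 and separation flagging, and ROC AUC with
Hanley–McNeil SE.

**Synthetic cohorts.** A seeded generator emulates the study design
(15 subjects 3/6/6 across ND/low/high groups, CL+NC cells, gene dropout,
correlated transcript blocks, subject-level JAK1 on/off states, artifact
wells, degraded cells) so every claim above is exercised end to end.

## Worked example

```r
library(ifnmono)

cfg    <- cohortConfig(cells_per_subject = c(CL = 25, NC = 25), seed = 42)
cohort <- generateCohort(cfg)
params <- assayParams()
serum  <- simulateSerum(cohort, params, seed = 43)

serum_results <- scoreSerum(serum, params = params)
table(serum_results$group3)
#> gt_1.3 le_1.3     ND
#>      6      6      3

me <- qcPipeline(simulateCells(cohort, cfg), serum_results)
me
#> MonocyteExperiment with 87 genes x 725 cells
#>   lineages: CL=364 NC=361
#>   group2: nonresponse_like=434 response_like=291
#>   mean expressed fraction: 0.705
```

All 15 subjects are regrouped correctly (3 ND, 6 with ratio ≤ 1.3, 6 with
ratio > 1.3), and 725 of the simulated cells survive QC. Per-gene
statistics in classical monocytes:

```r
st <- geneGroupStats(me, lineage = "CL")
df <- as.data.frame(st)
head(df[, c("gene", "odds_ratio", "ci_low", "ci_high",
            "p_fisher", "p_corrected", "significant")], 3)
#>      gene   odds_ratio     ci_low     ci_high     p_fisher  p_corrected significant
#> 1    JAK1 0.0005722877 3.4655e-05 0.009450623 2.408028e-68 2.004575e-66        TRUE
#> 2   IFI27 0.2470562739 0.15635883 0.390363653 6.823416e-10 5.680187e-08        TRUE
#> 3 HLADRB1 6.4881656805 3.34073195 12.60091935 2.203670e-09 1.834456e-07        TRUE
```

JAK1 has tiny odds of being expressed in the non-response-like group
(odds ratio ≈ 6e-4 in this simulated cohort, where 9 of 15 subjects are
planted JAK1 non-expressers), IFI27 is depleted and HLADRB1 enriched —
the planted group structure. The correction context behind `significant`
(`metadata(st)$correction`) reports m = 87 tests, 3,741 pairs,
mean |rho| = 0.043 and a raw-p threshold of 6.0e-4 for this matrix. The
on/off screen flags exactly one transcript:

```r
sc <- onoffScreen(me, "CL")
sc[sc$flagged, ]
#>   gene n_off n_on flagged
#> 1 JAK1     9    3    TRUE

onoffCalls(me, "JAK1", "CL")
#> OnOffResult: JAK1 in CL cells
#>     expresser non-expresser
#>             6             9
#> per-cell rate among expressers: 0.803 ; miscategorization prob at min cells: 0.000299
```

Nine subjects express JAK1 in zero cells; among expressers 80% of cells
are positive, so a true expresser with only 5 cells would be
misclassified with probability 3e-4. A multivariate model over the
significant genes separates the groups (JAK1 is separation-flagged, as a
near-perfect predictor should be):

```r
mod <- multivariateModel(me, df$gene[df$significant], "CL")
mod
#> ModelResult: 9 gene(s) retained: JAK1, IFI27, HLADRB1, IL8, CD11c, IFNAR1, TGFB, PDL1, TNFA
#>   separation-flagged: JAK1
#>   AUC 0.995 (SE 0.00337 , 95% CI 0.989-1 )
```

The whole workflow also runs from one config via `runPipeline(runConfig(),
"out_dir")` or the thin CLI `Rscript inst/scripts/ifnmono.R run --config
config.yaml --out DIR`.

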