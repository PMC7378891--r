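test_that("cohort generation respects group sizes and seeding", {
  cfg <- cohortConfig(seed = 11)
  cohort <- generateCohort(cfg)
  expect_equal(nrow(cohort), 15L)
  expect_equal(as.vector(table(cohort$group)[c("ND", "low_ratio",
                                               "high_ratio")]),
               c(3L, 6L, 6L))
  expect_identical(cohort, generateCohort(cfg))

  empty <- generateCohort(cohortConfig(
    n_per_group = c(ND = 0L, low_ratio = 0L, high_ratio = 0L), seed = 1))
  expect_equal(nrow(empty), 0L)
})

test_that("latent activities satisfy the group invariants", {
  cohort <- generateCohort(cohortConfig(
    n_per_group = c(ND = 20L, low_ratio = 20L, high_ratio = 20L),
    seed = 12))
  nd <- cohort[cohort$group == "ND", ]
  expect_true(all(nd$alpha_activity + nd$beta_activity < 1))
  hi <- cohort[cohort$group == "high_ratio", ]
  expect_true(all(hi$beta_activity / hi$alpha_activity > 1.3))
  lo <- cohort[cohort$group == "low_ratio", ]
  expect_true(all(lo$beta_activity / lo$alpha_activity <= 1.3))
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(n_per_group = c(bogus = 3L)), "group labels")
  expect_error(cohortConfig(dropout_base = 1.5), "probabilities")
  expect_error(cohortConfig(panel = c("A", "A", "B")), "duplicate")
  expect_error(cohortConfig(cells_per_subject = c(CL = -1, NC = 5)),
               ">= 0")
})

test_that("serum assay honours the blocking model at zero noise", {
  params <- assayParams(ct_noise_sd = 0)
  null_subj <- data.frame(subject_id = "s", alpha_activity = 0,
                          beta_activity = 0)
  rec <- simulateSerumAssay(null_subj, params)
  targets <- rec[rec$gene != "HK", ]
  expect_true(all(targets$ct == params$baseline_ct))

  # complete anti-alpha blocking: anti-alpha condition matches a serum
  # containing only the beta component
  params1 <- assayParams(ct_noise_sd = 0, anti_alpha_efficiency = 1)
  mixed <- data.frame(subject_id = "s", alpha_activity = 5,
                      beta_activity = 3)
  beta_only <- data.frame(subject_id = "s", alpha_activity = 0,
                          beta_activity = 3)
  rec_mixed <- simulateSerumAssay(mixed, params1)
  rec_beta <- simulateSerumAssay(beta_only, params1)
  expect_equal(rec_mixed$ct[rec_mixed$condition == "anti_alpha"],
               rec_beta$ct[rec_beta$condition == "none"])
})

test_that("single-cell simulation conserves counts and panel structure", {
  cfg <- cohortConfig(cells_per_subject = c(CL = 30, NC = 10), seed = 13)
  cohort <- generateCohort(cfg)
  cells <- simulateCells(cohort, cfg)
  expect_equal(nrow(cells), 87L)
  cd <- as.data.frame(SummarizedExperiment::colData(cells))
  n_artifact <- sum(cd$flag_empty | cd$flag_doublet | cd$flag_curve)
  expect_equal(ncol(cells) - n_artifact, 15L * 40L)
  # requested counts per subject x lineage among unflagged wells
  clean <- cd[!(cd$flag_empty | cd$flag_doublet | cd$flag_curve), ]
  expect_true(all(table(clean$subject_id, clean$lineage)[, "CL"] == 30))
  expect_true(all(table(clean$subject_id, clean$lineage)[, "NC"] == 10))
})

test_that("JAK1 is never amplified in non-expresser subjects", {
  cfg <- cohortConfig(cells_per_subject = c(CL = 15, NC = 15), seed = 14)
  cohort <- generateCohort(cfg)
  cells <- simulateCells(cohort, cfg)
  jak1 <- SummarizedExperiment::assay(cells, "Ct")["JAK1", ]
  nonexp <- cohort$subject_id[cohort$jak1_state == "non-expresser"]
  expect_true(length(nonexp) > 0)
  expect_true(all(is.na(jak1[cells$subject_id %in% nonexp])))
})

test_that("with no failures or artifacts every cell passes QC", {
  # runs of 5 cells: the max studentized deviate (n-1)/sqrt(n) < 2, so the
  # failure-score rule provably cannot fire on clean data
  cfg <- cohortConfig(cells_per_subject = c(CL = 5, NC = 5),
                      failure_rate = 0,
                      well_artifact_rates = c(empty = 0, doublet = 0,
                                              curve = 0),
                      seed = 15)
  cohort <- generateCohort(cfg)
  cells <- simulateCells(cohort, cfg)
  kept <- filterFailures(filterWells(cells))
  expect_equal(ncol(kept), ncol(cells))
  expect_equal(nrow(qcLog(kept)), 0L)
})

test_that("correlation blocks realize the target Spearman rho", {
  cfg <- cohortConfig(
    n_per_group = c(ND = 0L, low_ratio = 1L, high_ratio = 0L),
    cells_per_subject = c(CL = 2000L, NC = 0L),
    correlation_blocks = list(list(genes = c("ISG15", "OAS1"), rho = 0.5)),
    dropout_base = 0, failure_rate = 0,
    well_artifact_rates = c(empty = 0, doublet = 0, curve = 0),
    seed = 16)
  cohort <- generateCohort(cfg)
  cells <- simulateCells(cohort, cfg)
  ct <- SummarizedExperiment::assay(cells, "Ct")
  rho <- cor(ct["ISG15", ], ct["OAS1", ], method = "spearman")
  expect_gt(rho, 0.4)
  expect_lt(rho, 0.6)
  # genes outside the block stay uncorrelated
  rho_out <- cor(ct["ISG15", ], ct["TNFA", ], method = "spearman")
  expect_lt(abs(rho_out), 0.1)
})

test_that("fixtures round-trip losslessly and are byte-deterministic", {
  cfg <- cohortConfig(cells_per_subject = c(CL = 6, NC = 6), seed = 17)
  cohort <- generateCohort(cfg)
  params <- assayParams()
  serum <- simulateSerum(cohort, params, seed = 18)
  cells <- simulateCells(cohort, cfg)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeFixture(cohort, serum, cells, d1)
  writeFixture(generateCohort(cfg), simulateSerum(cohort, params, 18),
               simulateCells(cohort, cfg), d2)
  for (f in c("cohort.csv", "serum.csv", "single_cells.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  serum2 <- readSerumCSV(file.path(d1, "serum.csv"))
  expect_equal(serum2, serum)
  cells2 <- readSingleCellCSV(file.path(d1, "single_cells.csv"))
  expect_equal(SummarizedExperiment::assay(cells2, "Ct"),
               SummarizedExperiment::assay(cells, "Ct"),
               ignore_attr = FALSE)
  expect_equal(cells2$subject_id, cells$subject_id)
  expect_equal(cells2$flag_empty, cells$flag_empty)
})
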