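# Shared fixtures, built in code.

# A CtWellSet with a small panel and hand-set Ct values.
makeWellSet <- function(ct, subject = "s1", lineage = "CL",
                        flags = NULL) {
  n <- ncol(ct)
  wd <- data.frame(
    well_id = sprintf("w%03d", seq_len(n)),
    subject_id = rep_len(subject, n),
    lineage = rep_len(lineage, n),
    flag_empty = FALSE, flag_doublet = FALSE, flag_curve = FALSE,
    stringsAsFactors = FALSE)
  if (!is.null(flags)) for (f in names(flags)) wd[[f]] <- flags[[f]]
  CtWellSet(ct, wd)
}

# A MonocyteExperiment built directly from an expressed-pattern matrix:
# `expr` is a logical genes x cells matrix; expressed cells get Ct 22
# (Et 6), others no amplification.
makeME <- function(expr, subject_id, group2,
                   lineage = rep("CL", ncol(expr)),
                   et_expressed = 6) {
  ct <- ifelse(expr, 28 - et_expressed, NA_real_)
  dimnames(ct) <- dimnames(expr)
  ws <- makeWellSet(ct, subject = subject_id, lineage = lineage)
  serum <- data.frame(
    subject_id = unique(subject_id),
    group2 = group2[match(unique(subject_id), subject_id)],
    stringsAsFactors = FALSE)
  serum$group3 <- ifelse(serum$group2 == "nonresponse_like",
                         "gt_1.3", "le_1.3")
  buildMatrix(ws, serum)
}

# Small default-structure cohort for integration-style tests.
makeSmallCohortData <- function(seed = 101, cells = 20) {
  cfg <- cohortConfig(cells_per_subject = c(CL = cells, NC = cells),
                      seed = seed)
  cohort <- generateCohort(cfg)
  params <- assayParams()
  serum <- simulateSerum(cohort, params, seed = seed + 1)
  res <- scoreSerum(serum, params = params)
  cells <- simulateCells(cohort, cfg)
  list(cfg = cfg, cohort = cohort, params = params, serum = serum,
       serum_results = res, cells = cells,
       me = qcPipeline(cells, res))
}
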