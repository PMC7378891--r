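#' QC configuration
#'
#' @param sd_multiplier Cells whose failure score exceeds the run mean plus
#'   this many run SDs are excluded (default 2).
#' @param lod_ct Limit-of-detection cycle for the Et transform (default 28).
#' @param na_ct Cycle imputed for "no amplification" in the failure score
#'   (default 40, the maximum cycle).
#' @param grouping `"run"` (default; failure-score statistics per capture
#'   run) or `"pooled"` (one mean/SD over all cells).
#' @return A validated list of class `"QCConfig"`.
#' @export
qcConfig <- function(sd_multiplier = 2, lod_ct = 28, na_ct = 40,
                     grouping = c("run", "pooled")) {
  grouping <- match.arg(grouping)
  if (sd_multiplier <= 0) stop("sd_multiplier must be > 0")
  if (lod_ct <= 0 || lod_ct > 40) stop("lod_ct must lie in (0, 40]")
  structure(list(sd_multiplier = sd_multiplier, lod_ct = lod_ct,
                 na_ct = na_ct, grouping = grouping), class = "QCConfig")
}

.appendQCLog <- function(x, well_id, step, reason) {
  log <- qcLog(x)
  if (length(well_id))
    log <- rbind(log, data.frame(well_id = well_id, step = step,
                                 reason = reason, stringsAsFactors = FALSE))
  metadata(x)$qc_log <- log
  x
}

#' Remove flagged wells
#'
#' Drops wells carrying any artifact flag (empty well, more than one cell
#' captured, aberrant amplification curve), recording each exclusion with
#' its reason in the QC log.
#'
#' @param cells A [CtWellSet-class].
#' @return The filtered `CtWellSet`; exclusions appended to `qcLog()`.
#' @export
filterWells <- function(cells) {
  cd <- colData(cells)
  reason <- ifelse(cd$flag_empty, "empty well",
            ifelse(cd$flag_doublet, "doublet well",
            ifelse(cd$flag_curve, "amplification-curve failure", NA)))
  drop <- !is.na(reason)
  out <- cells[, !drop]
  .appendQCLog(out, cd$well_id[drop], "well_flags", reason[drop])
}

#' Panel-wide failure score
#'
#' The failure score of a cell is the total Ct over the full gene panel,
#' with "no amplification" imputed at the maximum cycle (`na_ct`, default
#' 40). Higher scores indicate globally degraded cells whose expression
#' cannot be trusted.
#'
#' @param cells A [CtWellSet-class].
#' @param na_ct Imputation cycle for non-amplified genes.
#' @return Named numeric vector (one score per well).
#' @export
#' @examples
#' ct <- matrix(20, nrow = 3, ncol = 2,
#'              dimnames = list(c("A", "B", "C"), NULL))
#' wd <- data.frame(well_id = c("w1", "w2"), subject_id = "s", lineage = "CL",
#'                  flag_empty = FALSE, flag_doublet = FALSE,
#'                  flag_curve = FALSE)
#' failureScore(CtWellSet(ct, wd))  # 60 60
failureScore <- function(cells, na_ct = 40) {
  ct <- assay(cells, "Ct")
  ct[is.na(ct)] <- na_ct
  stats::setNames(colSums(ct), cells$well_id)
}

#' Exclude degraded cells by failure score
#'
#' Within each capture run (or pooled, per `qc$grouping`), computes the mean
#' and sample SD of the failure scores once over all candidate cells, then
#' removes cells whose score is strictly greater than
#' `mean + sd_multiplier * SD`. Statistics are computed in a single pass
#' before any removal (no iterative re-computation). Runs with fewer than 3
#' cells are skipped with a warning (their cells are retained).
#'
#' @param cells A well-filtered [CtWellSet-class].
#' @param qc A [qcConfig()] object.
#' @return The filtered `CtWellSet`; exclusions appended to `qcLog()`.
#' @export
filterFailures <- function(cells, qc = qcConfig()) {
  scores <- failureScore(cells, qc$na_ct)
  strata <- if (qc$grouping == "run") cells$run_id
            else rep("pooled", ncol(cells))
  drop <- logical(ncol(cells))
  for (run in unique(strata)) {
    idx <- which(strata == run)
    if (length(idx) < 3L) {
      warning("run '", run, "' has fewer than 3 cells; failure-score ",
              "filter skipped for this run")
      next
    }
    cutoff <- mean(scores[idx]) + qc$sd_multiplier * stats::sd(scores[idx])
    drop[idx] <- scores[idx] > cutoff
  }
  out <- cells[, !drop]
  .appendQCLog(out, cells$well_id[drop], "failure_score",
               sprintf("failure score %.1f above run cutoff",
                       scores[drop]))
}

#' Ct to expression (Et) transform
#'
#' `Et = max(0, lod_ct - Ct)`; "no amplification" (`NA`) maps to 0. A gene
#' is expressed in a cell iff `Et > 0`, so amplification at or beyond the
#' limit-of-detection cycle counts as not expressed. The transform is
#' monotone non-increasing in Ct.
#'
#' @param ct Numeric vector/matrix of Ct values (`NA` = no amplification).
#' @param lod_ct Limit-of-detection cycle (default 28).
#' @return Object of the same shape with Et values.
#' @export
#' @examples
#' ctToExpression(c(24, 30, NA))  # 4 0 0
ctToExpression <- function(ct, lod_ct = 28) {
  et <- lod_ct - ct          # preserves vector/matrix shape
  et[is.na(et) | et < 0] <- 0
  et
}

#' Build the analyzable expression matrix
#'
#' Joins QC-passed cells with the serum-derived patient group labels and
#' applies the Et transform, yielding the [MonocyteExperiment-class] all
#' downstream analyses consume. Every subject present in the cells must
#' have a serum result.
#'
#' @param cells A QC-passed [CtWellSet-class].
#' @param serum_results Per-subject `data.frame` from [scoreSerum()] (needs
#'   `subject_id`, `group2`, `group3`).
#' @param lod_ct Limit-of-detection cycle for [ctToExpression()].
#' @return A [MonocyteExperiment-class].
#' @export
buildMatrix <- function(cells, serum_results, lod_ct = 28) {
  cd <- colData(cells)
  idx <- match(cd$subject_id, serum_results$subject_id)
  if (anyNA(idx)) {
    missing <- unique(cd$subject_id[is.na(idx)])
    stop("data error: no serum result for subject(s): ",
         paste(missing, collapse = ", "))
  }
  et <- ctToExpression(assay(cells, "Ct"), lod_ct)
  ann <- DataFrame(well_id = cd$well_id, subject_id = cd$subject_id,
                   lineage = cd$lineage,
                   group2 = serum_results$group2[idx],
                   group3 = serum_results$group3[idx])
  sce <- SingleCellExperiment(assays = list(Et = et, expressed = et > 0),
                              colData = ann)
  colnames(sce) <- cd$well_id
  out <- new("MonocyteExperiment", sce)
  metadata(out)$qc_log <- qcLog(cells)
  out
}

#' Run the full QC pipeline
#'
#' Applies the fixed QC order — artifact-well flags, then the failure-score
#' filter, then matrix construction with group annotation.
#'
#' @param cells A raw [CtWellSet-class].
#' @param serum_results Per-subject results from [scoreSerum()].
#' @param qc A [qcConfig()] object.
#' @return A [MonocyteExperiment-class] with the cumulative QC log.
#' @export
#' @examples
#' cfg <- cohortConfig(cells_per_subject = c(CL = 8, NC = 8), seed = 11)
#' cohort <- generateCohort(cfg)
#' cells <- simulateCells(cohort, cfg)
#' serum <- scoreSerum(simulateSerum(cohort, assayParams(), seed = 12),
#'                     ndScoreThreshold(assayParams()))
#' qcPipeline(cells, serum)
qcPipeline <- function(cells, serum_results, qc = qcConfig()) {
  kept <- filterFailures(filterWells(cells), qc)
  buildMatrix(kept, serum_results, qc$lod_ct)
}
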