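#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

## ---------------------------------------------------------------------------
## CtWellSet: raw single-cell qPCR wells (genes x wells), Ct scale
## ---------------------------------------------------------------------------

#' CtWellSet: raw single-cell qPCR Ct data
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container for raw
#' single-cell qPCR data: one column per capture well, one row per panel
#' gene, with a single `"Ct"` assay. `NA` encodes "no amplification".
#' Column metadata carries the well annotations used by quality control:
#' `well_id`, `subject_id`, `lineage` (`"CL"` or `"NC"`), `run_id` (capture
#' run; failure-score statistics are computed within runs), and the boolean
#' artifact flags `flag_empty`, `flag_doublet`, `flag_curve` set by visual
#' well inspection and amplification-curve review upstream of this package.
#'
#' QC exclusions accumulate in `metadata(x)$qc_log`.
#'
#' @aliases CtWellSet-class
#' @export
setClass("CtWellSet", contains = "SummarizedExperiment")

.validCtWellSet <- function(object) {
  msg <- character()
  if (!"Ct" %in% names(assays(object)))
    msg <- c(msg, "assay 'Ct' is required")
  need <- c("well_id", "subject_id", "lineage", "run_id",
            "flag_empty", "flag_doublet", "flag_curve")
  missing <- setdiff(need, colnames(colData(object)))
  if (length(missing))
    msg <- c(msg, paste0("missing colData columns: ",
                         paste(missing, collapse = ", ")))
  if ("Ct" %in% names(assays(object))) {
    ct <- assay(object, "Ct")
    if (any(ct <= 0 | ct > 40, na.rm = TRUE))
      msg <- c(msg, "amplified Ct values must lie in (0, 40]")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene names in panel")
  if (length(msg)) msg else TRUE
}
setValidity("CtWellSet", .validCtWellSet)

#' Construct a CtWellSet
#'
#' @param ct Numeric matrix, genes (rows) by wells (columns); `NA` means no
#'   amplification. Rownames are the panel genes.
#' @param wellData A `data.frame` or [S4Vectors::DataFrame] of per-well
#'   annotations (one row per column of `ct`) with columns `well_id`,
#'   `subject_id`, `lineage`, `run_id`, `flag_empty`, `flag_doublet`,
#'   `flag_curve`. `run_id` defaults to `subject_id:lineage` when absent.
#' @return A [CtWellSet-class] object with an empty QC log.
#' @export
#' @examples
#' ct <- matrix(c(20, 25, NA, 22), nrow = 2,
#'              dimnames = list(c("JAK1", "TNFA"), NULL))
#' wd <- data.frame(well_id = c("w1", "w2"), subject_id = "s1",
#'                  lineage = "CL", flag_empty = FALSE,
#'                  flag_doublet = FALSE, flag_curve = FALSE)
#' CtWellSet(ct, wd)
CtWellSet <- function(ct, wellData) {
  wellData <- as(wellData, "DataFrame")
  if (!"run_id" %in% colnames(wellData))
    wellData$run_id <- paste(wellData$subject_id, wellData$lineage, sep = ":")
  colnames(ct) <- wellData$well_id
  se <- SummarizedExperiment(assays = list(Ct = ct), colData = wellData)
  out <- new("CtWellSet", se)
  metadata(out)$qc_log <- .emptyQCLog()
  out
}

.emptyQCLog <- function() {
  data.frame(well_id = character(), step = character(),
             reason = character(), stringsAsFactors = FALSE)
}

#' @describeIn CtWellSet-class QC exclusion log accumulated by the filters.
#' @param x A `CtWellSet` or `MonocyteExperiment`.
#' @export
qcLog <- function(x) {
  log <- metadata(x)$qc_log
  if (is.null(log)) .emptyQCLog() else log
}

setMethod("show", "CtWellSet", function(object) {
  cat("CtWellSet with", nrow(object), "panel genes x", ncol(object),
      "wells\n")
  cat("  subjects:", length(unique(object$subject_id)),
      " runs:", length(unique(object$run_id)), "\n")
  nflag <- sum(object$flag_empty | object$flag_doublet | object$flag_curve)
  cat("  flagged wells:", nflag,
      " QC exclusions logged:", nrow(qcLog(object)), "\n")
})

## ---------------------------------------------------------------------------
## MonocyteExperiment: QC-passed expression matrix (Et scale)
## ---------------------------------------------------------------------------

#' MonocyteExperiment: QC-passed single-cell expression matrix
#'
#' A [SingleCellExperiment::SingleCellExperiment]-derived container holding
#' the analyzable expression matrix after quality control: assay `"Et"`
#' (expression on the Et = max(0, LOD - Ct) scale, so 0 means not detected)
#' and assay `"expressed"` (logical, `Et > 0`). Per-cell annotations carry
#' `subject_id`, `lineage`, and the serum-derived patient group labels
#' `group2` (two-way: non-response-like vs response-like) and `group3`
#' (three-way: ND / ratio at most 1.3 / ratio above 1.3).
#'
#' @aliases MonocyteExperiment-class
#' @export
setClass("MonocyteExperiment", contains = "SingleCellExperiment")

.validMonocyteExperiment <- function(object) {
  msg <- character()
  if (!all(c("Et", "expressed") %in% names(assays(object))))
    return("assays 'Et' and 'expressed' are required")
  et <- assay(object, "Et")
  ex <- assay(object, "expressed")
  if (any(et < 0, na.rm = TRUE))
    msg <- c(msg, "Et expression values must be >= 0")
  if (!identical(unname(ex), unname(et > 0)))
    msg <- c(msg, "'expressed' must equal Et > 0")
  need <- c("subject_id", "lineage", "group2", "group3")
  missing <- setdiff(need, colnames(colData(object)))
  if (length(missing))
    msg <- c(msg, paste0("missing colData columns: ",
                         paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("MonocyteExperiment", .validMonocyteExperiment)

#' @describeIn MonocyteExperiment-class Expression matrix (genes x cells,
#'   Et units).
#' @param object,x A `MonocyteExperiment`.
#' @export
etMatrix <- function(x) assay(x, "Et")

#' @describeIn MonocyteExperiment-class Logical expressed/not-expressed
#'   matrix (genes x cells).
#' @export
expressedMatrix <- function(x) assay(x, "expressed")

setMethod("show", "MonocyteExperiment", function(object) {
  cat("MonocyteExperiment with", nrow(object), "genes x", ncol(object),
      "cells\n")
  lin <- table(object$lineage)
  cat("  lineages:", paste(names(lin), lin, sep = "=", collapse = " "), "\n")
  g2 <- table(object$group2)
  cat("  group2:", paste(names(g2), g2, sep = "=", collapse = " "), "\n")
  cat("  mean expressed fraction:",
      round(mean(assay(object, "expressed")), 3), "\n")
})

## ---------------------------------------------------------------------------
## CorrectionContext: correlation-adjusted Bonferroni machinery
## ---------------------------------------------------------------------------

#' CorrectionContext: correlation-adjusted Bonferroni correction
#'
#' Holds the ingredients of the modified Bonferroni correction used for the
#' per-gene tests. With `m` transcripts the panel yields
#' `n_pairs = m(m-1)/2` pairwise Spearman correlations; the mean absolute
#' correlation `mean_abs_rho` discounts the effective number of independent
#' tests, giving the corrected p-value
#' `p_corr = p_obs * m * (1 - mean_abs_rho)` and the significance threshold
#' `threshold_p = alpha / (m * (1 - mean_abs_rho))`.
#'
#' @aliases CorrectionContext-class
#' @slot m Number of tests (genes).
#' @slot n_pairs Number of unordered transcript pairs, `m(m-1)/2`.
#' @slot mean_abs_rho Mean absolute pairwise Spearman correlation in [0, 1).
#' @slot alpha Family-wise error rate, default 0.05.
#' @slot threshold_p Raw-p significance threshold implied by the above.
#' @slot n_undefined Number of pairs with undefined correlation (constant
#'   genes) excluded from the mean.
#' @export
setClass("CorrectionContext",
  representation(m = "integer", n_pairs = "numeric", mean_abs_rho = "numeric",
                 alpha = "numeric", threshold_p = "numeric",
                 n_undefined = "numeric"))

.validCorrectionContext <- function(object) {
  msg <- character()
  if (object@m < 1L) msg <- c(msg, "m must be >= 1")
  if (object@n_pairs != object@m * (object@m - 1L) / 2)
    msg <- c(msg, "n_pairs must equal m(m-1)/2")
  if (object@mean_abs_rho < 0 || object@mean_abs_rho >= 1)
    msg <- c(msg, "mean_abs_rho must lie in [0, 1)")
  if (object@alpha <= 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in (0, 1]")
  expected <- object@alpha / (object@m * (1 - object@mean_abs_rho))
  if (abs(object@threshold_p - expected) > 1e-12)
    msg <- c(msg, "threshold_p inconsistent with alpha, m and mean_abs_rho")
  if (length(msg)) msg else TRUE
}
setValidity("CorrectionContext", .validCorrectionContext)

#' Construct a CorrectionContext
#'
#' @param m Integer number of tests (transcripts).
#' @param mean_abs_rho Mean absolute pairwise Spearman correlation, in
#'   `[0, 1)`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_undefined Count of excluded undefined pairs (default 0).
#' @return A [CorrectionContext-class] object.
#' @export
#' @examples
#' ctx <- correctionContext(87, 0.2816)
#' thresholdP(ctx)
correctionContext <- function(m, mean_abs_rho, alpha = 0.05,
                              n_undefined = 0) {
  m <- as.integer(m)
  if (mean_abs_rho >= 1)
    stop("mean_abs_rho must be < 1")
  new("CorrectionContext", m = m, n_pairs = m * (m - 1) / 2,
      mean_abs_rho = mean_abs_rho, alpha = alpha,
      threshold_p = alpha / (m * (1 - mean_abs_rho)),
      n_undefined = n_undefined)
}

#' @describeIn CorrectionContext-class Raw-p significance threshold.
#' @param x A `CorrectionContext`.
#' @export
thresholdP <- function(x) x@threshold_p

#' @describeIn CorrectionContext-class Mean absolute pairwise Spearman rho.
#' @export
meanAbsRho <- function(x) x@mean_abs_rho

#' @describeIn CorrectionContext-class Number of transcript pairs.
#' @export
nPairs <- function(x) x@n_pairs

setMethod("show", "CorrectionContext", function(object) {
  cat("CorrectionContext: m =", object@m, "tests,", object@n_pairs,
      "transcript pairs\n")
  cat("  mean |rho| =", signif(object@mean_abs_rho, 4),
      " alpha =", object@alpha,
      " threshold p <", signif(object@threshold_p, 4), "\n")
  if (object@n_undefined > 0)
    cat("  (", object@n_undefined, "undefined pairs excluded )\n")
})
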