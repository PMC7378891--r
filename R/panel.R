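#' Default 87-gene innate-immunity qPCR panel
#'
#' The gene panel used throughout the package: major cytokines, interferon
#' pathway members, Toll-like receptors and monocyte surface markers assayed
#' by single-cell qPCR. The panel drives the synthetic-cohort generator and
#' the per-gene statistics; its length (87) fixes the number of tests and
#' hence the 3,741 transcript pairs entering the correlation-adjusted
#' multiple-testing correction.
#'
#' @return Character vector of 87 unique gene symbols.
#' @export
#' @examples
#' length(defaultPanel())
defaultPanel <- function() {
  panel <- c(
    ## interferon receptors and JAK/STAT
    "JAK1", "JAK2", "JAK3", "TYK2", "IFNAR1", "IFNAR2",
    "STAT1", "STAT2", "STAT3", "STAT4",
    ## interferon regulatory factors and ISGs
    "IRF1", "IRF3", "IRF5", "IRF7", "IRF8", "IRF9",
    "IFI27", "IFIT2", "IFIH1", "ISG15", "OAS1", "MX2", "IFITM3", "PKR",
    "SOCS1", "SOCS3", "PRDM1", "MAVS", "TBK1",
    ## Toll-like receptors and adaptors
    "TLR1", "TLR2", "TLR3", "TLR4", "TLR5", "TLR6", "TLR7", "TLR8", "TLR9",
    "MYD88", "TRAF3", "TRAF6", "IRAK4", "NOD2", "NLRP3", "CASP1",
    ## cytokines
    "TNFA", "IL1A", "IL1B", "IL2", "IL4", "IL5", "IL6", "IL8", "IL10",
    "IL12", "IL13", "IL15", "IL18", "IL23A", "IFNG", "GMCSF", "TGFB",
    "BAFF",
    ## chemokines and receptors
    "CCL2", "CCL5", "CXCL10", "CCR2", "CCR4", "CCR5", "CX3CR1",
    ## surface markers and costimulation
    "CD14", "CD16", "CD11b", "CD11c", "CD36", "CD40", "CD64", "CD80",
    "CD83", "CD86", "CD127", "CTLA4", "PDL1", "HLADRB1", "FCER1G",
    "ILT7", "RANK"
  )
  stopifnot(length(panel) == 87L, !anyDuplicated(panel))
  panel
}

#' Serum reporter-assay gene set
#'
#' Canonical type-I-IFN-induced genes measured in the WISH reporter assay,
#' plus the housekeeping control used for delta-Ct normalisation.
#'
#' @return Named list with elements `targets` (MX1, PKR, IFIT1) and
#'   `housekeeping` ("HK").
#' @export
serumPanel <- function() {
  list(targets = c("MX1", "PKR", "IFIT1"), housekeeping = "HK")
}
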