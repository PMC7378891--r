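#' Standardized relative expression of the reporter genes
#'
#' Computes, per reporter gene, the delta-Ct versus housekeeping, the fold
#' change relative to the healthy-donor panel mean, and the standardized
#' score `(sample - healthy mean) / healthy SD` in healthy-panel SD units.
#' The default works on the linear fold-change scale (`2^(healthy mean
#' delta-Ct - sample delta-Ct)`), under which the score is proportional to
#' the induced activity and the downstream IFN-beta/alpha ratio is an
#' activity ratio; `scale = "log2"` standardizes the log2 fold change
#' instead.
#'
#' @param sample_cts Named numeric vector of Ct values covering the three
#'   reporter targets and the housekeeping gene.
#' @param healthy_panel Long `data.frame` (`subject_id`, `gene`, `ct`) of
#'   healthy reference donors, at least 3 donors per gene.
#' @param housekeeping Housekeeping gene name (default `"HK"`).
#' @param scale `"fold_change"` (default) or `"log2"`.
#' @return Named numeric vector of per-gene scores (SD units).
#' @export
#' @examples
#' hp <- data.frame(subject_id = rep(paste0("h", 1:4), each = 2),
#'                  gene = rep(c("MX1", "HK"), 4),
#'                  ct = rep(c(27, 18), 4) + rep(c(0, .1, -.1, .2), each = 2))
#' relativeExpression(c(MX1 = 24, HK = 18), hp)
relativeExpression <- function(sample_cts, healthy_panel,
                               housekeeping = "HK",
                               scale = c("fold_change", "log2")) {
  scale <- match.arg(scale)
  targets <- setdiff(unique(healthy_panel$gene), housekeeping)
  if (!housekeeping %in% names(sample_cts))
    stop("data error: housekeeping Ct missing from sample")
  missing <- setdiff(targets, names(sample_cts))
  if (length(missing))
    stop("data error: sample is missing gene(s): ",
         paste(missing, collapse = ", "))
  hk_h <- healthy_panel[healthy_panel$gene == housekeeping, ]
  scores <- vapply(targets, function(g) {
    hg <- healthy_panel[healthy_panel$gene == g, ]
    donors <- intersect(hg$subject_id, hk_h$subject_id)
    if (length(donors) < 3)
      stop("data error: healthy panel needs >= 3 donors for ", g)
    dct_h <- hg$ct[match(donors, hg$subject_id)] -
      hk_h$ct[match(donors, hk_h$subject_id)]
    dct_s <- sample_cts[[g]] - sample_cts[[housekeeping]]
    ## delta-delta-Ct vs the healthy mean, then fold change (or log2 FC)
    lfc_s <- mean(dct_h) - dct_s
    lfc_h <- mean(dct_h) - dct_h
    if (scale == "fold_change") {
      vals_h <- 2^lfc_h; val_s <- 2^lfc_s
    } else {
      vals_h <- lfc_h; val_s <- lfc_s
    }
    s <- stats::sd(vals_h)
    if (!is.finite(s) || s == 0)
      stop("data error: zero healthy-panel SD for ", g)
    (val_s - mean(vals_h)) / s
  }, numeric(1))
  scores
}

#' Total serum type I IFN activity score
#'
#' Sums the three standardized reporter-gene scores into the serum T1IFN
#' activity score.
#'
#' @param per_gene_score Named numeric vector of three per-gene scores.
#' @return Numeric total score.
#' @export
#' @examples
#' t1ifnActivity(c(MX1 = 1, PKR = 2, IFIT1 = 3))
t1ifnActivity <- function(per_gene_score) {
  if (length(per_gene_score) != 3L || any(!is.finite(per_gene_score)))
    stop("data error: exactly three finite per-gene scores required")
  sum(per_gene_score)
}

#' Decompose total activity into IFN-alpha and IFN-beta activities
#'
#' Under the residual convention (default), blocking one subtype leaves the
#' other's activity: the activity remaining after anti-IFN-alpha
#' pre-incubation quantifies IFN-beta, and the activity remaining after
#' anti-IFN-beta quantifies IFN-alpha. The alternative `"inhibition"`
#' reading takes the *drop* in activity caused by blocking one subtype as
#' the other subtype's activity. Both clip at zero; the consistency
#' diagnostic `|alpha + beta - untreated|` is returned.
#'
#' @param untreated Total activity score of untreated serum (must be the
#'   largest signal; all-negative inputs are a data error).
#' @param after_anti_alpha Activity score after anti-IFN-alpha blocking.
#' @param after_anti_beta Activity score after anti-IFN-beta blocking.
#' @param method `"residual"` (default) or `"inhibition"`.
#' @return List with `alpha`, `beta`, `diagnostic`.
#' @export
#' @examples
#' decomposeAlphaBeta(10, 6, 4)  # alpha 4, beta 6
decomposeAlphaBeta <- function(untreated, after_anti_alpha, after_anti_beta,
                               method = c("residual", "inhibition")) {
  method <- match.arg(method)
  if (untreated < 0 && after_anti_alpha < 0 && after_anti_beta < 0)
    stop("data error: all activities negative")
  if (method == "residual") {
    beta <- max(0, after_anti_alpha)
    alpha <- max(0, after_anti_beta)
  } else {
    alpha <- max(0, untreated - after_anti_alpha)
    beta <- max(0, untreated - after_anti_beta)
  }
  list(alpha = alpha, beta = beta,
       diagnostic = abs(alpha + beta - untreated))
}

#' IFN-beta/alpha activity ratio
#'
#' Returns `beta / alpha` when the alpha activity exceeds `epsilon`. When
#' alpha is at or below `epsilon` but beta is present, the ratio is
#' undefined-high and returned as `Inf`, which the grouping rules place in
#' the above-1.3 group. Both activities at or below `epsilon` indicate a
#' serum that should already have been flagged not-detected, and raise a
#' consistency error.
#'
#' @param alpha,beta Non-negative activity scores.
#' @param epsilon Detection floor in score units (the ND score threshold).
#' @return Numeric ratio, possibly `Inf`.
#' @export
#' @examples
#' ifnRatio(4, 6, epsilon = 0.5)
ifnRatio <- function(alpha, beta, epsilon) {
  if (alpha < 0 || beta < 0) stop("activities must be >= 0")
  if (alpha <= epsilon && beta <= epsilon)
    stop("consistency error: both activities below epsilon; ",
         "serum should have been categorized not-detected")
  if (alpha <= epsilon) return(Inf)
  beta / alpha
}

#' ND score threshold from assay calibration
#'
#' Converts the "very low total activity" rule (below ~1 pg/mL) into the
#' score units produced by [relativeExpression()]. On the linear fold-change
#' scale a serum at activity `A` scores
#' `((1 + A)^slope - 1) * mean(FC_healthy) / sd(FC_healthy)` per gene, so
#' the threshold is the summed per-gene score at the pg-equivalent
#' activity. When a healthy reference panel is supplied the fold-change
#' mean and SD are taken from it — the same standardization the scores use,
#' which keeps the threshold on the scale of any given panel realisation.
#' Without a panel, the analytic SD implied by the log-normal measurement
#' noise is used: delta-delta-Ct noise has SD `sqrt(2) * ct_noise_sd`
#' cycles, giving fold-change SD `sqrt(exp(l^2) - 1) * exp(l^2 / 2)` with
#' `l = log(2) * sqrt(2) * ct_noise_sd`.
#'
#' @param params An [assayParams()] object.
#' @param pg_threshold Detection limit in pg/mL (default 1).
#' @param healthy_panel Optional long `data.frame` (`subject_id`, `gene`,
#'   `ct`) of healthy reference donors for empirical calibration.
#' @param housekeeping Housekeeping gene name (empirical path).
#' @return Score-unit threshold (numeric).
#' @export
ndScoreThreshold <- function(params, pg_threshold = 1,
                             healthy_panel = NULL, housekeeping = "HK") {
  a_nd <- pg_threshold / params$pg_per_activity_unit
  gain <- (1 + a_nd)^params$induction_slope - 1
  if (is.null(healthy_panel)) {
    l <- log(2) * sqrt(2) * params$ct_noise_sd
    sd_fc <- sqrt(exp(l^2) - 1) * exp(l^2 / 2)
    return(3 * gain / sd_fc)
  }
  targets <- setdiff(unique(healthy_panel$gene), housekeeping)
  hk_h <- healthy_panel[healthy_panel$gene == housekeeping, ]
  per_gene <- vapply(targets, function(g) {
    hg <- healthy_panel[healthy_panel$gene == g, ]
    donors <- intersect(hg$subject_id, hk_h$subject_id)
    dct_h <- hg$ct[match(donors, hg$subject_id)] -
      hk_h$ct[match(donors, hk_h$subject_id)]
    fc_h <- 2^(mean(dct_h) - dct_h)
    gain * mean(fc_h) / stats::sd(fc_h)
  }, numeric(1))
  sum(per_gene)
}

#' Convert a total activity score back to activity units
#'
#' Inverts the mean score-vs-activity curve of the simulated assay, giving
#' recovered activities on the latent (pg-equivalent) scale. Used for
#' calibration checks of the decomposition, not by the grouping pipeline
#' (which only needs the scale-free ratio).
#'
#' @param score Total (three-gene) activity score.
#' @param params An [assayParams()] object.
#' @return Activity in latent units (clipped at 0).
#' @export
scoreToActivity <- function(score, params) {
  l <- log(2) * sqrt(2) * params$ct_noise_sd
  sd_fc <- sqrt(exp(l^2) - 1) * exp(l^2 / 2)
  pmax(0, (pmax(score, 0) * sd_fc / 3 + 1)^(1 / params$induction_slope) - 1)
}

#' Assign two- and three-way patient groups
#'
#' Three-way scheme: `ND` (not detected), `le_1.3` (ratio at most 1.3) and
#' `gt_1.3` (ratio strictly above 1.3; an undefined-high `Inf` ratio lands
#' here). Two-way scheme groups `ND` with `gt_1.3` as `nonresponse_like`
#' (the TNFi non-response-associated stratum) versus `response_like`.
#'
#' @param results `data.frame` with columns `nd` (logical) and `ratio`
#'   (numeric, `NA` allowed when `nd` is `TRUE`).
#' @param scheme `"two"`, `"three"`, or `"both"` (default).
#' @return `results` with `group2` and/or `group3` columns added.
#' @export
#' @examples
#' df <- data.frame(nd = c(TRUE, FALSE, FALSE), ratio = c(NA, 1.3, 1.31))
#' assignGroups(df)
assignGroups <- function(results, scheme = c("both", "two", "three")) {
  scheme <- match.arg(scheme)
  if (!all(c("nd", "ratio") %in% names(results)))
    stop("results must have 'nd' and 'ratio' columns")
  if (any(!results$nd & is.na(results$ratio)))
    stop("non-ND subjects must have a ratio")
  group3 <- ifelse(results$nd, "ND",
                   ifelse(results$ratio > 1.3, "gt_1.3", "le_1.3"))
  group2 <- ifelse(group3 == "le_1.3", "response_like", "nonresponse_like")
  if (scheme %in% c("three", "both")) results$group3 <- group3
  if (scheme %in% c("two", "both")) results$group2 <- group2
  results
}

#' Score a cohort's serum records end to end
#'
#' For each subject: per-condition standardized scores against the healthy
#' reference panel, the total T1IFN activity score, the ND rule on the
#' untreated total, alpha/beta decomposition of detected sera, the
#' IFN-beta/alpha ratio, and the two- and three-way group labels.
#'
#' @param serum Long `data.frame` from [simulateSerum()] or
#'   [readSerumCSV()]; healthy donors carry condition `healthy_ref`.
#' @param nd_threshold Score-unit ND threshold; by default calibrated
#'   empirically against the healthy panel via [ndScoreThreshold()].
#' @param params [assayParams()] used for the default threshold
#'   calibration.
#' @param housekeeping Housekeeping gene name.
#' @param scale Standardization scale passed to [relativeExpression()].
#' @param method Decomposition convention for [decomposeAlphaBeta()].
#' @return `data.frame` with one row per subject: per-gene scores (`mx1`,
#'   `pkr`, `ifit1`), `total`, `alpha`, `beta`, `ratio`, `nd`, `group2`,
#'   `group3`, and the decomposition `diagnostic`.
#' @export
#' @examples
#' cfg <- cohortConfig(seed = 5)
#' serum <- simulateSerum(generateCohort(cfg), assayParams(), seed = 6)
#' head(scoreSerum(serum))
scoreSerum <- function(serum, nd_threshold = NULL, params = assayParams(),
                       housekeeping = "HK",
                       scale = c("fold_change", "log2"),
                       method = c("residual", "inhibition")) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  healthy <- serum[serum$condition == "healthy_ref", ]
  if (!nrow(healthy)) stop("data error: no healthy_ref records")
  if (is.null(nd_threshold))
    nd_threshold <- ndScoreThreshold(params, healthy_panel = healthy,
                                     housekeeping = housekeeping)
  patients <- serum[serum$condition != "healthy_ref", ]
  sp <- serumPanel()
  rows <- lapply(split(patients, patients$subject_id), function(ps) {
    tot <- vapply(c("none", "anti_alpha", "anti_beta"), function(cond) {
      cs <- ps[ps$condition == cond, ]
      if (!nrow(cs)) stop("data error: missing condition ", cond,
                          " for subject ", ps$subject_id[1])
      cts <- stats::setNames(cs$ct, cs$gene)
      pg <- relativeExpression(cts, healthy, housekeeping, scale)
      t1ifnActivity(pg[sp$targets])
    }, numeric(1))
    cs0 <- ps[ps$condition == "none", ]
    pg0 <- relativeExpression(stats::setNames(cs0$ct, cs0$gene), healthy,
                              housekeeping, scale)
    nd <- tot[["none"]] < nd_threshold
    if (!nd) {
      dec <- decomposeAlphaBeta(tot[["none"]], tot[["anti_alpha"]],
                                tot[["anti_beta"]], method)
      alpha <- dec$alpha; beta <- dec$beta; diag <- dec$diagnostic
      ## epsilon = half the ND threshold: the two residuals sum to at
      ## least the untreated activity (up to noise), so both below
      ## threshold/2 means the apparent detection was a noise artifact --
      ## demote to ND rather than report a meaningless ratio
      eps <- nd_threshold / 2
      if (alpha <= eps && beta <= eps) {
        warning("subject ", ps$subject_id[1], ": total activity above the ",
                "detection threshold but both subtype residuals below it; ",
                "demoted to not-detected")
        nd <- TRUE
      } else {
        ratio <- ifnRatio(alpha, beta, epsilon = eps)
      }
    }
    if (nd) {
      alpha <- beta <- ratio <- NA_real_; diag <- NA_real_
    }
    data.frame(subject_id = ps$subject_id[1],
               mx1 = pg0[["MX1"]], pkr = pg0[["PKR"]], ifit1 = pg0[["IFIT1"]],
               total = tot[["none"]], alpha = alpha, beta = beta,
               ratio = ratio, nd = nd, diagnostic = diag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  assignGroups(out)
}
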