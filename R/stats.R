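#' 2x2 expressed-by-group contingency table for one gene
#'
#' Rows are expressed / not expressed; columns are the two patient groups
#' with the non-response-like (ND or ratio above 1.3) group first, so that
#' the derived odds ratio reads "odds of being expressed in the
#' non-response-like group".
#'
#' @param me A [MonocyteExperiment-class].
#' @param gene Panel gene name.
#' @param lineage Optional lineage (`"CL"` or `"NC"`) to restrict to.
#' @param grouping Cell annotation column with exactly two levels (default
#'   `"group2"`).
#' @return 2x2 integer matrix with dimnames.
#' @export
expressedTable <- function(me, gene, lineage = NULL, grouping = "group2") {
  if (!gene %in% rownames(me)) stop("data error: gene '", gene,
                                    "' not in panel")
  keep <- if (is.null(lineage)) rep(TRUE, ncol(me)) else me$lineage == lineage
  expr <- assay(me, "expressed")[gene, keep]
  grp <- colData(me)[[grouping]][keep]
  levels <- sort(unique(grp))
  if (length(levels) != 2L)
    stop("grouping must have exactly 2 levels, found ",
         length(levels))
  ## non-response-like stratum first
  first <- intersect(c("nonresponse_like", "gt_1.3"), levels)
  if (length(first)) levels <- c(first[1], setdiff(levels, first[1]))
  tab <- vapply(levels, function(g)
    c(sum(expr & grp == g), sum(!expr & grp == g)), integer(2))
  dimnames(tab) <- list(c("expressed", "not_expressed"), levels)
  tab
}

#' Odds ratio, confidence interval and Fisher exact p for a 2x2 table
#'
#' The odds ratio is the sample cross-product `(a*d)/(b*c)`, with the
#' Haldane-Anscombe +0.5 correction applied to all cells iff any cell is
#' zero; the 95% CI is Woolf's log-OR interval `exp(log OR +/- 1.96 * SE)`
#' with `SE = sqrt(sum of reciprocal cells)`. The two-sided p-value is the
#' Fisher exact test under the hypergeometric null: the sum of
#' probabilities of all tables (with the observed margins) no more likely
#' than the observed one. Optionally the conditional-MLE odds ratio from
#' [stats::fisher.test()] is reported instead.
#'
#' @param tab 2x2 non-negative integer matrix (rows expressed/not, columns
#'   groups).
#' @param or_method `"sample"` (cross-product, default) or `"conditional"`
#'   (exact conditional MLE).
#' @return List with `or`, `ci95` (length-2), `p`, `flagged` (TRUE when a
#'   zero margin makes the odds ratio undefined).
#' @export
#' @examples
#' fisherOR(matrix(c(9, 87, 155, 91), 2))$or  # ~0.061
fisherOR <- function(tab, or_method = c("sample", "conditional")) {
  or_method <- match.arg(or_method)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(or = NA_real_, ci95 = c(NA_real_, NA_real_), p = NA_real_,
                flagged = TRUE))
  a <- tab[1, 1]; c_ <- tab[2, 1]; b <- tab[1, 2]; d <- tab[2, 2]
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  if (or_method == "sample") {
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  } else {
    or <- unname(stats::fisher.test(tab)$estimate)
  }
  se <- sqrt(sum(1 / cells))
  ci <- exp(log((cells[1] * cells[4]) / (cells[2] * cells[3])) +
              c(-1, 1) * 1.96 * se)
  list(or = or, ci95 = ci, p = .fisherExactP(a, b, c_, d), flagged = FALSE)
}

## Two-sided Fisher exact p: sum of hypergeometric probabilities of all
## tables with the observed margins whose probability does not exceed the
## observed table's (with the conventional 1e-7 relative slack).
.fisherExactP <- function(a, b, c_, d) {
  m <- a + c_          # column-1 total
  n <- b + d           # column-2 total
  k <- a + b           # row-1 total
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  min(1, sum(dens[dens <= stats::dhyper(a, m, n, k) * (1 + 1e-7)]))
}

#' Mann-Whitney U test on raw values
#'
#' Two-sided rank-sum test of group A versus group B. `U` counts pairs
#' where an A value exceeds a B value (ties count one half), so complete
#' separation with A above B gives `U = nA * nB`. For small samples (both
#' groups at most `exact_max`) the p-value is computed by exhaustive
#' permutation of the group labels over the pooled (tied) ranks; otherwise
#' the tie-corrected normal approximation (no continuity correction) is
#' used. The permutation distribution of U is symmetric about
#' `nA * nB / 2`, so the two-sided p is the probability of a deviation at
#' least as large as observed.
#'
#' @param x,y Numeric vectors (groups A and B).
#' @param exact_max Largest per-group size for the exact path (default 8).
#' @return List with `U`, `p`, `exact` (logical).
#' @export
#' @examples
#' mannWhitneyU(c(5, 6, 7), c(1, 2, 3))$U  # 9 = complete separation
mannWhitneyU <- function(x, y, exact_max = 8L) {
  if (!length(x) || !length(y))
    return(list(U = NA_real_, p = NA_real_, exact = NA))
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (nx <= exact_max && ny <= exact_max) {
    splits <- utils::combn(nx + ny, nx)
    Us <- colSums(matrix(r[splits], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p = p, exact = TRUE))
  }
  N <- nx + ny
  t_ <- table(r)
  tie_term <- sum(t_^3 - t_) / (N * (N - 1))
  sigma <- sqrt(nx * ny / 12 * ((N + 1) - tie_term))
  if (sigma == 0) return(list(U = U, p = 1, exact = FALSE))
  z <- (U - mu) / sigma
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Mann-Whitney comparison of one gene's expression between groups
#'
#' @param me A [MonocyteExperiment-class].
#' @param gene Panel gene.
#' @param lineage Optional lineage restriction.
#' @param grouping Two-level cell annotation (default `"group2"`; the
#'   non-response-like group plays the role of group A).
#' @return List with `U`, `p`, `exact`, or `NA`s (flagged) when a group is
#'   empty.
#' @export
mannWhitneyGene <- function(me, gene, lineage = NULL, grouping = "group2") {
  if (!gene %in% rownames(me)) stop("data error: gene '", gene,
                                    "' not in panel")
  keep <- if (is.null(lineage)) rep(TRUE, ncol(me)) else me$lineage == lineage
  et <- assay(me, "Et")[gene, keep]
  grp <- colData(me)[[grouping]][keep]
  levels <- sort(unique(grp))
  first <- intersect(c("nonresponse_like", "gt_1.3"), levels)
  if (length(first)) levels <- c(first[1], setdiff(levels, first[1]))
  if (length(levels) != 2L)
    stop("grouping must have exactly 2 levels")
  mannWhitneyU(et[grp == levels[1]], et[grp == levels[2]])
}

#' Pairwise Spearman correlations and the correction context
#'
#' Computes the Spearman correlation over cells for every unordered pair of
#' panel transcripts, and summarizes them into a [CorrectionContext-class]:
#' with `m` genes there are `m(m-1)/2` pairs, and the mean absolute
#' correlation discounts the effective number of independent tests. Pairs
#' with undefined correlation (constant genes) are excluded from the mean
#' and counted.
#'
#' @param x A [MonocyteExperiment-class] or a genes-by-cells numeric matrix.
#' @param lineage Optional lineage restriction (MonocyteExperiment input).
#' @param alpha Family-wise error rate (default 0.05).
#' @return A [CorrectionContext-class].
#' @export
#' @examples
#' m <- matrix(rnorm(300), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), NULL))
#' nPairs(spearmanPairs(m))  # 3
spearmanPairs <- function(x, lineage = NULL, alpha = 0.05) {
  mat <- if (is(x, "MonocyteExperiment")) {
    keep <- if (is.null(lineage)) rep(TRUE, ncol(x)) else x$lineage == lineage
    assay(x, "Et")[, keep, drop = FALSE]
  } else x
  if (nrow(mat) < 2L) stop("need >= 2 genes")
  if (ncol(mat) < 3L) stop("need >= 3 cells")
  rho <- suppressWarnings(stats::cor(t(mat), method = "spearman"))
  vals <- rho[upper.tri(rho)]
  n_undef <- sum(is.na(vals))
  if (n_undef == length(vals))
    stop("data error: all pairwise correlations undefined")
  correctionContext(nrow(mat), mean(abs(vals), na.rm = TRUE), alpha,
                    n_undefined = n_undef)
}

#' Correlation-adjusted Bonferroni correction
#'
#' `p_corrected = p_obs * m * (1 - mean|rho|)`, capped at 1: the standard
#' Bonferroni multiplier `m` discounted by the mean absolute pairwise
#' Spearman correlation between transcripts. At zero correlation this is
#' exactly Bonferroni; it is linear in the observed p and never exceeds
#' `m * p_obs`.
#'
#' @param p_obs Observed p-value(s) in `[0, 1]` (vectorized).
#' @param ctx A [CorrectionContext-class].
#' @return Corrected p-value(s).
#' @export
#' @examples
#' correctedP(0.001, correctionContext(87, 0))  # 0.087
correctedP <- function(p_obs, ctx) {
  if (any(p_obs < 0 | p_obs > 1, na.rm = TRUE))
    stop("p_obs must lie in [0, 1]")
  if (ctx@mean_abs_rho >= 1) stop("mean_abs_rho must be < 1")
  pmin(1, p_obs * ctx@m * (1 - ctx@mean_abs_rho))
}

#' Per-gene group statistics table
#'
#' Runs, for every panel gene within a lineage, the categorical
#' expressed/not-expressed comparison (odds ratio with Woolf CI and Fisher
#' exact p) and the quantitative Mann-Whitney comparison, then applies the
#' correlation-adjusted correction. A gene is significant when its raw
#' Fisher p falls below the corrected threshold.
#'
#' @param me A [MonocyteExperiment-class].
#' @param lineage Lineage to analyze (`"CL"` or `"NC"`), or `NULL` for all
#'   cells.
#' @param grouping Two-level cell annotation (default `"group2"`).
#' @param ctx Optional precomputed [CorrectionContext-class]; by default it
#'   is computed from the same lineage's expression matrix.
#' @return A [S4Vectors::DataFrame] with one row per gene: `gene`,
#'   `lineage`, `odds_ratio`, `ci_low`, `ci_high`, `p_fisher`, `mw_u`,
#'   `p_mw`, `p_corrected`, `significant`; the context is stored in
#'   `metadata()$correction`.
#' @export
geneGroupStats <- function(me, lineage = NULL, grouping = "group2",
                           ctx = NULL) {
  if (is.null(ctx)) ctx <- spearmanPairs(me, lineage)
  genes <- rownames(me)
  rows <- lapply(genes, function(g) {
    tab <- expressedTable(me, g, lineage, grouping)
    fo <- fisherOR(tab)
    mw <- mannWhitneyGene(me, g, lineage, grouping)
    DataFrame(gene = g,
              lineage = if (is.null(lineage)) "all" else lineage,
              odds_ratio = fo$or, ci_low = fo$ci95[1], ci_high = fo$ci95[2],
              p_fisher = fo$p, mw_u = mw$U, p_mw = mw$p,
              p_corrected = if (is.na(fo$p)) NA_real_
                            else correctedP(fo$p, ctx),
              significant = !is.na(fo$p) & fo$p < thresholdP(ctx))
  })
  out <- do.call(rbind, rows)
  metadata(out)$correction <- ctx
  out[order(out$p_fisher), ]
}

#' Subject-level on/off calls for one transcript
#'
#' Classifies each subject by the fraction of its cells expressing the
#' transcript: a *non-expresser* has zero expressing cells out of at least
#' `min_cells`; an *expresser* has at least one expressing cell; subjects
#' with fewer than `min_cells` cells and no expression are *indeterminate*.
#' The pooled per-cell expression rate among expresser subjects, and the
#' probability that a true expresser with `min_cells` cells would show zero
#' expressing cells (the miscategorization bound), are reported.
#'
#' @param me A [MonocyteExperiment-class].
#' @param gene Panel gene.
#' @param lineage Optional lineage restriction.
#' @param min_cells Minimum cells for a determinate non-expresser call
#'   (default 5).
#' @return List of class `"OnOffResult"`: `gene`, `lineage`, `subjects`
#'   (data.frame with `subject_id`, `cells`, `frac_expressing`, `class`),
#'   `per_cell_rate`, `miscategorization_prob`.
#' @export
onoffCalls <- function(me, gene, lineage = NULL, min_cells = 5L) {
  if (min_cells < 1L) stop("min_cells must be >= 1")
  keep <- if (is.null(lineage)) rep(TRUE, ncol(me)) else me$lineage == lineage
  expr <- assay(me, "expressed")[gene, keep]
  subj <- colData(me)$subject_id[keep]
  tab <- lapply(split(expr, subj), function(e) {
    n <- length(e); k <- sum(e)
    cls <- if (k >= 1L) "expresser"
           else if (n >= min_cells) "non-expresser"
           else "indeterminate"
    data.frame(cells = n, frac_expressing = k / n, class = cls,
               stringsAsFactors = FALSE)
  })
  subjects <- do.call(rbind, tab)
  subjects <- data.frame(subject_id = rownames(subjects), subjects,
                         row.names = NULL, stringsAsFactors = FALSE)
  exp_idx <- subjects$class == "expresser"
  rate <- if (any(exp_idx)) {
    cells_exp <- subj %in% subjects$subject_id[exp_idx]
    mean(expr[cells_exp])
  } else NA_real_
  structure(list(gene = gene,
                 lineage = if (is.null(lineage)) "all" else lineage,
                 subjects = subjects, per_cell_rate = rate,
                 miscategorization_prob =
                   if (is.na(rate)) NA_real_
                   else miscategorizationProb(rate, min_cells)),
            class = "OnOffResult")
}

#' @export
print.OnOffResult <- function(x, ...) {
  cat("OnOffResult:", x$gene, "in", x$lineage, "cells\n")
  print(table(x$subjects$class))
  cat("per-cell rate among expressers:", signif(x$per_cell_rate, 3),
      "; miscategorization prob at min cells:",
      signif(x$miscategorization_prob, 3), "\n")
  invisible(x)
}

#' Miscategorization probability for an on/off call
#'
#' Probability that a subject whose cells truly express the transcript at
#' the given per-cell rate shows zero expressing cells among `n_cells`
#' sampled cells, i.e. `(1 - rate)^n` — the chance of wrongly calling an
#' expresser a non-expresser by sampling error.
#'
#' @param per_cell_rate Per-cell expression rate in `[0, 1]`.
#' @param n_cells Number of cells sampled (at least 1).
#' @return Probability.
#' @export
#' @examples
#' miscategorizationProb(0.83, 5)  # ~1.4e-4, i.e. 0.01%
miscategorizationProb <- function(per_cell_rate, n_cells) {
  if (per_cell_rate < 0 || per_cell_rate > 1)
    stop("per_cell_rate must lie in [0, 1]")
  if (n_cells < 1) stop("n_cells must be >= 1")
  (1 - per_cell_rate)^n_cells
}

#' Screen the panel for subject-level on/off transcripts
#'
#' A transcript exhibits the on/off pattern when at least one determinate
#' subject is a non-expresser (zero expressing cells with enough cells for
#' the call) *and* at least one subject expresses it in at least
#' `on_fraction` of its cells — the bimodal subject-level state shown by
#' JAK1 in this analysis.
#'
#' @param me A [MonocyteExperiment-class].
#' @param lineage Optional lineage restriction.
#' @param min_cells Determinacy threshold for the non-expresser call.
#' @param on_fraction Minimum per-subject expressing fraction on the "on"
#'   side (default 0.8).
#' @return `data.frame` with `gene`, `n_off` (determinate non-expressers),
#'   `n_on` (subjects at or above `on_fraction`), `flagged`.
#' @export
onoffScreen <- function(me, lineage = NULL, min_cells = 5L,
                        on_fraction = 0.8) {
  rows <- lapply(rownames(me), function(g) {
    oo <- onoffCalls(me, g, lineage, min_cells)
    s <- oo$subjects
    determinate <- s$cells >= min_cells
    n_off <- sum(s$class == "non-expresser")
    n_on <- sum(determinate & s$frac_expressing >= on_fraction)
    data.frame(gene = g, n_off = n_off, n_on = n_on,
               flagged = n_off >= 1L && n_on >= 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
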