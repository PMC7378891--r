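#' Principal component analysis of the expression matrix
#'
#' Centered (optionally unit-variance) PCA of cells in gene space via
#' [stats::prcomp()]. Constant genes are dropped with a warning. The sign
#' of each component is fixed by making the largest-magnitude loading
#' positive, so results are fully deterministic.
#'
#' @param me A [MonocyteExperiment-class] or genes-by-cells matrix.
#' @param lineage Optional lineage restriction.
#' @param scale Scale genes to unit variance (default `TRUE`).
#' @return List of class `"PCAResult"`: `scores` (cells x components),
#'   `loadings` (genes x components), `variance_explained` (fraction per
#'   component), `sdev`.
#' @export
#' @examples
#' m <- matrix(rnorm(200), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), NULL))
#' runPCA(m)$variance_explained
runPCA <- function(me, lineage = NULL, scale = TRUE) {
  mat <- if (is(me, "MonocyteExperiment")) {
    keep <- if (is.null(lineage)) rep(TRUE, ncol(me)) else
      me$lineage == lineage
    assay(me, "Et")[, keep, drop = FALSE]
  } else me
  v <- apply(mat, 1, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " constant gene(s) before PCA")
    mat <- mat[v > 0, , drop = FALSE]
  }
  if (nrow(mat) < 2L) stop("fewer than 2 non-constant genes")
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = scale)
  ## deterministic sign: largest-magnitude loading of each component > 0
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = pc$sdev^2 / sum(pc$sdev^2),
                 sdev = pc$sdev),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat("PCAResult:", ncol(x$loadings), "components over",
      nrow(x$loadings), "genes,", nrow(x$scores), "cells\n")
  ve <- round(100 * x$variance_explained[seq_len(min(3, length(x$sdev)))], 2)
  cat("  variance explained (%):", paste(ve, collapse = ", "), "...\n")
  invisible(x)
}

#' Unsupervised hierarchical clustering of genes and cells
#'
#' Clusters both axes of the expression matrix with [stats::hclust()]. The
#' default distance is correlation distance (1 - Pearson r), the default
#' linkage is average — the common choices for expression heatmaps. Pairs
#' with undefined distance (constant rows/columns under the correlation
#' metric) raise an error naming the offending items.
#'
#' @param me A [MonocyteExperiment-class] or genes-by-cells matrix.
#' @param lineage Optional lineage restriction.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return List of class `"ClusterResult"`: `gene_hclust`, `cell_hclust`,
#'   `gene_order`, `cell_order`, `ordered` (the reordered matrix).
#' @export
hcluster <- function(me, lineage = NULL,
                     distance = c("correlation", "euclidean"),
                     linkage = "average") {
  distance <- match.arg(distance)
  mat <- if (is(me, "MonocyteExperiment")) {
    keep <- if (is.null(lineage)) rep(TRUE, ncol(me)) else
      me$lineage == lineage
    assay(me, "Et")[, keep, drop = FALSE]
  } else me
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need >= 2 items on each axis")
  .dist <- function(m, what) {
    if (distance == "euclidean") return(stats::dist(m))
    d <- 1 - suppressWarnings(stats::cor(t(m)))
    if (anyNA(d)) {
      ## zero-variance items are the usual culprits; name them directly
      v <- apply(m, 1, stats::var)
      bad <- rownames(m)[v == 0]
      if (!length(bad)) bad <- rownames(m)[apply(is.na(d), 1, any)]
      stop("degenerate correlation distance for ", what, ": ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    stats::as.dist(d)
  }
  gh <- stats::hclust(.dist(mat, "genes"), method = linkage)
  ch <- stats::hclust(.dist(t(mat), "cells"), method = linkage)
  structure(list(gene_hclust = gh, cell_hclust = ch,
                 gene_order = gh$order, cell_order = ch$order,
                 ordered = mat[gh$order, ch$order, drop = FALSE]),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("ClusterResult:", nrow(x$ordered), "genes x", ncol(x$ordered),
      "cells (", x$gene_hclust$method, "linkage )\n")
  invisible(x)
}

#' Multivariate logistic model with backward elimination
#'
#' Fits a binomial GLM of patient group on the candidate genes' expression
#' and removes, one at a time, the non-significant coefficient with the
#' largest Wald p-value until all remaining coefficients have `p < p_stay`.
#' Genes showing (quasi-)complete separation — runaway coefficients with
#' huge standard errors — are retained with a `flagged` non-converged
#' coefficient and exempted from elimination, since their Wald p-values are
#' meaningless. The retained model's per-cell predicted probabilities are
#' summarized by ROC AUC.
#'
#' @param me A [MonocyteExperiment-class].
#' @param candidate_genes Genes pre-filtered by univariate significance.
#' @param lineage Optional lineage restriction.
#' @param grouping Two-level annotation; the non-response-like level is the
#'   positive class.
#' @param p_stay Retention threshold (default 0.05).
#' @return List of class `"ModelResult"`: `retained`, `flagged`,
#'   `coefficients` (matrix), `fitted_prob`, `labels`, `auc`, `auc_se`,
#'   `auc_ci95`, `fit`.
#' @export
multivariateModel <- function(me, candidate_genes, lineage = NULL,
                              grouping = "group2", p_stay = 0.05) {
  if (length(candidate_genes) < 1L) stop("need >= 1 candidate gene")
  keep <- if (is.null(lineage)) rep(TRUE, ncol(me)) else me$lineage == lineage
  grp <- colData(me)[[grouping]][keep]
  levels <- sort(unique(grp))
  if (length(levels) != 2L) stop("one class absent from grouping")
  pos <- intersect(c("nonresponse_like", "gt_1.3"), levels)
  pos <- if (length(pos)) pos[1] else levels[1]
  y <- as.integer(grp == pos)
  X <- t(assay(me, "Et")[candidate_genes, keep, drop = FALSE])
  current <- candidate_genes
  flagged <- character()
  repeat {
    df <- data.frame(y = y, X[, current, drop = FALSE], check.names = FALSE)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = df, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    co <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
    gene_of <- function(nm) gsub("^`|`$", "", nm)
    sep <- abs(co[, "Estimate"]) > 15 | co[, "Std. Error"] > 50
    flagged <- union(flagged, gene_of(rownames(co)[sep]))
    removable <- rownames(co)[!sep]
    if (!length(removable)) break
    pvals <- co[removable, "Pr(>|z|)"]
    worst <- removable[which.max(pvals)]
    if (max(pvals) < p_stay) break
    current <- setdiff(current, gene_of(worst))
    if (!length(current)) {
      fit <- stats::glm(y ~ 1, family = stats::binomial())
      break
    }
  }
  prob <- stats::fitted(fit)
  roc <- if (length(current)) rocAUC(prob, y) else
    list(auc = NA_real_, se = NA_real_, ci95 = c(NA_real_, NA_real_))
  structure(list(retained = current, flagged = intersect(flagged, current),
                 coefficients = summary(fit)$coefficients,
                 fitted_prob = prob, labels = y,
                 auc = roc$auc, auc_se = roc$se, auc_ci95 = roc$ci95,
                 fit = fit),
            class = "ModelResult")
}

#' @export
print.ModelResult <- function(x, ...) {
  cat("ModelResult:", length(x$retained), "gene(s) retained:",
      paste(x$retained, collapse = ", "), "\n")
  if (length(x$flagged))
    cat("  separation-flagged:", paste(x$flagged, collapse = ", "), "\n")
  cat("  AUC", signif(x$auc, 3), "(SE", signif(x$auc_se, 3), ", 95% CI",
      paste(signif(x$auc_ci95, 3), collapse = "-"), ")\n")
  invisible(x)
}

#' ROC area under the curve with Hanley-McNeil standard error
#'
#' AUC via the rank statistic (equivalent to the Mann-Whitney U divided by
#' `n1 * n0`), standard error by the Hanley-McNeil formula, and a normal
#' 95% CI truncated to `[0, 1]`.
#'
#' @param scores Numeric predicted scores or probabilities.
#' @param labels Binary labels (logical, 0/1, or two-level factor; the
#'   higher/TRUE level is the positive class).
#' @return List with `auc`, `se`, `ci95`.
#' @export
#' @examples
#' rocAUC(c(.9, .8, .2, .1), c(1, 1, 0, 0))$auc  # 1
rocAUC <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * se))
  list(auc = auc, se = se, ci95 = ci)
}
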