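test_that("expressed tables conserve counts and orient the groups", {
  expr <- matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE), nrow = 1,
                 dimnames = list("G1", NULL))
  me <- makeME(expr, subject_id = rep(c("s1", "s2"), each = 3),
               group2 = rep(c("nonresponse_like", "response_like"),
                            each = 3))
  tab <- expressedTable(me, "G1")
  expect_equal(colnames(tab), c("nonresponse_like", "response_like"))
  expect_equal(sum(tab), 6L)
  expect_equal(tab["expressed", "nonresponse_like"], 3L)
  expect_equal(tab["not_expressed", "nonresponse_like"], 0L)
  expect_error(expressedTable(me, "NOPE"), "not in panel")
})

test_that("odds ratio and CI follow the cross-product and Woolf forms", {
  # symmetric table
  res <- fisherOR(matrix(c(5, 5, 5, 5), 2))
  expect_equal(res$or, 1)
  expect_equal(res$p, 1)
  # Haldane-Anscombe applied to all cells iff any cell is zero
  res0 <- fisherOR(matrix(c(0, 10, 10, 10), 2))
  expect_equal(res0$or, (0.5 * 10.5) / (10.5 * 10.5))
  # zero margin -> undefined, flagged
  resm <- fisherOR(matrix(c(0, 0, 5, 5), 2))
  expect_true(resm$flagged)
  expect_true(is.na(resm$or))
})

test_that("Fisher p matches the enumeration oracle and fisher.test", {
  set.seed(31)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisherOR(tab)$p
    expect_equal(p, fisherOracle(tab[1, 1], tab[1, 2], tab[2, 1],
                                 tab[2, 2]),
                 tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("Mann-Whitney U counts exceedances and detects separation", {
  res <- mannWhitneyU(c(5, 6, 7), c(1, 2, 3))
  expect_equal(res$U, 9)   # complete separation: U = nA * nB
  # identical samples: U at its mean, p = 1 by exchange symmetry
  res2 <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$U, 4.5)
  expect_equal(res2$p, 1)
})

test_that("exact Mann-Whitney p equals the permutation oracle", {
  set.seed(32)
  for (i in 1:15) {
    x <- round(rnorm(5), 1)
    y <- round(rnorm(5), 1)   # rounding forces occasional ties
    res <- mannWhitneyU(x, y)
    expect_true(res$exact)
    expect_equal(res$p, mwOracle(x, y), tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney matches the tie-corrected normal", {
  set.seed(33)
  x <- round(rnorm(30), 1); y <- round(rnorm(25, 0.5), 1)
  res <- mannWhitneyU(x, y)
  expect_false(res$exact)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(res$U, unname(ref$statistic))
})

test_that("Spearman pair machinery counts pairs and handles degeneracy", {
  m <- matrix(rnorm(30), nrow = 3, dimnames = list(c("A", "B", "C"), NULL))
  ctx <- spearmanPairs(m)
  expect_equal(nPairs(ctx), 3)
  # duplicated gene rows give rho 1 for that pair
  m2 <- rbind(m, D = m["A", ])
  ctx2 <- spearmanPairs(m2)
  expect_equal(nPairs(ctx2), 6)
  rho <- cor(t(m2), method = "spearman")
  expect_equal(rho["A", "D"], 1)
  # constant genes are excluded from the mean with a logged count
  m3 <- rbind(m, K = rep(1, ncol(m)))
  ctx3 <- spearmanPairs(m3)
  expect_equal(ctx3@n_undefined, 3)
  expect_equal(meanAbsRho(ctx3), meanAbsRho(ctx))
})

test_that("the corrected p-value is the discounted Bonferroni product", {
  ctx0 <- correctionContext(87, 0)
  expect_equal(correctedP(0.001, ctx0), 0.087)
  expect_equal(correctedP(0, ctx0), 0)
  expect_equal(correctedP(0.5, ctx0), 1)   # capped
  # linear in p, monotone decreasing in mean |rho|, always <= m * p
  p <- c(1e-5, 1e-4, 1e-3)
  for (rho in c(0, 0.2, 0.5, 0.9)) {
    ctx <- correctionContext(87, rho)
    expect_equal(correctedP(p, ctx), p * 87 * (1 - rho))
    expect_true(all(correctedP(p, ctx) <= 87 * p + 1e-15))
  }
  expect_error(correctionContext(87, 1), "< 1")
  expect_error(correctedP(1.2, ctx0), "0, 1")
})

test_that("gene-level stats table flags planted group differences", {
  set.seed(34)
  n <- 120  # cells per group
  genes <- c("UP1", "UP2", "NULL1", "NULL2", "NULL3")
  p_non <- c(0.85, 0.80, 0.5, 0.5, 0.5)
  p_res <- c(0.45, 0.40, 0.5, 0.5, 0.5)
  expr <- rbind(
    vapply(seq_len(2 * n), function(i)
      runif(5) < if (i <= n) p_non else p_res, logical(5)))
  dimnames(expr) <- list(genes, NULL)
  me <- makeME(expr,
               subject_id = rep(c("s1", "s2", "s3", "s4"), each = n / 2),
               group2 = rep(c("nonresponse_like", "response_like"),
                            each = n))
  st <- geneGroupStats(me, ctx = correctionContext(5, 0))
  df <- as.data.frame(st)
  expect_true(all(df$significant[df$gene %in% c("UP1", "UP2")]))
  expect_false(any(df$significant[grepl("NULL", df$gene)]))
  expect_true(all(df$odds_ratio[df$gene %in% c("UP1", "UP2")] > 1))
  expect_equal(df$p_corrected, pmin(1, df$p_fisher * 5))
})

test_that("on/off subject classification follows the determinacy rules", {
  # subjects: 0/20 (non-expresser), 19/20 (expresser), 0/3 (indeterminate)
  expr <- matrix(c(rep(FALSE, 20), rep(TRUE, 19), FALSE, rep(FALSE, 3)),
                 nrow = 1, dimnames = list("JAK1", NULL))
  me <- makeME(expr,
               subject_id = c(rep("s1", 20), rep("s2", 20), rep("s3", 3)),
               group2 = c(rep("nonresponse_like", 20),
                          rep("response_like", 23)))
  oo <- onoffCalls(me, "JAK1", min_cells = 5)
  cls <- setNames(oo$subjects$class, oo$subjects$subject_id)
  expect_equal(cls[["s1"]], "non-expresser")
  expect_equal(cls[["s2"]], "expresser")
  expect_equal(cls[["s3"]], "indeterminate")
  expect_equal(oo$per_cell_rate, 19 / 20)
  expect_equal(oo$miscategorization_prob, (1 / 20)^5)
})

test_that("on/off states planted in a cohort are fully recovered", {
  dat <- makeSmallCohortData(seed = 302, cells = 25)
  oo_cl <- onoffCalls(dat$me, "JAK1", "CL", min_cells = 5)
  oo_nc <- onoffCalls(dat$me, "JAK1", "NC", min_cells = 5)
  truth <- setNames(dat$cohort$jak1_state, dat$cohort$subject_id)
  for (oo in list(oo_cl, oo_nc)) {
    det <- oo$subjects[oo$subjects$class != "indeterminate", ]
    expect_equal(det$class,
                 unname(ifelse(truth[det$subject_id] == "non-expresser",
                               "non-expresser", "expresser")))
  }
})

test_that("miscategorization probability is the zero-expression chance", {
  expect_equal(miscategorizationProb(1, 7), 0)
  expect_equal(miscategorizationProb(0.5, 3), 0.125)
  # Monte-Carlo oracle at 1e6 draws
  set.seed(35)
  mc <- mean(replicate(1e6, all(runif(3) > 0.5)))
  se <- sqrt(0.125 * 0.875 / 1e6)
  expect_lt(abs(mc - miscategorizationProb(0.5, 3)), 3 * se)
  expect_error(miscategorizationProb(1.2, 5), "0, 1")
})

test_that("the on/off screen flags only bimodal subject patterns", {
  dat <- makeSmallCohortData(seed = 303, cells = 25)
  sc <- onoffScreen(dat$me, "CL")
  expect_true(sc$flagged[sc$gene == "JAK1"])
  expect_false(any(sc$flagged[sc$gene != "JAK1"]))
  # a constant always-expressed gene is never flagged
  expr <- matrix(TRUE, nrow = 1, ncol = 40, dimnames = list("G", NULL))
  me <- makeME(expr, subject_id = rep(c("a", "b"), each = 20),
               group2 = rep(c("nonresponse_like", "response_like"),
                            each = 20))
  expect_false(any(onoffScreen(me)$flagged))
})
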