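# Healthy panel with donor-to-donor spread for standardization tests.
makeHealthyPanel <- function(spread = c(-0.2, -0.1, 0.1, 0.2)) {
  genes <- c("MX1", "PKR", "IFIT1")
  do.call(rbind, lapply(seq_along(spread), function(d) {
    data.frame(subject_id = sprintf("h%02d", d),
               gene = c(genes, "HK"),
               ct = c(27, 27, 27, 18) + c(rep(spread[d], 3), 0),
               stringsAsFactors = FALSE)
  }))
}

test_that("standardized scores behave at the healthy mean and +2 SD", {
  hp <- makeHealthyPanel()
  genes <- c("MX1", "PKR", "IFIT1")
  # log2 scale: delta-Ct at the healthy mean gives score 0 per gene
  at_mean <- c(stats::setNames(rep(27, 3), genes), HK = 18)
  s0 <- relativeExpression(at_mean, hp, scale = "log2")
  expect_equal(unname(s0), rep(0, 3))
  # 2 healthy-SDs above the mean (lower Ct = more expression)
  sd_h <- sd(c(-0.2, -0.1, 0.1, 0.2))
  up2 <- c(stats::setNames(rep(27 - 2 * sd_h, 3), genes), HK = 18)
  s2 <- relativeExpression(up2, hp, scale = "log2")
  expect_equal(unname(s2), rep(2, 3))
  expect_equal(t1ifnActivity(s2), 6)
})

test_that("relative expression validates its inputs", {
  hp <- makeHealthyPanel()
  expect_error(relativeExpression(c(MX1 = 24, PKR = 24, IFIT1 = 24), hp),
               "housekeeping")
  expect_error(relativeExpression(c(MX1 = 24, HK = 18), hp), "missing gene")
  hp0 <- makeHealthyPanel(spread = c(0, 0, 0))
  expect_error(
    relativeExpression(c(MX1 = 24, PKR = 24, IFIT1 = 24, HK = 18), hp0),
    "zero healthy-panel SD")
})

test_that("total activity is a plain sum with input checks", {
  expect_equal(t1ifnActivity(c(a = 1, b = 2, c = 3)), 6)
  expect_equal(t1ifnActivity(c(a = 0, b = 0, c = 0)), 0)
  expect_equal(t1ifnActivity(c(c = 3, a = 1, b = 2)), 6)
  expect_error(t1ifnActivity(c(1, 2)), "three")
})

test_that("score increases monotonically with planted activity", {
  params <- assayParams()
  acts <- seq(0.5, 20, length.out = 100)
  cohort <- data.frame(subject_id = sprintf("s%03d", seq_along(acts)),
                       group = "low_ratio", alpha_activity = acts / 2,
                       beta_activity = acts / 2, jak1_state = "expresser")
  serum <- simulateSerum(cohort, params, seed = 21)
  res <- scoreSerum(serum, params = params)
  res <- res[match(cohort$subject_id, res$subject_id), ]
  expect_gt(cor(res$total, acts, method = "spearman"), 0.9)
})

test_that("alpha/beta decomposition follows the residual convention", {
  d <- decomposeAlphaBeta(10, 6, 4)
  expect_equal(d$alpha, 4)
  expect_equal(d$beta, 6)
  expect_equal(d$diagnostic, 0)
  d2 <- decomposeAlphaBeta(10, 0, 10)  # pure IFN-alpha serum
  expect_equal(d2$alpha, 10)
  expect_equal(d2$beta, 0)
  # inhibition reading swaps the roles of the two blocked conditions
  d3 <- decomposeAlphaBeta(10, 6, 4, method = "inhibition")
  expect_equal(d3$alpha, 4)
  expect_equal(d3$beta, 6)
  expect_error(decomposeAlphaBeta(-1, -2, -3), "negative")
})

test_that("decomposition recovers planted activities within tolerance", {
  # 500 subjects at total activity 10, efficiencies 0.95, default noise;
  # mean absolute error of each recovered subtype < 10% of the total.
  # A large healthy panel isolates decomposition error from the shared
  # reference-SD estimation error.
  params <- assayParams(healthy_panel_size = 200)
  n <- 500
  cohort <- data.frame(subject_id = sprintf("s%03d", 1:n),
                       group = "low_ratio", alpha_activity = 4,
                       beta_activity = 6, jak1_state = "expresser")
  serum <- simulateSerum(cohort, params, seed = 22)
  res <- scoreSerum(serum, params = params)
  a_hat <- scoreToActivity(res$alpha, params)
  b_hat <- scoreToActivity(res$beta, params)
  expect_lt(mean(abs(a_hat - 4)), 1)
  expect_lt(mean(abs(b_hat - 6)), 1)
})

test_that("ratio handles detection-floor edge cases", {
  expect_equal(ifnRatio(4, 6, epsilon = 0.5), 1.5)
  expect_equal(ifnRatio(6, 6, epsilon = 0.5), 1)
  expect_identical(ifnRatio(0, 5, epsilon = 0.5), Inf)
  expect_error(ifnRatio(0.1, 0.2, epsilon = 0.5), "consistency")
})

test_that("group assignment matches the two- and three-way schemes", {
  df <- data.frame(
    nd = c(rep(TRUE, 3), rep(FALSE, 12)),
    ratio = c(rep(NA, 3), seq(0.4, 1.3, length.out = 6),
              c(1.31, 2, 2.5, 3, Inf, 1.7)))
  out <- assignGroups(df)
  expect_equal(as.vector(table(out$group3)[c("ND", "le_1.3", "gt_1.3")]),
               c(3L, 6L, 6L))
  expect_equal(as.vector(table(out$group2)[c("nonresponse_like",
                                             "response_like")]),
               c(9L, 6L))
  # exactly 1.3 stays in the at-most group (strict inequality)
  expect_equal(out$group3[9], "le_1.3")
  # two-way label is a function of the three-way label
  expect_true(all((out$group3 == "le_1.3") ==
                    (out$group2 == "response_like")))
  expect_error(assignGroups(data.frame(nd = FALSE, ratio = NA)), "ratio")
})

test_that("ratio and grouping are scale equivariant", {
  for (c_ in c(0.5, 2, 10)) {
    expect_equal(ifnRatio(4 * c_, 6 * c_, epsilon = 0.1), 1.5)
  }
})

test_that("simulated cohorts are regrouped correctly at default noise", {
  cfg <- cohortConfig(
    n_per_group = c(ND = 10L, low_ratio = 25L, high_ratio = 25L),
    seed = 23)
  cohort <- generateCohort(cfg)
  params <- assayParams()
  serum <- simulateSerum(cohort, params, seed = 24)
  res <- scoreSerum(serum, params = params)
  res <- res[match(cohort$subject_id, res$subject_id), ]
  truth <- ifelse(cohort$group == "ND", "ND",
                  ifelse(cohort$group == "high_ratio", "gt_1.3", "le_1.3"))
  expect_gte(mean(res$group3 == truth), 0.9)
})
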