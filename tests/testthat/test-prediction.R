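test_that("longitudinal features summarize a visit series", {
  f <- longitudinalFeatures(c(0, 1, 2), c(1, 3, 2))
  expect_equal(f, list(last_level = 2, max_level = 3,
                       last_slope = -1, max_slope = 2))
  g <- longitudinalFeatures(c(0, 1, 2), c(4, 4, 4))
  expect_equal(g$last_slope, 0); expect_equal(g$max_slope, 0)
  expect_equal(g$last_level, g$max_level)
  h <- longitudinalFeatures(c(0, 2), c(1, 5))
  expect_equal(h$last_slope, h$max_slope)
  expect_null(longitudinalFeatures(1, 5))
  expect_error(longitudinalFeatures(c(0, 0), c(1, 2)), "strictly increasing")
})

test_that("rank-based AUC equals the brute-force all-pairs oracle", {
  expect_equal(aucPredict(1:4, c(F, F, T, T))$auc, 1)
  expect_equal(aucPredict(c(3, 1, 2, 4), c(F, T, F, T))$auc, 0.5)
  expect_equal(aucPredict(rep(2, 6), c(T, T, F, F, F, T))$auc, 0.5)
  set.seed(7)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    v <- sample(0:10, n, replace = TRUE)  # heavy ties
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(l) == 0 || sum(!l) == 0) next
    expect_identical(aucPredict(v, l)$auc, bruteForceAUC(v, l))
  }
})

test_that("AUC of a marker and its negation sum to one", {
  set.seed(8)
  v <- rnorm(40); l <- rep(c(TRUE, FALSE), 20)
  expect_equal(aucPredict(v, l)$auc + aucPredict(-v, l)$auc, 1)
  # orienting by direction is equivalent to negating the values
  expect_equal(aucPredict(v, l, "decreased")$auc, aucPredict(-v, l)$auc)
  expect_error(aucPredict(v, rep(TRUE, 40)), "non-empty")
})

test_that("Cox prediction is calibrated on exponential survival draws", {
  set.seed(12)
  n <- 2000
  z <- rnorm(n)
  t <- rexp(n, rate = 0.2 * exp(0 * z))
  cens <- runif(n, 0, 10)
  ev <- t <= cens
  r0 <- hazardPredict(z, pmin(t, cens), ev)
  se <- sqrt(1 / sum(ev))
  expect_lt(abs(log(r0$ratio)), 3 * se)  # null marker: ratio near 1

  set.seed(13)
  n <- 500
  z <- rnorm(n)
  t <- rexp(n, rate = 0.2 * exp(log(2) * z))
  cens <- runif(n, 0, 10)
  ev <- t <= cens
  r <- hazardPredict(z, pmin(t, cens), ev)
  expect_gte(r$ratio, 1.7); expect_lte(r$ratio, 2.3)

  flat <- hazardPredict(rep(1, 20), rexp(20, 1), rep(TRUE, 20))
  expect_false(flat$converged)
  expect_error(hazardPredict(rnorm(5), rexp(5), rep(FALSE, 5)), "no events")
})

test_that("per-category points take the maximum stratum level", {
  res <- function(types, ps) data.frame(stratum_type = types, p = ps)
  expect_identical(step4Points(res(c("ALL", "gender_dx"), c(0.01, 0.001))), 3L)
  expect_identical(step4Points(res(c("gender", "gender_dx"), c(0.03, 0.01))), 2L)
  expect_identical(step4Points(res("gender_dx", 0.04)), 1L)
  expect_identical(step4Points(res(c("ALL", "gender"), c(0.2, 0.8))), 0L)
  expect_identical(step4Points(NULL), 0L)
  # monotone: adding a significant stratum never lowers the points
  base <- res("gender_dx", 0.01)
  expect_gte(step4Points(rbind(base, res("gender", 0.01))),
             step4Points(base))
})

test_that("Bonferroni survival is strict at 0.05 / n", {
  expect_true(bonferroniFlag(4.78e-4, 95))   # cut 5.26e-4
  expect_false(bonferroniFlag(0.04, 95))
  expect_false(bonferroniFlag(0.05 / 95, 95))
})

test_that("stratified testing ranks planted trait markers above nulls", {
  sim <- simulateCohort(smallSimConfig(seed = 41, n_subjects_test = 120))
  arms <- splitArms(sim$cohort)
  test <- zscoreByStratum(arms$test)
  truth <- sim$truth
  nulls <- setdiff(rownames(test),
                   c(truth$state_marker_ids, truth$trait_marker_ids))[1:10]
  cand <- data.frame(
    probeset = c(truth$trait_marker_ids, nulls),
    direction = c(truth$directions[truth$trait_marker_ids],
                  rep("increased", 10)),
    stringsAsFactors = FALSE)
  pred <- testPrediction(test, cand)
  cox_all <- pred[pred$target == "hosp_all_future" & pred$stratum == "ALL" &
                    pred$mode == "cross_sectional", ]
  planted_or <- cox_all$statistic[cox_all$probeset %in% truth$trait_marker_ids]
  null_or <- cox_all$statistic[cox_all$probeset %in% nulls]
  expect_gt(median(planted_or), median(null_or))
  expect_gt(median(planted_or), 1.3)
  # schema and invariant checks on the tidy output
  auc_rows <- pred[pred$target != "hosp_all_future", ]
  expect_true(all(auc_rows$statistic >= 0 & auc_rows$statistic <= 1))
  expect_true(all(pred$n_pos <= pred$n_total))
  expect_true(all(c("cross_sectional", "longitudinal") %in% pred$mode))
})
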