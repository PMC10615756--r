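test_that("identical seeds give bit-identical cohorts", {
  a <- simulateCohort(smallSimConfig(seed = 42))
  b <- simulateCohort(smallSimConfig(seed = 42))
  expect_identical(exprsMatrix(a$cohort), exprsMatrix(b$cohort))
  expect_identical(visitData(a$cohort), visitData(b$cohort))
  expect_identical(a$truth, b$truth)
  c <- simulateCohort(smallSimConfig(seed = 43))
  expect_false(identical(exprsMatrix(a$cohort), exprsMatrix(c$cohort)))
})

test_that("planted state-marker separability matches the binormal closed form", {
  # null effect: AUC within 0.5 +/- 3 SE
  sim0 <- simulateCohort(smallSimConfig(seed = 5, state_effect = 0,
                                        severe_extra_effect = 0))
  lab0 <- stateLabels(sim0$cohort)
  pole0 <- lab0 %in% c("HIGH", "SEVERE")
  use0 <- pole0 | lab0 == "LOW"
  x0 <- exprsMatrix(sim0$cohort)
  n1 <- sum(pole0[use0]); n0 <- sum(use0) - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  auc0 <- vapply(sim0$truth$state_marker_ids, function(ps) {
    d <- if (sim0$truth$directions[ps] == "increased") 1 else -1
    aucPredict(d * x0[ps, use0], pole0[use0])$auc
  }, numeric(1))
  expect_lt(abs(mean(auc0) - 0.5), 3 * se)

  # effect d with unit noise: AUC ~ pnorm(d / sqrt(2))
  d <- 1.2
  sim <- simulateCohort(cohortSimConfig(
    n_subjects_discovery = 40, n_subjects_validation = 20,
    n_subjects_test = 150, n_probesets = 120, n_state_markers = 20,
    n_trait_markers = 0, state_effect = d, severe_extra_effect = 0,
    seed = 6))
  lab <- stateLabels(sim$cohort)
  pole <- lab %in% c("HIGH", "SEVERE")
  use <- pole | lab == "LOW"
  x <- exprsMatrix(sim$cohort)
  auc <- vapply(sim$truth$state_marker_ids, function(ps) {
    s <- if (sim$truth$directions[ps] == "increased") 1 else -1
    aucPredict(s * x[ps, use], pole[use])$auc
  }, numeric(1))
  expect_equal(mean(auc), pnorm(d / sqrt(2)), tolerance = 0.02)
})

test_that("synthetic evidence tables honor their annotation rates", {
  sim <- simulateCohort(smallSimConfig(seed = 9))
  planted <- c(sim$truth$state_marker_ids, sim$truth$trait_marker_ids)
  ann <- sim$truth$annotation
  planted_genes <- ann$gene_symbol[match(planted, ann$probeset)]

  full <- simulateEvidenceTable(sim$truth, sensitivity = 1,
                                false_positive_rate = 0, seed = 1)
  expect_setequal(unique(full$gene_symbol), planted_genes)
  expect_true(all(table(full$gene_symbol) == 6))

  empty <- simulateEvidenceTable(sim$truth, sensitivity = 0,
                                 false_positive_rate = 0, seed = 1)
  expect_identical(nrow(empty), 0L)

  # false positives follow binomial(n_null, fpr): 99% interval
  big <- simulateCohort(cohortSimConfig(
    n_subjects_discovery = 4, n_subjects_validation = 2,
    n_subjects_test = 4, n_probesets = 1020, n_state_markers = 10,
    n_trait_markers = 10, seed = 2))
  tab <- simulateEvidenceTable(big$truth, sensitivity = 0,
                               false_positive_rate = 0.05, seed = 8)
  n_annotated <- length(unique(tab$gene_symbol))
  ci <- qbinom(c(0.005, 0.995), 1000, 0.05)
  expect_gte(n_annotated, ci[1])
  expect_lte(n_annotated, ci[2])
})

test_that("hospitalization frequency rises with the planted trait hazard", {
  # the hazard acts through the trait score, so the observable consequence
  # is the event-rate gap between high- and low-trait-score subjects: it is
  # zero in expectation at trait_log_hazard = 0 and widens monotonically
  gap <- vapply(c(0, 0.7, 1.4), function(b) {
    sim <- simulateCohort(smallSimConfig(seed = 21, trait_log_hazard = b,
                                         n_subjects_test = 150))
    v <- visitData(sim$cohort)
    x <- exprsMatrix(sim$cohort)
    first <- v[v$cohort == "test" & v$visit_index == 1, ]
    dsign <- ifelse(sim$truth$directions[sim$truth$trait_marker_ids] ==
                      "increased", 1, -1)
    score <- colMeans(x[sim$truth$trait_marker_ids, first$sample_id] * dsign)
    hi <- score > stats::median(score)
    mean(first$followup_any_future_hosp[hi]) -
      mean(first$followup_any_future_hosp[!hi])
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
  expect_lt(abs(gap[1]), 0.2)  # no spurious association without the hazard
  expect_gt(gap[3], 0.3)
})

test_that("simulated cohorts satisfy the data-model contracts", {
  sim <- simulateCohort(smallSimConfig(seed = 13))
  expect_true(methods::validObject(sim$cohort))
  v <- visitData(sim$cohort)
  # every discovery subject carries at least one diametric pair
  pairs <- findDiametricPairs(sim$cohort[, v$cohort == "discovery"])
  expect_setequal(unique(pairs$subject_id),
                  unique(v$subject_id[v$cohort == "discovery"]))
  # validation arm is uniformly SEVERE
  lab <- stateLabels(sim$cohort)
  expect_true(all(lab[v$cohort == "validation"] == "SEVERE"))
  # follow-up timing is internally consistent
  ok <- !is.na(v$time_to_first_hosp)
  expect_true(all(v$time_to_first_hosp[ok] <= v$censor_time[ok]))
})
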