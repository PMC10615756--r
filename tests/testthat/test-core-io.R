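test_that("reading a cohort preserves shape and rejects malformed input", {
  dir <- withr::local_tempdir()
  ep <- file.path(dir, "expr.tsv")
  mp <- file.path(dir, "meta.tsv")
  visits <- toyVisits(c("LOW", "HIGH", "LOW", "HIGH"))
  x <- matrix(round(rnorm(12), 3), 3, 4,
              dimnames = list(c("a_at", "b_at", "c_at"), visits$sample_id))
  write.table(data.frame(probeset = rownames(x), x, check.names = FALSE),
              ep, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(visits, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  ch <- readCohort(ep, mp)
  expect_identical(dim(exprsMatrix(ch)), c(3L, 4L))
  expect_identical(nrow(visitData(ch)), 4L)

  # unmatched metadata sample must be named in the error
  bad <- visits; bad$sample_id[2] <- "S9"
  write.table(bad, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCohort(ep, mp), "S9")

  # duplicate probeset and non-numeric cells are hard errors
  dup <- data.frame(probeset = c("a_at", "a_at", "c_at"), x,
                    check.names = FALSE)
  write.table(dup, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(visits, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCohort(ep, mp), "a_at")
  xc <- data.frame(probeset = rownames(x), x, check.names = FALSE)
  xc[2, 3] <- "oops"
  write.table(xc, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCohort(ep, mp), "b_at")
})

test_that("write-then-read round-trips a simulated cohort", {
  sim <- simulateCohort(smallSimConfig(seed = 11))
  dir <- withr::local_tempdir()
  ep <- file.path(dir, "expr.tsv"); mp <- file.path(dir, "meta.tsv")
  dp <- file.path(dir, "calls.tsv")
  writeCohort(sim$cohort, ep, mp, dp)
  back <- readCohort(ep, mp, dp)
  expect_equal(exprsMatrix(back), exprsMatrix(sim$cohort), tolerance = 1e-12)
  expect_identical(detectionCalls(back), detectionCalls(sim$cohort))
  v0 <- visitData(sim$cohort); v1 <- visitData(back)
  expect_equal(v1[names(v0)], v0, tolerance = 1e-12)
})

test_that("state labels follow the SAS-4 / STAI thresholds exactly", {
  expect_equal(as.character(labelState(35)), "LOW")
  expect_equal(as.character(labelState(70, 60)), "SEVERE")
  expect_equal(as.character(labelState(50)), "INTERMEDIATE")
  # boundaries are inclusive; missing STAI never makes SEVERE
  expect_equal(as.character(labelState(c(40, 60, 60, 60), c(NA, 55, 54, NA))),
               c("LOW", "SEVERE", "HIGH", "HIGH"))
  expect_error(labelState(NA_real_), "missing")
  # total and order-independent
  sas <- runif(50, 0, 100); stai <- runif(50, 20, 80)
  perm <- sample(50)
  expect_identical(labelState(sas, stai)[perm],
                   labelState(sas[perm], stai[perm]))
})

test_that("stratified z-scoring normalizes each stratum and is idempotent", {
  visits <- rbind(toyVisits(c("LOW", "HIGH", "LOW"), "P1", "M", "BP"),
                  toyVisits(c("HIGH", "LOW", "HIGH"), "P2", "F", "MDD",
                            start_id = 4L))
  ch <- toyCohort(c(1, 2, 3, 10, 20, 30), visits)
  z <- zscoreByStratum(ch)
  expect_equal(unname(exprsMatrix(z)[1, 1:3]), c(-1, 0, 1))
  expect_equal(unname(exprsMatrix(z)[1, 4:6]), c(-1, 0, 1))
  # pooled post-hoc mean is 0 within 1e-12 for any probeset
  sim <- simulateCohort(smallSimConfig(seed = 3))
  zs <- zscoreByStratum(sim$cohort)
  expect_lt(max(abs(rowMeans(exprsMatrix(zs)))), 1e-12)
  # idempotence up to 1e-9
  zz <- zscoreByStratum(zs)
  expect_lt(max(abs(exprsMatrix(zz) - exprsMatrix(zs))), 1e-9)
})

test_that("z-scoring flags degenerate strata and zero-variance probesets", {
  visits <- rbind(toyVisits(c("LOW", "HIGH"), "P1", "M", "BP"),
                  toyVisits("LOW", "P2", "F", "MDD", start_id = 3L))
  ch <- toyCohort(c(1, 2, 5), visits)
  expect_error(zscoreByStratum(ch), "F.MDD")
  visits2 <- toyVisits(c("LOW", "HIGH", "LOW"))
  flat <- toyCohort(c(4, 4, 4), visits2)
  expect_warning(z <- zscoreByStratum(flat), "zero-variance")
  expect_equal(unname(exprsMatrix(z)[1, ]), c(0, 0, 0))
})

test_that("frozen z-scoring parameters place a new cohort on the reference scale", {
  visits <- toyVisits(c("LOW", "HIGH", "LOW", "HIGH"))
  ref <- toyCohort(c(1, 2, 3, 4), visits)
  zref <- zscoreByStratum(ref)
  other <- toyCohort(c(10, 20, 30, 40), toyVisits(c("HIGH", "HIGH", "HIGH", "HIGH")))
  zo <- zscoreByStratum(other, params = zscoreParams(zref))
  # (10 - 2.5) / sd(1:4)
  expect_equal(unname(exprsMatrix(zo)[1, 1]), (10 - 2.5) / sd(1:4))
})
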