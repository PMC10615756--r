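test_that("digitization maps z-values to {0, 0.5, 1} with mirrored rules", {
  expect_equal(digitizeBiomarker(2.0, 1.0, -1.0, "increased"), 1)
  expect_equal(digitizeBiomarker(0.0, 1.0, -1.0, "increased"), 0.5)
  expect_equal(digitizeBiomarker(-2.0, 1.0, -1.0, "increased"), 0)
  # decreased markers: below the high-group average scores 1
  expect_equal(digitizeBiomarker(-2.0, -1.0, 1.0, "decreased"), 1)
  expect_equal(digitizeBiomarker(0.0, -1.0, 1.0, "decreased"), 0.5)
  expect_equal(digitizeBiomarker(2.0, -1.0, 1.0, "decreased"), 0)
  z <- seq(-3, 3, by = 0.1)
  s <- digitizeBiomarker(z, 0.8, -0.8, "increased")
  expect_true(all(s %in% c(0, 0.5, 1)))
  expect_true(all(diff(s) >= 0))  # raising z never lowers the score
})

test_that("risk percentiles normalize digitized scores to 0-100", {
  expect_equal(riskPercentile(rep(1, 19)), 100)
  expect_equal(riskPercentile(rep(0, 19)), 0)
  expect_equal(riskPercentile(c(rep(1, 15), rep(0.5, 4))), 100 * 17 / 19)
  expect_error(riskPercentile(numeric(0)), "no included")
})

test_that("reference thresholds flag non-concordant markers", {
  visits <- toyVisits(c("LOW", "LOW", "HIGH", "HIGH"))
  ch <- toyCohort(c(0, 0, 2, 2,   3, 3, 1, 1), visits)
  panel <- data.frame(probeset = c("ps01_at", "ps02_at"),
                      direction = "increased", stringsAsFactors = FALSE)
  th <- referenceThresholds(ch, panel, high_idx = 3:4, low_idx = 1:2)
  expect_true(th$concordant[1])
  expect_false(th$concordant[2])  # drops, despite "increased" direction
})

test_that("drug match percentiles follow the digitized-score normalization", {
  scores <- c(A = 1, B = 0.5, C = 1, D = 0)
  dirs <- c(A = "increased", B = "increased", C = "decreased",
            D = "increased")
  tab <- data.frame(
    drug = c("d1", "d1", "d2", "d3"),
    gene_symbol = c("A", "B", "Z", "C"),
    modulation = c("decreases", "decreases", "decreases", "decreases"),
    stringsAsFactors = FALSE)
  out <- drugMatchPercentile(scores, dirs, tab)
  expect_equal(unname(out["d1"]), 100 * 1.5 / 3)  # 3 markers score >= 0.5
  expect_equal(unname(out["d2"]), 0)              # matches nothing measured
  expect_equal(unname(out["d3"]), 0)  # modulation is not opposite for C
  none <- drugMatchPercentile(c(A = 0), dirs["A"], tab)
  expect_true(all(is.na(none)))
})

test_that("published drug modulation reproduces the panel coverage table", {
  panel <- read.csv(extdata("published_panel.csv"), stringsAsFactors = FALSE)
  drugs <- read.csv(extdata("published_drug_modulation.csv"),
                    stringsAsFactors = FALSE)
  cov <- drugCoverage(panel, drugs)
  expect_equal(unname(cov["Valproate"]), 100 * 6 / 18, tolerance = 1e-9)
  # gene-level dedup: duplicated probesets of one gene do not change shares
  cov2 <- drugCoverage(rbind(panel, panel[panel$gene_symbol == "NTRK3", ]),
                       drugs)
  expect_equal(cov, cov2)
  all_hit <- data.frame(drug = "everything",
                        gene_symbol = unique(panel$gene_symbol),
                        modulation = ifelse(
                          panel$direction[!duplicated(panel$gene_symbol)] ==
                            "increased", "decreases", "increases"),
                        stringsAsFactors = FALSE)
  expect_equal(unname(drugCoverage(panel, all_hit)), 100)
})

test_that("clinician reports summarize risk and match drugs deterministically", {
  panel <- data.frame(probeset = paste0("p", 1:4),
                      gene_symbol = c("A", "B", "C", "D"),
                      direction = c("increased", "increased", "decreased",
                                    "increased"),
                      stringsAsFactors = FALSE)
  th <- data.frame(probeset = panel$probeset, direction = panel$direction,
                   high_group_mean = c(1, 1, -1, 1),
                   low_group_mean = c(-1, -1, 1, -1),
                   concordant = TRUE, stringsAsFactors = FALSE)
  ths <- list(state = th, first_year = th, all_future = th)
  drugs <- data.frame(drug = c("dx", "dx"), gene_symbol = c("A", "B"),
                      modulation = "decreases", stringsAsFactors = FALSE)
  hi <- c(p1 = 2, p2 = 2, p3 = -2, p4 = 2)
  lo <- c(p1 = -2, p2 = -2, p3 = 2, p4 = -2)
  rep_hi <- clinicianReport(hi, panel, ths, drugs, subject_id = "high")
  expect_equal(rep_hi$percentiles$state, 100)
  expect_equal(rep_hi$percentiles$chronic_risk, 100)
  expect_equal(unname(rep_hi$medication_match["dx"]), 100 * 2 / 4)
  rep_lo <- clinicianReport(lo, panel, ths, drugs, subject_id = "low")
  expect_equal(rep_lo$percentiles$state, 0)
  expect_equal(rep_lo$percentiles$chronic_risk, 0)
  # golden determinism: identical inputs serialize byte-identically
  d <- withr::local_tempdir()
  f1 <- file.path(d, "r1.json"); f2 <- file.path(d, "r2.json")
  writeClinicianReport(rep_hi, f1)
  writeClinicianReport(clinicianReport(hi, panel, ths, drugs,
                                       subject_id = "high"), f2)
  expect_identical(readLines(f1), readLines(f2))
  txt <- file.path(d, "r.txt")
  writeClinicianReport(rep_hi, text_path = txt)
  expect_true(any(grepl("chronic", readLines(txt))))
})
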