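#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defaults describe the study design the pipeline assumes: a discovery arm
#' of longitudinally followed psychiatric subjects with 2-5 visits each and
#' guaranteed diametric LOW/HIGH anxiety changes between consecutive visits,
#' a clinically severe validation arm (SAS-4 >= 60 with STAI State >= 55),
#' and an independent test arm with mixed anxiety states and
#' time-to-hospitalization follow-up. Planted state markers shift by
#' `state_effect` SD between LOW and HIGH visits (plus `severe_extra_effect`
#' in SEVERE visits); planted trait markers carry a stable subject-level
#' liability whose direction-aligned mean z-score drives an exponential
#' hospitalization hazard with log-effect `trait_log_hazard` per SD.
#'
#' @param n_subjects_discovery,n_subjects_validation,n_subjects_test arm sizes.
#' @param visits_min,visits_max range of visits per discovery/test subject
#'   (uniform over the range; validation subjects contribute one severe visit).
#' @param n_probesets,n_state_markers,n_trait_markers array size and planted
#'   marker counts.
#' @param state_effect,severe_extra_effect,noise_sd expression-scale effects
#'   (SD units of the visit-level noise).
#' @param trait_log_hazard log hazard-rate effect per SD of trait-marker score.
#' @param baseline_hazard events per year at trait score 0.
#' @param detection_threshold expression level above which a call is Present.
#' @param gender_mix,dx_mix named probability vectors over genders M/F and
#'   diagnoses BP, MDD, SZ, SZA, PTSD; subjects are allocated to gender x
#'   diagnosis strata proportionally (largest-remainder), so every stratum
#'   with appreciable probability is populated in every arm.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A validated `SimulationConfig` list.
#' @export
cohortSimConfig <- function(n_subjects_discovery = 60,
                            n_subjects_validation = 40,
                            n_subjects_test = 200,
                            visits_min = 2, visits_max = 5,
                            n_probesets = 2000,
                            n_state_markers = 20,
                            n_trait_markers = 20,
                            state_effect = 1.0,
                            severe_extra_effect = 0.5,
                            noise_sd = 1.0,
                            trait_log_hazard = log(2),
                            baseline_hazard = 0.08,
                            detection_threshold = 6,
                            gender_mix = c(M = 0.7, F = 0.3),
                            dx_mix = c(BP = 0.25, MDD = 0.20, SZ = 0.25,
                                       SZA = 0.20, PTSD = 0.10),
                            seed = 1L) {
  cfg <- as.list(environment())
  if (n_subjects_discovery < 1) stop("need at least one discovery subject")
  if (n_state_markers + n_trait_markers > n_probesets)
    stop("more planted markers than probesets")
  if (abs(sum(gender_mix) - 1) > 1e-8 || abs(sum(dx_mix) - 1) > 1e-8)
    stop("gender_mix and dx_mix must each sum to 1")
  if (visits_min < 2 || visits_max > 5 || visits_min > visits_max)
    stop("visits per subject must lie in 2..5")
  structure(cfg, class = "SimulationConfig")
}

# largest-remainder allocation of n subjects over gender x dx strata
.allocateStrata <- function(n, gender_mix, dx_mix) {
  p <- as.vector(outer(gender_mix, dx_mix))
  labs <- as.vector(outer(names(gender_mix), names(dx_mix), paste, sep = "."))
  raw <- n * p
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  stats::setNames(cnt, labs)
}

#' Simulate a three-arm longitudinal anxiety cohort with planted markers
#'
#' @param config a [cohortSimConfig] object.
#' @return A list with elements `cohort` (an [AnxietyCohort-class] covering
#'   all three arms, with a `cohort` visit column naming the arm and a
#'   detection assay) and `truth` (planted state/trait marker identities,
#'   directions, effect sizes, and the probeset-to-gene annotation).
#' @export
simulateCohort <- function(config = cohortSimConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  P <- config$n_probesets
  probesets <- sprintf("ps%05d_at", seq_len(P))
  genes <- sprintf("G%05d", seq_len(P))
  planted <- sample.int(P, config$n_state_markers + config$n_trait_markers)
  state_idx <- planted[seq_len(config$n_state_markers)]
  trait_idx <- setdiff(planted, state_idx)
  direction <- stats::setNames(sample(c("increased", "decreased"),
                                      length(planted), replace = TRUE),
                               probesets[planted])
  baseline <- stats::rnorm(P, mean = 6, sd = 1)

  subj <- .simSubjects(config)
  vis <- .simVisits(subj, config)
  n_vis <- nrow(vis)
  vis$sample_id <- sprintf("S%04d", seq_len(n_vis))

  # expression: baseline + state shift + trait liability + noise
  x <- matrix(stats::rnorm(P * n_vis, sd = config$noise_sd), P, n_vis,
              dimnames = list(probesets, vis$sample_id))
  x <- x + baseline
  lab <- labelState(vis$sas4, vis$stai_state)
  h <- as.numeric(lab %in% c("HIGH", "SEVERE"))
  sev <- as.numeric(lab == "SEVERE")
  shift <- config$state_effect * h + config$severe_extra_effect * sev
  dsign <- ifelse(direction == "increased", 1, -1)
  for (k in seq_along(state_idx))
    x[state_idx[k], ] <- x[state_idx[k], ] +
      dsign[probesets[state_idx[k]]] * shift
  liability <- stats::setNames(stats::rnorm(nrow(subj)), subj$subject_id)
  for (k in seq_along(trait_idx))
    x[trait_idx[k], ] <- x[trait_idx[k], ] +
      dsign[probesets[trait_idx[k]]] * liability[vis$subject_id]

  vis <- .simFollowup(vis, x, probesets[trait_idx],
                      dsign[probesets[trait_idx]], config)

  detection <- x > config$detection_threshold
  cohort <- AnxietyCohort(x, vis, detection = detection)
  truth <- list(
    state_marker_ids = probesets[state_idx],
    trait_marker_ids = probesets[trait_idx],
    directions = direction,
    state_effect = config$state_effect,
    trait_log_hazard = config$trait_log_hazard,
    annotation = data.frame(probeset = probesets, gene_symbol = genes,
                            stringsAsFactors = FALSE)
  )
  list(cohort = cohort, truth = truth)
}

.simSubjects <- function(config) {
  arms <- c(discovery = config$n_subjects_discovery,
            validation = config$n_subjects_validation,
            test = config$n_subjects_test)
  out <- list()
  sid <- 0
  disc_cnt <- .allocateStrata(arms[["discovery"]], config$gender_mix,
                              config$dx_mix)
  for (arm in names(arms)) {
    if (arm == "discovery") {
      cnt <- disc_cnt
    } else {
      # restrict later arms to strata the discovery arm populates, so the
      # frozen normalization parameters always cover them
      gm <- config$gender_mix; dm <- config$dx_mix
      p <- as.vector(outer(gm, dm))
      p[disc_cnt == 0] <- 0
      labs <- names(disc_cnt)
      raw <- arms[[arm]] * p / sum(p)
      cnt <- floor(raw)
      rem <- arms[[arm]] - sum(cnt)
      if (rem > 0) {
        ord <- order(raw - cnt, decreasing = TRUE)
        cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
      }
      names(cnt) <- labs
    }
    gd <- rep(names(cnt), cnt)
    parts <- strsplit(gd, ".", fixed = TRUE)
    out[[arm]] <- data.frame(
      subject_id = sprintf("Phchp%03d", sid + seq_along(gd)),
      cohort = arm,
      gender = vapply(parts, `[`, "", 1),
      diagnosis = vapply(parts, `[`, "", 2),
      stringsAsFactors = FALSE
    )
    sid <- sid + length(gd)
  }
  do.call(rbind, out)
}

.simVisits <- function(subj, config) {
  rows <- vector("list", nrow(subj))
  for (i in seq_len(nrow(subj))) {
    s <- subj[i, ]
    if (s$cohort == "validation") {
      nv <- 1L
    } else {
      nv <- sample(seq(config$visits_min, config$visits_max), 1L)
    }
    times <- cumsum(c(0, stats::runif(nv - 1, 0.25, 0.5)))
    if (s$cohort == "discovery") {
      # alternate LOW/HIGH targets so every consecutive pair is diametric
      start_low <- stats::runif(1) < 0.5
      is_low <- rep(c(start_low, !start_low), length.out = nv)
      sas4 <- ifelse(is_low, stats::runif(nv, 10, 38), stats::runif(nv, 62, 90))
    } else if (s$cohort == "validation") {
      sas4 <- stats::runif(nv, 62, 95)
    } else {
      u <- stats::runif(nv)
      sas4 <- ifelse(u < 0.45, stats::runif(nv, 10, 40),
              ifelse(u < 0.65, stats::runif(nv, 41, 59),
                     stats::runif(nv, 60, 90)))
    }
    stai <- pmin(80, pmax(20, 0.75 * sas4 + stats::rnorm(nv, 0, 6)))
    if (s$cohort == "validation")
      stai <- pmax(stai, stats::runif(nv, 55, 62))  # severe arm: STAI >= 55
    rows[[i]] <- data.frame(
      subject_id = s$subject_id, cohort = s$cohort, gender = s$gender,
      diagnosis = s$diagnosis, visit_index = seq_len(nv),
      visit_time = times, sas4 = sas4, stai_state = stai,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# exponential time-to-hospitalization for test subjects; log-hazard is
# trait_log_hazard * (direction-aligned mean z of trait markers per subject)
.simFollowup <- function(vis, x, trait_ids, trait_sign, config) {
  vis$time_to_first_hosp <- NA_real_
  vis$censor_time <- NA_real_
  vis$followup_first_year_hosp <- NA
  vis$followup_any_future_hosp <- NA
  test_vis <- vis$cohort == "test"
  if (!any(test_vis) || length(trait_ids) == 0) return(vis)
  subj <- unique(vis$subject_id[test_vis])
  sub_mean <- vapply(subj, function(s) {
    cols <- vis$sample_id[test_vis & vis$subject_id == s]
    mean(colMeans(x[trait_ids, cols, drop = FALSE] * trait_sign))
  }, numeric(1))
  z <- (sub_mean - mean(sub_mean)) / stats::sd(sub_mean)
  rate <- config$baseline_hazard * exp(config$trait_log_hazard * z)
  t_event <- stats::rexp(length(subj), rate = rate)
  t_censor <- stats::runif(length(subj), 3, 12)
  names(t_event) <- names(t_censor) <- subj
  for (s in subj) {
    rows <- which(test_vis & vis$subject_id == s)
    vt <- vis$visit_time[rows]
    last <- max(vt)
    cens <- last + t_censor[s]
    ev <- t_event[s] + 0  # event clock starts at the subject's first visit
    observed <- ev <= cens
    for (r in seq_along(rows)) {
      i <- rows[r]
      rel_c <- cens - vt[r]
      vis$censor_time[i] <- rel_c
      if (observed && ev > vt[r]) {
        rel_t <- ev - vt[r]
        vis$time_to_first_hosp[i] <- rel_t
        vis$followup_any_future_hosp[i] <- TRUE
        vis$followup_first_year_hosp[i] <- rel_t <= 1
      } else {
        vis$followup_any_future_hosp[i] <- FALSE
        vis$followup_first_year_hosp[i] <- FALSE
      }
    }
  }
  vis
}

#' Simulate a Convergent Functional Genomics evidence table
#'
#' Stands in for curated literature evidence: each planted marker's gene
#' receives each of the six evidence categories (human/animal x genetic,
#' brain expression, peripheral expression) independently with probability
#' `sensitivity` at full weight 2; each null gene is annotated with
#' probability `false_positive_rate`, receiving one random category at
#' weight 1.
#'
#' @param truth the `truth` element returned by [simulateCohort].
#' @param sensitivity,false_positive_rate annotation rates in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame with columns gene_symbol, species, evidence_kind, weight.
#' @export
simulateEvidenceTable <- function(truth, sensitivity = 0.8,
                                  false_positive_rate = 0.05, seed = 1L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            false_positive_rate >= 0, false_positive_rate <= 1)
  set.seed(seed)
  ann <- truth$annotation
  planted_ps <- c(truth$state_marker_ids, truth$trait_marker_ids)
  planted_genes <- ann$gene_symbol[match(planted_ps, ann$probeset)]
  null_genes <- setdiff(ann$gene_symbol, planted_genes)
  cats <- expand.grid(species = c("human", "animal"),
                      evidence_kind = c("genetic", "expression_brain",
                                        "expression_peripheral"),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (g in planted_genes) {
    hit <- stats::runif(nrow(cats)) < sensitivity
    if (any(hit))
      rows[[length(rows) + 1]] <- data.frame(
        gene_symbol = g, cats[hit, , drop = FALSE], weight = 2,
        stringsAsFactors = FALSE)
  }
  fp <- null_genes[stats::runif(length(null_genes)) < false_positive_rate]
  if (length(fp)) {
    pick <- sample.int(nrow(cats), length(fp), replace = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      gene_symbol = fp, cats[pick, , drop = FALSE], weight = 1,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_symbol = character(), species = character(),
                      evidence_kind = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
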