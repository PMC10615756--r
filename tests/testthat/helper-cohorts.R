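# shared fixtures, built in code

# tiny hand-specified cohort: `states` gives per-visit SAS-4-implied labels
toyVisits <- function(states, subject = "P1", gender = "M", dx = "BP",
                      start_id = 1L) {
  sas <- c(LOW = 30, INTERMEDIATE = 50, HIGH = 70)[states]
  data.frame(
    sample_id = sprintf("S%03d", start_id + seq_along(states) - 1L),
    subject_id = subject, visit_index = seq_along(states),
    visit_time = (seq_along(states) - 1) * 0.4,
    gender = gender, diagnosis = dx, sas4 = unname(sas),
    stai_state = NA_real_, cohort = "discovery",
    stringsAsFactors = FALSE
  )
}

toyCohort <- function(values, visits, detection = NULL) {
  x <- matrix(values, ncol = nrow(visits), byrow = TRUE,
              dimnames = list(sprintf("ps%02d_at", seq_len(length(values) / nrow(visits))),
                              visits$sample_id))
  AnxietyCohort(x, visits, detection = detection)
}

# small simulation settings that keep unit tests fast; `...` overrides any
# of the small defaults
smallSimConfig <- function(seed = 1L, ...) {
  args <- list(n_subjects_discovery = 20, n_subjects_validation = 12,
               n_subjects_test = 60, n_probesets = 300,
               n_state_markers = 10, n_trait_markers = 10, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohortSimConfig, args)
}

# brute-force all-pairs AUC oracle (ties count one half)
bruteForceAUC <- function(values, labels) {
  pos <- values[labels]; neg <- values[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

extdata <- function(name) {
  system.file("extdata", name, package = "anxietyCFE", mustWork = TRUE)
}

# convert a semicolon list of significant stratum types into the tidy
# results shape step4Points consumes
sigStrataToResults <- function(sig) {
  if (is.na(sig) || !nzchar(sig))
    return(data.frame(stratum_type = character(), p = numeric()))
  types <- strsplit(sig, ";", fixed = TRUE)[[1]]
  data.frame(stratum_type = types, p = 0.01, stringsAsFactors = FALSE)
}
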