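# In-code fixtures: tiny hand-built cohorts used across test files.

# A cohort from explicit per-patient SF vectors (months 1..length).
toy_cohort <- function(sf_list, variant_class = NULL, asm = NULL,
                       milestones = NULL, assessments = NULL) {
  ids <- names(sf_list)
  if (is.null(variant_class)) variant_class <- rep("unknown", length(ids))
  patients <- data.frame(
    patient_id = ids, sex = "unknown", variant_class = variant_class,
    variant_label = "", obs_start_month = 1L,
    obs_end_month = vapply(sf_list, length, integer(1)),
    has_epilepsy = vapply(sf_list, function(x) any(x > 0, na.rm = TRUE),
                          logical(1)),
    stringsAsFactors = FALSE)
  seizures <- do.call(rbind, lapply(ids, function(id) {
    sf <- sf_list[[id]]
    data.frame(patient_id = id, seizure_type = "overall",
               month = seq_along(sf), sf = sf,
               unknown = FALSE, imputed = FALSE, stringsAsFactors = FALSE)
  }))
  sf_cohort(patients, seizures, asm = asm, milestones = milestones,
            assessments = assessments)
}

# Milestone-only cohorts for the development-outcome layer.
mk_milestones <- function(n_achieved, n_assessed, milestone = "roll_over",
                          ages = NULL) {
  ids <- sprintf("m%03d", seq_len(n_assessed))
  achieved <- seq_len(n_assessed) <= n_achieved
  if (is.null(ages)) ages <- sample(3:36, n_assessed, replace = TRUE)
  data.frame(patient_id = ids, milestone = milestone, achieved = achieved,
             age_achieved_months = ifelse(achieved, ages, NA),
             age_last_assessed_months = 60, stringsAsFactors = FALSE)
}

cohort_with_milestones <- function(mil) {
  ids <- unique(mil$patient_id)
  patients <- data.frame(
    patient_id = ids, sex = "unknown", variant_class = "unknown",
    variant_label = "", obs_start_month = 1L, obs_end_month = 60L,
    has_epilepsy = FALSE, stringsAsFactors = FALSE)
  seizures <- data.frame(patient_id = ids[1], seizure_type = "overall",
                         month = 1L, sf = 0L, unknown = FALSE,
                         imputed = FALSE, stringsAsFactors = FALSE)
  sf_cohort(patients, seizures, milestones = mil)
}

# Brute-force remission oracle: first index i (in months after onset) such
# that months i..i+min_run-1 are all zero; independent of the rle-based scan.
brute_remission <- function(sf, min_run = 12L) {
  onset <- which(sf > 0)[1]
  if (is.na(onset)) return(NULL)
  months <- seq_along(sf)
  for (i in (onset + 1):length(sf)) {
    if (i + min_run - 1 > length(sf)) break
    if (all(sf[i:(i + min_run - 1)] == 0))
      return(list(offset_month = months[i], qualified = TRUE))
  }
  NULL
}

# Two-sided Fisher p by direct hypergeometric enumeration (oracle).
hyper_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-sided (alternative: less) exact signed-rank p by enumeration over all
# sign assignments; requires untied nonzero absolute differences.
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mean(v_all <= v_obs)
}
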