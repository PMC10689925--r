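## Developmental milestone acquisition, standardized-assessment summaries
## and onset-outcome association tests.

SCORE_SCALES <- c("gmfm66is", "pdms2_grasping", "pdms2_vmi")
LEVEL_SCALES <- c("gmfcs_er", "macs", "cfcs")

#' Fraction of the cohort achieving a milestone
#'
#' @param cohort an `sf_cohort` with a milestone table.
#' @param milestone milestone name (e.g. `"roll_over"`).
#' @return list with `n_achieved`, `n_assessed`, `fraction` (rounded to
#'   2 decimals for reporting; the raw counts are always carried).
#' @export
#' @examples
#' \dontrun{achieved_fraction(cohort, "roll_over")}
achieved_fraction <- function(cohort, milestone) {
  mil <- cohort$milestones
  abort_if(is.null(mil), "cohort has no milestone table")
  d <- mil[mil$milestone == milestone, , drop = FALSE]
  abort_if(!nrow(d), "milestone %s not assessed in any patient",
           sQuote(milestone))
  n_a <- sum(d$achieved)
  list(n_achieved = n_a, n_assessed = nrow(d),
       fraction = round(n_a / nrow(d), 2))
}

#' Quantiles of milestone acquisition age
#'
#' Empirical quantiles of the age achieved, conditioning on achievers only
#' (the convention of cumulative-acquisition reporting). The `"km"` mode
#' instead computes Kaplan-Meier quantiles over all assessed patients,
#' treating non-achievers as censored at their last assessment age -
#' unbiased where the achievers-only conditioning is optimistic.
#'
#' @param cohort an `sf_cohort` with a milestone table.
#' @param milestone milestone name.
#' @param q quantile probabilities.
#' @param mode `"achievers"` (default) or `"km"`.
#' @param min_achievers minimum achievers required (default 5).
#' @return named numeric vector of ages in months (NA = not reached /
#'   not computed).
#' @export
milestone_quantiles <- function(cohort, milestone,
                                q = c(0.25, 0.5, 0.75, 0.9),
                                mode = c("achievers", "km"),
                                min_achievers = 5L) {
  mode <- match.arg(mode)
  mil <- cohort$milestones
  abort_if(is.null(mil), "cohort has no milestone table")
  d <- mil[mil$milestone == milestone, , drop = FALSE]
  abort_if(!nrow(d), "milestone %s not assessed in any patient",
           sQuote(milestone))
  if (sum(d$achieved) < min_achievers) {
    message(sprintf("milestone %s: fewer than %d achievers; not computed",
                    milestone, min_achievers))
    return(stats::setNames(rep(NA_real_, length(q)), paste0("q", q * 100)))
  }
  if (mode == "achievers") {
    ages <- d$age_achieved_months[d$achieved]
    stats::setNames(as.numeric(stats::quantile(ages, q)),
                    paste0("q", q * 100))
  } else {
    time <- ifelse(d$achieved, d$age_achieved_months,
                   d$age_last_assessed_months)
    quantiles(km_fit(time, as.integer(d$achieved)), q)
  }
}

#' Association between seizure-onset stratum and a developmental outcome
#'
#' Splits the epileptic cohort into neonatal (onset month 1) versus later
#' onset and tests the association with an outcome: a binary milestone via
#' [fisher_or()] (rows later/neonatal x achieved/not), an ordinal
#' classification level via a two-sided Wilcoxon rank-sum test, or a
#' continuous score via Spearman correlation with the onset age itself.
#'
#' @param cohort an imputed `sf_cohort`.
#' @param outcome milestone name, level-scale name (`"gmfcs_er"`,
#'   `"macs"`, `"cfcs"`), or score-scale name (`"gmfm66is"`,
#'   `"pdms2_grasping"`, `"pdms2_vmi"`).
#' @return list whose shape depends on the outcome type: Fisher OR and CI
#'   for milestones; Wilcoxon statistic and p for levels; Spearman rho and
#'   p for scores. Degenerate (constant) outcomes return `NA` with a note.
#' @export
onset_outcome_association <- function(cohort, outcome) {
  on <- onset_table(cohort)
  on <- on[!is.na(on$onset_month), , drop = FALSE]
  abort_if(!nrow(on), "cohort has no patients with seizure onset")
  neonatal <- stats::setNames(on$neonatal, on$patient_id)
  if (!is.null(cohort$milestones) &&
      outcome %in% cohort$milestones$milestone) {
    d <- cohort$milestones[cohort$milestones$milestone == outcome, ]
    d <- d[d$patient_id %in% names(neonatal), ]
    abort_if(!nrow(d), "no epileptic patients assessed for %s", outcome)
    neo <- neonatal[d$patient_id]
    abort_if(!any(neo) || all(neo),
             "both onset strata must be nonempty for %s", outcome)
    if (length(unique(d$achieved)) < 2)
      return(list(type = "milestone", or = NA_real_,
                  note = "constant outcome"))
    tab <- matrix(c(sum(!neo & d$achieved), sum(!neo & !d$achieved),
                    sum(neo & d$achieved), sum(neo & !d$achieved)),
                  2, byrow = TRUE,
                  dimnames = list(c("later", "neonatal"),
                                  c("achieved", "not_achieved")))
    fo <- fisher_or(tab)
    return(c(list(type = "milestone", table = tab), fo[c(
      "or", "ci_low", "ci_high", "p")]))
  }
  a <- cohort$assessments
  abort_if(is.null(a) || !outcome %in% a$scale,
           "unknown outcome %s", sQuote(outcome))
  d <- a[a$scale == outcome & a$patient_id %in% names(neonatal), ]
  ## one record per patient: the latest exam
  d <- d[order(d$patient_id, -d$age_months), ]
  d <- d[!duplicated(d$patient_id), ]
  abort_if(nrow(d) < 4, "too few epileptic patients assessed for %s",
           outcome)
  if (length(unique(d$value)) < 2)
    return(list(type = "scale", statistic = NA_real_,
                note = "constant outcome"))
  if (outcome %in% LEVEL_SCALES) {
    neo <- neonatal[d$patient_id]
    abort_if(!any(neo) || all(neo),
             "both onset strata must be nonempty for %s", outcome)
    wt <- suppressWarnings(stats::wilcox.test(d$value[neo], d$value[!neo]))
    list(type = "level", statistic = unname(wt$statistic), p = wt$p.value,
         median_neonatal = stats::median(d$value[neo]),
         median_later = stats::median(d$value[!neo]))
  } else {
    onset_age <- on$onset_month[match(d$patient_id, on$patient_id)]
    ct <- suppressWarnings(stats::cor.test(onset_age, d$value,
                                           method = "spearman"))
    list(type = "score", rho = unname(ct$estimate), p = ct$p.value,
         n = nrow(d))
  }
}

#' Summaries of standardized assessment scores by age bin
#'
#' For score scales, per-age-bin 25/50/75/90th percentiles; for
#' classification scales, counts of levels I-V. Bins with fewer than
#' `min_n` records are suppressed with a note.
#'
#' @param cohort an `sf_cohort` with an assessment table.
#' @param scale assessment scale name.
#' @param breaks age-bin breakpoints in months (right-open; default
#'   `c(0, 12, 24, 60, Inf)`).
#' @param min_n minimum records per reported bin (default 3).
#' @return data.frame of per-bin quantiles (score scales) or per-bin level
#'   tallies (classification scales), with an `n_exams` column.
#' @export
score_summary <- function(cohort, scale, breaks = c(0, 12, 24, 60, Inf),
                          min_n = 3L) {
  a <- cohort$assessments
  abort_if(is.null(a), "cohort has no assessment table")
  abort_if(!scale %in% c(SCORE_SCALES, LEVEL_SCALES),
           "unknown scale %s", sQuote(scale))
  d <- a[a$scale == scale, , drop = FALSE]
  abort_if(!nrow(d), "no records for scale %s", sQuote(scale))
  if (scale %in% LEVEL_SCALES) {
    tally <- table(factor(d$value, levels = 1:5,
                          labels = paste0("level_", c("I", "II", "III",
                                                      "IV", "V"))))
    out <- as.data.frame(t(as.matrix(tally)))
    out$n_exams <- nrow(d)
    return(out)
  }
  d$bin <- cut(d$age_months, breaks, right = FALSE)
  rows <- lapply(levels(d$bin), function(b) {
    v <- d$value[d$bin == b]
    if (length(v) < min_n) {
      if (length(v) > 0)
        message(sprintf("bin %s: %d record(s), below min_n = %d; suppressed",
                        b, length(v), min_n))
      return(NULL)
    }
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75, 0.9))
    data.frame(age_bin = b, n_exams = length(v), q25 = qs[[1]],
               q50 = qs[[2]], q75 = qs[[3]], q90 = qs[[4]])
  })
  out <- do.call(rbind, rows)
  abort_if(is.null(out), "all bins below min_n for scale %s", sQuote(scale))
  out
}

#' CDC reference ages for milestone attainment
#'
#' Static annotation table: the age (months) by which 75% of typically
#' developing children attain each milestone, per the CDC developmental
#' milestone checklists. Shipped as reference annotation for plotting
#' alongside cohort acquisition curves; nothing is computed from it.
#'
#' @return data.frame with `milestone` and `cdc_age_months`.
#' @export
cdc_reference_ages <- function() {
  data.frame(
    milestone = c("head_control", "roll_over", "sit_unassisted", "grasp",
                  "walk", "walk_unassisted", "first_words",
                  "nonverbal_communication"),
    cdc_age_months = c(4, 6, 9, 9, 12, 15, 15, 9),
    stringsAsFactors = FALSE)
}
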