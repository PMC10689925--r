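## Onset/remission detection, Kaplan-Meier survival layer and month-wise
## subgroup comparison of SF distributions.

#' Detect seizure onset
#'
#' Onset is the earliest month of life with overall SF > 0 within the
#' observation window; `NA` if the patient never seizes. Month 1 onset is
#' the neonatal category.
#'
#' @param sf named numeric vector of monthly SF scores (names = months of
#'   life), as returned by [sf_series()].
#' @return onset month (integer) or `NA`.
#' @export
detect_onset <- function(sf) {
  hit <- which(!is.na(sf) & sf > 0)
  if (!length(hit)) return(NA_integer_)
  as.integer(names(sf)[hit[1]])
}

#' Detect seizure remission
#'
#' Remission is the first run of at least `min_run` consecutive SF = 0
#' months beginning after onset. The reported `offset_month` is the first
#' seizure-free month of the qualifying run (an alternative anchoring at
#' the last seizure month is available via `anchor`). A zero run truncated
#' by the end of observation before reaching `min_run` months does not
#' qualify (the patient is censored). Seizure recurrence after a
#' qualifying run is visible to callers via `run_length`, but no
#' recurrence survival analysis is built on it.
#'
#' @param sf named numeric vector of monthly SF scores.
#' @param min_run minimum run length in months (default 12).
#' @param anchor `"first_free_month"` (default) or `"last_seizure_month"`.
#' @return list with `offset_month`, `qualified`, `run_length`, or `NULL`
#'   if the patient has no onset or no post-onset zero run of any length.
#' @export
detect_remission <- function(sf, min_run = 12L,
                             anchor = c("first_free_month",
                                        "last_seizure_month")) {
  abort_if(min_run < 1, "min_run must be >= 1")
  anchor <- match.arg(anchor)
  onset <- detect_onset(sf)
  if (is.na(onset)) return(NULL)
  months <- as.integer(names(sf))
  idx <- which(months > onset)
  if (!length(idx)) return(NULL)
  z <- !is.na(sf[idx]) & sf[idx] == 0
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zero_runs <- which(r$values)
  if (!length(zero_runs)) return(NULL)
  for (j in zero_runs) {
    if (r$lengths[j] >= min_run) {
      first_free <- months[idx[starts[j]]]
      off <- if (anchor == "first_free_month") first_free else first_free - 1L
      return(list(offset_month = off, qualified = TRUE,
                  run_length = as.integer(r$lengths[j])))
    }
  }
  ## longest (censored) trailing information only: no qualifying run
  j <- zero_runs[length(zero_runs)]
  truncated <- ends[j] == length(z)
  first_free <- months[idx[starts[j]]]
  list(offset_month = if (anchor == "first_free_month") first_free
                      else first_free - 1L,
       qualified = FALSE, run_length = as.integer(r$lengths[j]),
       censored_run = truncated)
}

#' Per-patient onset table
#'
#' @param cohort an imputed `sf_cohort`.
#' @param seizure_type `"overall"` or an HPO term id.
#' @return data.frame with `patient_id`, `onset_month`, `neonatal`,
#'   `obs_end_month`.
#' @export
onset_table <- function(cohort, seizure_type = "overall") {
  ids <- cohort$patients$patient_id
  onset <- vapply(ids, function(id)
    detect_onset(suppressWarnings(sf_series(cohort, id, seizure_type))),
    integer(1))
  data.frame(patient_id = ids, onset_month = onset,
             neonatal = !is.na(onset) & onset == 1L,
             obs_end_month = cohort$patients$obs_end_month,
             stringsAsFactors = FALSE)
}

#' Per-patient remission table for survival analysis
#'
#' One row per patient with seizure onset and at least `min_follow` months
#' of post-onset observation. `time` is the age (month of life) at the
#' remission offset for qualifying patients, otherwise the age at end of
#' observation with `event = 0` (censored).
#'
#' @param cohort an imputed `sf_cohort`.
#' @param min_run remission definition (consecutive seizure-free months).
#' @param min_follow minimum post-onset observation in months to enter the
#'   risk set (default 12, i.e. at least one year of follow-up).
#' @param seizure_type `"overall"` or an HPO term id.
#' @return data.frame with `patient_id`, `onset_month`, `time`, `event`.
#' @export
remission_table <- function(cohort, min_run = 12L, min_follow = 12L,
                            seizure_type = "overall") {
  out <- lapply(cohort$patients$patient_id, function(id) {
    sf <- suppressWarnings(sf_series(cohort, id, seizure_type))
    onset <- detect_onset(sf)
    if (is.na(onset)) return(NULL)
    obs_end <- as.integer(names(sf)[length(sf)])
    if (obs_end - onset < min_follow) return(NULL)
    rem <- detect_remission(sf, min_run = min_run)
    if (!is.null(rem) && isTRUE(rem$qualified))
      data.frame(patient_id = id, onset_month = onset,
                 time = rem$offset_month, event = 1L,
                 stringsAsFactors = FALSE)
    else
      data.frame(patient_id = id, onset_month = onset,
                 time = obs_end, event = 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Kaplan-Meier fit on monthly event ages
#'
#' Product-limit estimate of the survival function over months of life,
#' delegated to [survival::survfit()]. The quantile convention is the
#' smallest time t with S(t) <= 1 - q; quantiles the curve never reaches
#' are reported as `NA` ("not reached").
#'
#' @param time event or censoring age in months.
#' @param event 1 = event observed, 0 = censored.
#' @return an object of class `sf_km` with the time grid, survival,
#'   at-risk/event/censor counts and the underlying `survfit` object.
#' @export
#' @examples
#' km <- km_fit(c(2, 2, 4, 10), c(1, 1, 1, 1))
#' quantiles(km, c(0.25, 0.5, 0.75))
km_fit <- function(time, event) {
  abort_if(any(time < 0), "negative event/censoring ages")
  abort_if(length(time) == 0, "no observations")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, censored = TRUE)
  structure(list(
    month = s$time, survival = s$surv, at_risk = s$n.risk,
    events = s$n.event, censored = s$n.censor, n = length(time),
    survfit = fit), class = "sf_km")
}

#' Survival-curve quantiles
#'
#' @param curve an `sf_km` object.
#' @param q quantile probabilities (e.g. `c(0.25, 0.5, 0.75, 0.9)`).
#' @return named numeric vector of months; `NA` where not reached.
#' @export
quantiles <- function(curve, q = c(0.25, 0.5, 0.75, 0.9)) {
  stopifnot(inherits(curve, "sf_km"))
  out <- vapply(q, function(qq) {
    i <- which(curve$survival <= 1 - qq + 1e-12)
    if (!length(i)) NA_real_ else curve$month[i[1]]
  }, numeric(1))
  names(out) <- paste0("q", q * 100)
  out
}

#' @export
print.sf_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events\n",
              x$n, sum(x$events)))
  qs <- quantiles(x)
  cat("  quantiles (months): ",
      paste(names(qs), ifelse(is.na(qs), "not reached", format(qs)),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.sf_km <- function(x, xlab = "month of life", ylab = "survival", ...) {
  graphics::plot(x$survfit, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Convert an `sf_km` curve to a data.frame
#'
#' @param x an `sf_km` object.
#' @param ... unused.
#' @return data.frame with month, survival, at_risk, events, censored.
#' @export
as.data.frame.sf_km <- function(x, ...) {
  data.frame(month = x$month, survival = x$survival, at_risk = x$at_risk,
             events = x$events, censored = x$censored)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 df, delegated to
#' [survival::survdiff()].
#'
#' @param time event/censoring ages in months.
#' @param event 1 = event, 0 = censored.
#' @param group two-level grouping vector.
#' @return list with `statistic`, `p`, `df`.
#' @export
logrank <- function(time, event, group) {
  g <- factor(group)
  abort_if(nlevels(g) != 2, "logrank requires exactly two groups")
  abort_if(sum(event) == 0, "no events in either group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(statistic = sd$chisq, p = stats::pchisq(sd$chisq, df = 1,
                                               lower.tail = FALSE), df = 1L)
}

#' Month-wise comparison of SF distributions between subgroups
#'
#' Two-sided Wilcoxon rank-sum test of the overall SF distribution between
#' two patient groups, separately in each month of life. Months in which
#' either group has fewer than `min_per_group` observed patients are
#' flagged untested rather than tested. Raw p-values are reported; a
#' Benjamini-Hochberg adjusted column is appended when `adjust = TRUE`
#' (no correction is applied by default).
#'
#' @param cohort an imputed `sf_cohort`.
#' @param grouping patient column to group by (default `"variant_class"`).
#' @param groups character vector of the two group labels to compare.
#' @param months months of life to test.
#' @param seizure_type `"overall"` or an HPO term id.
#' @param min_per_group minimum patients per group per month (default 2).
#' @param adjust append a BH-adjusted p column?
#' @return data.frame: `month`, `n1`, `n2`, `statistic`, `p`, `tested`
#'   (and `p_adj` if requested).
#' @export
monthly_group_comparison <- function(cohort, grouping = "variant_class",
                                     groups = c("ptv_del", "missense"),
                                     months = 1:24,
                                     seizure_type = "overall",
                                     min_per_group = 2L, adjust = FALSE) {
  p <- cohort$patients
  abort_if(!grouping %in% names(p), "unknown grouping column %s",
           sQuote(grouping))
  ids1 <- p$patient_id[p[[grouping]] == groups[1]]
  ids2 <- p$patient_id[p[[grouping]] == groups[2]]
  series <- lapply(stats::setNames(p$patient_id, p$patient_id),
                   function(id) sf_series(cohort, id))
  month_sf <- function(ids, m) {
    v <- vapply(ids, function(id) {
      s <- series[[id]]
      if (as.character(m) %in% names(s)) s[[as.character(m)]] else NA_real_
    }, numeric(1))
    v[!is.na(v)]
  }
  rows <- lapply(months, function(m) {
    x <- month_sf(ids1, m); y <- month_sf(ids2, m)
    if (length(x) < min_per_group || length(y) < min_per_group)
      return(data.frame(month = m, n1 = length(x), n2 = length(y),
                        statistic = NA_real_, p = NA_real_, tested = FALSE))
    if (length(unique(c(x, y))) == 1L)   # fully tied: no evidence either way
      return(data.frame(month = m, n1 = length(x), n2 = length(y),
                        statistic = length(x) * length(y) / 2, p = 1,
                        tested = TRUE))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
    data.frame(month = m, n1 = length(x), n2 = length(y),
               statistic = unname(wt$statistic), p = wt$p.value,
               tested = TRUE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
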