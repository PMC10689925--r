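## Patient-month treatment-response classification and comparative
## effectiveness of anti-seizure medications (ASMs), plus time-locked
## response curves aligned at treatment initiation.

#' Classify a patient-month treatment response
#'
#' The unit of effectiveness analysis is the patient-month, classified
#' from the SF transition into the month: `reduced` when SF falls from a
#' nonzero value; `freedom_maintained` when two consecutive seizure-free
#' months follow a prior seizure history; `unchanged_or_worse` when SF
#' stays at or above a nonzero previous value, or seizures reappear after
#' a seizure-free month; `not_evaluable` before seizure onset.
#'
#' @param sf named numeric vector of monthly SF scores ([sf_series()]).
#' @param month month of life to classify (must have a preceding observed
#'   month).
#' @return one of `"reduced"`, `"unchanged_or_worse"`,
#'   `"freedom_maintained"`, `"not_evaluable"`.
#' @export
#' @examples
#' s <- stats::setNames(c(0, 3, 4, 2, 0, 0), 1:6)
#' classify_month(s, 4)  # "reduced"
#' classify_month(s, 6)  # "freedom_maintained"
classify_month <- function(sf, month) {
  m <- as.character(month)
  pm <- as.character(month - 1L)
  abort_if(!(m %in% names(sf)) || !(pm %in% names(sf)),
           "month %s needs an observed preceding month", m)
  cur <- sf[[m]]; prev <- sf[[pm]]
  if (is.na(cur) || is.na(prev)) return("not_evaluable")
  onset <- detect_onset(sf)
  if (is.na(onset) || month <= onset) {
    ## pre-onset months carry no response information (the onset month
    ## itself is the first informative transition: 0 -> >0)
    if (!is.na(onset) && month == onset) return("unchanged_or_worse")
    return("not_evaluable")
  }
  if (cur < prev && prev > 0) return("reduced")
  if (cur == 0 && prev == 0) return("freedom_maintained")
  "unchanged_or_worse"
}

#' Patient-month response table
#'
#' Classifies every evaluable patient-month in the cohort and attaches the
#' set of drugs active that month.
#'
#' @param cohort an imputed `sf_cohort` with an `asm` table.
#' @param seizure_type `"overall"` or an HPO term id.
#' @return data.frame: `patient_id`, `month`, `response`, `exposed`
#'   (semicolon-joined drug names, `""` if none).
#' @export
month_response_table <- function(cohort, seizure_type = "overall") {
  asm <- cohort$asm
  out <- lapply(cohort$patients$patient_id, function(id) {
    sf <- suppressWarnings(sf_series(cohort, id, seizure_type))
    months <- as.integer(names(sf))
    months <- months[-1]
    if (!length(months)) return(NULL)
    resp <- vapply(months, function(m) classify_month(sf, m), character(1))
    exposed <- vapply(months, function(m) {
      if (is.null(asm)) return("")
      d <- asm$drug[asm$patient_id == id & asm$start_month <= m &
                      asm$end_month >= m]
      paste(sort(unique(d)), collapse = ";")
    }, character(1))
    data.frame(patient_id = id, month = months, response = resp,
               exposed = exposed, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fisher's exact test with cross-product odds ratio and Woolf CI
#'
#' Two-sided Fisher's exact p-value (delegated to [stats::fisher.test()])
#' together with the sample (cross-product) odds ratio. When any cell is
#' zero, the Haldane-Anscombe correction adds 0.5 to every cell before the
#' odds ratio and CI are computed. The 95% confidence interval is Woolf's
#' log-normal interval on the (corrected) counts. Note the point estimate
#' is the cross-product ratio, not the conditional MLE that
#' `fisher.test()` itself reports.
#'
#' @param table 2x2 matrix of nonnegative integer counts
#'   (rows: exposed/unexposed; columns: favorable/unfavorable).
#' @return list with `or`, `ci_low`, `ci_high`, `p`, `table`.
#' @export
#' @examples
#' fisher_or(matrix(c(6, 2, 3, 9), 2, byrow = TRUE))  # OR = 9
fisher_or <- function(table) {
  tab <- as.matrix(table)
  abort_if(!all(dim(tab) == c(2, 2)), "table must be 2x2")
  abort_if(any(tab < 0) || any(tab %% 1 != 0),
           "table must contain nonnegative integer counts")
  abort_if(sum(tab) == 0, "all-zero table")
  p <- stats::fisher.test(tab)$p.value
  ct <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  se <- sqrt(sum(1 / ct))
  z <- stats::qnorm(0.975)
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se), p = p, table = tab)
}

#' Comparative effectiveness of one ASM from patient-month data
#'
#' Builds the 2x2 contingency table of evaluable patient-months (exposure
#' to `drug` that month vs not, against a favorable response) and
#' delegates to [fisher_or()]. Favorable means `reduced` for the
#' `short_term` outcome, `reduced` or `freedom_maintained` for
#' `long_term`, and `freedom_maintained` alone for `freedom_only`.
#' A month under several drugs counts as exposed for each of them;
#' `sole_exposure = TRUE` restricts exposed months to months under that
#' drug alone. Drugs used by fewer than `min_patients` patients are
#' refused.
#'
#' Patient-months within a patient are serially correlated, so the Woolf
#' interval (which treats months as independent) is anti-conservative;
#' `ci = "bootstrap"` instead resamples patients with replacement and
#' takes percentile bounds of the cross-product odds ratio, respecting
#' the clustering.
#'
#' @param cohort an imputed `sf_cohort` with an `asm` table.
#' @param drug canonical lowercase drug name.
#' @param outcome `"short_term"`, `"long_term"`, or `"freedom_only"`.
#' @param min_patients minimum number of distinct exposed patients
#'   (default 10).
#' @param seizure_type `"overall"` or an HPO term id.
#' @param sole_exposure restrict to months with no co-medication?
#' @param responses optional precomputed [month_response_table()] (saves
#'   recomputation when scoring several drugs).
#' @param ci `"woolf"` (default, log-normal on the corrected counts) or
#'   `"bootstrap"` (patient-level cluster bootstrap, percentile 95% CI).
#' @param n_boot bootstrap replicates when `ci = "bootstrap"`.
#' @param boot_seed seed for the bootstrap resampling.
#' @return an object of class `asm_effect`: drug, outcome, 2x2 table,
#'   odds ratio with Woolf 95% CI, Fisher p, and patient counts.
#' @export
comparative_effectiveness <- function(cohort, drug,
                                      outcome = c("short_term", "long_term",
                                                  "freedom_only"),
                                      min_patients = 10L,
                                      seizure_type = "overall",
                                      sole_exposure = FALSE,
                                      responses = NULL,
                                      ci = c("woolf", "bootstrap"),
                                      n_boot = 500L, boot_seed = 1L) {
  outcome <- match.arg(outcome)
  ci <- match.arg(ci)
  abort_if(is.null(cohort$asm), "cohort has no ASM exposure table")
  n_pat <- length(unique(cohort$asm$patient_id[cohort$asm$drug == drug]))
  abort_if(n_pat < min_patients,
           "drug %s used by %d patient(s), below min_patients = %d; skipped",
           sQuote(drug), n_pat, min_patients)
  if (is.null(responses)) responses <- month_response_table(cohort,
                                                            seizure_type)
  ev <- responses[responses$response != "not_evaluable", , drop = FALSE]
  drugs <- strsplit(ev$exposed, ";", fixed = TRUE)
  exposed <- vapply(drugs, function(d) drug %in% d, logical(1))
  if (sole_exposure) exposed <- exposed & lengths(drugs) == 1L
  favorable <- switch(outcome,
    short_term = ev$response == "reduced",
    long_term = ev$response %in% c("reduced", "freedom_maintained"),
    freedom_only = ev$response == "freedom_maintained")
  tab <- matrix(c(sum(exposed & favorable), sum(exposed & !favorable),
                  sum(!exposed & favorable), sum(!exposed & !favorable)),
                2, byrow = TRUE,
                dimnames = list(c("exposed", "unexposed"),
                                c("favorable", "unfavorable")))
  fo <- fisher_or(tab)
  ci_low <- fo$ci_low; ci_high <- fo$ci_high
  if (ci == "bootstrap") {
    ids <- unique(ev$patient_id)
    cross_or <- function(e, f) {
      t2 <- c(sum(e & f), sum(e & !f), sum(!e & f), sum(!e & !f))
      if (any(t2 == 0)) t2 <- t2 + 0.5
      (t2[1] * t2[4]) / (t2[2] * t2[3])
    }
    ors <- with_seed(boot_seed, vapply(seq_len(n_boot), function(b) {
      take <- sample(ids, replace = TRUE)
      rows <- unlist(lapply(take, function(id) which(ev$patient_id == id)))
      cross_or(exposed[rows], favorable[rows])
    }, numeric(1)))
    qs <- stats::quantile(ors, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    ci_low <- qs[1]; ci_high <- qs[2]
  }
  structure(list(drug = drug, outcome = outcome, table = tab,
                 or = fo$or, ci_low = ci_low, ci_high = ci_high,
                 ci_method = ci, p = fo$p, n_patients = n_pat,
                 n_months = sum(tab)), class = "asm_effect")
}

#' @export
print.asm_effect <- function(x, ...) {
  cat(sprintf("%s, %s response: OR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              x$drug, x$outcome, x$or, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  %d patients, %d evaluable patient-months\n",
              x$n_patients, x$n_months))
  print(x$table)
  invisible(x)
}

#' Effectiveness screen across all sufficiently used drugs
#'
#' Applies [comparative_effectiveness()] to every drug in the exposure
#' table used by at least `min_patients` patients; drugs below the
#' threshold are skipped with a message.
#'
#' @inheritParams comparative_effectiveness
#' @return data.frame with one row per drug scored.
#' @export
effectiveness_screen <- function(cohort, outcome = "short_term",
                                 min_patients = 10L,
                                 seizure_type = "overall") {
  abort_if(is.null(cohort$asm), "cohort has no ASM exposure table")
  responses <- month_response_table(cohort, seizure_type)
  drugs <- sort(unique(cohort$asm$drug))
  rows <- lapply(drugs, function(d) {
    e <- tryCatch(comparative_effectiveness(
      cohort, d, outcome = outcome, min_patients = min_patients,
      seizure_type = seizure_type, responses = responses),
      error = function(err) { message(conditionMessage(err)); NULL })
    if (is.null(e)) return(NULL)
    data.frame(drug = d, outcome = outcome, or = e$or, ci_low = e$ci_low,
               ci_high = e$ci_high, p = e$p, n_patients = e$n_patients,
               n_months = e$n_months, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Time-locked treatment-response curve
#'
#' Aligns patients at their first initiation of `drug` (or of any ASM)
#' and reports, for each month after initiation, the percent reduction in
#' mean SF relative to the month before initiation:
#' reduction(m) = 1 - mean SF(t0 + m) / mean SF(t0 - 1), over patients
#' still observed at t0 + m. Patients whose baseline SF at t0 - 1 is zero
#' carry no ratio information and are excluded (their count is reported).
#' When the cohort has a spasm-type series, the cumulative fraction of
#' spasm patients whose spasm series has permanently stopped by m months
#' after initiation is also returned.
#'
#' @param cohort an imputed `sf_cohort` with an `asm` table.
#' @param drug drug name or `"any"` for any ASM exposure.
#' @param horizon months after initiation to report (default 12).
#' @return an object of class `asm_response_curve` with `curve`
#'   (data.frame `months_after`, `mean_sf`, `reduction`, `n`),
#'   `spasm_offset` (data.frame or NULL), `baseline_mean`, `n_excluded`.
#' @export
time_locked_response <- function(cohort, drug = "any", horizon = 12L) {
  asm <- cohort$asm
  abort_if(is.null(asm), "cohort has no ASM exposure table")
  sub <- if (drug == "any") asm else asm[asm$drug == drug, , drop = FALSE]
  abort_if(!nrow(sub), "no exposures for drug %s", sQuote(drug))
  t0 <- tapply(sub$start_month, sub$patient_id, min)
  ids <- names(t0)
  base <- vapply(ids, function(id) {
    s <- sf_series(cohort, id)
    b <- as.character(t0[[id]] - 1L)
    if (b %in% names(s)) s[[b]] else NA_real_
  }, numeric(1))
  keep <- !is.na(base) & base > 0
  n_excluded <- sum(!keep)
  abort_if(!any(keep),
           "no patient has a nonzero pre-initiation baseline month")
  ids <- ids[keep]; base <- base[keep]
  rows <- lapply(0:horizon, function(m) {
    v <- vapply(ids, function(id) {
      s <- sf_series(cohort, id)
      mm <- as.character(t0[[id]] + m)
      if (mm %in% names(s)) s[[mm]] else NA_real_
    }, numeric(1))
    ok <- !is.na(v)
    if (!any(ok)) return(NULL)
    data.frame(months_after = m, mean_sf = mean(v[ok]),
               reduction = 1 - mean(v[ok]) / mean(base[ok]),
               n = sum(ok))
  })
  curve <- do.call(rbind, rows)
  ## spasm offset: fraction of treated spasm patients whose spasm-type
  ## series is permanently zero by m months after initiation
  spasm_offset <- NULL
  sz <- cohort$seizures
  spasm_ids <- intersect(ids, unique(
    sz$patient_id[sz$seizure_type == HPO_SPASMS & sz$sf > 0]))
  if (length(spasm_ids) >= 3) {
    last_spasm <- vapply(spasm_ids, function(id) {
      r <- sz[sz$patient_id == id & sz$seizure_type == HPO_SPASMS &
                sz$sf > 0, ]
      max(r$month)
    }, numeric(1))
    offs <- last_spasm - vapply(spasm_ids, function(id) t0[[id]], numeric(1))
    spasm_offset <- data.frame(
      months_after = 0:horizon,
      fraction_offset = vapply(0:horizon, function(m)
        mean(offs <= m), numeric(1)),
      n = length(spasm_ids))
  }
  structure(list(drug = drug, curve = curve, spasm_offset = spasm_offset,
                 baseline_mean = mean(base), n = length(ids),
                 n_excluded = n_excluded), class = "asm_response_curve")
}

#' @export
print.asm_response_curve <- function(x, ...) {
  cat(sprintf(
    "Time-locked response to %s: %d patients (baseline mean SF %.2f)\n",
    x$drug, x$n, x$baseline_mean))
  if (x$n_excluded)
    cat(sprintf("  excluded for zero baseline: %d\n", x$n_excluded))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.asm_response_curve <- function(x, ...) {
  graphics::plot(x$curve$months_after, 100 * x$curve$reduction, type = "b",
                 xlab = "months after initiation",
                 ylab = "% reduction in mean SF",
                 main = sprintf("Response to %s", x$drug), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
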