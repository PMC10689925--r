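## Virtual clinical-trial simulator: eligibility sampling, injected percent
## seizure reduction over a trial window, synthetic-control significance
## evaluation against the same patients' observed frequencies, and the
## Observed Frequency of Trial Success (OFTS) curve across start months.

#' Trial configuration
#'
#' @param start_month month of life at which the trial starts.
#' @param duration trial window length in months (6 or 12 in the default
#'   design; any positive integer is accepted).
#' @param reduction injected fractional seizure reduction in `[0, 1]`
#'   (design grid 0.10/0.15/0.20; an extended grid up to 0.50 is equally
#'   valid).
#' @param n_subjects patients sampled per trial (default 20; smaller
#'   eligible pools are used whole).
#' @param n_trials simulated trials per start month (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seizure_type `"overall"` or an HPO term id.
#' @param min_eligible minimum eligible pool to run a trial (default 5).
#' @param test `"signed_rank"` (paired one-sided Wilcoxon signed-rank on
#'   per-patient cumulative window SF, the default) or `"rank_sum"`
#'   (unpaired one-sided Wilcoxon rank-sum of treated vs observed
#'   cumulative SF).
#' @param ordinal_rounding round treated SF back to the 0-5 ordinal grid?
#'   (default FALSE: the reduced series stays on a continuous scale).
#' @return an object of class `trial_config` (named list).
#' @export
trial_config <- function(start_month = 12L, duration = 6L, reduction = 0.2,
                         n_subjects = 20L, n_trials = 1000L, alpha = 0.05,
                         seizure_type = "overall", min_eligible = 5L,
                         test = c("signed_rank", "rank_sum"),
                         ordinal_rounding = FALSE) {
  abort_if(reduction < 0 || reduction > 1, "reduction must lie in [0, 1]")
  abort_if(n_subjects < 2, "n_subjects must be >= 2")
  abort_if(alpha <= 0 || alpha >= 1, "alpha must lie in (0, 1)")
  abort_if(duration < 1, "duration must be >= 1")
  structure(list(start_month = as.integer(start_month),
                 duration = as.integer(duration), reduction = reduction,
                 n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), alpha = alpha,
                 seizure_type = seizure_type,
                 min_eligible = as.integer(min_eligible),
                 test = match.arg(test),
                 ordinal_rounding = ordinal_rounding),
            class = "trial_config")
}

#' Exact one-sided Wilcoxon signed-rank p-value
#'
#' P(V <= v_obs) for the signed-rank statistic V (sum of ranks of positive
#' differences `x - y`), under the null of independent sign flips - the
#' one-sided test of `x` shifted below `y`. Zero differences are dropped;
#' ties in the absolute differences are handled exactly: the null
#' distribution of V is built by dynamic programming over the 2^n sign
#' assignments (tied ranks are midranks, doubled to stay on an integer
#' grid), so no normal approximation is involved at any n.
#'
#' @param x,y paired numeric vectors.
#' @return exact one-sided p-value in (0, 1].
#' @export
#' @examples
#' signed_rank_p(rep(8, 20), rep(10, 20))  # 20 identical drops: 2^-20
signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) return(1)
  w <- as.integer(round(2 * rank(abs(d))))   # doubled midranks: integers
  v_obs <- sum(w[d > 0])
  probs <- 1
  for (wi in w) {
    new <- numeric(length(probs) + wi)
    new[seq_along(probs)] <- probs * 0.5
    idx <- seq_along(probs) + wi
    new[idx] <- new[idx] + probs * 0.5
    probs <- new
  }
  sum(probs[seq_len(v_obs + 1L)])
}

#' Patients eligible for a trial at a given start month
#'
#' Eligible patients have ongoing seizures (SF > 0 for the requested
#' seizure type) at the start month and an observation window extending
#' through the whole trial window.
#'
#' @param cohort an imputed `sf_cohort`.
#' @param start_month trial start (month of life).
#' @param duration window length in months; the window covers months
#'   `start_month` to `start_month + duration - 1`.
#' @param seizure_type `"overall"` or an HPO term id.
#' @return character vector of patient ids.
#' @export
eligible_patients <- function(cohort, start_month, duration = 6L,
                              seizure_type = "overall") {
  p <- cohort$patients
  ids <- p$patient_id[p$obs_end_month >= start_month + duration - 1L &
                        p$obs_start_month <= start_month]
  keep <- vapply(ids, function(id) {
    s <- suppressWarnings(sf_series(cohort, id, seizure_type))
    m <- as.character(start_month)
    m %in% names(s) && !is.na(s[[m]]) && s[[m]] > 0
  }, logical(1))
  ids[keep]
}

## eligible pool with precomputed per-patient window series; one evaluation
## per (start month, duration) serves every trial replicate
trial_pool <- function(cohort, config) {
  elig <- eligible_patients(cohort, config$start_month, config$duration,
                            config$seizure_type)
  months <- seq.int(config$start_month,
                    config$start_month + config$duration - 1L)
  series <- vapply(elig, function(id) {
    s <- suppressWarnings(sf_series(cohort, id, config$seizure_type))
    v <- s[as.character(months)]
    v[is.na(v)] <- 0
    v
  }, numeric(length(months)))
  if (length(elig)) series <- matrix(series, nrow = length(months),
                                     dimnames = list(months, elig))
  list(ids = elig, series = series, cum = if (length(elig))
    colSums(series) else numeric(0))
}

## one trial replicate on a precomputed pool
run_trial_on_pool <- function(pool, config) {
  if (length(pool$ids) < config$min_eligible)
    return(list(p = NA_real_, success = NA, n_sampled = 0L,
                n_eligible = length(pool$ids)))
  take <- if (length(pool$ids) > config$n_subjects)
    sample(pool$ids, config$n_subjects) else pool$ids
  cum_obs <- pool$cum[take]
  scale <- 1 - config$reduction
  cum_trt <- if (config$ordinal_rounding)
    colSums(pmin(5, pmax(0, round_half_up(
      pool$series[, take, drop = FALSE] * scale))))
  else cum_obs * scale
  p <- if (all(cum_trt == cum_obs)) 1
  else if (config$test == "signed_rank") signed_rank_p(cum_trt, cum_obs)
  else suppressWarnings(stats::wilcox.test(
    cum_trt, cum_obs, alternative = "less"))$p.value
  list(p = p, success = p < config$alpha, n_sampled = length(take),
       n_eligible = length(pool$ids))
}

#' Run one virtual trial
#'
#' Samples `n_subjects` eligible patients without replacement (a pool
#' smaller than `n_subjects` is used whole), scales each sampled patient's
#' observed monthly SF over the trial window by `1 - reduction` (kept on a
#' continuous scale unless `ordinal_rounding`), and evaluates the
#' simulated effect against the same patients' observed frequencies - the
#' synthetic-control comparison - with a one-sided Wilcoxon test on the
#' per-patient cumulative window SF. Success means p < alpha.
#'
#' @param cohort an imputed `sf_cohort`.
#' @param config a `trial_config`.
#' @return list with `p`, `success`, `n_sampled`, `n_eligible`; or, when
#'   the eligible pool is below `min_eligible`, `success = NA` with
#'   `p = NA` (the month is undefined, not failed).
#' @export
run_trial <- function(cohort, config) {
  run_trial_on_pool(trial_pool(cohort, config), config)
}

#' Observed Frequency of Trial Success across start months
#'
#' For each start month and each (duration, reduction) combination, runs
#' `n_trials` seeded virtual trials and reports the OFTS: the proportion
#' of trials in which a significant effect (p < alpha) was detected.
#' Months whose eligible pool is below the minimum are flagged undefined
#' (`ofts = NA`), never zero-filled, and the per-month pool size is
#' reported so that repeated-sampling artefacts in sparse windows remain
#' visible.
#'
#' @param cohort an imputed `sf_cohort`.
#' @param months start months of life to scan.
#' @param durations trial durations in months (default `c(6, 12)`).
#' @param reductions injected reductions (default `c(0.10, 0.15, 0.20)`).
#' @param n_trials trials per month (default 1000).
#' @param seed integer seed.
#' @param ... further arguments passed to [trial_config()].
#' @return an object of class `ofts_curve`: a data.frame with columns
#'   `start_month`, `duration`, `reduction`, `n_eligible`, `trials_run`,
#'   `ofts`, plus the configuration as attributes.
#' @export
ofts <- function(cohort, months = 1:48, durations = c(6L, 12L),
                 reductions = c(0.10, 0.15, 0.20), n_trials = 1000L,
                 seed = 1L, ...) {
  grid <- expand.grid(start_month = months, duration = durations,
                      reduction = reductions)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      cfg <- trial_config(start_month = grid$start_month[i],
                          duration = grid$duration[i],
                          reduction = grid$reduction[i],
                          n_trials = n_trials, ...)
      pool <- trial_pool(cohort, cfg)
      if (length(pool$ids) < cfg$min_eligible)
        return(data.frame(start_month = cfg$start_month,
                          duration = cfg$duration,
                          reduction = cfg$reduction,
                          n_eligible = length(pool$ids), trials_run = 0L,
                          ofts = NA_real_))
      succ <- vapply(seq_len(n_trials), function(t)
        isTRUE(run_trial_on_pool(pool, cfg)$success), logical(1))
      data.frame(start_month = cfg$start_month, duration = cfg$duration,
                 reduction = cfg$reduction, n_eligible = length(pool$ids),
                 trials_run = n_trials, ofts = mean(succ))
    })
    out <- do.call(rbind, rows)
    structure(out, class = c("ofts_curve", "data.frame"),
              n_trials = n_trials, seed = seed)
  })
}

#' @export
print.ofts_curve <- function(x, ...) {
  cat(sprintf("OFTS curve: %d start months x %d designs, %d trials each\n",
              length(unique(x$start_month)),
              nrow(unique(x[c("duration", "reduction")])),
              attr(x, "n_trials")))
  defined <- x[!is.na(x$ofts), , drop = FALSE]
  if (nrow(defined)) {
    best <- defined[which.max(defined$ofts), ]
    cat(sprintf(
      "  max OFTS %.3f at start month %d (duration %d, reduction %.0f%%)\n",
      best$ofts, best$start_month, best$duration, 100 * best$reduction))
  }
  cat(sprintf("  undefined months (pool below minimum): %d\n",
              sum(is.na(x$ofts))))
  invisible(x)
}

#' @export
plot.ofts_curve <- function(x, duration = NULL, reduction = NULL, ...) {
  d <- if (is.null(duration)) x$duration[1] else duration
  r <- if (is.null(reduction)) max(x$reduction) else reduction
  sub <- x[x$duration == d & x$reduction == r, , drop = FALSE]
  graphics::plot(sub$start_month, sub$ofts, type = "s", ylim = c(0, 1),
                 xlab = "trial start (month of life)", ylab = "OFTS",
                 main = sprintf("OFTS: %d-month trial, %.0f%% reduction",
                                d, 100 * r), ...)
  invisible(x)
}
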