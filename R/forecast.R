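## k-nearest-neighbour longitudinal seizure-frequency forecasting:
## first-year pairwise similarity, per-month median neighbour prediction
## after month 12, permutation test of better-than-chance forecasting, and
## the high/low-fidelity partition with first-year risk-feature enrichment.

#' First-year distance between two seizure histories
#'
#' Mean absolute difference of overall SF scores over months 1-12. This is
#' a metric on the ordinal SF scale (it is the L1 distance divided by 12),
#' bounded by 5 (constant 5 vs constant 0). Alternative metrics are
#' available via `metric`.
#'
#' @param a,b numeric vectors of SF scores for months 1-12 (length 12,
#'   no missing values).
#' @param metric `"mean_abs"` (default), `"euclidean"`, or
#'   `"rank_correlation"` (1 - Spearman correlation, 0 when either series
#'   is constant-tied).
#' @return nonnegative distance.
#' @export
#' @examples
#' first_year_distance(rep(5, 12), rep(0, 12))  # 5, the scale bound
first_year_distance <- function(a, b,
                                metric = c("mean_abs", "euclidean",
                                           "rank_correlation")) {
  metric <- match.arg(metric)
  abort_if(length(a) != 12 || length(b) != 12,
           "first-year series must have length 12")
  abort_if(anyNA(a) || anyNA(b), "first-year series must be complete")
  switch(metric,
         mean_abs = mean(abs(a - b)),
         euclidean = sqrt(sum((a - b)^2)),
         rank_correlation = {
           if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
           1 - stats::cor(a, b, method = "spearman")
         })
}

#' Pairwise first-year similarity matrix
#'
#' Symmetric matrix of pairwise first-year distances over all patients
#' with complete overall SF histories in months 1-12.
#'
#' @param cohort an imputed `sf_cohort`.
#' @param metric see [first_year_distance()].
#' @return matrix with patient ids as dimnames; attribute `"eligible"`
#'   carries the eligible id vector.
#' @export
similarity_matrix <- function(cohort, metric = "mean_abs") {
  first_year <- first_year_block(cohort)
  ids <- rownames(first_year)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        first_year_distance(first_year[i, ], first_year[j, ], metric = metric)
    }
  }
  attr(d, "eligible") <- ids
  d
}

## patients x 12 matrix of first-year SF; rows only for complete histories
first_year_block <- function(cohort) {
  p <- cohort$patients
  rows <- lapply(p$patient_id, function(id) {
    if (p$obs_end_month[match(id, p$patient_id)] < 12L) return(NULL)
    s <- sf_series(cohort, id)
    v <- s[as.character(1:12)]
    if (anyNA(v)) return(NULL)
    v
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  rownames(out) <- p$patient_id[keep]
  out
}

#' Forecast post-first-year seizure trajectories
#'
#' For every patient with a complete first-year (months 1-12) overall SF
#' history, predicts the SF score for each month after month 12 up to the
#' patient's last observed month (capped at `horizon`) as the per-month
#' median SF of the `k` most phenotypically similar patients (smallest
#' first-year distance; distance ties broken by patient order after a
#' seeded shuffle; even-count medians rounded half-up to the ordinal
#' grid). Months at which no reference patient is still observed are
#' dropped from the divergence, with the dropped count reported. The
#' per-patient divergence is the mean absolute difference between
#' predicted and observed SF over the forecast months.
#'
#' A permutation test then asks whether the forecast tracks the observed
#' trajectory better than chance: the null draws `n_perm` random
#' trajectories with SF i.i.d. uniform on \{0..5\} per forecast month and
#' compares their divergence from the observed trajectory with the
#' forecast's divergence; p = (1 + #\{null <= observed\}) / (n_perm + 1),
#' so p is never 0, and "better than chance" means p < alpha.
#'
#' @param cohort an imputed `sf_cohort`.
#' @param k number of reference neighbours (default 10).
#' @param horizon last month of life to forecast (default 120); each
#'   patient is only forecast through their own last observed month.
#' @param n_perm permutation draws per patient (default 100000).
#' @param seed integer seed for tie-breaking and the permutation draws.
#' @param metric see [first_year_distance()].
#' @param aggregate neighbour aggregation, `"median"` (default, rounded
#'   half-up) or `"mean"`.
#' @param alpha significance level for better-than-chance (default 0.05).
#' @return an object of class `sf_forecast`: a list with `results` (one
#'   row per patient: divergence, n months forecast, dropped months,
#'   permutation p, better-than-chance flag, reference ids), `predicted`
#'   and `observed` matrices, and the call parameters.
#' @export
forecast_sf <- function(cohort, k = 10L, horizon = 120L, n_perm = 1e5,
                        seed = 1L, metric = "mean_abs",
                        aggregate = c("median", "mean"), alpha = 0.05) {
  abort_if(n_perm < 1, "n_perm must be >= 1")
  aggregate <- match.arg(aggregate)
  d <- similarity_matrix(cohort, metric = metric)
  ids <- rownames(d)
  n <- length(ids)
  abort_if(n < k + 1, "need at least k + 1 = %d eligible patients, have %d",
           k + 1, n)
  p <- cohort$patients
  obs_end <- p$obs_end_month[match(ids, p$patient_id)]
  hor <- pmin(obs_end, horizon)
  series <- lapply(stats::setNames(ids, ids), function(id)
    sf_series(cohort, id))
  months_all <- seq.int(13L, max(c(13L, hor)))
  obs_mat <- matrix(NA_real_, n, length(months_all),
                    dimnames = list(ids, months_all))
  for (i in seq_len(n)) {
    s <- series[[i]]
    m <- intersect(as.integer(names(s)), months_all)
    m <- m[m <= hor[i]]
    if (length(m)) obs_mat[i, as.character(m)] <- s[as.character(m)]
  }
  with_seed(seed, {
    shuffle <- sample.int(n)           # tie-break order for equal distances
    pred_mat <- matrix(NA_real_, n, length(months_all),
                       dimnames = list(ids, months_all))
    res <- vector("list", n)
    for (i in seq_len(n)) {
      di <- d[i, ]
      di[i] <- Inf
      ord <- order(di, match(seq_len(n), shuffle))
      refs <- ord[seq_len(min(k, n - 1))]
      fm <- months_all[months_all <= hor[i] &
                         !is.na(obs_mat[i, as.character(months_all)])]
      dropped <- 0L
      for (m in fm) {
        v <- obs_mat[refs, as.character(m)]
        v <- v[!is.na(v)]
        if (!length(v)) { dropped <- dropped + 1L; next }
        pred_mat[i, as.character(m)] <- if (aggregate == "median")
          round_half_up(stats::median(v)) else mean(v)
      }
      use <- fm[!is.na(pred_mat[i, as.character(fm)])]
      if (!length(use)) {
        res[[i]] <- data.frame(
          patient_id = ids[i], n_months = 0L, n_dropped = dropped,
          divergence = NA_real_, permutation_p = NA_real_,
          better_than_chance = NA,
          reference_ids = paste(ids[refs], collapse = ";"),
          stringsAsFactors = FALSE)
        next
      }
      obs <- obs_mat[i, as.character(use)]
      prd <- pred_mat[i, as.character(use)]
      divergence <- mean(abs(prd - obs))
      null_mat <- matrix(sample(0:5, n_perm * length(use), replace = TRUE),
                         nrow = n_perm)
      null_div <- rowMeans(abs(sweep(null_mat, 2, obs)))
      pp <- (1 + sum(null_div <= divergence)) / (n_perm + 1)
      res[[i]] <- data.frame(
        patient_id = ids[i], n_months = length(use), n_dropped = dropped,
        divergence = divergence, permutation_p = pp,
        better_than_chance = pp < alpha,
        reference_ids = paste(ids[refs], collapse = ";"),
        stringsAsFactors = FALSE)
    }
    structure(list(
      results = do.call(rbind, res), predicted = pred_mat,
      observed = obs_mat, k = k, n_perm = n_perm, alpha = alpha,
      metric = metric, seed = seed), class = "sf_forecast")
  })
}

#' @export
print.sf_forecast <- function(x, ...) {
  r <- x$results
  ok <- r[!is.na(r$divergence), ]
  cat(sprintf("Seizure trajectory forecast: %d patients, k = %d, %s perms\n",
              nrow(r), x$k, format(x$n_perm, big.mark = ",")))
  cat(sprintf("  better than chance (p < %.2f): %d/%d (%.0f%%)\n", x$alpha,
              sum(ok$better_than_chance), nrow(ok),
              100 * mean(ok$better_than_chance)))
  cat(sprintf("  median divergence: %.3f SF points\n",
              stats::median(ok$divergence)))
  invisible(x)
}

#' @export
summary.sf_forecast <- function(object, ...) {
  r <- object$results[!is.na(object$results$divergence), ]
  list(n = nrow(r),
       better_than_chance_fraction = mean(r$better_than_chance),
       divergence_quantiles = stats::quantile(r$divergence,
                                              c(0.25, 0.5, 0.75)))
}

#' @export
plot.sf_forecast <- function(x, patient_id = NULL, ...) {
  ids <- rownames(x$predicted)
  id <- if (is.null(patient_id)) ids[1] else patient_id
  months <- as.integer(colnames(x$predicted))
  obs <- x$observed[id, ]
  prd <- x$predicted[id, ]
  graphics::plot(months, obs, type = "s", ylim = c(0, 5),
                 xlab = "month of life", ylab = "SF score",
                 main = sprintf("Observed vs forecast trajectory: %s", id),
                 ...)
  graphics::lines(months, prd, type = "s", lty = 2, col = 2)
  graphics::legend("topright", legend = c("observed", "forecast"),
                   lty = c(1, 2), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Partition patients into high- and low-fidelity forecast subgroups
#'
#' Low fidelity means the trajectory could not be forecast: permutation
#' p >= alpha, or divergence above a threshold (default the cohort's
#' 66.7th percentile of divergence among patients with any seizures).
#' Everyone else - including seizure-free patients whose all-zero
#' trajectories are predicted exactly - is high fidelity.
#'
#' @param forecast an `sf_forecast` object.
#' @param cohort the cohort the forecast was computed on (used to identify
#'   patients with any seizures for the divergence threshold).
#' @param alpha significance level (default the forecast's alpha).
#' @param divergence_quantile quantile of seizing patients' divergence used
#'   as the threshold (default 2/3).
#' @return list with `labels` (data.frame `patient_id`, `divergence`,
#'   `permutation_p`, `fidelity`), `threshold`, and counts `n_high`,
#'   `n_low`.
#' @export
partition_fidelity <- function(forecast, cohort, alpha = forecast$alpha,
                               divergence_quantile = 2 / 3) {
  r <- forecast$results[!is.na(forecast$results$divergence), ]
  abort_if(nrow(r) == 0, "no scored patients to partition")
  seizing <- vapply(r$patient_id, function(id)
    any(sf_series(cohort, id) > 0, na.rm = TRUE), logical(1))
  thr <- if (any(seizing))
    stats::quantile(r$divergence[seizing], divergence_quantile, names = FALSE)
  else Inf
  low <- r$permutation_p >= alpha | r$divergence > thr
  labels <- data.frame(patient_id = r$patient_id,
                       divergence = r$divergence,
                       permutation_p = r$permutation_p,
                       fidelity = ifelse(low, "low", "high"),
                       stringsAsFactors = FALSE)
  list(labels = labels, threshold = thr,
       n_high = sum(!low), n_low = sum(low))
}

#' First-year seizure features enriched in the low-fidelity subgroup
#'
#' Computes, for each binary first-year feature, the Fisher's-exact odds
#' ratio of low-fidelity membership: ongoing seizures at month 12, seizure
#' offset by month 7 (onset occurred and months 8-12 seizure-free), spasms
#' after month 6 (spasm-type series active beyond month 6), and a maximum
#' run of consecutive seizure months in the first year above
#' `consecutive_threshold`. Degenerate (constant) features are reported
#' with an `NA` odds ratio and a note.
#'
#' @param cohort an imputed `sf_cohort`.
#' @param labels the `labels` data.frame from [partition_fidelity()].
#' @param consecutive_threshold months (default 6).
#' @return data.frame: `feature`, `or`, `ci_low`, `ci_high`, `p`, `note`.
#' @export
first_year_risk_features <- function(cohort, labels,
                                     consecutive_threshold = 6L) {
  ids <- labels$patient_id
  fy <- t(vapply(ids, function(id) {
    s <- sf_series(cohort, id)
    v <- s[as.character(1:12)]
    sp <- suppressWarnings(tryCatch(sf_series(cohort, id, HPO_SPASMS),
                                    warning = function(w) NULL))
    onset <- detect_onset(s)
    c(ongoing_m12 = !is.na(v[12]) && v[12] > 0,
      offset_by_7 = !is.na(onset) && onset <= 7 &&
        all(v[as.character(8:12)] == 0, na.rm = TRUE),
      spasms_after_6 = !is.null(sp) &&
        any(sp[as.integer(names(sp)) > 6] > 0, na.rm = TRUE),
      long_consecutive = max_run(!is.na(v) & v > 0) > consecutive_threshold)
  }, logical(4)))
  low <- labels$fidelity == "low"
  rows <- lapply(colnames(fy), function(f) {
    x <- fy[, f]
    if (length(unique(x)) < 2 || length(unique(low)) < 2)
      return(data.frame(feature = f, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        note = "degenerate (constant) feature or labels",
                        stringsAsFactors = FALSE))
    tab <- matrix(c(sum(x & low), sum(x & !low),
                    sum(!x & low), sum(!x & !low)), 2, byrow = TRUE)
    fo <- fisher_or(tab)
    note <- if (any(tab == 0)) "zero cell: Haldane-Anscombe corrected" else ""
    data.frame(feature = f, or = fo$or, ci_low = fo$ci_low,
               ci_high = fo$ci_high, p = fo$p, note = note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
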