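## Core cohort data model: ordinal seizure-frequency (SF) encoding,
## long-format patient x month containers, validation, cohort-median
## imputation and CSV round-trip I/O.

#' Six-level ordinal seizure-frequency scale
#'
#' The monthly seizure-frequency (SF) score is an ordinal severity scale:
#' 0 = no seizures, 1 = monthly, 2 = weekly, 3 = daily, 4 = several daily
#' (2-5/day), 5 = multiple daily (>5/day). `sf_scale()` returns the named
#' mapping; [encode_sf()] maps frequency descriptors onto it.
#'
#' @return named integer vector mapping descriptor to score.
#' @export
#' @examples
#' sf_scale()
sf_scale <- function() {
  c("none" = 0L, "monthly" = 1L, "weekly" = 2L,
    "daily" = 3L, "2-5/day" = 4L, ">5/day" = 5L)
}

#' Encode seizure-frequency descriptors as SF scores
#'
#' Bijective mapping from the six categorical monthly frequency descriptors
#' to the ordinal SF score 0-5 (see [sf_scale()]).
#'
#' @param descriptor character vector of descriptors, each one of
#'   `">5/day"`, `"2-5/day"`, `"daily"`, `"weekly"`, `"monthly"`, `"none"`.
#' @return integer vector of SF scores in 0..5.
#' @export
#' @examples
#' encode_sf(c(">5/day", "none", "weekly"))
encode_sf <- function(descriptor) {
  map <- sf_scale()
  bad <- setdiff(unique(descriptor), names(map))
  abort_if(length(bad) > 0,
           "unrecognized seizure-frequency descriptor(s): %s",
           paste(sQuote(bad), collapse = ", "))
  unname(map[descriptor])
}

SENTINEL_UNKNOWN <- "present_unknown"
VARIANT_CLASSES <- c("missense", "ptv_del", "inframe_indel", "unknown")

#' Construct a seizure-frequency cohort
#'
#' Bundles the long-format tables of a natural-history cohort into a single
#' validated container. Months of life are 1-based closed intervals
#' (month 1 = first calendar month after birth, the "neonatal" month).
#'
#' @param patients data.frame with columns `patient_id`, `sex`
#'   (`male`/`female`/`unknown`), `variant_class` (`missense`, `ptv_del`,
#'   `inframe_indel`, `unknown`), `variant_label`, `obs_start_month`,
#'   `obs_end_month`, `has_epilepsy`.
#' @param seizures data.frame with columns `patient_id`, `seizure_type`
#'   (HPO CURIE such as `"HP:0012469"` or the sentinel `"overall"`),
#'   `month`, `sf` (integer 0-5, or NA when `unknown` is TRUE), and logical
#'   columns `unknown` (seizures present, frequency unknown) and `imputed`.
#' @param asm optional data.frame of treatment exposures: `patient_id`,
#'   `drug` (canonical lowercase name), `start_month`, `end_month` (closed
#'   interval). Overlapping intervals for the same drug are merged.
#' @param milestones optional data.frame: `patient_id`, `milestone`,
#'   `achieved` (logical), `age_achieved_months` (NA when not achieved),
#'   `age_last_assessed_months`.
#' @param assessments optional data.frame: `patient_id`, `scale`,
#'   `age_months`, `value` (numeric score or integer level 1-5).
#' @param provenance list describing data origin (e.g. generator seed).
#' @param validate run [validate_cohort()] before returning?
#' @return an object of class `sf_cohort`.
#' @seealso [read_cohort()], [generate_cohort()]
#' @export
sf_cohort <- function(patients, seizures, asm = NULL, milestones = NULL,
                      assessments = NULL, provenance = list(),
                      validate = TRUE) {
  patients <- as.data.frame(patients)
  seizures <- as.data.frame(seizures)
  if (is.null(seizures$unknown)) seizures$unknown <- FALSE
  if (is.null(seizures$imputed)) seizures$imputed <- FALSE
  if (!is.null(asm) && nrow(asm)) asm <- merge_exposures(as.data.frame(asm))
  obj <- structure(list(
    patients = patients,
    seizures = canonical_seizures(seizures),
    asm = asm,
    milestones = if (is.null(milestones)) NULL else as.data.frame(milestones),
    assessments = if (is.null(assessments)) NULL else as.data.frame(assessments),
    provenance = provenance
  ), class = "sf_cohort")
  if (validate) validate_cohort(obj)
  obj
}

## canonical row order so that write/read round-trips are stable
canonical_seizures <- function(sz) {
  sz <- sz[order(sz$patient_id, sz$seizure_type, sz$month), , drop = FALSE]
  rownames(sz) <- NULL
  sz
}

## merge overlapping/adjacent exposure intervals per (patient, drug)
merge_exposures <- function(asm) {
  asm <- asm[order(asm$patient_id, asm$drug, asm$start_month), , drop = FALSE]
  out <- lapply(split(asm, list(asm$patient_id, asm$drug), drop = TRUE),
                function(d) {
    if (nrow(d) == 1) return(d)
    keep <- d[1, , drop = FALSE]
    for (i in 2:nrow(d)) {
      j <- nrow(keep)
      if (d$start_month[i] <= keep$end_month[j] + 1L) {
        keep$end_month[j] <- max(keep$end_month[j], d$end_month[i])
      } else keep <- rbind(keep, d[i, , drop = FALSE])
    }
    keep
  })
  out <- do.call(rbind, out)
  out <- out[order(out$patient_id, out$drug, out$start_month), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a cohort's referential and domain integrity
#'
#' Checks patient-id uniqueness, non-empty observation windows, SF domain
#' (integers 0-5 or unknown-present markers), months within each patient's
#' observation window, duplicate (patient, type, month) keys, referential
#' integrity of exposure/milestone/assessment tables, and - for fully known
#' histories - that the overall SF at a month is at least the maximum
#' per-type SF. All violations are aggregated and reported together with
#' the offending rows.
#'
#' @param cohort an `sf_cohort`.
#' @return the cohort, invisibly; stops with an aggregated message on error.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$patients; sz <- cohort$seizures
  errs <- character()
  add <- function(...) errs <<- c(errs, sprintf(...))

  if (anyDuplicated(p$patient_id))
    add("duplicate patient_id in patients: %s",
        paste(unique(p$patient_id[duplicated(p$patient_id)]), collapse = ", "))
  bad_win <- which(p$obs_end_month < p$obs_start_month | p$obs_start_month < 1)
  if (length(bad_win))
    add("empty or invalid observation window for patient(s): %s",
        paste(p$patient_id[bad_win], collapse = ", "))
  bad_vc <- which(!p$variant_class %in% VARIANT_CLASSES)
  if (length(bad_vc))
    add("unknown variant_class at patients row(s) %s",
        paste(bad_vc, collapse = ", "))

  if (nrow(sz)) {
    orphan <- which(!sz$patient_id %in% p$patient_id)
    if (length(orphan))
      add("seizure rows for unknown patient(s): %s (rows %s)",
          paste(unique(sz$patient_id[orphan]), collapse = ", "),
          paste(utils::head(orphan, 5), collapse = ", "))
    key <- paste(sz$patient_id, sz$seizure_type, sz$month)
    dup <- which(duplicated(key))
    if (length(dup))
      add("duplicate (patient, type, month) rows: %s",
          paste(utils::head(key[dup], 5), collapse = "; "))
    known <- !sz$unknown
    bad_sf <- which(known & (is.na(sz$sf) | sz$sf %% 1 != 0 |
                               sz$sf < 0 | sz$sf > 5))
    if (length(bad_sf))
      add("sf outside {0..5} at seizure row(s) %s",
          paste(utils::head(bad_sf, 5), collapse = ", "))
    idx <- match(sz$patient_id, p$patient_id)
    out_win <- which(!is.na(idx) &
                       (sz$month < p$obs_start_month[idx] |
                          sz$month > p$obs_end_month[idx]))
    if (length(out_win))
      add("seizure month outside observation window at row(s) %s",
          paste(utils::head(out_win, 5), collapse = ", "))
    ## overall >= per-type max, checked where everything at the month is known
    if (!any(sz$unknown)) {
      per_type <- sz[sz$seizure_type != "overall", , drop = FALSE]
      if (nrow(per_type)) {
        k <- paste(per_type$patient_id, per_type$month)
        mx <- tapply(per_type$sf, k, max)
        ov <- sz[sz$seizure_type == "overall", , drop = FALSE]
        ko <- paste(ov$patient_id, ov$month)
        m <- mx[ko]
        viol <- which(!is.na(m) & ov$sf < m)
        if (length(viol))
          add("overall SF below per-type maximum for key(s): %s",
              paste(utils::head(ko[viol], 5), collapse = "; "))
      }
    }
  }
  for (tbl in c("asm", "milestones", "assessments")) {
    d <- cohort[[tbl]]
    if (!is.null(d) && nrow(d)) {
      orphan <- unique(d$patient_id[!d$patient_id %in% p$patient_id])
      if (length(orphan))
        add("%s rows for unknown patient(s): %s", tbl,
            paste(orphan, collapse = ", "))
    }
  }
  if (!is.null(cohort$asm) && nrow(cohort$asm)) {
    bad <- which(cohort$asm$end_month < cohort$asm$start_month)
    if (length(bad))
      add("asm exposure with end < start at row(s) %s",
          paste(bad, collapse = ", "))
  }
  abort_if(length(errs) > 0, "invalid cohort:\n- %s",
           paste(errs, collapse = "\n- "))
  invisible(cohort)
}

#' @export
print.sf_cohort <- function(x, ...) {
  p <- x$patients
  cat(sprintf("Seizure-frequency cohort: %d patients, %d seizure rows\n",
              nrow(p), nrow(x$seizures)))
  cat(sprintf("  epilepsy: %d/%d; patient-months observed: %d\n",
              sum(p$has_epilepsy), nrow(p),
              sum(p$obs_end_month - p$obs_start_month + 1L)))
  if (!is.null(x$asm))
    cat(sprintf("  ASM exposures: %d intervals, %d drugs\n",
                nrow(x$asm), length(unique(x$asm$drug))))
  if (!is.null(x$milestones))
    cat(sprintf("  milestones: %d records\n", nrow(x$milestones)))
  if (!is.null(x$assessments))
    cat(sprintf("  assessments: %d records\n", nrow(x$assessments)))
  if (any(x$seizures$unknown))
    cat(sprintf("  unimputed unknown-frequency months: %d\n",
                sum(x$seizures$unknown)))
  invisible(x)
}

#' @export
summary.sf_cohort <- function(object, ...) {
  p <- object$patients
  on <- onset_table(object)
  out <- list(
    n_patients = nrow(p),
    n_epilepsy = sum(p$has_epilepsy),
    variant_mix = table(p$variant_class),
    median_onset = stats::median(on$onset_month, na.rm = TRUE),
    n_neonatal = sum(on$onset_month == 1, na.rm = TRUE),
    patient_months = sum(p$obs_end_month - p$obs_start_month + 1L)
  )
  class(out) <- "summary.sf_cohort"
  out
}

#' @export
print.summary.sf_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (%d with epilepsy), %d patient-months\n",
              x$n_patients, x$n_epilepsy, x$patient_months))
  cat(sprintf("  median seizure onset: month %s; neonatal onset: %d\n",
              format(x$median_onset), x$n_neonatal))
  cat("  variant classes:\n")
  print(x$variant_mix)
  invisible(x)
}

#' Extract one patient's monthly SF series
#'
#' Returns the SF series over the patient's observation window, indexed by
#' month of life. Months with no recorded row are NA; unknown-present
#' months (pre-imputation) are NA with attribute tracking.
#'
#' @param cohort an `sf_cohort`.
#' @param patient_id patient identifier.
#' @param seizure_type `"overall"` (default) or an HPO term id. If the
#'   requested type has no rows for this patient, falls back to `"overall"`
#'   with a warning.
#' @return named numeric vector (names = months of life).
#' @export
sf_series <- function(cohort, patient_id, seizure_type = "overall") {
  p <- cohort$patients
  i <- match(patient_id, p$patient_id)
  abort_if(is.na(i), "unknown patient_id %s", sQuote(patient_id))
  months <- seq.int(p$obs_start_month[i], p$obs_end_month[i])
  sz <- cohort$seizures
  rows <- sz[sz$patient_id == patient_id & sz$seizure_type == seizure_type, ]
  if (!nrow(rows) && seizure_type != "overall") {
    warning(sprintf("no %s series for %s; falling back to overall",
                    sQuote(seizure_type), patient_id), call. = FALSE)
    rows <- sz[sz$patient_id == patient_id & sz$seizure_type == "overall", ]
  }
  out <- rep(NA_real_, length(months))
  names(out) <- months
  m <- match(rows$month, months)
  out[m[!is.na(m)]] <- rows$sf[!is.na(m)]
  out
}

#' Impute unknown-present seizure months by cohort median
#'
#' Months flagged "seizures present, frequency unknown" are replaced by the
#' median SF, in the same calendar month of life and seizure-type series,
#' over donor patients. By default donors are patients with a known nonzero
#' SF that month (the target is known to be seizing, so seizure-free
#' patients are excluded as donors); `donors = "all"` uses every known SF.
#' Even-count medians are rounded half-up to stay on the ordinal grid.
#' When a month has no donors, the global median of nonzero known SF across
#' all months of the same series is used (and reported via `message()`).
#' Imputed cells keep `imputed = TRUE` so downstream analyses can exclude
#' them.
#'
#' @param cohort an `sf_cohort`.
#' @param donors `"seizing"` (default) or `"all"`.
#' @return the cohort with no remaining unknown-present cells.
#' @export
impute_unknown_present <- function(cohort, donors = c("seizing", "all")) {
  donors <- match.arg(donors)
  sz <- cohort$seizures
  todo <- which(sz$unknown)
  if (!length(todo)) return(cohort)
  known <- sz[!sz$unknown, , drop = FALSE]
  abort_if(!nrow(known) || !any(known$sf > 0, na.rm = TRUE),
           "no patient with a known nonzero SF available as imputation donor")
  n_fallback <- 0L
  for (i in todo) {
    pool <- known[known$seizure_type == sz$seizure_type[i] &
                    known$month == sz$month[i], "sf"]
    if (donors == "seizing") pool <- pool[pool > 0]
    if (!length(pool)) {
      pool <- known[known$seizure_type == sz$seizure_type[i], "sf"]
      pool <- pool[pool > 0]
      if (!length(pool)) pool <- known$sf[known$sf > 0]
      n_fallback <- n_fallback + 1L
    }
    sz$sf[i] <- round_half_up(stats::median(pool))
    sz$unknown[i] <- FALSE
    sz$imputed[i] <- TRUE
  }
  if (n_fallback > 0)
    message(sprintf(
      "impute_unknown_present: %d cell(s) imputed from the global nonzero median (no same-month donors)",
      n_fallback))
  ## consistency pass: imputed cells must respect the overall >= per-type
  ## ordering; known cells are never touched
  for (i in todo) {
    same <- sz$patient_id == sz$patient_id[i] & sz$month == sz$month[i]
    if (sz$seizure_type[i] == "overall") {
      mx <- suppressWarnings(max(sz$sf[same & sz$seizure_type != "overall"]))
      if (is.finite(mx)) sz$sf[i] <- max(sz$sf[i], mx)
    } else {
      ov <- sz$sf[same & sz$seizure_type == "overall"]
      if (length(ov) && !any(sz$imputed[same & sz$seizure_type == "overall"]))
        sz$sf[i] <- min(sz$sf[i], ov[1])
    }
  }
  cohort$seizures <- sz
  cohort
}

#' Read a cohort from long-format CSV files
#'
#' Reads the standard file set (`patients.csv`, `seizures.csv`, and
#' optionally `asm.csv`, `milestones.csv`, `assessments.csv`) from a
#' directory. `seizures.csv` may carry the sentinel `"present_unknown"` in
#' its `sf` column for months where seizures occurred at unknown frequency.
#' Schema problems (missing columns, duplicate keys, out-of-window months)
#' are aggregated into a single error naming the offending rows.
#'
#' @param dir directory containing the CSV files.
#' @return an `sf_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(dir) {
  need <- function(fname, cols) {
    path <- file.path(dir, fname)
    abort_if(!file.exists(path), "missing required file %s", path)
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(cols, names(d))
    abort_if(length(missing) > 0, "%s: missing required column(s) %s",
             fname, paste(missing, collapse = ", "))
    d
  }
  opt <- function(fname) {
    path <- file.path(dir, fname)
    if (file.exists(path)) utils::read.csv(path, stringsAsFactors = FALSE)
    else NULL
  }
  patients <- need("patients.csv",
                   c("patient_id", "sex", "variant_class", "variant_label",
                     "obs_start_month", "obs_end_month"))
  patients$variant_label <- ifelse(is.na(patients$variant_label), "",
                                   as.character(patients$variant_label))
  sz <- need("seizures.csv", c("patient_id", "seizure_type", "month", "sf"))
  sz$unknown <- sz$sf == SENTINEL_UNKNOWN
  sz$sf <- suppressWarnings(as.numeric(ifelse(sz$unknown, NA, sz$sf)))
  if (is.null(sz$imputed)) sz$imputed <- FALSE else
    sz$imputed <- as.logical(sz$imputed)
  if (is.null(patients$has_epilepsy)) {
    ov <- sz[sz$seizure_type == "overall" & (sz$unknown | sz$sf > 0), ]
    patients$has_epilepsy <- patients$patient_id %in% ov$patient_id
  } else patients$has_epilepsy <- as.logical(patients$has_epilepsy)
  mil <- opt("milestones.csv")
  if (!is.null(mil)) {
    mil$achieved <- as.logical(mil$achieved)
    mil$age_achieved_months <- suppressWarnings(
      as.numeric(mil$age_achieved_months))
  }
  sf_cohort(patients, sz, asm = opt("asm.csv"), milestones = mil,
            assessments = opt("assessments.csv"),
            provenance = list(source = normalizePath(dir)))
}

#' Write a cohort to long-format CSV files
#'
#' Inverse of [read_cohort()]: writes `patients.csv`, `seizures.csv` and,
#' when present, `asm.csv`, `milestones.csv`, `assessments.csv` into `dir`.
#' Unknown-present cells are serialized as the sentinel `"present_unknown"`.
#' A written-then-read cohort equals the original in canonical form.
#'
#' @param cohort an `sf_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, fname) utils::write.csv(
    d, file.path(dir, fname), row.names = FALSE, quote = TRUE)
  sz <- cohort$seizures
  sz$sf <- ifelse(sz$unknown, SENTINEL_UNKNOWN, format(sz$sf, trim = TRUE))
  sz$unknown <- NULL
  w(sz, "seizures.csv")
  w(cohort$patients, "patients.csv")
  if (!is.null(cohort$asm)) w(cohort$asm, "asm.csv")
  if (!is.null(cohort$milestones)) w(cohort$milestones, "milestones.csv")
  if (!is.null(cohort$assessments)) w(cohort$assessments, "assessments.csv")
  invisible(dir)
}
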