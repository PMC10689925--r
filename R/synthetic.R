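## Seeded synthetic-cohort generator. Emulates the statistical structure of
## a rare-genetic-epilepsy natural-history cohort: ~71% epilepsy prevalence
## with a neonatal-onset subgroup, variant-class-specific seizure signatures
## (PTV/deletion: infantile-spasm peak at months 5-6 followed by remission;
## missense: persistent focal seizures in months 10-24), >=12-month
## seizure-free remission runs, ASM exposures with configurable true effects,
## and milestone ages coupled to onset age. Every latent draw is recorded in
## a GroundTruth object for parameter-recovery testing; analysis functions
## never read it.

#' Configuration for the synthetic-cohort generator
#'
#' Returns the default generator configuration, with any named argument
#' overridden. Defaults encode the cohort structure the analyses assume:
#' epilepsy prevalence 72/101, neonatal onset in 31/72 of epileptic
#' patients, onset ages from a discretized log-normal with median 2 months
#' (meanlog = log 2, sdlog = 1.86, giving quantiles ~ 1/2/7/20 months),
#' variant mix 0.53/0.44/0.03 over PTV-deletion / missense / in-frame
#' indel, an infantile-spasm window at months 5-6 for PTV patients followed
#' by boosted remission, suppressed remission (persistent focal seizures)
#' in months 10-24 for missense patients, and per-drug true effects.
#'
#' Monthly SF dynamics are a mean-reverting Markov chain on \{0..5\}: each
#' patient has a latent active seizure level; the chain drifts toward the
#' current target (the level, raised to 5 in the spasm window, scaled by
#' the strongest active drug's `sf_multiplier`). Remission is an absorbing
#' run of zero months entered with a per-month hazard; drugs with a
#' `freedom` effect > 1 multiply that hazard and divide the relapse
#' probability while active.
#'
#' @param ... named overrides of any default listed below.
#' @return an object of class `cohort_config` (a named list).
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 50, seed = 7)
#' cfg$epilepsy_fraction
cohort_config <- function(...) {
  cfg <- list(
    n_patients = 101L,
    seed = 1L,
    epilepsy_fraction = 72 / 101,
    neonatal_fraction = 31 / 72,
    onset_meanlog = log(2), onset_sdlog = 1.86,
    variant_mix = c(ptv_del = 0.53, missense = 0.44, inframe_indel = 0.03),
    ptv_spasm_window = c(5L, 6L), ptv_spasm_prob = 0.65,
    missense_persistence_window = c(10L, 24L),
    missense_persistence = 0.3,  # remission-hazard multiplier inside window
    remission_hazard = c(ptv_del = 0.09, missense = 0.05,
                         inframe_indel = 0.07),
    ## refractory subgroup that rarely remits; more frequent under missense
    intractable_prob = c(ptv_del = 0.22, missense = 0.50,
                         inframe_indel = 0.35),
    intractable_hazard_factor = 0.05,
    spasm_remission_boost = 8,
    relapse_prob = 0.015,        # per month, after a completed 12-month run
    active_level_range = c(2L, 4L),
    dropout_meanlog = log(72), dropout_sdlog = 0.9,
    obs_bounds = c(6L, 180L),
    asm_effects = list(
      phenobarbital  = list(sf_multiplier = 0.50, freedom = 1.0),
      levetiracetam  = list(sf_multiplier = 0.85, freedom = 1.2),
      topiramate     = list(sf_multiplier = 0.80, freedom = 1.3),
      vigabatrin     = list(sf_multiplier = 0.60, freedom = 1.5),
      acth           = list(sf_multiplier = 0.55, freedom = 1.0),
      clobazam       = list(sf_multiplier = 0.85, freedom = 2.5),
      ketogenic_diet = list(sf_multiplier = 0.90, freedom = 1.6)
    ),
    milestone_model = data.frame(
      milestone = c("head_control", "roll_over", "sit_unassisted", "grasp",
                    "walk", "walk_unassisted", "first_words",
                    "nonverbal_communication"),
      p_achieve = c(0.95, 0.90, 0.72, 0.85, 0.57, 0.45, 0.14, 0.95),
      meanlog = log(c(6.3, 7.6, 12, 10, 29, 32, 24, 18)),
      sdlog = c(0.7, 0.5, 0.5, 0.45, 0.5, 0.5, 0.6, 0.5),
      stringsAsFactors = FALSE
    ),
    ## neonatal-onset patients achieve motor/language milestones at roughly
    ## a third of the later-onset rate (e.g. independent walking 25% vs 68%)
    milestone_neonatal_prob_factor = 0.35,
    milestone_neonatal_delay = 1.8,   # multiplicative age delay
    milestone_epilepsy_prob_factor = 0.85,
    milestone_epilepsy_delay = 1.2,
    assessment_fraction = 0.45
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  abort_if(length(bad) > 0, "unknown cohort_config field(s): %s",
           paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "cohort_config")
}

validate_config <- function(cfg) {
  probs <- c(cfg$epilepsy_fraction, cfg$neonatal_fraction, cfg$ptv_spasm_prob,
             cfg$relapse_prob, cfg$variant_mix, cfg$remission_hazard,
             cfg$missense_persistence, cfg$assessment_fraction,
             cfg$intractable_prob)
  abort_if(any(probs < 0 | probs > 1),
           "cohort_config: all probabilities must lie in [0, 1]")
  abort_if(abs(sum(cfg$variant_mix) - 1) > 1e-9,
           "cohort_config: variant_mix must sum to 1 (got %.12f)",
           sum(cfg$variant_mix))
  abort_if(cfg$n_patients < 1, "cohort_config: n_patients must be >= 1")
  invisible(cfg)
}

HPO_SPASMS <- "HP:0012469"   # infantile spasms
HPO_FOCAL  <- "HP:0007359"   # focal-onset seizure

## One step of the mean-reverting SF chain.
sf_step <- function(prev, target) {
  delta <- target - prev
  p_up <- 0.5 * stats::plogis(1.8 * delta)
  p_dn <- 0.5 * stats::plogis(-1.8 * delta)
  u <- stats::runif(1)
  nxt <- prev + (u < p_up) - (u > 1 - p_dn)
  min(5L, max(0L, nxt))
}

sim_patient <- function(id, cfg) {
  obs_end <- as.integer(round_half_up(
    stats::rlnorm(1, cfg$dropout_meanlog, cfg$dropout_sdlog)))
  obs_end <- min(max(obs_end, cfg$obs_bounds[1]), cfg$obs_bounds[2])
  sex <- sample(c("male", "female"), 1)
  vclass <- sample(names(cfg$variant_mix), 1, prob = cfg$variant_mix)
  has_epi <- stats::runif(1) < cfg$epilepsy_fraction

  months <- seq_len(obs_end)
  sf <- integer(obs_end)
  spasm_sf <- integer(obs_end)
  focal_sf <- integer(obs_end)
  mult_track <- rep(1, obs_end)
  onset <- NA_integer_; remit_month <- NA_integer_
  spasm <- FALSE; intractable <- FALSE
  level <- NA_integer_
  exposures <- NULL

  if (has_epi) {
    onset <- if (stats::runif(1) < cfg$neonatal_fraction) 1L else {
      o <- 2L
      for (try in 1:50) {
        o <- as.integer(ceiling(stats::rlnorm(1, cfg$onset_meanlog,
                                              cfg$onset_sdlog)))
        if (o >= 2L) break
      }
      max(2L, o)
    }
    if (onset > obs_end) onset <- sample.int(obs_end, 1)
    level <- sample(seq(cfg$active_level_range[1], cfg$active_level_range[2]),
                    1)
    sw <- cfg$ptv_spasm_window
    spasm <- vclass == "ptv_del" && onset <= sw[2] &&
      stats::runif(1) < cfg$ptv_spasm_prob
    intractable <- !spasm && stats::runif(1) < cfg$intractable_prob[[vclass]]

    ## ASM exposure plan (drug, start, duration); clamped to the window later
    plan <- list(
      phenobarbital = c(if (onset <= 2) 0.75 else 0.2, onset + 1L,
                        sample(2:6, 1)),
      levetiracetam = c(0.6, onset + 1L + sample(0:3, 1), sample(6:36, 1)),
      topiramate = c(0.3, onset + sample(3:12, 1), sample(6:24, 1)),
      vigabatrin = c(if (spasm) 0.7 else 0.05, max(sw[1], onset + 1L),
                     sample(3:12, 1)),
      acth = c(if (spasm) 0.5 else 0.02, max(sw[1], onset + 1L),
               sample(1:3, 1)),
      clobazam = c(0.25, max(onset + 6L, 12L) + sample(0:12, 1),
                   sample(12:48, 1)),
      ketogenic_diet = c(0.15, 18L + sample(0:18, 1), sample(12:36, 1))
    )
    for (drug in names(plan)) {
      p <- plan[[drug]]
      if (stats::runif(1) < p[1]) {
        s <- max(as.integer(p[2]), 1L)
        e <- min(s + as.integer(p[3]) - 1L, obs_end)
        if (s <= obs_end)
          exposures <- rbind(exposures, data.frame(
            patient_id = id, drug = drug, start_month = s, end_month = e,
            stringsAsFactors = FALSE))
      }
    }
    active_drugs <- function(m) {
      if (is.null(exposures)) return(character())
      exposures$drug[exposures$start_month <= m & exposures$end_month >= m]
    }

    active <- TRUE
    run0 <- 0L      # length of current remission run
    chain_prev <- 0L
    pw <- cfg$missense_persistence_window
    for (m in onset:obs_end) {
      drugs <- active_drugs(m)
      eff <- cfg$asm_effects[drugs]
      mult <- if (length(eff)) min(vapply(eff, `[[`, 1, "sf_multiplier")) else 1
      freedom <- if (length(eff)) max(vapply(eff, `[[`, 1, "freedom")) else 1
      mult_track[m] <- mult

      if (active) {
        ## remission hazard, modulated by subgroup signatures and treatment
        hz <- cfg$remission_hazard[[vclass]]
        if (intractable) hz <- hz * cfg$intractable_hazard_factor
        if (spasm && m > sw[2]) hz <- hz * cfg$spasm_remission_boost
        if (vclass == "missense" && m >= pw[1] && m <= pw[2])
          hz <- hz * cfg$missense_persistence
        hz <- min(1, hz * freedom)
        if (m > onset && stats::runif(1) < hz) {
          active <- FALSE
          remit_month <- m
          run0 <- 1L
          next
        }
        target <- level * mult
        s <- if (m == onset) max(1L, as.integer(round_half_up(target)))
             else sf_step(chain_prev, target)
        chain_prev <- s
        if (spasm && m >= sw[1] && m <= sw[2]) {
          ## spasms ride on top of the baseline course as a sharp episodic
          ## peak in the window; the underlying chain state is untouched
          peak <- min(5L, max(0L, as.integer(round_half_up(
            sample(4:5, 1) * mult))))
          s <- max(s, peak)
          if (s > 0) spasm_sf[m] <- min(s, sample(3:5, 1))
        }
        sf[m] <- s
        if (vclass == "missense" && s > 0) focal_sf[m] <- s
      } else {
        ## remitted: stay at zero; relapse possible after a completed run
        run0 <- run0 + 1L
        if (run0 > 12L && stats::runif(1) < cfg$relapse_prob / freedom) {
          active <- TRUE
          chain_prev <- max(1L, sf_step(level, level))
          sf[m] <- chain_prev
        }
      }
    }
  }

  patient <- data.frame(
    patient_id = id, sex = sex, variant_class = vclass,
    variant_label = "", obs_start_month = 1L, obs_end_month = obs_end,
    has_epilepsy = has_epi, stringsAsFactors = FALSE)

  sz <- data.frame(patient_id = id, seizure_type = "overall",
                   month = months, sf = sf, unknown = FALSE, imputed = FALSE,
                   stringsAsFactors = FALSE)
  if (any(spasm_sf > 0))
    sz <- rbind(sz, data.frame(patient_id = id, seizure_type = HPO_SPASMS,
                               month = months[spasm_sf > 0],
                               sf = spasm_sf[spasm_sf > 0], unknown = FALSE,
                               imputed = FALSE, stringsAsFactors = FALSE))
  if (any(focal_sf > 0))
    sz <- rbind(sz, data.frame(patient_id = id, seizure_type = HPO_FOCAL,
                               month = months[focal_sf > 0],
                               sf = focal_sf[focal_sf > 0], unknown = FALSE,
                               imputed = FALSE, stringsAsFactors = FALSE))

  ## milestones, coupled to onset severity stratum
  mm <- cfg$milestone_model
  neon <- has_epi && !is.na(onset) && onset == 1L
  pf <- if (neon) cfg$milestone_neonatal_prob_factor
        else if (has_epi) cfg$milestone_epilepsy_prob_factor else 1
  df <- if (neon) cfg$milestone_neonatal_delay
        else if (has_epi) cfg$milestone_epilepsy_delay else 1
  true_age <- round_half_up(stats::rlnorm(nrow(mm), mm$meanlog, mm$sdlog) * df)
  true_age <- pmax(true_age, 1)
  would <- stats::runif(nrow(mm)) < mm$p_achieve * pf
  achieved <- would & true_age <= obs_end
  mil <- data.frame(
    patient_id = id, milestone = mm$milestone, achieved = achieved,
    age_achieved_months = ifelse(achieved, true_age, NA_real_),
    age_last_assessed_months = obs_end, stringsAsFactors = FALSE)

  ## standardized assessments for a subset of patients
  assess <- NULL
  if (stats::runif(1) < cfg$assessment_fraction) {
    sev <- if (neon) 0.55 else if (has_epi) 0.75 else 1
    n_exam <- sample(1:2, 1)
    ages <- sort(sample(seq(6, max(obs_end, 7)), n_exam))
    gmfm <- pmin(100, pmax(0, 100 * sev *
      stats::plogis((log(ages) - log(36)) / 0.8) +
      stats::rnorm(n_exam, 0, 5)))
    assess <- data.frame(patient_id = id, scale = "gmfm66is",
                         age_months = ages, value = round(gmfm, 1),
                         stringsAsFactors = FALSE)
    lvl <- min(5L, max(1L, as.integer(round_half_up(
      2 + 1.2 * has_epi + 1.3 * neon + stats::rnorm(1, 0, 0.9)))))
    assess <- rbind(assess, data.frame(
      patient_id = id, scale = "gmfcs_er", age_months = ages[n_exam],
      value = lvl, stringsAsFactors = FALSE))
  }

  list(patient = patient, seizures = sz, exposures = exposures,
       milestones = mil, assessments = assess,
       truth = data.frame(
         patient_id = id, has_epilepsy = has_epi, variant_class = vclass,
         onset_month = onset, spasm = spasm, intractable = intractable,
         active_level = if (is.na(level)) NA_integer_ else level,
         remission_month = remit_month, stringsAsFactors = FALSE),
       truth_mult = data.frame(patient_id = id, month = months,
                               multiplier = mult_track,
                               stringsAsFactors = FALSE),
       truth_milestones = data.frame(
         patient_id = id, milestone = mm$milestone, true_age = true_age,
         would_achieve = would, stringsAsFactors = FALSE))
}

#' Generate a synthetic seizure-frequency cohort
#'
#' Simulates a cohort under [cohort_config()] together with a ground-truth
#' record of every latent draw (true onset month, subgroup, spasm status,
#' remission month, per-patient-month applied drug multiplier, true
#' milestone ages). Identical `(config, seed)` yields an identical cohort.
#' The ground truth exists for parameter-recovery tests only; analysis
#' functions take the cohort alone.
#'
#' @param config a `cohort_config` object.
#' @return list with elements `cohort` (an `sf_cohort`) and `ground_truth`
#'   (list of data.frames: `patients`, `exposure_multiplier`, `milestones`).
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(n_patients = 20, seed = 42))
#' sim$cohort
generate_cohort <- function(config = cohort_config()) {
  validate_config(config)
  with_seed(config$seed, {
    ids <- sprintf("P%03d", seq_len(config$n_patients))
    sims <- lapply(ids, sim_patient, cfg = config)
    cohort <- sf_cohort(
      patients = do.call(rbind, lapply(sims, `[[`, "patient")),
      seizures = do.call(rbind, lapply(sims, `[[`, "seizures")),
      asm = do.call(rbind, lapply(sims, `[[`, "exposures")),
      milestones = do.call(rbind, lapply(sims, `[[`, "milestones")),
      assessments = do.call(rbind, lapply(sims, `[[`, "assessments")),
      provenance = list(source = "synthetic", seed = config$seed,
                        n_patients = config$n_patients))
    ground_truth <- list(
      patients = do.call(rbind, lapply(sims, `[[`, "truth")),
      exposure_multiplier = do.call(rbind, lapply(sims, `[[`, "truth_mult")),
      milestones = do.call(rbind, lapply(sims, `[[`, "truth_milestones")))
    list(cohort = cohort, ground_truth = ground_truth)
  })
}

#' Overwrite seizure courses with a known predictable/unpredictable split
#'
#' Replaces the overall seizure course of every epileptic patient with one
#' of two canonical patterns, for forecast-recovery experiments: a
#' configurable fraction receives an early-offset pattern (moderate
#' seizures resolving by month 7, all-zero afterwards), the remainder a
#' high-variance refractory pattern (random month-to-month SF with ongoing
#' seizures at month 12). Exactly `round(fraction * n)` patients are
#' assigned to the predictable arm, sampled without replacement. Per-type
#' series of modified patients are dropped. The true labels are returned.
#'
#' @param cohort an `sf_cohort`, typically from [generate_cohort()].
#' @param fraction_predictable fraction of epileptic patients given the
#'   predictable pattern, in `[0, 1]`.
#' @param seed integer seed for the assignment and pattern draws.
#' @return list with elements `cohort` and `truth` (data.frame
#'   `patient_id`, `predictable`).
#' @export
inject_predictability_structure <- function(cohort, fraction_predictable,
                                            seed = 1L) {
  abort_if(fraction_predictable < 0 || fraction_predictable > 1,
           "fraction_predictable must lie in [0, 1]")
  epi <- cohort$patients$patient_id[cohort$patients$has_epilepsy]
  abort_if(length(epi) == 0, "cohort has no epileptic patients")
  with_seed(seed, {
    n_pred <- round_half_up(fraction_predictable * length(epi))
    pred_ids <- sample(epi, n_pred)
    sz <- cohort$seizures
    sz <- sz[!(sz$patient_id %in% epi), , drop = FALSE]
    pat <- cohort$patients
    new_rows <- lapply(epi, function(id) {
      i <- match(id, pat$patient_id)
      ## ensure room to observe a post-first-year trajectory
      end <- max(pat$obs_end_month[i], 24L)
      pat$obs_end_month[i] <<- end
      months <- seq_len(end)
      if (id %in% pred_ids) {
        onset <- sample(1:4, 1)
        offset <- sample(max(onset + 1L, 5L):7L, 1)
        sf <- integer(end)
        sf[onset:(offset - 1L)] <- sample(2:4, offset - onset, replace = TRUE)
      } else {
        sf <- sample(0:5, end, replace = TRUE)
        if (sf[12] == 0L) sf[12] <- sample(1:5, 1)
        if (all(sf[1:11] == 0L)) sf[sample(1:11, 1)] <- sample(1:5, 1)
      }
      data.frame(patient_id = id, seizure_type = "overall", month = months,
                 sf = sf, unknown = FALSE, imputed = FALSE,
                 stringsAsFactors = FALSE)
    })
    cohort$patients <- pat
    cohort$seizures <- canonical_seizures(rbind(sz, do.call(rbind, new_rows)))
    cohort$provenance$predictability_injection <- list(
      fraction = fraction_predictable, seed = seed)
    validate_cohort(cohort)
    list(cohort = cohort,
         truth = data.frame(patient_id = epi,
                            predictable = epi %in% pred_ids,
                            stringsAsFactors = FALSE))
  })
}
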