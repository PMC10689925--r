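# 12-month series shorthand
fy <- function(...) c(...)

test_that("first-year distance matches hand computations and scale bounds", {
  a <- fy(0, 0, 3, 3, 0, 0, 0, 0, 0, 0, 0, 0)
  b <- fy(0, 0, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(first_year_distance(a, a), 0)
  expect_equal(first_year_distance(rep(5, 12), rep(0, 12)), 5)
  expect_equal(first_year_distance(a, b), 4 / 12)
  expect_error(first_year_distance(a[1:11], b), "length 12")
  expect_error(first_year_distance(replace(a, 1, NA), b), "complete")
})

test_that("the default metric is symmetric, zero-diagonal and obeys the triangle inequality", {
  set.seed(31)
  series <- replicate(8, sample(0:5, 12, replace = TRUE), simplify = FALSE)
  d <- outer(seq_along(series), seq_along(series),
             Vectorize(function(i, j)
               first_year_distance(series[[i]], series[[j]])))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("similarity_matrix restricts to complete first-year histories", {
  sf_list <- list(p1 = rep(1, 24), p2 = rep(2, 24), p3 = rep(0, 24),
                  short = rep(3, 8))  # censored inside the first year
  co <- toy_cohort(sf_list)
  d <- similarity_matrix(co)
  expect_setequal(rownames(d), c("p1", "p2", "p3"))
  expect_equal(d["p1", "p2"], 1)
  expect_equal(d["p2", "p3"], 2)
})

test_that("neighbour aggregation is the per-month rounded median", {
  # 3 references with SF {1, 2, 4} at month 14 under a k = 3 design
  sf_list <- list(
    tgt = c(rep(c(0, 1), 6), 0, 2),
    r1 = c(rep(c(0, 1), 6), 0, 1),
    r2 = c(rep(c(0, 1), 6), 0, 2),
    r3 = c(2, rep(c(1, 0), 5), 1, 0, 4),  # slightly farther: breaks the tie
    far = c(rep(5, 12), 5, 5))
  co <- toy_cohort(sf_list)
  fc <- forecast_sf(co, k = 3, n_perm = 200, seed = 1)
  expect_equal(fc$predicted["tgt", "14"], 2)  # median of {1,2,4}
  refs <- strsplit(fc$results$reference_ids[
    fc$results$patient_id == "tgt"], ";")[[1]]
  expect_setequal(refs, c("r1", "r2", "r3"))
  # even count: median of {1, 2} = 1.5 rounds half-up to 2
  fc2 <- forecast_sf(co, k = 2, n_perm = 200, seed = 1)
  expect_equal(fc2$predicted["tgt", "14"], 2)
})

test_that("a patient identical to its references has zero divergence and minimal p", {
  sf_list <- c(list(tgt = rep(c(2, 0), 12)),
               stats::setNames(replicate(10, rep(c(2, 0), 12),
                                         simplify = FALSE),
                               paste0("dup", 1:10)))
  co <- toy_cohort(sf_list)
  fc <- forecast_sf(co, k = 10, n_perm = 500, seed = 3)
  r <- fc$results[fc$results$patient_id == "tgt", ]
  expect_equal(r$divergence, 0)
  expect_equal(r$permutation_p, 1 / 501)   # add-one rule lower bound
  expect_true(r$better_than_chance)
})

test_that("permutation p is never zero and is reproducible under a fixed seed", {
  sim <- generate_cohort(cohort_config(n_patients = 30, seed = 13))
  fc1 <- forecast_sf(sim$cohort, n_perm = 300, seed = 5)
  fc2 <- forecast_sf(sim$cohort, n_perm = 300, seed = 5)
  expect_identical(fc1$results, fc2$results)
  expect_true(all(fc1$results$permutation_p > 0, na.rm = TRUE))
  expect_true(all(fc1$results$permutation_p <= 1, na.rm = TRUE))
})

test_that("Monte-Carlo permutation p matches exact enumeration on a 1-month horizon", {
  # single forecast month: the null divergence |U - observed| is exactly
  # enumerable over U in {0..5}
  sf_list <- c(list(tgt = c(rep(1, 12), 4)),
               stats::setNames(replicate(10, c(rep(1, 12), 1),
                                         simplify = FALSE),
                               paste0("r", 1:10)))
  co <- toy_cohort(sf_list)
  n_perm <- 4000
  fc <- forecast_sf(co, k = 10, n_perm = n_perm, seed = 7)
  r <- fc$results[fc$results$patient_id == "tgt", ]
  # predicted = 1, observed = 4, divergence = 3;
  # null: |U - 4| <= 3 for U in {1..5} -> exact probability 5/6
  p_exact <- mean(abs(0:5 - 4) <= r$divergence)
  expect_equal(p_exact, 5 / 6)
  mc_se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(r$permutation_p - p_exact), 3 * mc_se + 2 / n_perm)
})

test_that("fidelity partition applies the p-value and divergence rules", {
  sf_list <- c(list(tgt = rep(c(2, 0), 12)),
               stats::setNames(replicate(11, rep(c(2, 0), 12),
                                         simplify = FALSE),
                               paste0("dup", 1:11)))
  co <- toy_cohort(sf_list)
  fc <- forecast_sf(co, k = 10, n_perm = 400, seed = 2)
  pf <- partition_fidelity(fc, co)
  expect_true(all(pf$labels$fidelity == "high"))  # every forecast exact
  expect_equal(pf$n_low, 0)
  # force the p-rule: patients at or above alpha must be low fidelity
  fc$results$permutation_p[1] <- 0.5
  pf2 <- partition_fidelity(fc, co)
  expect_identical(pf2$labels$fidelity[1], "low")
})

test_that("an injected 0.68 predictable split is recovered as a 53/25 partition at n = 78", {
  sim <- generate_cohort(cohort_config(n_patients = 120, seed = 21,
                                       epilepsy_fraction = 0.70))
  epi_ids <- sim$cohort$patients$patient_id[sim$cohort$patients$has_epilepsy]
  # trim to the 78-patient analysis cohort before injecting the split
  expect_gte(length(epi_ids), 78)
  keep <- c(setdiff(sim$cohort$patients$patient_id, epi_ids),
            epi_ids[seq_len(78)])
  co <- sim$cohort
  for (tbl in c("patients", "seizures", "asm", "milestones", "assessments"))
    co[[tbl]] <- co[[tbl]][co[[tbl]]$patient_id %in% keep, ]
  inj <- inject_predictability_structure(co, 0.68, seed = 3)
  expect_equal(sum(inj$truth$predictable), 53)
  fc <- forecast_sf(inj$cohort, n_perm = 1000, seed = 4)
  lab <- partition_fidelity(fc, inj$cohort)$labels
  lab <- lab[lab$patient_id %in% inj$truth$patient_id, ]
  expect_lte(abs(sum(lab$fidelity == "high") - 53), 5)
  expect_lte(abs(sum(lab$fidelity == "low") - 25), 5)
})

test_that("ongoing seizures at month 12 raise the odds of low-fidelity membership", {
  sim <- generate_cohort(cohort_config(n_patients = 120, seed = 22))
  inj <- inject_predictability_structure(sim$cohort, 0.68, seed = 5)
  fc <- forecast_sf(inj$cohort, n_perm = 800, seed = 6)
  pf <- partition_fidelity(fc, inj$cohort)
  feats <- first_year_risk_features(inj$cohort, pf$labels)
  ongoing <- feats[feats$feature == "ongoing_m12", ]
  expect_gt(ongoing$or, 1)
  expect_lt(ongoing$p, 0.05)
  offset7 <- feats[feats$feature == "offset_by_7", ]
  expect_lt(offset7$or, 1)   # early offset is protective
})

test_that("label shuffling centres risk-feature odds ratios at 1", {
  sim <- generate_cohort(cohort_config(n_patients = 100, seed = 23))
  inj <- inject_predictability_structure(sim$cohort, 0.6, seed = 7)
  fc <- forecast_sf(inj$cohort, n_perm = 400, seed = 8)
  labels <- partition_fidelity(fc, inj$cohort)$labels
  set.seed(9)
  log_ors <- replicate(30, {
    shuffled <- labels
    shuffled$fidelity <- sample(shuffled$fidelity)
    f <- first_year_risk_features(inj$cohort, shuffled)
    log(f$or[f$feature == "ongoing_m12"])
  })
  expect_lt(abs(mean(log_ors, na.rm = TRUE)), 0.35)
})
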