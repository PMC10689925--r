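mk <- function(x) stats::setNames(x, seq_along(x))

test_that("onset is the first nonzero month; neonatal is month 1", {
  expect_identical(detect_onset(mk(c(0, 0, 3, 2, 0))), 3L)
  expect_identical(detect_onset(mk(rep(0, 24))), NA_integer_)
  expect_identical(detect_onset(mk(c(2, 0, 1))), 1L)
  co <- toy_cohort(list(p1 = c(2, 0, 1), p2 = rep(0, 3)))
  ot <- onset_table(co)
  expect_true(ot$neonatal[ot$patient_id == "p1"])
  expect_true(is.na(ot$onset_month[ot$patient_id == "p2"]))
})

test_that("remission needs 12 consecutive zero months after onset", {
  r <- detect_remission(mk(c(3, 2, rep(0, 12))))
  expect_true(r$qualified)
  expect_identical(r$offset_month, 3L)
  r11 <- detect_remission(mk(c(3, rep(0, 11), 2, 1)))
  expect_false(isTRUE(r11$qualified))
  # first qualifying run wins; recurrence afterwards is visible separately
  r2 <- detect_remission(mk(c(4, rep(0, 12), 1, rep(0, 12))))
  expect_true(r2$qualified)
  expect_identical(r2$offset_month, 2L)
  expect_identical(r2$run_length, 12L)
  # run truncated by end of observation does not qualify
  tr <- detect_remission(mk(c(3, rep(0, 8))))
  expect_false(isTRUE(tr$qualified))
  expect_error(detect_remission(mk(c(1, 0)), min_run = 0), "min_run")
})

test_that("remission detection agrees with a brute-force run scan", {
  set.seed(42)
  for (i in 1:400) {
    len <- sample(13:60, 1)
    sf <- sample(0:5, len, replace = TRUE,
                 prob = c(0.55, 0.12, 0.1, 0.1, 0.08, 0.05))
    got <- detect_remission(mk(sf))
    want <- brute_remission(sf)
    if (is.null(want)) {
      expect_true(is.null(got) || !isTRUE(got$qualified))
    } else {
      expect_identical(got$offset_month, want$offset_month)
      expect_true(got$qualified)
    }
  }
})

test_that("alternative remission anchor reports the last seizure month", {
  r <- detect_remission(mk(c(3, 2, rep(0, 12))), anchor = "last_seizure_month")
  expect_identical(r$offset_month, 2L)
})

test_that("Kaplan-Meier quantiles follow the product-limit convention", {
  km <- km_fit(c(2, 2, 4, 10), rep(1, 4))
  q <- quantiles(km, c(0.25, 0.5, 0.75, 0.9))
  expect_equal(unname(q[["q50"]]), 2)   # S(2) = 0.5
  expect_equal(unname(q[["q75"]]), 4)
  expect_equal(unname(q[["q90"]]), 10)
  all_cens <- km_fit(c(5, 8, 9), c(0, 0, 0))
  expect_true(is.na(quantiles(all_cens, 0.5)[["q50"]]))
  mixed <- km_fit(c(3, 5), c(0, 1))     # S drops to 0 at 5
  expect_equal(unname(quantiles(mixed, 0.5)[["q50"]]), 5)
  expect_error(km_fit(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM quantiles are monotone in q and match empirical quantiles without censoring", {
  set.seed(7)
  for (i in 1:20) {
    ages <- sample(1:60, 25, replace = TRUE)
    km <- km_fit(ages, rep(1, length(ages)))
    q <- quantiles(km, c(0.25, 0.5, 0.75, 0.9))
    expect_true(all(diff(q[!is.na(q)]) >= 0))
    # with no censoring, the q-quantile is the smallest t with
    # empirical S(t) <= 1 - q, i.e. a type-1 empirical quantile
    # with no censoring the KM quantile (smallest t with S(t) <= 1 - q)
    # is the type-1 empirical quantile of the event ages
    for (qq in c(0.25, 0.5, 0.75))
      expect_equal(unname(quantiles(km, qq)),
                   as.numeric(quantile(ages, qq, type = 1)))
  }
})

test_that("log-rank separates distinct survival and is null on identical groups", {
  t1 <- c(2, 4, 6, 8, 10, 12)
  lr0 <- logrank(c(t1, t1), rep(1, 12), rep(c("a", "b"), each = 6))
  expect_lt(lr0$statistic, 1e-8)
  expect_equal(lr0$p, 1)
  early <- 1:10; late <- 41:50
  lr1 <- logrank(c(early, late), rep(1, 20), rep(c("a", "b"), each = 10))
  expect_lt(lr1$p, 0.001)
  expect_error(logrank(t1, rep(1, 6), rep("a", 6)), "two groups")
  expect_error(logrank(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("missense-like intractability yields a significant remission log-rank at n = 200/arm", {
  hits <- 0L
  for (seed in 1:5) {
    sim <- generate_cohort(cohort_config(
      n_patients = 400, seed = seed, epilepsy_fraction = 1,
      variant_mix = c(ptv_del = 0.5, missense = 0.5, inframe_indel = 0)))
    rt <- remission_table(sim$cohort)
    vc <- sim$cohort$patients$variant_class[
      match(rt$patient_id, sim$cohort$patients$patient_id)]
    lr <- logrank(rt$time, rt$event, vc)
    hits <- hits + (lr$p < 0.05)
  }
  expect_gte(hits, 5L * 0.9)
})

test_that("month-wise comparison flags sparse months and is null on identical groups", {
  co <- toy_cohort(list(a1 = c(2, 3, 1), a2 = c(2, 3, 1),
                        b1 = c(2, 3, 1), b2 = c(2, 3, 1)),
                   variant_class = c("ptv_del", "ptv_del",
                                     "missense", "missense"))
  mc <- monthly_group_comparison(co, months = 1:3)
  expect_true(all(mc$p == 1))
  co2 <- toy_cohort(list(a1 = c(2, 3), b1 = c(2, 3)),
                    variant_class = c("ptv_del", "missense"))
  mc2 <- monthly_group_comparison(co2, months = 1:2)
  expect_false(any(mc2$tested))
  expect_true(all(is.na(mc2$p)))
  expect_error(monthly_group_comparison(co, grouping = "nope"), "nope")
})

test_that("the spasm-window contrast is localized to months 5-6", {
  # configuration isolating the PTV spasm peak: subgroup dynamics otherwise
  # identical (equal remission hazards, equal intractability, persistence
  # effects outside the first year, treatment effects switched off)
  neutral <- lapply(cohort_config()$asm_effects, function(e)
    list(sf_multiplier = 1, freedom = 1))
  sim <- generate_cohort(cohort_config(
    n_patients = 260, seed = 6, epilepsy_fraction = 1,
    variant_mix = c(ptv_del = 0.5, missense = 0.5, inframe_indel = 0),
    remission_hazard = c(ptv_del = 0.05, missense = 0.05,
                         inframe_indel = 0.05),
    intractable_prob = c(ptv_del = 0.3, missense = 0.3, inframe_indel = 0.3),
    spasm_remission_boost = 1,
    missense_persistence_window = c(13L, 24L),
    ptv_spasm_prob = 0.8, asm_effects = neutral))
  mc <- monthly_group_comparison(sim$cohort, months = 1:12)
  expect_true(which.min(mc$p) %in% 5:6)
  expect_lt(min(mc$p, na.rm = TRUE), 0.05)
})
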