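test_that("patient-month response classes follow the SF transition rules", {
  s <- stats::setNames(c(0, 0, 3, 4, 2, 0, 0, 1), 1:8)
  expect_identical(classify_month(s, 2), "not_evaluable")   # pre-onset
  expect_identical(classify_month(s, 3), "unchanged_or_worse") # onset month
  expect_identical(classify_month(s, 4), "unchanged_or_worse") # 3 -> 4
  expect_identical(classify_month(s, 5), "reduced")            # 4 -> 2
  expect_identical(classify_month(s, 7), "freedom_maintained") # 0 -> 0
  expect_identical(classify_month(s, 8), "unchanged_or_worse") # 0 -> 1
  expect_error(classify_month(s, 1), "preceding month")
  # seizure-free patient: freedom months need a prior seizure history
  z <- stats::setNames(rep(0, 6), 1:6)
  expect_identical(classify_month(z, 4), "not_evaluable")
})

test_that("response classes partition the evaluable patient-months", {
  sim <- generate_cohort(cohort_config(n_patients = 40, seed = 14))
  mr <- month_response_table(sim$cohort)
  expect_true(all(mr$response %in% c("reduced", "unchanged_or_worse",
                                     "freedom_maintained", "not_evaluable")))
  p <- sim$cohort$patients
  expect_identical(nrow(mr),
                   sum(p$obs_end_month - p$obs_start_month))
})

test_that("fisher_or reproduces hand-computed odds ratios and corrections", {
  sym <- fisher_or(matrix(c(10, 10, 10, 10), 2))
  expect_equal(sym$or, 1)
  expect_equal(sym$p, 1)
  cp <- fisher_or(matrix(c(6, 2, 3, 9), 2, byrow = TRUE))
  expect_equal(cp$or, 9)                     # (6*9)/(2*3)
  expect_equal(cp$p, hyper_fisher_p(6, 2, 3, 9), tolerance = 1e-10)
  hc <- fisher_or(matrix(c(5, 0, 2, 7), 2, byrow = TRUE))
  expect_equal(hc$or, (5.5 * 7.5) / (0.5 * 2.5))  # 16.5 on corrected counts
  expect_error(fisher_or(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_or(matrix(c(1, -1, 2, 3), 2)), "nonnegative")
  expect_error(fisher_or(matrix(1, 3, 3)), "2x2")
})

test_that("the Woolf interval brackets the point estimate on the log scale", {
  set.seed(15)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 12), 2)
    if (sum(tab) == 0) next
    fo <- fisher_or(tab)
    expect_lt(fo$ci_low, fo$or + 1e-12)
    expect_gt(fo$ci_high, fo$or - 1e-12)
    expect_gt(fo$or, 0)
  }
})

test_that("drugs below the patient threshold are refused and screened out", {
  asm <- data.frame(patient_id = c("p1", "p2", "p3"),
                    drug = "rufinamide",
                    start_month = 2L, end_month = 5L)
  co <- toy_cohort(list(p1 = c(0, 3, 2, 2, 1, 0), p2 = c(1, 2, 2, 1, 0, 0),
                        p3 = c(0, 0, 4, 3, 3, 2)), asm = asm)
  expect_error(comparative_effectiveness(co, "rufinamide"),
               "below min_patients")
  eff <- comparative_effectiveness(co, "rufinamide", min_patients = 3)
  expect_s3_class(eff, "asm_effect")
  expect_identical(sum(eff$table), nrow(month_response_table(co)) -
                     sum(month_response_table(co)$response == "not_evaluable"))
})

test_that("an injected short-term drug effect is recovered as OR > 1 with CI excluding 1", {
  sim <- generate_cohort(cohort_config(n_patients = 300, seed = 16))
  eff <- comparative_effectiveness(sim$cohort, "phenobarbital",
                                   outcome = "short_term")
  expect_gt(eff$or, 1)
  expect_gt(eff$ci_low, 1)
  expect_lt(eff$p, 0.05)
})

test_that("a no-effect drug yields OR confidence intervals covering 1 in most replicates", {
  # the valid null is exchangeable exposure: a drug with no injected effect
  # assigned over random patient-month intervals (the generator's clinical
  # drugs start near onset, so their exposure label is confounded with
  # disease phase even when their effect is switched off)
  covered <- vapply(1:25, function(seed) {
    sim <- generate_cohort(cohort_config(n_patients = 70, seed = 100 + seed))
    co <- sim$cohort
    set.seed(seed)
    takers <- sample(co$patients$patient_id, 30)
    ends <- co$patients$obs_end_month[match(takers, co$patients$patient_id)]
    start <- vapply(ends, function(e) sample.int(max(e - 6L, 1L), 1),
                    integer(1))
    co$asm <- rbind(co$asm, data.frame(
      patient_id = takers, drug = "placebo", start_month = start,
      end_month = pmin(start + sample(3:24, 30, replace = TRUE), ends)))
    eff <- comparative_effectiveness(co, "placebo", outcome = "short_term",
                                     min_patients = 5, ci = "bootstrap",
                                     n_boot = 300, boot_seed = seed)
    eff$ci_low <= 1 && eff$ci_high >= 1
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("time-locked response recovers the injected reduction scale", {
  sim <- generate_cohort(cohort_config(n_patients = 200, seed = 17))
  tl <- time_locked_response(sim$cohort, "any", horizon = 8)
  # the generator's strongest early drugs halve the drift target: by five
  # months after initiation the cohort mean reduction should be around 50%
  late <- tl$curve$reduction[tl$curve$months_after %in% 4:6]
  expect_gt(mean(late), 0.3)
  expect_true(all(diff(tl$curve$reduction[1:5]) > -0.15)) # broadly monotone
})

test_that("without injected effects the time-locked curve stays near zero", {
  neutral <- lapply(cohort_config()$asm_effects, function(e)
    list(sf_multiplier = 1, freedom = 1))
  sim <- generate_cohort(cohort_config(n_patients = 200, seed = 18,
                                       asm_effects = neutral))
  tl <- time_locked_response(sim$cohort, "any", horizon = 6)
  expect_lt(max(abs(tl$curve$reduction[tl$curve$months_after <= 3])), 0.25)
})

test_that("spasm patients mostly reach spasm offset within a few months of treatment", {
  sim <- generate_cohort(cohort_config(n_patients = 250, seed = 19))
  tl <- time_locked_response(sim$cohort, "any", horizon = 6)
  expect_false(is.null(tl$spasm_offset))
  expect_gte(tl$spasm_offset$fraction_offset[
    tl$spasm_offset$months_after == 3][1], 0.5)
})
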