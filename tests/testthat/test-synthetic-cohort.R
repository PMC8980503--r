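test_that("generation is deterministic for a fixed seed", {
  spec <- cohort_spec(n = 60, seed = 123)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  # and byte-for-byte after serialization
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("with zero effects and vanishing noise, outcomes equal the baseline", {
  spec <- cohort_spec(n = 50, seed = 5,
                      noise_sd = stats::setNames(rep(1e-9, 10), outcome_names()))
  ch <- generate_cohort(spec)
  base <- baseline_outcomes(ch, spec)
  ranges <- list(eq5d_utility = c(-0.285, 1), dass_depression = c(0, 42),
                 dass_anxiety = c(0, 42), dass_stress = c(0, 42),
                 mpai_ability = c(0, 48), mpai_adjustment = c(0, 30),
                 mpai_participation = c(0, 30), sprs_occupational = c(0, 16),
                 sprs_interpersonal = c(0, 16), sprs_independent = c(0, 16))
  for (oc in outcome_names()) {
    clipped <- pmin(pmax(base[, oc], ranges[[oc]][1]), ranges[[oc]][2])
    # equality up to the instrument's response grid (rounding can tip either
    # way when a baseline sits exactly on a grid boundary)
    grid_half <- if (oc == "eq5d_utility") 5e-4 else
      if (startsWith(oc, "dass")) 1 else 0.5
    expect_true(all(abs(ch[[oc]] - unname(clipped)) <= grid_half + 1e-6))
  }
})

test_that("service-use marginals match their calibration targets", {
  ch <- generate_cohort(cohort_spec(n = 5000, seed = 77))
  expect_identical(median(ch$op_medical), 2)
  expect_identical(median(ch$op_nursing), 0)
  expect_identical(median(ch$op_allied), 3)
  expect_identical(median(ch$medical_acute), 1)
  expect_lt(abs(mean(ch$rehosp > 0) - 0.27), 0.03)
  expect_lt(abs(mean(ch$trans_rehab) - 0.83), 0.02)
  expect_lt(abs(mean(ch$gender == "male") - 0.71), 0.02)
  expect_lt(abs(median(ch$fim_motor) - 90), 1.5)
})

test_that("outpatient allied-health median is stable near 3 across seeds", {
  meds <- vapply(1:60, function(s)
    median(generate_cohort(cohort_spec(n = 41, seed = 500 + s))$op_allied),
    numeric(1))
  expect_lt(abs(median(meds) - 3), 1)
})

test_that("an injected effect is recovered by a covariate-adjusted oracle", {
  spec <- cohort_spec(n = 2000, seed = 31,
                      true_effects = list(trans_rehab = c(dass_depression = -6)),
                      baseline_intercepts = c(dass_depression = 21),
                      noise_sd = c(dass_depression = 1))
  ch <- generate_cohort(spec)
  fit <- stats::lm(dass_depression ~ trans_rehab + fim_motor + irsad +
                     marital + unmet_need + sos_treatment, data = ch)
  expect_lt(abs(stats::coef(fit)[["trans_rehab"]] - (-6)), 0.5)
})

test_that("all generated outcomes stay inside instrument ranges", {
  set.seed(9)
  for (i in 1:3) {
    spec <- cohort_spec(n = 300, seed = 900 + i,
                        true_effects = list(trans_rehab = stats::setNames(
                          rep(-50, 10), outcome_names())),
                        noise_sd = stats::setNames(rep(30, 10), outcome_names()))
    ch <- generate_cohort(spec)
    expect_true(all(ch$eq5d_utility >= -0.285 & ch$eq5d_utility <= 1))
    for (oc in c("dass_depression", "dass_anxiety", "dass_stress"))
      expect_true(all(ch[[oc]] >= 0 & ch[[oc]] <= 42))
    expect_true(all(ch$mpai_ability >= 0 & ch$mpai_ability <= 48))
    for (oc in c("mpai_adjustment", "mpai_participation"))
      expect_true(all(ch[[oc]] >= 0 & ch[[oc]] <= 30))
    for (oc in c("sprs_occupational", "sprs_interpersonal", "sprs_independent"))
      expect_true(all(ch[[oc]] >= 0 & ch[[oc]] <= 16))
    expect_true(all(ch$op_medical >= 0 & ch$op_medical == round(ch$op_medical)))
    expect_true(all(ch$trans_rehab %in% 0:1))
  }
})

test_that("missing-at-random blanking honors its rates and conditioning", {
  spec0 <- cohort_spec(n = 200, seed = 1)
  ch <- generate_cohort(spec0)
  # no rules: identity
  expect_identical(inject_missingness(ch, spec0), ch)
  # rate 0.2 on one outcome at n=1000: binomial 99% interval
  spec1 <- cohort_spec(n = 1000, seed = 2, missing_rates = list(
    list(var = "dass_anxiety", by = "age", rates = c(low = 0.2, high = 0.2))))
  g <- inject_missingness(generate_cohort(spec1), spec1)
  frac <- mean(is.na(g$dass_anxiety))
  expect_gt(frac, 0.16); expect_lt(frac, 0.24)
  # conditioning on gender with rate 0 for females: no female blanks
  spec2 <- cohort_spec(n = 800, seed = 3, missing_rates = list(
    list(var = "eq5d_utility", by = "gender",
         rates = c(male = 0.3, female = 0))))
  g2 <- inject_missingness(generate_cohort(spec2), spec2)
  expect_false(anyNA(g2$eq5d_utility[g2$gender == "female"]))
  expect_gt(mean(is.na(g2$eq5d_utility[g2$gender == "male"])), 0.2)
})

test_that("invalid missingness configurations are rejected", {
  expect_error(cohort_spec(missing_rates = list(
    list(var = "trans_rehab", by = "age", rates = c(low = .1, high = .1)))),
    "never blanked")
  expect_error(cohort_spec(missing_rates = list(
    list(var = "funding", by = "dass_stress", rates = c(low = .1, high = 0)),
    list(var = "dass_stress", by = "age", rates = c(low = .1, high = 0)))),
    "configuration error")
  expect_error(cohort_spec(missing_rates = list(
    list(var = "funding", by = "age", rates = c(low = 1.2, high = 0)))),
    "\\[0, 1\\]")
})

test_that("spec validation names the offending field", {
  expect_error(cohort_spec(n = 0), "n_participants")
  expect_error(cohort_spec(noise_sd = c(dass_depression = 0)), "noise_sd")
  expect_error(cohort_spec(noise_sd = c(nonsense = 2)), "nonsense")
  expect_error(cohort_spec(attendance_prob = 1.4), "attendance_prob")
  expect_error(cohort_spec(true_effects = list(shoe_size = c(dass_stress = 1))),
               "shoe_size")
})

test_that("item responses hit the degenerate consistency cases", {
  spec <- cohort_spec(n = 400, seed = 21)
  def <- scale_registry()$dass_depression
  perfect <- generate_item_responses(spec, def, loading = 1)
  expect_true(all(perfect == perfect[, 1]))
  expect_equal(cronbach_alpha(perfect), 1, tolerance = 1e-12)
  indep <- generate_item_responses(spec, def, loading = 0)
  expect_lt(abs(cronbach_alpha(indep)), 0.15)
  expect_true(all(indep >= def$rating_min & indep <= def$rating_max))
})

test_that("cohorts round-trip through the delimited file and sidecar", {
  spec <- cohort_spec(n = 30, seed = 8, missing_rates = list(
    list(var = "funding", by = "age", rates = c(low = 0.2, high = 0.2))))
  ch <- inject_missingness(generate_cohort(spec), spec)
  path <- tempfile(fileext = ".csv")
  write_cohort(ch, path)
  back <- read_cohort(path)
  for (v in names(ch)) expect_equal(back[[v]], ch[[v]])
  expect_true(is.factor(back$gender))
  expect_identical(levels(back$marital), levels(ch$marital))
  echo <- attr(back, "spec")
  expect_equal(echo$n, 30)
  expect_equal(echo$seed, 8)
  expect_equal(echo$attendance_prob, 0.83)
})
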