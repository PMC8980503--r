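test_that("service-use counts discretize at the printed cut rules", {
  specs <- default_treatment_specs()
  expect_identical(discretize_service_use(c(0, 1, 2, 7), specs$op_medical),
                   c(0L, 0L, 1L, 1L))
  expect_identical(discretize_service_use(c(0, 1), specs$op_nursing),
                   c(0L, 1L))
  expect_identical(discretize_service_use(c(1, 2), specs$op_allied),
                   c(0L, 1L))
  expect_identical(discretize_service_use(2, specs$rehosp), 1L)
  expect_identical(discretize_service_use(c(0, 1), specs$trans_rehab),
                   c(0L, 1L))
  expect_error(discretize_service_use(-1, specs$rehosp), "non-negative")
})

test_that("first-quartile cuts behave and match the printed grouping", {
  expect_equal(first_quartile_cut(rep(0, 20)), 0)
  x <- c(0, 1, 1, 1, 2, 2, 3, 4, 4, 6, 8, 9)
  expect_identical(first_quartile_cut(x), first_quartile_cut(sample(x)))
  # lower quartile 1 implies the treated group starts at 2 contacts
  counts <- c(1, 1, 1, 2, 2, 3, 4, 4, 5, 6, 10, 1)
  q1 <- first_quartile_cut(counts)
  expect_equal(floor(q1) + 1, 2)
  expect_error(first_quartile_cut(c(1, 2, 3)), "at least 4")
})

test_that("hand-built posteriors give exact counterfactual effects", {
  schema <- list(z = list(type = "categorical", levels = c("0", "1")),
                 x = list(type = "continuous"))
  X <- data.frame(z = factor(c("0", "1", "1"), levels = c("0", "1")),
                  x = c(-1, 0, 3))
  # tree splits only on the treatment: 1 if control, 3 if treated
  fit <- hand_fit(list(list(stump_binary_factor(0, 1, 3))), schema)
  ites <- individual_treatment_effects(fit, X, "z")
  expect_true(all(ites$tau == 2))
  # posterior that never splits on the treatment: all effects exactly zero
  fit0 <- hand_fit(list(list(stump_continuous(1, 0, -5, 5))), schema)
  ites0 <- individual_treatment_effects(fit0, X, "z")
  expect_true(all(ites0$tau == 0))
  expect_error(individual_treatment_effects(fit, X, "w"), "not in the model")
})

test_that("ATE draws conserve the mean of ITE draws and negate under label swap", {
  ch <- generate_cohort(cohort_spec(
    n = 120, seed = 6, true_effects = list(medical_acute = c(dass_stress = -4)),
    baseline_intercepts = c(dass_stress = 20)))
  X <- model_frame(ch)
  fit <- bart(X, ch$dass_stress, tiny_bart(), seed = 3)
  ites <- individual_treatment_effects(fit, X, "medical_acute")
  ate <- average_treatment_effect(ites)
  expect_identical(ate, rowMeans(ites$tau))
  # independent recomputation through the two counterfactual predictions
  X1 <- X; X1$medical_acute <- factor("1", levels = c("0", "1"))
  X0 <- X; X0$medical_acute <- factor("0", levels = c("0", "1"))
  expect_equal(ate, rowMeans(predict(fit, X1)) - rowMeans(predict(fit, X0)),
               tolerance = 1e-12)
  # swapping treated/control labels negates every draw exactly
  swapped <- individual_treatment_effects(fit, X, "medical_acute",
                                          treated_level = "0")
  expect_identical(swapped$tau, -ites$tau)
})

test_that("subgroup CATEs aggregate consistently", {
  ch <- generate_cohort(cohort_spec(n = 90, seed = 14))
  X <- model_frame(ch)
  fit <- bart(X, ch$sprs_independent, tiny_bart(), seed = 5)
  ites <- individual_treatment_effects(fit, X, "rehosp")
  all_mask <- rep(TRUE, nrow(X))
  expect_identical(conditional_ate(ites, all_mask),
                   average_treatment_effect(ites))
  m1 <- X$gender == "male"
  n1 <- sum(m1); n0 <- sum(!m1)
  combined <- (n1 * conditional_ate(ites, m1) +
                 n0 * conditional_ate(ites, !m1)) / (n1 + n0)
  expect_equal(combined, average_treatment_effect(ites), tolerance = 1e-12)
  expect_error(conditional_ate(ites, rep(FALSE, nrow(X))), "empty subgroup")
})

test_that("effect summaries report intervals, probabilities and the flag", {
  neg <- list(-abs(rnorm(500)) - 0.1)
  s <- summarize_effect(neg, direction = "lower_is_better")
  expect_equal(s$prob_beneficial, 1)
  expect_true(s$evidence)
  set.seed(2)
  sym <- list(rnorm(20000))
  s2 <- summarize_effect(sym, direction = "lower_is_better")
  expect_lt(abs(s2$prob_beneficial - 0.5), 0.02)
  expect_false(s2$evidence)
  expect_lt(s2$ci66[1], 0); expect_gt(s2$ci66[2], 0)
  # 66% interval nests inside the 95% interval
  expect_gte(s2$ci66[1], s2$ci95[1]); expect_lte(s2$ci66[2], s2$ci95[2])
  # identical imputations: both pooling modes agree
  d <- rnorm(300)
  five <- rep(list(d), 5)
  sa <- summarize_effect(five, "pool_draws", "higher_is_better")
  sb <- summarize_effect(five, "average_summaries", "higher_is_better")
  expect_equal(sa$ate_mean, sb$ate_mean, tolerance = 1e-12)
  expect_equal(sa$ci66, sb$ci66, tolerance = 1e-12)
  expect_equal(sa$ci95, sb$ci95, tolerance = 1e-12)
  expect_error(summarize_effect(neg, direction = "sideways"))
})

test_that("constant individual effects yield zero CATE differences, no flags", {
  tau <- matrix(1.5, nrow = 40, ncol = 30)
  ites <- structure(list(tau = tau, treatment = "trans_rehab"),
                    class = "ite_draws")
  data <- data.frame(marital = factor(rep(c("married", "never_married"), 15)),
                     age = rnorm(30))
  scr <- heterogeneity_screen(ites, data, c("marital", "age"))
  expect_true(all(scr$mean_diff == 0))
  expect_false(any(scr$flagged))
})

test_that("an injected subgroup effect orders the subgroup CATEs correctly", {
  spec <- cohort_spec(
    n = 600, seed = 26,
    true_effects = list(trans_rehab = c(dass_depression = -2)),
    heterogeneity = list(list(treatment = "trans_rehab",
                              outcome = "dass_depression",
                              moderator = "marital", level = "married",
                              extra = -6)),
    baseline_intercepts = c(dass_depression = 21),
    noise_sd = c(dass_depression = 6))
  ch <- generate_cohort(spec)
  X <- model_frame(ch)
  fit <- bart(X, ch$dass_depression, bart_fast_profile(), seed = 27)
  ites <- individual_treatment_effects(fit, X, "trans_rehab")
  cate_married <- mean(conditional_ate(ites, X$marital == "married"))
  cate_other <- mean(conditional_ate(ites, X$marital != "married"))
  expect_lt(cate_married, cate_other)
  # single-level moderators are skipped with a notice
  one_level <- data.frame(only = factor(rep("a", nrow(X))))
  expect_message(heterogeneity_screen(ites, one_level, "only"), "skipped")
})
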