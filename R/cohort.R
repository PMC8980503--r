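#' Specification for a synthetic post-discharge ABI cohort
#'
#' Defines the generative model for a synthetic acquired-brain-injury cohort:
#' covariate marginals (age, gender, marital status, employment, length of
#' stay, injury type, comorbidities, funding, residence, IRSAD decile, FIM
#' motor, unmet need, service-obstacle scores), over-dispersed negative
#' binomial service-contact counts, transitional-rehabilitation attendance,
#' outcome baselines on each instrument's natural scale, injected additive
#' treatment effects (on the discretized treatment indicators), optional
#' treatment-by-moderator interactions, per-outcome residual noise, and
#' missing-at-random blanking rules. Defaults are calibrated to the marginal
#' summaries of a 6-month post-discharge rehabilitation cohort (n = 41,
#' median age 46, 71% male, 83% transitional-rehabilitation attendance,
#' outpatient-allied-health median 3 contacts, EQ-5D utility median 0.783,
#' and so on); the methods vignette records the calibration.
#'
#' @param n number of participants.
#' @param seed integer seed; every generation call is reproducible given it.
#' @param true_effects named list: `treatment -> named numeric of additive
#'   effects by outcome`, applied on the outcome's natural scale to the
#'   discretized treatment indicator. Default: no effects.
#' @param heterogeneity list of interaction triples, each a list with
#'   elements `treatment`, `outcome`, `moderator`, `level`, `extra`: the
#'   subgroup with `moderator == level` receives `extra` additional effect.
#' @param noise_sd named numeric of per-outcome residual standard deviations
#'   (natural scale); must be positive. Partial overrides allowed.
#' @param baseline_intercepts named numeric overriding per-outcome baseline
#'   intercepts (natural scale).
#' @param baseline_form `"linear"` (default) or `"threshold"`; the threshold
#'   form adds a step at FIM motor < 75 so that tree ensembles have signal a
#'   linear fit misses.
#' @param attendance_prob probability of transitional-rehabilitation
#'   attendance.
#' @param service_rate_params named list of `c(size, mu)` negative binomial
#'   parameters for the five count-valued service-use variables.
#' @param missing_rates list of MAR blanking rules, each a list with `var`
#'   (variable to blank), `by` (observed conditioning variable) and `rates`
#'   (named per-level probabilities for a categorical conditioner, or
#'   `c(low=, high=)` split at the median for a continuous one). Default: no
#'   missingness.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 41, seed = NULL, true_effects = list(),
                        heterogeneity = list(), noise_sd = NULL,
                        baseline_intercepts = NULL,
                        baseline_form = c("linear", "threshold"),
                        attendance_prob = 0.83,
                        service_rate_params = NULL,
                        missing_rates = list()) {
  baseline_form <- match.arg(baseline_form)
  if (n < 1) stop("invalid spec: n_participants must be >= 1")

  default_noise <- c(eq5d_utility = 0.12, dass_depression = 7,
                     dass_anxiety = 5, dass_stress = 6, mpai_ability = 6,
                     mpai_adjustment = 7, mpai_participation = 5.5,
                     sprs_occupational = 4, sprs_interpersonal = 4,
                     sprs_independent = 2.8)
  ns <- default_noise
  if (!is.null(noise_sd)) {
    bad <- setdiff(names(noise_sd), names(default_noise))
    if (length(bad)) stop("invalid spec: unknown outcome in noise_sd: ",
                          paste(bad, collapse = ", "))
    ns[names(noise_sd)] <- noise_sd
  }
  if (any(ns <= 0)) stop("invalid spec: noise_sd must be > 0 per outcome")

  default_intercepts <- c(eq5d_utility = 0.78, dass_depression = 10,
                          dass_anxiety = 5.5, dass_stress = 11,
                          mpai_ability = 13, mpai_adjustment = 11.5,
                          mpai_participation = 10.5, sprs_occupational = 7.5,
                          sprs_interpersonal = 12, sprs_independent = 12.5)
  ic <- default_intercepts
  if (!is.null(baseline_intercepts)) {
    bad <- setdiff(names(baseline_intercepts), names(default_intercepts))
    if (length(bad)) stop("invalid spec: unknown outcome in baseline_intercepts: ",
                          paste(bad, collapse = ", "))
    ic[names(baseline_intercepts)] <- baseline_intercepts
  }

  default_rates <- list(op_medical = c(size = 2, mu = 3),
                        op_nursing = c(size = 0.4, mu = 0.8),
                        op_allied = c(size = 0.55, mu = 6.5),
                        medical_acute = c(size = 0.9, mu = 1.3),
                        rehosp = c(size = 1.5, mu = 0.32))
  sr <- default_rates
  if (!is.null(service_rate_params)) {
    bad <- setdiff(names(service_rate_params), names(default_rates))
    if (length(bad)) stop("invalid spec: unknown service in service_rate_params: ",
                          paste(bad, collapse = ", "))
    sr[names(service_rate_params)] <- service_rate_params
  }
  for (nm in names(sr))
    if (any(sr[[nm]] <= 0)) stop("invalid spec: service_rate_params for ", nm,
                                 " must be positive")
  if (attendance_prob < 0 || attendance_prob > 1)
    stop("invalid spec: attendance_prob must be in [0, 1]")

  marginals <- list(
    gender = c(male = 0.71, female = 0.29),
    marital = c(married = 0.46, divorced = 0.17, never_married = 0.37),
    employment = c(employed = 0.68, unemployed = 0.10, student = 0.07,
                   home_duties = 0.07, retired = 0.08),
    injury_type = c(non_traumatic = 0.39, traumatic_severe = 0.61),
    funding = c(none = 0.42, niis = 0.34, other_government = 0.24),
    residence = c(private = 0.85, interim = 0.05, other_facility = 0.10)
  )
  for (nm in names(marginals)) {
    p <- marginals[[nm]]
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-6)
      stop("invalid spec: categorical probabilities for ", nm,
           " must be in [0,1] and sum to 1")
  }

  known_treatments <- c("op_medical", "op_nursing", "op_allied",
                        "medical_acute", "rehosp", "trans_rehab")
  for (tr in names(true_effects)) {
    if (!tr %in% known_treatments)
      stop("invalid spec: unknown treatment in true_effects: ", tr)
    bad <- setdiff(names(true_effects[[tr]]), names(default_noise))
    if (length(bad)) stop("invalid spec: unknown outcome in true_effects: ",
                          paste(bad, collapse = ", "))
  }
  for (h in heterogeneity) {
    need <- c("treatment", "outcome", "moderator", "level", "extra")
    if (!all(need %in% names(h)))
      stop("invalid spec: heterogeneity entries need fields ",
           paste(need, collapse = ", "))
  }
  for (mr in missing_rates) {
    if (!all(c("var", "by", "rates") %in% names(mr)))
      stop("invalid spec: missing_rates entries need var, by, rates")
    if (any(mr$rates < 0) || any(mr$rates > 1))
      stop("invalid spec: missing rates must be in [0, 1] for ", mr$var)
    if (identical(mr$var, "trans_rehab"))
      stop("invalid spec: the transitional-rehabilitation indicator is never blanked")
  }
  blanked <- vapply(missing_rates, `[[`, "", "var")
  for (mr in missing_rates)
    if (mr$by %in% blanked)
      stop("configuration error: conditioning variable '", mr$by,
           "' is itself subject to blanking")

  structure(list(n = as.integer(n), seed = seed,
                 covariate_marginals = marginals,
                 service_rate_params = sr, attendance_prob = attendance_prob,
                 true_effects = true_effects, heterogeneity = heterogeneity,
                 noise_sd = ns, baseline_intercepts = ic,
                 baseline_form = baseline_form,
                 missing_rates = missing_rates),
            class = "cohort_spec")
}

#' Names of the outcome columns
#' @return character vector of the 10 outcome score columns.
#' @export
outcome_names <- function() {
  c("eq5d_utility", "dass_depression", "dass_anxiety", "dass_stress",
    "mpai_ability", "mpai_adjustment", "mpai_participation",
    "sprs_occupational", "sprs_interpersonal", "sprs_independent")
}

#' Names of the predictor columns
#' @return character vector: 6 service-use variables then 15 covariates.
#' @export
predictor_names <- function() {
  c("op_medical", "op_nursing", "op_allied", "medical_acute", "rehosp",
    "trans_rehab", "age", "gender", "residence", "marital", "employment",
    "los", "injury_type", "comorbidities", "funding", "irsad", "fim_motor",
    "unmet_need", "sos_transport", "sos_finances", "sos_treatment")
}

# instrument range + rounding grid per outcome
outcome_ranges <- function() {
  list(eq5d_utility = list(min = -0.285, max = 1, grid = "utility"),
       dass_depression = list(min = 0, max = 42, grid = "even"),
       dass_anxiety = list(min = 0, max = 42, grid = "even"),
       dass_stress = list(min = 0, max = 42, grid = "even"),
       mpai_ability = list(min = 0, max = 48, grid = "integer"),
       mpai_adjustment = list(min = 0, max = 30, grid = "integer"),
       mpai_participation = list(min = 0, max = 30, grid = "integer"),
       sprs_occupational = list(min = 0, max = 16, grid = "integer"),
       sprs_interpersonal = list(min = 0, max = 16, grid = "integer"),
       sprs_independent = list(min = 0, max = 16, grid = "integer"))
}

# clip to instrument range then round to the instrument's response grid
# (utilities to 3 dp; DASS to even integers since subscale sums are doubled)
clip_round_outcome <- function(x, outcome) {
  r <- outcome_ranges()[[outcome]]
  x <- pmin(pmax(x, r$min), r$max)
  switch(r$grid,
         utility = round(x, 3),
         even = 2 * round(x / 2),
         integer = round(x))
}

#' Expected outcome baselines for a cohort's covariates
#'
#' The deterministic part of the outcome model, before treatment effects and
#' noise: linear in standardized age, FIM motor and IRSAD plus categorical
#' offsets (marital status, employment, unmet need, treatment-obstacle score),
#' with an optional step at FIM motor < 75 under the threshold form.
#' Coefficient signs follow the instruments' conventions (higher DASS/MPAI =
#' worse, higher utility/SPRS = better).
#'
#' @param covariates data.frame holding the covariate columns of a cohort.
#' @param spec the generating [cohort_spec()].
#' @return numeric matrix, rows = participants, columns = the 10 outcomes.
#' @export
baseline_outcomes <- function(covariates, spec) {
  zage <- (covariates$age - 44) / 20
  zfim <- (covariates$fim_motor - 85) / 10
  zirsad <- (covariates$irsad - 5.5) / 3
  married <- as.numeric(covariates$marital == "married")
  employed <- as.numeric(covariates$employment == "employed")
  unmet <- as.numeric(covariates$unmet_need == "yes")
  sos_c <- covariates$sos_treatment - 12
  ic <- spec$baseline_intercepts

  b <- cbind(
    eq5d_utility = ic[["eq5d_utility"]] + 0.03 * zfim + 0.01 * zirsad -
      0.02 * zage - 0.04 * unmet + 0.02 * married,
    dass_depression = ic[["dass_depression"]] - 1.5 * zfim - 0.8 * zirsad +
      2.5 * unmet - 1.5 * married + 0.15 * sos_c,
    dass_anxiety = ic[["dass_anxiety"]] - 1.0 * zfim - 0.5 * zirsad +
      2.0 * unmet + 0.12 * sos_c,
    dass_stress = ic[["dass_stress"]] - 1.2 * zfim + 2.0 * unmet -
      1.2 * married + 0.12 * sos_c,
    mpai_ability = ic[["mpai_ability"]] - 3.5 * zfim + 1.0 * zage,
    mpai_adjustment = ic[["mpai_adjustment"]] - 2.0 * zfim + 0.1 * sos_c,
    mpai_participation = ic[["mpai_participation"]] - 2.5 * zfim + 1.0 * zage,
    sprs_occupational = ic[["sprs_occupational"]] + 1.2 * zfim - 1.0 * zage +
      1.0 * employed,
    sprs_interpersonal = ic[["sprs_interpersonal"]] + 1.0 * zfim +
      0.8 * married,
    sprs_independent = ic[["sprs_independent"]] + 1.5 * zfim - 0.5 * zage
  )
  if (spec$baseline_form == "threshold") {
    step <- as.numeric(covariates$fim_motor < 75)
    worse <- c(eq5d_utility = -0.08, dass_depression = 5, dass_anxiety = 4,
               dass_stress = 4, mpai_ability = 5, mpai_adjustment = 5,
               mpai_participation = 4, sprs_occupational = -3,
               sprs_interpersonal = -3, sprs_independent = -2)
    b <- b + outer(step, worse[colnames(b)])
  }
  b
}

#' Generate a complete synthetic cohort
#'
#' Draws covariates and service-use counts from the spec's marginals, then
#' builds each outcome as `baseline(covariates) + sum_t effect(t) * z_t +
#' interaction terms + noise`, where `z_t` is the discretized treatment
#' indicator under the default first-quartile cut rules, finally clipping and
#' rounding to the instrument's range and response grid. No missing values are
#' produced; see [inject_missingness()].
#'
#' @param spec a [cohort_spec()].
#' @return a tibble of class `cohort_table`, one row per participant, with the
#'   21 predictor columns and 10 outcome columns; the generating spec is
#'   attached as attribute `"spec"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  m <- spec$covariate_marginals
  draw_cat <- function(p) factor(sample(names(p), n, replace = TRUE, prob = p),
                                 levels = names(p))

  covars <- tibble::tibble(
    age = pmin(pmax(round(stats::rnorm(n, 44, 20)), 18), 90),
    gender = draw_cat(m$gender),
    residence = draw_cat(m$residence),
    marital = draw_cat(m$marital),
    employment = draw_cat(m$employment),
    los = pmax(round(stats::rlnorm(n, log(47), 0.65)), 1),
    injury_type = draw_cat(m$injury_type),
    comorbidities = stats::rnbinom(n, size = 1.2, mu = 2.5),
    funding = draw_cat(m$funding),
    irsad = pmin(pmax(round(stats::rnorm(n, 6, 3.5)), 1), 10),
    fim_motor = pmax(91 - stats::rnbinom(n, size = 0.25, mu = 11), 13),
    unmet_need = factor(ifelse(stats::runif(n) < 0.10, "yes", "no"),
                        levels = c("no", "yes")),
    sos_transport = factor(ifelse(stats::runif(n) < 0.26, "agree", "disagree"),
                           levels = c("disagree", "agree")),
    sos_finances = factor(ifelse(stats::runif(n) < 0.50, "agree", "disagree"),
                          levels = c("disagree", "agree")),
    sos_treatment = pmin(pmax(round(stats::rnorm(n, 12, 5.5)), 4), 28)
  )

  sr <- spec$service_rate_params
  services <- tibble::tibble(
    op_medical = stats::rnbinom(n, size = sr$op_medical[["size"]],
                                mu = sr$op_medical[["mu"]]),
    op_nursing = stats::rnbinom(n, size = sr$op_nursing[["size"]],
                                mu = sr$op_nursing[["mu"]]),
    op_allied = stats::rnbinom(n, size = sr$op_allied[["size"]],
                               mu = sr$op_allied[["mu"]]),
    medical_acute = stats::rnbinom(n, size = sr$medical_acute[["size"]],
                                   mu = sr$medical_acute[["mu"]]),
    rehosp = stats::rnbinom(n, size = sr$rehosp[["size"]],
                            mu = sr$rehosp[["mu"]]),
    trans_rehab = as.integer(stats::runif(n) < spec$attendance_prob)
  )

  z <- vapply(default_treatment_specs(), function(ts)
    discretize_service_use(services[[ts$name]], ts), integer(n))
  colnames(z) <- names(default_treatment_specs())

  base <- baseline_outcomes(covars, spec)
  eff <- matrix(0, n, length(outcome_names()),
                dimnames = list(NULL, outcome_names()))
  for (tr in names(spec$true_effects))
    for (oc in names(spec$true_effects[[tr]]))
      eff[, oc] <- eff[, oc] + spec$true_effects[[tr]][[oc]] * z[, tr]
  for (h in spec$heterogeneity) {
    sub <- as.numeric(as.character(covars[[h$moderator]]) == h$level)
    eff[, h$outcome] <- eff[, h$outcome] + h$extra * z[, h$treatment] * sub
  }

  out <- sapply(outcome_names(), function(oc) {
    raw <- base[, oc] + eff[, oc] + stats::rnorm(n, 0, spec$noise_sd[[oc]])
    clip_round_outcome(raw, oc)
  })
  if (n == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, outcome_names()))

  cohort <- tibble::as_tibble(cbind(services, covars, tibble::as_tibble(out)))
  cohort <- cohort[, c(predictor_names(), outcome_names())]
  attr(cohort, "spec") <- spec
  class(cohort) <- c("cohort_table", class(cohort))
  cohort
}

#' Blank entries missing-at-random
#'
#' Blanks entries of the named variables with a probability that depends only
#' on the observed conditioning variable (MAR). For a categorical conditioner
#' the rates are per level; for a continuous conditioner, `c(low=, high=)`
#' split at the median. The transitional-rehabilitation indicator is never
#' blanked.
#'
#' @param cohort a complete `cohort_table`.
#' @param spec the [cohort_spec()] carrying `missing_rates`.
#' @return the cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (anyNA(cohort)) stop("cohort must be complete before blanking")
  if (!length(spec$missing_rates)) return(cohort)
  if (!is.null(spec$seed)) set.seed(spec$seed + 1L)
  n <- nrow(cohort)
  for (mr in spec$missing_rates) {
    cond <- cohort[[mr$by]]
    if (is.null(cond)) stop("conditioning variable not found: ", mr$by)
    if (is.numeric(cond)) {
      lev <- ifelse(cond <= stats::median(cond), "low", "high")
    } else {
      lev <- as.character(cond)
    }
    p <- mr$rates[lev]
    p[is.na(p)] <- 0
    blank <- stats::runif(n) < p
    col <- cohort[[mr$var]]
    col[blank] <- NA
    cohort[[mr$var]] <- col
  }
  cohort
}

#' Generate item-level instrument responses
#'
#' One-factor fixture generator for scoring and internal-consistency tests:
#' each participant has a latent trait; item ratings are a shared loading on
#' the trait plus unique noise, mapped onto the instrument's rating range and
#' rounded. With loading 1 all items are identical (alpha = 1); with loading 0
#' items are independent (alpha near 0); intermediate loadings approach a
#' target pairwise correlation of `loading^2` before discretization.
#'
#' @param spec a [cohort_spec()] (supplies `n` and `seed`).
#' @param instrument a [scale_definition()].
#' @param loading shared factor loading in `[0, 1]`.
#' @return numeric matrix `n x item_count`, columns `<scale>_item<k>`, all
#'   entries within the instrument's rating range.
#' @export
generate_item_responses <- function(spec, instrument, loading = 0.7) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(instrument, "scale_definition"))
  if (loading < 0 || loading > 1) stop("loading must be in [0, 1]")
  if (!is.null(spec$seed))  # instrument-specific sub-seed, still reproducible
    set.seed((spec$seed + sum(utf8ToInt(instrument$name))) %%
               .Machine$integer.max)
  n <- spec$n
  k <- instrument$item_count
  latent <- stats::rnorm(n)
  zz <- loading * matrix(latent, n, k) +
    sqrt(1 - loading^2) * matrix(stats::rnorm(n * k), n, k)
  mid <- (instrument$rating_min + instrument$rating_max) / 2
  width <- instrument$rating_max - instrument$rating_min
  ratings <- round(mid + zz * width / 4)
  ratings <- pmin(pmax(ratings, instrument$rating_min), instrument$rating_max)
  colnames(ratings) <- paste0(instrument$name, "_item", seq_len(k))
  ratings
}

#' Write a cohort and its spec sidecar
#'
#' The cohort is written as delimited text (CSV, header row, missing entries
#' as empty fields); the generating spec - including seed and injected true
#' effects - and the column types go to a JSON sidecar at `<path>.json` so the
#' file round-trips through [read_cohort()].
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  spec <- attr(cohort, "spec")
  sidecar <- list(
    spec = if (!is.null(spec)) unclass(spec) else NULL,
    columns = lapply(cohort, function(col)
      if (is.factor(col)) list(type = "factor", levels = levels(col))
      else list(type = class(col)[1]))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path CSV path; the `<path>.json` sidecar must sit beside it.
#' @return a `cohort_table` with factor levels restored and the spec echo
#'   attached as attribute `"spec"`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = FALSE)
    for (nm in names(sidecar$columns)) {
      info <- sidecar$columns[[nm]]
      if (identical(info$type, "factor"))
        df[[nm]] <- factor(df[[nm]], levels = unlist(info$levels))
    }
    spec <- sidecar$spec
  } else {
    spec <- NULL
  }
  out <- tibble::as_tibble(df)
  attr(out, "spec") <- spec
  class(out) <- c("cohort_table", class(out))
  out
}
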