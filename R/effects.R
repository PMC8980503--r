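#' Treatment discretization rule
#'
#' A service-use "treatment" is the raw contact count (or attendance flag)
#' dichotomized at a threshold: `z = 1` when `count >= threshold`.
#'
#' @param name treatment name.
#' @param threshold non-negative cut; counts at or above it are "treated".
#' @return object of class `treatment_spec`.
#' @export
treatment_spec <- function(name, threshold) {
  stopifnot(is.character(name), threshold >= 0)
  structure(list(name = name, threshold = threshold), class = "treatment_spec")
}

#' Default service-use cut rules
#'
#' The printed first-quartile-based groupings: outpatient medical < 2 vs >= 2
#' contacts; outpatient nursing 0 vs >= 1; outpatient allied health < 2 vs
#' >= 2; medical acute 0 vs >= 1; re-hospitalization 0 vs >= 1; transitional
#' rehabilitation did-not-attend vs attended.
#'
#' @return named list of [treatment_spec()] objects.
#' @export
default_treatment_specs <- function() {
  list(op_medical = treatment_spec("op_medical", 2),
       op_nursing = treatment_spec("op_nursing", 1),
       op_allied = treatment_spec("op_allied", 2),
       medical_acute = treatment_spec("medical_acute", 1),
       rehosp = treatment_spec("rehosp", 1),
       trans_rehab = treatment_spec("trans_rehab", 1))
}

#' Dichotomize service-use counts
#'
#' @param counts non-negative integer counts (or a 0/1 attendance flag).
#' @param spec a [treatment_spec()].
#' @return integer vector of 0/1 treatment indicators.
#' @export
discretize_service_use <- function(counts, spec) {
  stopifnot(inherits(spec, "treatment_spec"))
  if (any(is.na(counts))) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  as.integer(counts >= spec$threshold)
}

#' First-quartile of a count distribution
#'
#' The lower-quartile value (linear-interpolation quantile, R type 7) of a set
#' of service-use counts, for deriving dichotomization thresholds on new
#' cohorts; a count is then "treated" when it exceeds this quartile (threshold
#' `floor(q1) + 1`). The printed default cut rules override derived ones where
#' present.
#'
#' @param counts non-negative integer counts, at least 4 of them.
#' @return the first-quartile value.
#' @export
first_quartile_cut <- function(counts) {
  if (length(counts) < 4) stop("need at least 4 observations")
  if (any(counts < 0)) stop("counts must be non-negative")
  unname(stats::quantile(counts, 0.25, type = 7))
}

#' Counterfactual individual treatment effects
#'
#' For every participant, predicts the outcome with the treatment indicator
#' forced to 1 and to 0 (all other covariates untouched) at every retained
#' posterior state, and returns the elementwise differences
#' `tau_i = y_i(1) - y_i(0)`. States whose trees never split on the treatment
#' give exactly zero effects.
#'
#' @param posterior a fitted [bart()] model whose covariates include the
#'   treatment indicator.
#' @param X covariate data.frame matching the training schema.
#' @param treatment name of the treatment column in `X`.
#' @param treated_level for a factor treatment, the level counted as
#'   "treated" (default: the second level). Swapping the labels negates every
#'   effect draw exactly.
#' @return object of class `ite_draws`: `tau` (matrix, states x participants),
#'   `treatment`.
#' @export
individual_treatment_effects <- function(posterior, X, treatment,
                                         treated_level = NULL) {
  stopifnot(inherits(posterior, "bart_fit"))
  if (!treatment %in% names(posterior$schema))
    stop("treatment '", treatment, "' is not in the model schema")
  sch <- posterior$schema[[treatment]]
  X1 <- X; X0 <- X
  if (sch$type == "categorical") {
    if (length(sch$levels) != 2)
      stop("treatment '", treatment, "' must be binary")
    if (is.null(treated_level)) treated_level <- sch$levels[2]
    if (!treated_level %in% sch$levels)
      stop("treated_level must be one of: ", paste(sch$levels, collapse = ", "))
    control_level <- setdiff(sch$levels, treated_level)
    X1[[treatment]] <- factor(treated_level, levels = sch$levels)
    X0[[treatment]] <- factor(control_level, levels = sch$levels)
  } else {
    if (is.null(treated_level)) treated_level <- 1
    X1[[treatment]] <- treated_level
    X0[[treatment]] <- 1 - treated_level
  }
  tau <- predict(posterior, X1) - predict(posterior, X0)
  structure(list(tau = tau, treatment = treatment), class = "ite_draws")
}

#' Average treatment effect draws
#'
#' Per-state mean of the individual effects over all participants; by
#' construction each ATE draw is exactly the mean of that state's ITE draws.
#'
#' @param ites an `ite_draws`.
#' @return numeric vector, one ATE draw per retained state.
#' @export
average_treatment_effect <- function(ites) {
  stopifnot(inherits(ites, "ite_draws"))
  if (!length(ites$tau)) stop("empty draws")
  rowMeans(ites$tau)
}

#' Conditional average treatment effect draws
#'
#' Per-state mean of the individual effects over a subgroup.
#'
#' @param ites an `ite_draws`.
#' @param mask logical vector selecting at least one participant.
#' @return numeric vector of CATE draws.
#' @export
conditional_ate <- function(ites, mask) {
  stopifnot(inherits(ites, "ite_draws"), is.logical(mask),
            length(mask) == ncol(ites$tau))
  if (!any(mask)) stop("empty subgroup")
  rowMeans(ites$tau[, mask, drop = FALSE])
}

#' Beneficial direction of each outcome
#'
#' Lower DASS-21 and MPAI-4 scores are better; higher EQ-5D utility and
#' SPRS-2 scores are better.
#'
#' @return named character vector, `"lower_is_better"` / `"higher_is_better"`.
#' @export
outcome_directions <- function() {
  c(eq5d_utility = "higher_is_better",
    dass_depression = "lower_is_better", dass_anxiety = "lower_is_better",
    dass_stress = "lower_is_better", mpai_ability = "lower_is_better",
    mpai_adjustment = "lower_is_better", mpai_participation = "lower_is_better",
    sprs_occupational = "higher_is_better",
    sprs_interpersonal = "higher_is_better",
    sprs_independent = "higher_is_better")
}

#' Summarize ATE draws across imputations
#'
#' Pools the ATE posterior over the completed datasets and reports the
#' posterior mean, equal-tailed 66% and 95% credible intervals, the posterior
#' probability of the beneficial direction (fraction of pooled draws strictly
#' on the beneficial side of zero), and the "weak evidence" flag set when the
#' 66% interval excludes zero. Pooling `"pool_draws"` concatenates draws
#' across imputations before summarizing; `"average_summaries"` computes
#' per-imputation summaries and averages them.
#'
#' @param draws_by_imputation list of numeric ATE draw vectors, one per
#'   completed dataset (a single vector is accepted).
#' @param pooling `"pool_draws"` (default) or `"average_summaries"`.
#' @param direction `"lower_is_better"` or `"higher_is_better"`.
#' @return object of class `effect_summary`: `ate_mean`, `ci66`, `ci95`,
#'   `prob_beneficial`, `evidence`, `pooling`, `direction`.
#' @export
summarize_effect <- function(draws_by_imputation,
                             pooling = c("pool_draws", "average_summaries"),
                             direction = c("lower_is_better",
                                           "higher_is_better")) {
  pooling <- match.arg(pooling)
  direction <- match.arg(direction)
  if (is.numeric(draws_by_imputation))
    draws_by_imputation <- list(draws_by_imputation)
  if (!length(draws_by_imputation)) stop("need draws from at least one imputation")

  # inverse-ECDF quantiles (type 1): invariant under draw replication, so
  # pooling identical per-imputation draw sets reproduces their summary
  summarize_one <- function(d) {
    c(mean = mean(d),
      lo66 = unname(stats::quantile(d, 0.17, type = 1)),
      hi66 = unname(stats::quantile(d, 0.83, type = 1)),
      lo95 = unname(stats::quantile(d, 0.025, type = 1)),
      hi95 = unname(stats::quantile(d, 0.975, type = 1)))
  }
  if (pooling == "pool_draws") {
    s <- summarize_one(unlist(draws_by_imputation, use.names = FALSE))
  } else {
    per <- vapply(draws_by_imputation, summarize_one, numeric(5))
    s <- rowMeans(per)
  }
  pooled <- unlist(draws_by_imputation, use.names = FALSE)
  prob <- if (direction == "lower_is_better") mean(pooled < 0) else
    mean(pooled > 0)
  evidence <- s[["lo66"]] > 0 || s[["hi66"]] < 0
  structure(list(ate_mean = s[["mean"]],
                 ci66 = c(s[["lo66"]], s[["hi66"]]),
                 ci95 = c(s[["lo95"]], s[["hi95"]]),
                 prob_beneficial = prob, evidence = evidence,
                 pooling = pooling, direction = direction),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("ATE %.3f  66%% CI [%.3f, %.3f]  95%% CI [%.3f, %.3f]\n",
              x$ate_mean, x$ci66[1], x$ci66[2], x$ci95[1], x$ci95[2]))
  cat(sprintf("P(better outcome) = %.2f  [%s]%s\n", x$prob_beneficial,
              x$direction, if (x$evidence) "  * 66% CI excludes 0" else ""))
  invisible(x)
}

#' Screen candidate moderators for effect heterogeneity
#'
#' For each candidate moderator, forms subgroup CATE draws and the posterior
#' of the CATE difference between subgroups: for a factor, each level against
#' the rest; for a continuous moderator, above versus at-or-below the median
#' (screening only). A moderator is flagged when any difference's equal-tailed
#' 95% interval excludes zero. Moderators with a single observed level are
#' skipped with a message. Where nothing is flagged, effects are reported
#' averaged over the whole cohort (the ATE).
#'
#' @param ites an `ite_draws` (draws may be pooled across imputations).
#' @param data data.frame holding the moderator columns (same rows as the ITE
#'   matrix's columns).
#' @param moderators character vector of column names to screen.
#' @return data.frame with one row per (moderator, contrast): posterior mean
#'   difference, 95% interval, and `flagged`.
#' @export
heterogeneity_screen <- function(ites, data, moderators) {
  stopifnot(inherits(ites, "ite_draws"))
  rows <- list()
  for (mod in moderators) {
    col <- data[[mod]]
    if (is.null(col)) stop("moderator not found: ", mod)
    if (is.numeric(col)) {
      masks <- list(above_median = col > stats::median(col))
    } else {
      col <- as.factor(droplevels(as.factor(col)))
      if (nlevels(col) < 2) {
        message("moderator '", mod, "' has a single level; skipped")
        next
      }
      masks <- lapply(stats::setNames(levels(col), levels(col)),
                      function(l) col == l)
    }
    for (contrast in names(masks)) {
      mask <- masks[[contrast]]
      if (!any(mask) || all(mask)) next
      diff_draws <- conditional_ate(ites, mask) - conditional_ate(ites, !mask)
      lo <- unname(stats::quantile(diff_draws, 0.025))
      hi <- unname(stats::quantile(diff_draws, 0.975))
      rows[[length(rows) + 1]] <- data.frame(
        moderator = mod, contrast = contrast, mean_diff = mean(diff_draws),
        lo95 = lo, hi95 = hi, flagged = lo > 0 | hi < 0)
    }
  }
  if (!length(rows))
    return(data.frame(moderator = character(), contrast = character(),
                      mean_diff = numeric(), lo95 = numeric(),
                      hi95 = numeric(), flagged = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
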