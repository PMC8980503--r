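#' End-to-end analysis configuration
#'
#' Bundles every stage's settings for [run_analysis()]: the cohort source, the
#' outcomes and treatments to analyse, candidate heterogeneity moderators, the
#' imputation and BART sampler settings, the imputation pooling mode and the
#' master seed from which all stage seeds are derived deterministically.
#'
#' @param cohort a `cohort_table`, a path to a cohort CSV written by
#'   [write_cohort()], or a [cohort_spec()] to simulate from.
#' @param outcomes outcome columns to model (default: all 10).
#' @param treatments treatments to toggle (default: all 6; each is toggled one
#'   at a time while the others stay at their observed values).
#' @param moderators covariates screened for effect heterogeneity (default:
#'   the personal-factor, unmet-need and service-obstacle variables).
#' @param imputation an [imputation_config()].
#' @param bart a [bart_config()].
#' @param pooling `"pool_draws"` or `"average_summaries"`.
#' @param out_dir optional directory; when set, result tables, completed
#'   datasets, diagnostics and a run manifest are written there.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort, outcomes = outcome_names(),
                       treatments = names(default_treatment_specs()),
                       moderators = c("residence", "marital", "unmet_need",
                                      "sos_transport", "sos_finances",
                                      "sos_treatment"),
                       imputation = imputation_config(),
                       bart = bart_config(),
                       pooling = c("pool_draws", "average_summaries"),
                       out_dir = NULL, seed = 1) {
  pooling <- match.arg(pooling)
  stopifnot(all(outcomes %in% outcome_names()),
            all(treatments %in% names(default_treatment_specs())))
  structure(list(cohort = cohort, outcomes = outcomes, treatments = treatments,
                 moderators = moderators, imputation = imputation, bart = bart,
                 pooling = pooling, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

# deterministic stage seeds below 2^31, derived from the master seed
stage_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + 1000003 * index) %% 2147483647)
}

# replace raw service-use columns by two-level treatment indicator factors
discretize_treatments <- function(df, specs = default_treatment_specs()) {
  for (ts in specs)
    df[[ts$name]] <- factor(discretize_service_use(df[[ts$name]], ts),
                            levels = c(0, 1))
  df
}

#' Run the full analysis pipeline
#'
#' Simulates or loads the cohort, imputes missing entries by chained PMM,
#' discretizes the six service-use treatments at their cut rules, fits one
#' BART model per outcome and completed dataset (all 21 predictors in every
#' model), computes counterfactual individual treatment effects per treatment,
#' pools ATE draws over the completed datasets, screens the candidate
#' moderators for heterogeneity, and assembles the treatment x outcome effect
#' table. Fully deterministic for a fixed config.
#'
#' @param config a [run_config()].
#' @return object of class `rehabite_result`: `effects` (tibble, one row per
#'   treatment x outcome), `heterogeneity` (screen results with treatment and
#'   outcome columns), `summaries` (nested list of `effect_summary` objects),
#'   `manifest`, and `cohort` (the analysed table before imputation).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))

  # ---- cohort ----
  cohort <- config$cohort
  if (inherits(cohort, "cohort_spec")) {
    spec <- cohort
    if (is.null(spec$seed)) spec$seed <- stage_seed(config$seed, 1)
    cohort <- generate_cohort(spec)
    cohort <- inject_missingness(cohort, spec)
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  }
  missing_cols <- setdiff(c(predictor_names(), config$outcomes), names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(cohort), c(predictor_names(), outcome_names()))
  if (length(extra))
    stop("cohort has unrecognized column(s): ", paste(extra, collapse = ", "))

  # ---- imputation ----
  analysed <- cohort[, c(predictor_names(), config$outcomes)]
  if (anyNA(analysed)) {
    imp_config <- config$imputation
    if (is.null(imp_config$seed)) imp_config$seed <- stage_seed(config$seed, 2)
    stack <- run_chained_imputation(analysed, imp_config)
    completed <- stack$completed
  } else {
    stack <- NULL
    completed <- rep(list(tibble::as_tibble(analysed)),
                     config$imputation$m_datasets)
  }

  # ---- per-outcome BART fits and treatment effects ----
  directions <- outcome_directions()
  summaries <- list()
  het_rows <- list()
  effect_rows <- list()
  fits_sigma <- list()

  for (oi in seq_along(config$outcomes)) {
    oc <- config$outcomes[[oi]]
    ate_draws <- stats::setNames(
      rep(list(list()), length(config$treatments)), config$treatments)
    ite_pooled <- stats::setNames(
      vector("list", length(config$treatments)), config$treatments)

    for (mi in seq_along(completed)) {
      dat <- discretize_treatments(completed[[mi]])
      X <- as.data.frame(dat[, predictor_names()])
      y <- dat[[oc]]
      fit <- bart(X, y, config$bart,
                  seed = stage_seed(config$seed, 100 + oi * 10 + mi))
      fits_sigma[[paste(oc, mi, sep = ".")]] <- fit$sigma
      for (tr in config$treatments) {
        ites <- individual_treatment_effects(fit, X, tr)
        ate_draws[[tr]][[mi]] <- average_treatment_effect(ites)
        ite_pooled[[tr]] <- rbind(ite_pooled[[tr]], ites$tau)
      }
    }

    for (tr in config$treatments) {
      summ <- summarize_effect(ate_draws[[tr]], config$pooling,
                               directions[[oc]])
      summaries[[oc]][[tr]] <- summ
      effect_rows[[length(effect_rows) + 1]] <- tibble::tibble(
        treatment = tr, outcome = oc, ate_mean = summ$ate_mean,
        lo66 = summ$ci66[1], hi66 = summ$ci66[2],
        lo95 = summ$ci95[1], hi95 = summ$ci95[2],
        prob_beneficial = summ$prob_beneficial, evidence = summ$evidence,
        direction = summ$direction)

      ites_all <- structure(list(tau = ite_pooled[[tr]], treatment = tr),
                            class = "ite_draws")
      scr <- heterogeneity_screen(ites_all,
                                  discretize_treatments(completed[[1]]),
                                  config$moderators)
      if (nrow(scr)) {
        scr$treatment <- tr
        scr$outcome <- oc
        het_rows[[length(het_rows) + 1]] <- scr
      }
    }
  }

  effects <- do.call(rbind, effect_rows)
  heterogeneity <- if (length(het_rows)) do.call(rbind, het_rows) else
    data.frame()

  manifest <- list(
    package_version = as.character(utils::packageVersion("rehabite")),
    seed = config$seed, pooling = config$pooling,
    outcomes = config$outcomes, treatments = config$treatments,
    moderators = config$moderators,
    n_participants = nrow(cohort),
    m_datasets = length(completed),
    bart = unclass(config$bart)[c("n_trees", "alpha", "beta", "k", "nu", "q",
                                  "n_draws", "n_burn", "thin")],
    imputation = unclass(config$imputation)[c("m_datasets", "chain_iterations",
                                              "donor_pool_k")])

  result <- structure(list(effects = effects, heterogeneity = heterogeneity,
                           summaries = summaries, manifest = manifest,
                           cohort = cohort, imputed = stack,
                           sigma_traces = fits_sigma),
                      class = "rehabite_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(effects),
                     file.path(config$out_dir, "effects.csv"),
                     row.names = FALSE)
    if (nrow(heterogeneity))
      utils::write.csv(heterogeneity,
                       file.path(config$out_dir, "heterogeneity.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    for (mi in seq_along(completed))
      utils::write.csv(as.data.frame(completed[[mi]]),
                       file.path(config$out_dir,
                                 sprintf("completed_%d.csv", mi)),
                       row.names = FALSE, na = "")
  }
  result
}

#' @export
print.rehabite_result <- function(x, ...) {
  cat("rehabite analysis:", x$manifest$n_participants, "participants,",
      length(x$manifest$outcomes), "outcome(s) x",
      length(x$manifest$treatments), "treatment(s),",
      x$manifest$m_datasets, "completed dataset(s)\n\n")
  df <- as.data.frame(x$effects)
  df[] <- lapply(df, function(c) if (is.numeric(c)) signif(c, 3) else c)
  print(df, row.names = FALSE)
  flagged <- if (nrow(x$heterogeneity)) sum(x$heterogeneity$flagged) else 0
  cat("\nheterogeneity screen:", flagged, "flagged contrast(s)\n")
  invisible(x)
}

#' Simulate a cohort to disk
#'
#' Generates a cohort from the spec (with its missing-at-random gaps applied)
#' and writes the CSV plus the spec sidecar, so the ground truth travels with
#' the data.
#'
#' @param spec a [cohort_spec()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
simulate_cohort <- function(spec, path) {
  cohort <- generate_cohort(spec)
  cohort <- inject_missingness(cohort, spec)
  attr(cohort, "spec") <- spec
  write_cohort(cohort, path)
}
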