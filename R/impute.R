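#' Chained-equations imputation settings
#'
#' @param m_datasets number of completed datasets (default 5, the number over
#'   which downstream results are pooled).
#' @param chain_iterations sweeps of the variable cycle per dataset.
#' @param donor_pool_k size of the predictive-mean-matching donor pool.
#' @param seed integer seed.
#' @param variables_to_impute optional character vector restricting which
#'   variables are imputed; by default every variable with missing entries.
#' @return object of class `imputation_config`.
#' @export
imputation_config <- function(m_datasets = 5, chain_iterations = 10,
                              donor_pool_k = 5, seed = NULL,
                              variables_to_impute = NULL) {
  stopifnot(m_datasets >= 1, chain_iterations >= 1, donor_pool_k >= 1)
  structure(list(m_datasets = as.integer(m_datasets),
                 chain_iterations = as.integer(chain_iterations),
                 donor_pool_k = as.integer(donor_pool_k), seed = seed,
                 variables_to_impute = variables_to_impute),
            class = "imputation_config")
}

# numeric working copy of a data.frame for the imputation models: factors ->
# integer codes.  PMM's donor property guarantees imputed codes are observed
# codes, so factors always round-trip to legal levels.
numeric_coding <- function(df) {
  codes <- lapply(df, function(col) if (is.numeric(col)) col
                  else as.numeric(as.factor(col)))
  as.data.frame(codes)
}

#' Predictive-mean-matching imputation of one variable
#'
#' Fits a Bayesian linear model of the target on the predictors over the
#' observed cases (flat prior: sigma^2 drawn from the scaled inverse
#' chi-square residual posterior, coefficients from their conditional normal).
#' Observed cases are scored with the posterior-mean coefficients and missing
#' cases with the drawn coefficients; for each missing case the
#' `donor_pool_k` observed cases with nearest predicted values form the donor
#' pool and the imputed value is one donor's observed value, chosen uniformly.
#' Imputed values therefore always lie in the target's observed support.
#'
#' @param data data.frame; predictors must be complete.
#' @param target name of the variable with missing entries.
#' @param predictors character vector of predictor names.
#' @param donor_pool_k donor pool size.
#' @return numeric vector of imputed values, one per missing case (empty if
#'   none are missing), in row order of the missing cases.
#' @export
pmm_impute_variable <- function(data, target, predictors,
                                donor_pool_k = 5) {
  y <- data[[target]]
  is_fac <- is.factor(y)
  if (is_fac) y <- as.numeric(y)  # integer level codes; donors keep them legal
  mis <- is.na(y)
  if (!any(mis)) return(numeric(0))
  obs <- which(!mis)
  if (length(obs) < donor_pool_k)
    stop("only ", length(obs), " observed cases for '", target,
         "'; reduce donor_pool_k to at most that")
  yobs <- y[obs]
  if (length(unique(yobs)) == 1L) return(rep(yobs[1], sum(mis)))

  Xdf <- numeric_coding(data[predictors])
  if (anyNA(Xdf)) stop("predictors for '", target, "' must be complete")
  X <- cbind(1, as.matrix(Xdf))
  Xo <- X[obs, , drop = FALSE]

  qr_o <- qr(Xo)
  keep <- qr_o$pivot[seq_len(qr_o$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[mis, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, yobs)
  beta_hat <- fit$coefficients
  dfres <- max(length(obs) - fit$rank, 1)
  rss <- sum(fit$residuals^2)

  # posterior draw under a flat prior (proper imputation variability)
  sigma2_star <- max(rss, 1e-12) / stats::rchisq(1, dfres)
  XtX_inv <- chol2inv(qr.R(qr(Xo)))
  L <- chol(sigma2_star * XtX_inv + diag(1e-12, ncol(Xo)))
  beta_star <- beta_hat + drop(t(L) %*% stats::rnorm(ncol(Xo)))

  pred_obs <- drop(Xo %*% beta_hat)
  pred_mis <- drop(Xm %*% beta_star)

  vapply(pred_mis, function(pm) {
    d <- abs(pred_obs - pm)
    pool <- order(d)[seq_len(donor_pool_k)]
    yobs[pool[sample.int(donor_pool_k, 1)]]
  }, numeric(1))
}

#' Multiple imputation by chained equations with PMM draws
#'
#' Produces `m` completed copies of the cohort. Each copy starts by filling
#' missing entries with random draws from the variable's observed values, then
#' cycles through the incomplete variables for `chain_iterations` sweeps,
#' re-imputing each via [pmm_impute_variable()] with all other variables as
#' predictors. Chains are independent (distinct sub-seeds). Observed entries
#' are never touched, and by the PMM donor property every imputed value equals
#' some observed value of its variable.
#'
#' @param table a data.frame/`cohort_table`, possibly with missing entries.
#' @param config an [imputation_config()].
#' @return object of class `imputed_stack`: `completed` (list of `m` complete
#'   tables), `where` (logical matrix of imputed positions), `config`.
#' @export
run_chained_imputation <- function(table, config = imputation_config()) {
  stopifnot(inherits(config, "imputation_config"))
  df <- as.data.frame(table)
  where <- is.na(df)
  incomplete <- names(df)[colSums(where) > 0]
  if (!is.null(config$variables_to_impute)) {
    uncovered <- setdiff(incomplete, config$variables_to_impute)
    if (length(uncovered))
      stop("variable(s) with missing entries not listed for imputation: ",
           paste(uncovered, collapse = ", "))
    incomplete <- intersect(config$variables_to_impute, incomplete)
  }
  all_missing <- incomplete[colSums(!where[, incomplete, drop = FALSE]) == 0]
  if (length(all_missing))
    stop("variable(s) with every entry missing cannot be imputed: ",
         paste(all_missing, collapse = ", "))

  completed <- vector("list", config$m_datasets)
  for (chain in seq_len(config$m_datasets)) {
    if (!is.null(config$seed))
      set.seed((config$seed * 131L + chain) %% .Machine$integer.max)
    work <- df
    # initialize by random draws from observed values
    for (v in incomplete) {
      miss <- where[, v]
      obs_vals <- work[[v]][!miss]
      work[[v]][miss] <- sample(obs_vals, sum(miss), replace = TRUE)
    }
    for (it in seq_len(config$chain_iterations)) {
      for (v in incomplete) {
        miss <- where[, v]
        col <- work[[v]]
        col[miss] <- NA
        tmp <- work
        tmp[[v]] <- col
        preds <- setdiff(names(df), v)
        imp <- pmm_impute_variable(tmp, v, preds, config$donor_pool_k)
        if (is.factor(work[[v]])) {
          # imp holds integer level codes of observed donors
          work[[v]][miss] <- factor(levels(df[[v]])[imp],
                                    levels = levels(df[[v]]))
        } else {
          work[[v]][miss] <- imp
        }
      }
    }
    completed[[chain]] <- tibble::as_tibble(work)
  }
  structure(list(completed = completed, where = where, config = config),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("imputed_stack:", length(x$completed), "completed datasets,",
      sum(x$where), "imputed entries across",
      sum(colSums(x$where) > 0), "variable(s)\n")
  invisible(x)
}
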