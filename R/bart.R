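#' BART sampler configuration
#'
#' Hyperparameters and MCMC settings for the sum-of-trees sampler. Defaults
#' follow the canonical regularizing choices for BART with a reduced tree
#' count suitable for desk-scale cohorts: `n_trees = 50`, tree-prior base
#' `alpha = 0.95` and power `beta = 2` (so a node at depth d splits with prior
#' probability `alpha * (1 + d)^-beta`), leaf shrinkage `k = 2` (leaf values
#' have prior sd `0.5 / (k * sqrt(n_trees))` on the rescaled outcome), and a
#' scaled-inverse-chi-square noise prior with `nu = 3` degrees of freedom,
#' scaled so that the prior puts probability `q = 0.90` below the residual
#' scale of an ordinary linear fit.
#'
#' @param n_trees number of trees in the ensemble.
#' @param alpha,beta tree prior: split probability at depth d is
#'   `alpha * (1 + d)^-beta`; `alpha` in (0,1), `beta > 0`.
#' @param k leaf shrinkage; larger values shrink leaf values harder.
#' @param nu,q noise prior degrees of freedom and calibration quantile.
#' @param n_draws retained posterior draws (after burn-in and thinning).
#' @param n_burn burn-in iterations.
#' @param thin thinning interval.
#' @param proposal_probs named weights for the grow/prune/change tree moves;
#'   must be non-negative and sum to 1.
#' @param sigma_fixed optionally pin the noise sd (on the original outcome
#'   scale) instead of sampling it; used mainly for validation against
#'   closed-form conjugate posteriors.
#' @return an object of class `bart_config`.
#' @export
bart_config <- function(n_trees = 50, alpha = 0.95, beta = 2, k = 2,
                        nu = 3, q = 0.90, n_draws = 1000, n_burn = 1000,
                        thin = 1,
                        proposal_probs = c(grow = 0.25, prune = 0.25, change = 0.5),
                        sigma_fixed = NULL) {
  stopifnot(n_trees >= 1, alpha > 0, alpha < 1, beta > 0, k > 0, nu > 0,
            q > 0, q < 1, n_draws >= 1, n_burn >= 0, thin >= 1)
  pp <- proposal_probs[c("grow", "prune", "change")]
  if (anyNA(pp) || any(pp < 0) || abs(sum(pp) - 1) > 1e-8)
    stop("proposal_probs must be named grow/prune/change weights summing to 1")
  structure(list(n_trees = as.integer(n_trees), alpha = alpha, beta = beta,
                 k = k, nu = nu, q = q, n_draws = as.integer(n_draws),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 proposal_probs = pp, sigma_fixed = sigma_fixed),
            class = "bart_config")
}

#' Reduced-size sampler settings for simulation studies
#'
#' A lighter configuration (20 trees, 250 burn-in, 500 retained draws) used by
#' the package's own simulation experiments so that replicate studies complete
#' quickly while keeping posterior summaries stable enough for average
#' treatment effects.
#'
#' @param ... overrides passed on to [bart_config()].
#' @return a `bart_config`.
#' @export
bart_fast_profile <- function(...) {
  defaults <- list(n_trees = 20, n_burn = 250, n_draws = 500)
  args <- utils::modifyList(defaults, list(...))
  do.call(bart_config, args)
}

# Encode a covariate data.frame for the C++ sampler: numeric columns kept,
# factors/characters/logicals -> 0-based integer level codes.  Returns the
# matrix plus the schema needed to encode new data identically.
encode_covariates <- function(X, schema = NULL) {
  stopifnot(is.data.frame(X))
  if (anyNA(X))
    stop("covariates contain missing values; impute before fitting (see run_chained_imputation)")
  if (is.null(schema)) {
    schema <- lapply(X, function(col) {
      if (is.numeric(col)) {
        list(type = "continuous")
      } else {
        col <- as.factor(col)
        if (nlevels(col) > 52) stop("categorical covariate with more than 52 levels")
        list(type = "categorical", levels = levels(col))
      }
    })
  } else {
    missing_cols <- setdiff(names(schema), names(X))
    if (length(missing_cols))
      stop("newdata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  cols <- lapply(names(schema), function(nm) {
    col <- X[[nm]]
    sc <- schema[[nm]]
    if (sc$type == "continuous") {
      if (!is.numeric(col)) stop("column '", nm, "' must be numeric")
      as.numeric(col)
    } else {
      col <- as.character(col)
      code <- match(col, sc$levels) - 1L
      if (anyNA(code))
        stop("column '", nm, "' has level(s) not seen in training: ",
             paste(unique(col[is.na(code)]), collapse = ", "))
      as.numeric(code)
    }
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(schema)
  vtype <- vapply(schema, function(s) if (s$type == "continuous") 0L else 1L,
                  integer(1))
  nlev <- vapply(schema, function(s)
    if (s$type == "continuous") 0L else length(s$levels), integer(1))
  list(mat = mat, vtype = unname(vtype), nlev = unname(nlev), schema = schema)
}

#' Fit a Bayesian Additive Regression Trees model
#'
#' Fits the sum-of-trees model `y = sum_j g(x; T_j, M_j) + e`,
#' `e ~ N(0, sigma^2)`, by backfitting MCMC. The outcome is rescaled to
#' `[-0.5, 0.5]`; leaf values get a `N(0, (0.5 / (k sqrt(m)))^2)` prior; the
#' noise variance gets a scaled-inverse-chi-square prior with `nu` degrees of
#' freedom calibrated so that `Pr(sigma < sigma_hat) = q`, where `sigma_hat`
#' is the residual scale of an ordinary linear fit (or `sd(y)` when the linear
#' fit is not well determined). Each iteration sweeps the trees, proposing a
#' grow, prune or rule-change move accepted by Metropolis-Hastings on the
#' integrated likelihood of the tree's partial residuals, then redraws leaf
#' values and sigma from their conjugate full conditionals.
#'
#' Categorical covariates (factors) are split natively by level subsets;
#' continuous covariates by thresholds on observed values.
#'
#' @param X data.frame of covariates (numeric and/or factor columns), no
#'   missing values.
#' @param y numeric outcome vector, no missing values.
#' @param config a [bart_config()].
#' @param seed optional integer seed (calls `set.seed`).
#' @return an object of class `bart_fit` with retained forest states, sigma
#'   draws (original outcome scale), rescaling constants, covariate schema and
#'   move acceptance rates.
#' @export
bart <- function(X, y, config = bart_config(), seed = NULL) {
  stopifnot(is.data.frame(X), is.numeric(y), nrow(X) == length(y))
  if (nrow(X) < 2) stop("need at least 2 observations")
  if (anyNA(y)) stop("outcome contains missing values; impute before fitting")
  if (!inherits(config, "bart_config")) stop("config must be a bart_config")
  if (!is.null(seed)) set.seed(seed)

  enc <- encode_covariates(X)

  ymin <- min(y); ymax <- max(y)
  if (ymax - ymin == 0) {
    # degenerate outcome: the posterior predictive is the constant itself
    fit <- structure(list(constant = ymin, n_states = config$n_draws,
                          schema = enc$schema, config = config,
                          center = ymin, range = 1,
                          sigma = rep(0, config$n_draws), states = NULL,
                          accept_rates = c(grow = NA, prune = NA, change = NA)),
                     class = "bart_fit")
    return(fit)
  }
  center <- (ymin + ymax) / 2
  range_y <- ymax - ymin
  ytil <- (y - center) / range_y

  # calibrate lambda from a linear-fit residual scale on the rescaled outcome
  mm <- stats::model.matrix(~ ., data = X)
  sigma_hat <- sd(ytil)
  if (nrow(mm) > ncol(mm) + 2) {
    lf <- stats::lm.fit(mm, ytil)
    dfres <- nrow(mm) - lf$rank
    if (dfres > 2) {
      s <- sqrt(sum(lf$residuals^2) / dfres)
      if (is.finite(s) && s > 0) sigma_hat <- s
    }
  }
  if (!is.finite(sigma_hat) || sigma_hat <= 0) sigma_hat <- 1e-6
  lambda <- sigma_hat^2 * stats::qchisq(1 - config$q, config$nu) / config$nu

  sigma_mu <- 0.5 / (config$k * sqrt(config$n_trees))
  sigma_fixed <- if (is.null(config$sigma_fixed)) -1 else
    config$sigma_fixed / range_y

  # global split-candidate set per continuous covariate: all observed unique
  # values except the maximum (a cut there would always empty the right child)
  cutpoints <- lapply(seq_along(enc$vtype), function(j) {
    if (enc$vtype[j] != 0) return(numeric(0))
    u <- sort(unique(enc$mat[, j]))
    u[-length(u)]
  })

  res <- .bart_mcmc(enc$mat, ytil, enc$vtype, enc$nlev, cutpoints,
                    config$n_trees, config$alpha, config$beta,
                    sigma_mu, config$nu, lambda, sigma_hat, sigma_fixed,
                    config$n_burn, config$n_draws, config$thin,
                    config$proposal_probs[["grow"]],
                    config$proposal_probs[["prune"]],
                    config$proposal_probs[["change"]])

  acc <- ifelse(res$proposals > 0, res$accepts / res$proposals, NA_real_)
  names(acc) <- c("grow", "prune", "change")

  structure(list(states = res$states, sigma = res$sigma * range_y,
                 center = center, range = range_y, schema = enc$schema,
                 config = config, n_states = length(res$sigma),
                 constant = NULL, accept_rates = acc),
            class = "bart_fit")
}

#' Posterior predictions from a fitted BART model
#'
#' Evaluates every retained forest state at the supplied covariate points.
#' Deterministic given the fitted object: no new randomness is used.
#'
#' @param object a `bart_fit`.
#' @param newdata data.frame matching the training covariate schema.
#' @param ... unused.
#' @return numeric matrix, retained states x rows of `newdata`, on the
#'   original outcome scale.
#' @export
predict.bart_fit <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  absent <- setdiff(names(object$schema), names(newdata))
  if (length(absent))
    stop("newdata is missing column(s): ", paste(absent, collapse = ", "))
  enc <- encode_covariates(newdata[names(object$schema)], object$schema)
  if (!is.null(object$constant))
    return(matrix(object$constant, object$n_states, nrow(newdata)))
  raw <- .bart_predict(object$states, enc$mat, enc$vtype)
  raw * object$range + object$center
}

#' Per-covariate split-use proportions
#'
#' For each covariate, the proportion of retained posterior states in which at
#' least one tree splits on it. A coarse screen for which covariates the
#' ensemble actually uses.
#'
#' @param fit a `bart_fit`.
#' @return named numeric vector of proportions in `[0, 1]`.
#' @export
variable_inclusion <- function(fit) {
  stopifnot(inherits(fit, "bart_fit"))
  vars <- names(fit$schema)
  if (!is.null(fit$constant) || fit$n_states == 0)
    return(stats::setNames(rep(0, length(vars)), vars))
  counts <- numeric(length(vars))
  for (state in fit$states) {
    used <- logical(length(vars))
    for (tr in state) {
      vv <- tr[, 1]
      vv <- vv[vv >= 0]
      if (length(vv)) used[unique(as.integer(vv)) + 1L] <- TRUE
    }
    counts <- counts + used
  }
  stats::setNames(counts / fit$n_states, vars)
}

#' @export
print.bart_fit <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat("BART fit (degenerate: constant outcome", x$constant, ")\n")
    return(invisible(x))
  }
  cat("BART fit:", x$config$n_trees, "trees,", x$n_states, "retained states\n")
  cat("posterior mean sigma:", signif(mean(x$sigma), 4), "\n")
  cat("acceptance rates:",
      paste(names(x$accept_rates), signif(x$accept_rates, 2), collapse = ", "),
      "\n")
  invisible(x)
}

#' Sample tree skeletons from the regularizing tree prior
#'
#' Draws tree shapes from the prior alone (no data): a node at depth d becomes
#' internal with probability `alpha * (1 + d)^-beta`, independently, down to
#' `max_depth` where growth is truncated. Used to validate that the sampler's
#' prior is the one intended.
#'
#' @param n_trees number of trees to draw.
#' @param alpha,beta tree prior parameters.
#' @param max_depth truncation depth.
#' @return data.frame with one row per node: `tree`, `depth`, `split`
#'   (logical; whether the node is internal).
#' @export
sample_tree_prior <- function(n_trees, alpha = 0.95, beta = 2, max_depth = 10) {
  depths <- integer(0); splits <- logical(0); ids <- integer(0)
  for (tr in seq_len(n_trees)) {
    # iterative expansion, queue of node depths
    queue <- 0L
    while (length(queue)) {
      d <- queue[[1]]; queue <- queue[-1]
      sp <- d < max_depth && stats::runif(1) < alpha * (1 + d)^(-beta)
      depths <- c(depths, d); splits <- c(splits, sp); ids <- c(ids, tr)
      if (sp) queue <- c(queue, d + 1L, d + 1L)
    }
  }
  data.frame(tree = ids, depth = depths, split = splits)
}
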