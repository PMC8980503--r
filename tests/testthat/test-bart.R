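test_that("a pinned root-only tree matches the conjugate normal posterior", {
  cfg <- bart_config(n_trees = 1, n_burn = 50, n_draws = 2000,
                     proposal_probs = c(grow = 0, prune = 0.5, change = 0.5),
                     sigma_fixed = 1)
  set.seed(1)
  X <- data.frame(x = rnorm(50))
  y <- rnorm(50, 2, 1)
  fit <- bart(X, y, cfg, seed = 7)
  draws <- predict(fit, X[1, , drop = FALSE])[, 1]
  # closed form on the rescaled outcome: prior N(0, 0.25), n obs at noise 1/range
  rg <- max(y) - min(y); ctr <- (max(y) + min(y)) / 2
  yt <- (y - ctr) / rg
  s2 <- (1 / rg)^2; s2mu <- 0.25
  post_mean <- sum(yt) * s2mu / (s2 + 50 * s2mu)
  post_var <- s2 * s2mu / (s2 + 50 * s2mu)
  D <- length(draws)
  expect_lt(abs(mean(draws) - (post_mean * rg + ctr)),
            3 * sqrt(post_var / D) * rg)
  expect_lt(abs(stats::sd(draws) - sqrt(post_var) * rg),
            3 * sqrt(post_var / (2 * D)) * rg)
})

test_that("a constant outcome gives a degenerate posterior returning it", {
  X <- data.frame(x = 1:10, g = factor(rep(c("a", "b"), 5)))
  fit <- bart(X, rep(4.2, 10), bart_config(n_draws = 50), seed = 1)
  pr <- predict(fit, X)
  expect_true(all(pr == 4.2))
  expect_equal(dim(pr), c(50, 10))
  expect_true(all(variable_inclusion(fit) == 0))
})

test_that("hand-built trees evaluate exactly, with deterministic prediction", {
  schema <- list(x1 = list(type = "continuous"), x2 = list(type = "continuous"))
  fit <- hand_fit(list(list(stump_continuous(0, 0, -1, 1))), schema)
  X <- data.frame(x1 = c(-2, -0.1, 0, 0.3, 5), x2 = rnorm(5))
  expect_equal(predict(fit, X)[1, ], c(-1, -1, -1, 1, 1))
  # duplicate rows give identical prediction columns
  Xd <- X[c(1, 1, 4, 4), ]
  pd <- predict(fit, Xd)
  expect_identical(pd[, 1], pd[, 2])
  expect_identical(pd[, 3], pd[, 4])
})

test_that("prediction validates the covariate schema", {
  ch <- generate_cohort(cohort_spec(n = 50, seed = 13))
  X <- model_frame(ch)
  fit <- bart(X, ch$dass_stress, tiny_bart(), seed = 2)
  expect_equal(dim(predict(fit, X)), c(200, 50))
  expect_error(predict(fit, X[, -3]), "missing column")
  bad <- X; bad$gender <- factor("other")
  expect_error(predict(fit, bad), "not seen in training")
  expect_error(bart(X[1, , drop = FALSE], 1), "at least 2")
  Xna <- X; Xna$age[1] <- NA
  expect_error(bart(Xna, ch$dass_stress), "impute")
})

test_that("the sampler beats a linear fit on a nonlinear response surface", {
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 260
    X <- as.data.frame(matrix(stats::runif(n * 10), n))
    names(X) <- paste0("x", 1:10)
    f <- function(d) 10 * sin(pi * d$x1 * d$x2) + 20 * (d$x3 - 0.5)^2 +
      10 * d$x4 + 5 * d$x5
    y <- f(X) + stats::rnorm(n)
    train <- seq_len(200); test <- setdiff(seq_len(n), train)
    fit <- bart(X[train, ], y[train], bart_fast_profile(), seed = 1000 + s)
    pred_bart <- colMeans(predict(fit, X[test, ]))
    lmfit <- stats::lm(y ~ ., data = cbind(X[train, ], y = y[train]))
    pred_lm <- stats::predict(lmfit, X[test, ])
    wins <- wins + (mean((pred_bart - y[test])^2) < mean((pred_lm - y[test])^2))
  }
  expect_gte(wins, 9)
})

test_that("back-transformed predictions are affine-equivariant", {
  ch <- generate_cohort(cohort_spec(n = 80, seed = 17))
  X <- model_frame(ch)
  y <- ch$mpai_ability
  f1 <- bart(X, y, tiny_bart(), seed = 9)
  f2 <- bart(X, 3 * y + 10, tiny_bart(), seed = 9)
  p1 <- colMeans(predict(f1, X))
  p2 <- colMeans(predict(f2, X))
  expect_equal(p2, 3 * p1 + 10, tolerance = 1e-8)
})

test_that("split-use proportions reflect which variables the forest uses", {
  schema <- list(x1 = list(type = "continuous"), x2 = list(type = "continuous"))
  # root-only states: nothing used
  fit0 <- hand_fit(list(list(matrix(leaf_node(0.5), 1)),
                        list(matrix(leaf_node(0.2), 1))), schema)
  expect_equal(unname(variable_inclusion(fit0)), c(0, 0))
  # every state splits on x1 only
  fit1 <- hand_fit(list(list(stump_continuous(0, 0, -1, 1)),
                        list(stump_continuous(0, 1, 0, 2))), schema)
  expect_equal(unname(variable_inclusion(fit1)), c(1, 0))
})

test_that("a pure-noise covariate is used less than the active ones", {
  hits <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    n <- 150
    X <- as.data.frame(matrix(stats::runif(n * 6), n))
    names(X) <- c(paste0("x", 1:5), "noise")
    y <- 10 * sin(pi * X$x1 * X$x2) + 20 * (X$x3 - 0.5)^2 + 10 * X$x4 +
      5 * X$x5 + stats::rnorm(n)
    fit <- bart(X, y, tiny_bart(), seed = 400 + s)
    incl <- variable_inclusion(fit)
    hits <- hits + (incl[["noise"]] < stats::median(incl[paste0("x", 1:5)]))
  }
  expect_gte(hits, 9)
})

test_that("prior tree sampling reproduces the depth-split probabilities", {
  set.seed(99)
  trees <- sample_tree_prior(4000, alpha = 0.95, beta = 2)
  for (d in 0:2) {
    at_d <- trees[trees$depth == d, ]
    p_hat <- mean(at_d$split)
    p <- 0.95 * (1 + d)^(-2)
    half_width <- stats::qnorm(0.995) * sqrt(p * (1 - p) / nrow(at_d))
    expect_lt(abs(p_hat - p), half_width + 1e-9)
  }
})

test_that("fits are reproducible for a fixed seed", {
  ch <- generate_cohort(cohort_spec(n = 60, seed = 23))
  X <- model_frame(ch)
  f1 <- bart(X, ch$eq5d_utility, tiny_bart(), seed = 42)
  f2 <- bart(X, ch$eq5d_utility, tiny_bart(), seed = 42)
  expect_identical(f1$sigma, f2$sigma)
  expect_identical(predict(f1, X), predict(f2, X))
})
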