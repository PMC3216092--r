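test_that("noiseless single-factor model is recovered exactly", {
  set.seed(11)
  logb <- sample(c(0, 1), 40, replace = TRUE)
  y <- 0.5 * logb
  est <- estimate_activities_at_timepoint(y, matrix(logb, ncol = 1,
                                                    dimnames = list(NULL, "TF1")))
  expect_equal(unname(est$alpha), 0.5, tolerance = 1e-10)
  expect_equal(est$intercept, 0, tolerance = 1e-10)
  expect_lt(est$sigma_final, 1e-8)
})

test_that("robust sigma follows the MAD/0.6745 rule", {
  expect_equal(sigma_mad(c(-0.6745, 0, 0.6745)), 1.0)
  # shifting residuals does not change the scale (deviation from median)
  expect_equal(sigma_mad(c(-0.6745, 0, 0.6745) + 3), 1.0)
  # sigma_final is never below sigma_robust
  set.seed(2)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, paste0("TF", 1:3)))
  y <- drop(X %*% c(1, -0.5, 0.2)) + rt(200, df = 3) * 0.3
  est <- estimate_activities_at_timepoint(y, X)
  expect_gte(est$sigma_final, est$sigma_robust)
})

test_that("IRLS equals the normal-equations oracle on noiseless data", {
  set.seed(7)
  for (rep in 1:3) {
    X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, paste0("TF", 1:3)))
    truth <- rnorm(3)
    y <- drop(X %*% truth) + 0.3
    est <- estimate_activities_at_timepoint(y, X)
    oracle <- ols_normal_equations(cbind(1, X), y)
    expect_equal(unname(c(est$intercept, est$alpha)), unname(oracle),
                 tolerance = 1e-8)
    expect_equal(unname(est$alpha), truth, tolerance = 1e-8)
  }
})

test_that("robust fit agrees with an independent bisquare implementation", {
  set.seed(21)
  X <- matrix(rnorm(300 * 4), 300, 4, dimnames = list(NULL, paste0("TF", 1:4)))
  y <- drop(X %*% c(0.8, -0.4, 0, 0.6)) + rnorm(300, sd = 0.3)
  y[1:10] <- y[1:10] + 5  # outliers the bisquare should shrug off
  est <- estimate_activities_at_timepoint(y, X)
  ref <- MASS::rlm(y ~ X, psi = MASS::psi.bisquare, c = 4.685, maxit = 100)
  expect_equal(unname(est$alpha), unname(coef(ref)[-1]), tolerance = 1e-3)
})

test_that("the timecourse recovers a noiseless planted activity matrix", {
  spec <- synthetic_spec(n_genes = 200, n_sine = 5, n_spike_pairs = 2,
                         n_decoy_tfs = 1, noise_sd = 0, missing_frac = 0,
                         rng_seed = 5L)
  ds <- generate_dataset(spec)
  fit <- estimate_activities(ds$expression, ds$binding)
  expect_equal(fit$alpha, ds$true_activities, tolerance = 1e-6)
  expect_true(all(fit$diagnostics$sigma_final < 1e-6))
})

test_that("with log-noise the estimates track truth per factor (r > 0.9)", {
  spec <- synthetic_spec(n_genes = 200, n_sine = 5, n_spike_pairs = 2,
                         n_decoy_tfs = 1, noise_sd = 0.2, missing_frac = 0,
                         rng_seed = 8L)
  ds <- generate_dataset(spec)
  fit <- suppressWarnings(estimate_activities(ds$expression, ds$binding))
  active <- ds$truth$tf[ds$truth$family != "decoy"]
  for (tf in active) {
    expect_gt(cor(fit$alpha[tf, ], ds$true_activities[tf, ]), 0.9)
  }
})

test_that("estimates are invariant to gene order and equivariant in scale", {
  spec <- synthetic_spec(n_genes = 120, n_sine = 3, n_spike_pairs = 1,
                         n_decoy_tfs = 0, noise_sd = 0.1, missing_frac = 0,
                         rng_seed = 3L)
  ds <- generate_dataset(spec)
  fit <- suppressWarnings(estimate_activities(ds$expression, ds$binding))

  perm <- sample(nrow(ds$expression$values))
  expr_p <- expression_matrix(ds$expression$values[perm, ], ds$grid)
  fit_p <- suppressWarnings(estimate_activities(expr_p, ds$binding))
  expect_equal(fit_p$alpha, fit$alpha, tolerance = 1e-8)

  # scaling all expression by k shifts only the intercept, by log k
  expr_k <- expression_matrix(ds$expression$values * 5, ds$grid)
  fit_k <- suppressWarnings(estimate_activities(expr_k, ds$binding))
  expect_equal(fit_k$alpha, fit$alpha, tolerance = 1e-6)
  expect_equal(fit_k$intercept, fit$intercept + log(5), tolerance = 1e-6)
})

test_that("underdetermined and missing-heavy time points are handled", {
  X <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_error(estimate_activities_at_timepoint(rnorm(4), X),
               "underdetermined")
  # a column of mostly-missing expression flags rather than aborts
  spec <- synthetic_spec(n_genes = 60, n_sine = 2, n_spike_pairs = 0,
                         n_decoy_tfs = 0, noise_sd = 0, missing_frac = 0,
                         rng_seed = 2L)
  ds <- generate_dataset(spec)
  vals <- ds$expression$values
  vals[seq_len(59), 4] <- NA
  expr <- expression_matrix(vals, ds$grid)
  fit <- suppressWarnings(estimate_activities(expr, ds$binding))
  expect_true(all(is.na(fit$alpha[, 4])))
  expect_false(anyNA(fit$alpha[, -4]))
})

test_that("iterative selection keeps planted factors and reaches a fixed point", {
  spec <- synthetic_spec(n_genes = 200, n_sine = 5, n_spike_pairs = 0,
                         n_decoy_tfs = 50, noise_sd = 0.1, missing_frac = 0,
                         rng_seed = 13L)
  ds <- generate_dataset(spec)
  sel <- suppressWarnings(iterative_tf_selection(ds$expression, ds$binding))
  planted <- ds$truth$tf[ds$truth$family != "decoy"]
  expect_setequal(sel$retained, planted)

  # retained sets shrink monotonically: no factor re-enters
  sets <- split(sel$history$tf[sel$history$retained],
                sel$history$iteration[sel$history$retained])
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  # the last iteration is a fixed point
  last <- sel$history[sel$history$iteration == sel$n_iterations, ]
  expect_true(all(last$retained))
})

test_that("selection edge cases: everything passes, or everything fails", {
  spec <- synthetic_spec(n_genes = 150, n_sine = 4, n_spike_pairs = 0,
                         n_decoy_tfs = 0, noise_sd = 0.05, missing_frac = 0,
                         rng_seed = 9L)
  ds <- generate_dataset(spec)
  sel <- suppressWarnings(iterative_tf_selection(ds$expression, ds$binding))
  expect_equal(sel$n_iterations, 1L)
  expect_setequal(sel$retained, colnames(ds$binding$values))

  cfg <- tfa_config(min_significant_timepoints = 37)
  expect_error(
    suppressWarnings(iterative_tf_selection(ds$expression, ds$binding, cfg)),
    "eliminated"
  )
})
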