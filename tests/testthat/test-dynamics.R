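test_that("oxygen normalization matches activity scale and is affine-invariant", {
  set.seed(3)
  alpha <- matrix(rnorm(5 * 36, sd = rep(c(0.3, 0.5, 0.7, 0.9, 1.1), 36)),
                  5, 36, dimnames = list(paste0("TF", 1:5), NULL))
  trace <- cumsum(rnorm(36))
  row <- normalize_oxygen(trace, alpha)
  expect_equal(sd(row), median(apply(alpha, 1, sd)), tolerance = 1e-9)
  # using an existing activity row keeps that scale family
  row2 <- normalize_oxygen(alpha[3, ], alpha)
  expect_equal(sd(row2) / median(apply(alpha, 1, sd)), 1, tolerance = 1e-9)
  # affine transforms of the trace change nothing
  expect_equal(normalize_oxygen(2.5 * trace - 7, alpha), row, tolerance = 1e-9)
  expect_error(normalize_oxygen(rep(1, 36), alpha), "zero-variance")
})

test_that("a scalar autoregression is identified exactly", {
  traj <- matrix(0.9^(0:9), 1, 10, dimnames = list("A", NULL))
  model <- estimate_transition_unconstrained(traj)
  expect_equal(unname(model$T[1, 1]), 0.9, tolerance = 1e-12)
})

test_that("a noiseless stable system is recovered to numerical precision", {
  sys <- generate_linear_system(5, spectral_radius = 0.95, n_steps = 35,
                                seed = 42L)
  model <- estimate_transition_unconstrained(sys$trajectory)
  expect_lt(sqrt(sum((model$T - sys$T_true)^2)), 1e-8)
  # and against the explicit normal-equations oracle
  A <- sys$trajectory[, -36]
  B <- sys$trajectory[, -1]
  T_oracle <- t(solve(A %*% t(A), A %*% t(B)))
  expect_equal(unname(model$T), unname(T_oracle), tolerance = 1e-8)
  # residuals of the self-fitted noiseless system vanish
  resid <- model_residuals(model, sys$trajectory)
  expect_lt(max(abs(resid$mean_residual)), 1e-8)
  expect_lt(max(resid$rmse), 1e-8)
})

test_that("a rotation is recovered with its eigenstructure intact", {
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  traj <- simulate_transition(R, c(1, 0), 35)
  model <- estimate_transition_unconstrained(traj)
  expect_equal(unname(model$T), unname(R), tolerance = 1e-9)
  modes <- asymptotic_modes(model)
  expect_equal(modes$modulus[1], 1, tolerance = 1e-9)
  expect_equal(modes$period_samples[1], 12, tolerance = 1e-9)
  expect_true(modes$oscillatory[1])
  # damped rotation: modulus shrinks, period unchanged
  traj2 <- simulate_transition(0.95 * R, c(1, 0), 35)
  modes2 <- asymptotic_modes(estimate_transition_unconstrained(traj2))
  expect_equal(modes2$modulus[1], 0.95, tolerance = 1e-6)
  expect_equal(modes2$period_samples[1], 12, tolerance = 1e-6)
  # pure decay has no oscillatory mode
  modes3 <- asymptotic_modes(0.9 * diag(2))
  expect_false(any(modes3$oscillatory))
  expect_equal(modes3$modulus[1], 0.9)
})

test_that("NNLS agrees with the unconstrained fit when truth is non-negative", {
  set.seed(12)
  T_true <- matrix(runif(9, 0.05, 0.5), 3, 3,
                   dimnames = list(letters[1:3], letters[1:3]))
  T_true <- T_true * (0.9 / max(Mod(eigen(T_true)$values)))
  traj <- simulate_transition(T_true, c(1, 2, -1), 20)
  unc <- estimate_transition_unconstrained(traj)
  nn <- estimate_transition_nonneg(traj)
  expect_lt(max(abs(nn$T - unc$T)), 1e-8)
  expect_lt(max(abs(nn$T - T_true)), 1e-8)
})

test_that("NNLS matches the KKT enumeration oracle row by row", {
  set.seed(23)
  for (rep in 1:5) {
    A <- matrix(rnorm(4 * 15), 4, 15)
    b <- rnorm(15)
    x_pkg <- pracma::lsqnonneg(t(A), b)$x
    x_oracle <- nnls_enumerate(t(A), b)
    expect_equal(x_pkg, x_oracle, tolerance = 1e-6)
  }
})

test_that("negative true couplings pin NNLS entries at zero and cost fit", {
  sys <- generate_linear_system(4, spectral_radius = 0.9, n_steps = 30,
                                seed = 77L)
  stopifnot(any(sys$T_true < 0))
  unc <- estimate_transition_unconstrained(sys$trajectory)
  nn <- estimate_transition_nonneg(sys$trajectory)
  expect_true(all(nn$T >= 0))
  # strongly negative true entries land at (or near) the boundary
  strong_neg <- sys$T_true < -0.2
  expect_true(all(nn$T[strong_neg] < 0.05))
  expect_gt(nn$frobenius_rss, unc$frobenius_rss)
  # zero activity gives a zero transition matrix
  zero <- estimate_transition_nonneg(matrix(0, 3, 10))
  expect_true(all(zero$T == 0))
})

test_that("the unconstrained fit never loses to the constrained one", {
  for (seed in 1:8) {
    sys <- generate_linear_system(4, spectral_radius = 0.9, n_steps = 25,
                                  noise_sd = 0.2, seed = seed)
    unc <- estimate_transition_unconstrained(sys$trajectory)
    nn <- estimate_transition_nonneg(sys$trajectory)
    expect_lte(unc$frobenius_rss, nn$frobenius_rss + 1e-10)
    expect_lte(mean(unc$residuals$rmse^2), mean(nn$residuals$rmse^2) + 1e-10)
  }
})

test_that("simulation follows the matrix powers", {
  expect_equal(simulate_transition(diag(3), c(1, 2, 3), 5),
               matrix(c(1, 2, 3), 3, 6))
  z <- simulate_transition(matrix(0, 2, 2), c(1, 1), 3)
  expect_true(all(z[, -1] == 0))
  s <- simulate_transition(matrix(0.5, 1, 1), 8, 3)
  expect_equal(drop(s), c(8, 4, 2, 1))
  expect_error(simulate_transition(diag(2), c(1, 2, 3), 2), "length")
})

test_that("network extraction applies the threshold and pair rule", {
  Tm <- matrix(c(0.6, -0.7, -0.2, 0.1), 2, 2,
               dimnames = list(c("F1", "F2"), c("F1", "F2")))
  # T[2,1] = -0.7: edge F1 -> F2; T[1,1] = 0.6: self-loop
  net <- extract_network(Tm, 0.5)
  edges <- tidy(net)
  expect_equal(nrow(edges), 2)
  loop <- edges[edges$self_loop, ]
  expect_equal(loop$from, "F1")
  expect_equal(loop$weight, 0.6)
  cross <- edges[!edges$self_loop, ]
  expect_equal(cross$from, "F1")
  expect_equal(cross$to, "F2")
  expect_equal(cross$weight, -0.7)
  # graph export drops the self-loop by default
  path <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, path, "edgelist")
  back <- read_network_tsv(path)
  expect_equal(nrow(back$edges), 1)

  expect_equal(nrow(extract_network(matrix(0, 3, 3), 0.5)$edges), 0)

  # bidirectional pair: keep the larger-magnitude direction only
  Tb <- matrix(0, 2, 2, dimnames = list(c("F1", "F2"), c("F1", "F2")))
  Tb[2, 1] <- 0.8   # F1 -> F2
  Tb[1, 2] <- -0.9  # F2 -> F1, stronger
  eb <- tidy(extract_network(Tb, 0.5))
  expect_equal(nrow(eb), 1)
  expect_equal(eb$from, "F2")
  expect_equal(eb$to, "F1")
  expect_equal(eb$weight, -0.9)
  # an exact tie keeps both directions, flagged
  Tt <- Tb; Tt[1, 2] <- -0.8
  et <- tidy(extract_network(Tt, 0.5))
  expect_equal(nrow(et), 2)
  expect_true(all(et$tie))
  # threshold boundary is inclusive by default, strict on request
  expect_equal(nrow(tidy(extract_network(Tb, 0.8))), 1)
  expect_equal(nrow(tidy(extract_network(Tb, 0.8, comparator = ">"))), 1)
  Ts <- matrix(c(0, 0.8, 0, 0), 2, 2, dimnames = dimnames(Tb))
  expect_equal(nrow(tidy(extract_network(Ts, 0.8))), 1)
  expect_equal(nrow(tidy(extract_network(Ts, 0.8, comparator = ">"))), 0)
})

test_that("network extraction is invariant to factor reordering", {
  sys <- generate_linear_system(5, seed = 5L)
  net1 <- extract_network(sys$T_true, 0.3)
  perm <- c(3, 1, 5, 2, 4)
  Tp <- sys$T_true[perm, perm]
  net2 <- extract_network(Tp, 0.3)
  key <- function(net) {
    e <- tidy(net)
    sort(paste(e$from, e$to, signif(e$weight, 10)))
  }
  expect_identical(key(net1), key(net2))
})

test_that("network exports write valid DOT/GraphML and empty graphs", {
  Tm <- matrix(0, 3, 3, dimnames = list(paste0("F", 1:3), paste0("F", 1:3)))
  Tm[2, 1] <- 0.8   # F1 -> F2
  Tm[3, 2] <- -0.6  # F2 -> F3
  net <- extract_network(Tm, 0.5)
  dot <- withr::local_tempfile(fileext = ".dot")
  export_network(net, dot, "dot")
  expect_equal(length(grep("->", readLines(dot))), 2)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  expect_true(any(grepl("graphml", readLines(gml, n = 5))))
  # empty network still writes a valid file
  empty <- extract_network(matrix(0, 2, 2), 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_network(empty, path, "edgelist")
  expect_equal(nrow(read_network_tsv(path)$edges), 0)
})

test_that("attach_oxygen appends a scale-matched row without inference stats", {
  spec <- synthetic_spec(n_genes = 100, n_sine = 3, n_spike_pairs = 1,
                         n_decoy_tfs = 0, noise_sd = 0.05, missing_frac = 0,
                         rng_seed = 6L)
  ds <- generate_dataset(spec)
  fit <- suppressWarnings(estimate_activities(ds$expression, ds$binding))
  aug <- attach_oxygen(fit, ds$oxygen$trace)
  expect_equal(nrow(aug$alpha), nrow(fit$alpha) + 1)
  expect_equal(aug$oxygen_row, "O2")
  expect_true(all(is.na(aug$se["O2", ])))
  expect_true(all(is.na(aug$pvalue["O2", ])))
})
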