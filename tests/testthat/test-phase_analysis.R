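test_that("noiseless sinusoids are recovered to the phase grid", {
  grid <- small_grid()
  t <- 0:35
  x <- 0.1 * sin(2 * pi * t / 12 + 40 * pi / 180)
  fit <- fit_sine(x, grid)
  expect_equal(fit$phase_deg, 40, tolerance = 1.0)
  expect_equal(fit$amplitude, 0.1, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  # cosine is a sine at 90 degrees
  fit2 <- fit_sine(cos(2 * pi * t / 12), grid)
  expect_equal(fit2$phase_deg, 90, tolerance = 1.0)
})

test_that("grid search matches the closed-form sin/cos regression oracle", {
  grid <- small_grid()
  set.seed(17)
  for (rep in 1:5) {
    x <- runif(1, 0.2, 2) * sin(2 * pi * (0:35) / 12 + runif(1, 0, 2 * pi)) +
      rnorm(36, sd = 0.2) + runif(1, -1, 1)
    fit <- fit_sine(x, grid)
    oracle <- sincos_fit(x, 12)
    expect_lt(circular_diff_deg(fit$phase_deg, oracle$phase_deg), 1.0)
    expect_equal(fit$amplitude, oracle$amplitude, tolerance = 1e-2)
    expect_equal(fit$offset, oracle$offset, tolerance = 1e-2)
    expect_lte(oracle$rss, fit$rss + 1e-9)
    expect_lt(fit$rss - oracle$rss, 1e-3 * max(oracle$rss, 1))
  }
})

test_that("zero-variance profiles are flagged indeterminate", {
  grid <- small_grid()
  fit <- fit_sine(rep(1.5, 36), grid)
  expect_true(fit$indeterminate)
  expect_equal(fit$amplitude, 0)
  expect_equal(fit$offset, 1.5)
})

test_that("sine-fit phase is equivariant under time shifts", {
  grid <- small_grid()
  x <- 0.7 * sin(2 * pi * (0:47) / 12 + 0.5)
  grid48 <- time_grid(seq(0, by = 25, length.out = 48), period_minutes = 300)
  base <- fit_sine(x[1:36], grid)
  for (k in c(1, 3, 5)) {
    shifted <- fit_sine(x[(1 + k):(36 + k)], grid)
    expected <- (base$phase_deg + k * 30) %% 360
    expect_lt(circular_diff_deg(shifted$phase_deg, expected), 1.5)
  }
})

test_that("cycle averaging folds profiles correctly", {
  grid <- small_grid()
  one_cycle <- rnorm(12)
  expect_equal(average_cycles(rep(one_cycle, 3), grid), one_cycle)
  # cycles c, c + d, c + 2d average to c + d
  x <- c(one_cycle, one_cycle + 1, one_cycle + 2)
  expect_equal(average_cycles(x, grid), one_cycle + 1)
  # a clean sine averages to one clean cycle
  s <- sin(2 * pi * (0:35) / 12)
  expect_equal(average_cycles(s, grid), sin(2 * pi * (0:11) / 12),
               tolerance = 1e-12)
  expect_warning(
    avg <- average_cycles(rnorm(38), small_grid(38)),
    "dropping"
  )
  expect_length(avg, 12)
  expect_error(average_cycles(rnorm(5), small_grid(12)), "exceeds")
})

test_that("peak phase maps maxima to degrees with earliest-wins ties", {
  grid <- small_grid()
  prof <- rep(0, 36)
  prof[c(4, 16, 28)] <- 1  # position 3 in every cycle
  pk <- peak_phase(prof, grid)
  expect_equal(pk$angle_deg, 90)
  expect_false(pk$tied)

  prof0 <- rep(0, 36); prof0[c(1, 13, 25)] <- 2
  expect_equal(peak_phase(prof0, grid)$angle_deg, 0)

  tied <- rep(0, 36); tied[c(3, 15, 27)] <- 1; tied[c(8, 20, 32)] <- 1
  pk2 <- peak_phase(tied, grid)
  expect_equal(pk2$angle_deg, 60)  # earliest position (2) wins
  expect_true(pk2$tied)

  flat <- peak_phase(rep(1, 36), grid)
  expect_true(flat$indeterminate)
})

test_that("peak phase of a sine sits at (90 - phase) mod 360", {
  grid <- small_grid()
  for (phi in seq(0, 330, by = 30)) {
    x <- sin(2 * pi * (0:35) / 12 + phi * pi / 180)
    pk <- peak_phase(x, grid)
    expect_lte(circular_diff_deg(pk$angle_deg, (90 - phi) %% 360), 30)
  }
})

test_that("phase labels partition the circle with the stated arcs", {
  expect_equal(classify_phase(300), "Ox")
  expect_equal(classify_phase(225), "R/B")
  expect_equal(classify_phase(0), "R/C")
  angles <- seq(0, 359.5, by = 0.5)
  labels <- classify_phase(angles)
  expect_true(all(labels %in% c("Ox", "R/B", "R/C")))
  # arc lengths: R/C (180) > R/B (120) > Ox (60)
  expect_equal(unname(table(labels)["R/C"] / length(labels)), 0.5)
  expect_equal(unname(table(labels)["R/B"] / length(labels)), 1 / 3)
  expect_equal(unname(table(labels)["Ox"] / length(labels)), 1 / 6)
  # boundaries are half-open at the lower edge; wrapping works
  expect_equal(classify_phase(285), "Ox")
  expect_equal(classify_phase(345), "R/C")
  expect_equal(classify_phase(-15), "R/C")
  expect_equal(classify_phase(360 + 225), "R/B")
})

test_that("oxygen-based labelling recovers the sawtooth construction", {
  spec <- synthetic_spec(rng_seed = 1L)
  oxy <- generate_oxygen(spec)
  lab <- classify_cycle_phases_from_oxygen(oxy$trace, oxy$grid)
  expect_equal(lab$label, oxy$labels)
  # negating the trace swaps Ox and R/B
  neg <- classify_cycle_phases_from_oxygen(-oxy$trace, oxy$grid)
  swapped <- ifelse(oxy$labels == "Ox", "R/B",
                    ifelse(oxy$labels == "R/B", "Ox", "R/C"))
  expect_equal(neg$label, swapped)
  # constant trace: everything R/C, with a warning
  expect_warning(
    flat <- classify_cycle_phases_from_oxygen(rep(1, 36), oxy$grid),
    "constant"
  )
  expect_true(all(flat$label == "R/C"))
})

test_that("a sinusoidal oxygen trace splits into near-equal drop/rise arcs", {
  grid <- small_grid()
  x <- sin(2 * pi * (0:35) / 12)
  lab <- classify_cycle_phases_from_oxygen(x, grid)
  n_ox <- sum(lab$label == "Ox")
  n_rb <- sum(lab$label == "R/B")
  expect_equal(n_ox, n_rb, tolerance = 2)
  expect_gt(n_ox, 36 / 4 - 3)
})
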