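#' Fit a single sinusoid to an activity profile
#'
#' Simplified phase decomposition: because all candidate model patterns
#' share the cycle period, the decomposition reduces to the single sine
#' wave that best fits the profile. The model is
#' \eqn{\hat x_t = A \sin(2\pi t/P + \phi) + m} with t = 0 at the first
#' time point and P = `grid$period_samples`. The phase is searched on a
#' degree grid (default 1 degree); at each candidate phase the amplitude A
#' and offset m are set by exact least squares, and the phase minimizing
#' the residual sum of squares wins. Over whole cycles the best phase does
#' not depend on the trial amplitude, so this sequential search equals
#' joint minimization (a property the test suite checks against the
#' closed-form sin/cos-regression fit). The reported amplitude is
#' non-negative (a negative amplitude is equivalent to a 180-degree phase
#' shift, which the grid covers).
#'
#' @param profile Complete numeric vector.
#' @param grid A [time_grid()].
#' @param phase_grid_step Grid step in degrees (default 1).
#' @return A one-row tibble of class `tfa_sine_fit`: `phase_deg` in
#'   [0, 360), `amplitude` >= 0, `offset`, `rss`, `indeterminate` (true
#'   for a zero-variance profile, whose phase is meaningless).
#' @export
fit_sine <- function(profile, grid, phase_grid_step = 1) {
  stopifnot(inherits(grid, "time_grid"))
  x <- as.numeric(profile)
  if (any(!is.finite(x))) stop("profile must be complete", call. = FALSE)
  n <- length(x)
  P <- grid$period_samples
  t <- seq_len(n) - 1
  if (sd(x) == 0) {
    return(new_sine_fit(0, 0, mean(x), 0, indeterminate = TRUE))
  }
  phases <- seq(0, 360 - phase_grid_step, by = phase_grid_step)
  best <- list(rss = Inf)
  for (phi in phases) {
    s <- sin(2 * pi * t / P + phi * pi / 180)
    fit <- lm.fit(cbind(1, s), x)
    A <- fit$coefficients[2]
    rss <- sum(fit$residuals^2)
    if (A >= 0 && rss < best$rss - 1e-12) {
      best <- list(phase = phi, amplitude = unname(A),
                   offset = unname(fit$coefficients[1]), rss = rss)
    }
  }
  new_sine_fit(best$phase, best$amplitude, best$offset, best$rss,
               indeterminate = best$amplitude == 0)
}

new_sine_fit <- function(phase, amplitude, offset, rss, indeterminate) {
  out <- tibble::tibble(
    phase_deg = phase %% 360,
    amplitude = amplitude,
    offset = offset,
    rss = rss,
    indeterminate = indeterminate
  )
  class(out) <- c("tfa_sine_fit", class(out))
  out
}

#' Sine fits for every factor in an activity matrix
#'
#' @param activity A `tfa_activity` object or factors x time matrix.
#' @param grid Required for a bare matrix.
#' @param phase_grid_step Grid step in degrees (default 1).
#' @return A tibble with one row per factor: `tf`, `phase_deg`,
#'   `amplitude`, `offset`, `rss`, `indeterminate`.
#' @export
fit_sines <- function(activity, grid = NULL, phase_grid_step = 1) {
  if (inherits(activity, "tfa_activity")) {
    mat <- activity$alpha
    grid <- activity$grid
  } else {
    mat <- as.matrix(activity)
    if (is.null(grid)) stop("`grid` is required for a bare matrix",
                            call. = FALSE)
  }
  fits <- purrr::map(rownames(mat), function(tf) {
    f <- fit_sine(mat[tf, ], grid, phase_grid_step)
    dplyr::mutate(f, tf = tf, .before = 1)
  })
  dplyr::bind_rows(fits)
}

#' Average a profile over its cycles
#'
#' Folds the time course onto one cycle: position k of the result is the
#' mean of x_k, x_(k+P), x_(k+2P), ... For the 36-point, period-12 study
#' grid this averages the three observed cycles down to 12 points. A
#' trailing remainder (length not divisible by P) is dropped with a
#' warning.
#'
#' @param profile Complete numeric vector.
#' @param grid A [time_grid()].
#' @return Numeric vector of length `grid$period_samples`.
#' @export
average_cycles <- function(profile, grid) {
  stopifnot(inherits(grid, "time_grid"))
  x <- as.numeric(profile)
  P <- grid$period_samples
  n <- length(x)
  if (P > n) stop("period_samples exceeds the profile length", call. = FALSE)
  k <- n %/% P
  if (n %% P != 0) {
    warning("profile length ", n, " is not a multiple of the period (", P,
            " samples); dropping the trailing ", n %% P, " points",
            call. = FALSE)
  }
  rowMeans(matrix(x[seq_len(k * P)], nrow = P))
}

#' Peak phase of the cycle-averaged profile
#'
#' Averages the profile over cycles, finds the maximum of the averaged
#' curve, and converts its position along the cycle to degrees: position 0
#' (the first time point of the series) maps to 0 degrees, position k to
#' k * 360 / P. Ties are broken by the earliest position and flagged.
#'
#' @param profile Complete numeric vector.
#' @param grid A [time_grid()].
#' @return A list with `angle_deg`, `position` (0-based), `tied`,
#'   `indeterminate` (all-equal averaged profile).
#' @export
peak_phase <- function(profile, grid) {
  avg <- average_cycles(profile, grid)
  P <- length(avg)
  if (max(avg) == min(avg)) {
    return(list(angle_deg = NA_real_, position = NA_integer_,
                tied = FALSE, indeterminate = TRUE))
  }
  at_max <- which(avg == max(avg))
  k <- at_max[1] - 1L
  list(
    angle_deg = k * 360 / P,
    position = k,
    tied = length(at_max) > 1,
    indeterminate = FALSE
  )
}

#' Peak phases for every factor
#'
#' @param activity A `tfa_activity` object or factors x time matrix.
#' @param grid Required for a bare matrix.
#' @return A tibble: `tf`, `peak_deg`, `position`, `tied`,
#'   `indeterminate`, `phase_label` (from [classify_phase()]).
#' @export
peak_phases <- function(activity, grid = NULL) {
  if (inherits(activity, "tfa_activity")) {
    mat <- activity$alpha
    grid <- activity$grid
  } else {
    mat <- as.matrix(activity)
    if (is.null(grid)) stop("`grid` is required for a bare matrix",
                            call. = FALSE)
  }
  rows <- purrr::map(rownames(mat), function(tf) {
    pk <- peak_phase(mat[tf, ], grid)
    tibble::tibble(
      tf = tf, peak_deg = pk$angle_deg, position = pk$position,
      tied = pk$tied, indeterminate = pk$indeterminate,
      phase_label = if (is.na(pk$angle_deg)) NA_character_
                    else classify_phase(pk$angle_deg)
    )
  })
  dplyr::bind_rows(rows)
}

#' Map an angle to a metabolic-cycle phase label
#'
#' The three phases of the yeast metabolic cycle partition the circle:
#' Ox (oxidative; sharp oxygen drop) occupies [285, 345), R/B
#' (reductive/building; oxygen rise) occupies [165, 285), and R/C
#' (reductive/charging, the longest phase) occupies the remaining
#' wrapped arc [345, 360) U [0, 165). Boundaries are half-open at the
#' lower edge; any real angle is reduced mod 360 first.
#'
#' @param angle_degrees Numeric vector of angles in degrees.
#' @return Character vector of labels in `{"Ox", "R/B", "R/C"}`.
#' @export
classify_phase <- function(angle_degrees) {
  a <- angle_degrees %% 360
  dplyr::case_when(
    a >= 285 & a < 345 ~ "Ox",
    a >= 165 & a < 285 ~ "R/B",
    TRUE ~ "R/C"
  )
}

#' Label time points with cycle phases from the oxygen trace
#'
#' The cycle phases are defined by the dissolved-oxygen dynamics: oxygen
#' drops steeply during Ox, rises during R/B, and stays roughly constant
#' during R/C. Each time point is labelled from the finite-difference
#' slope s_t of the trace (forward differences, last value repeated):
#' Ox where s_t < -theta, R/B where s_t > +theta, R/C otherwise, with
#' theta defaulting to half the standard deviation of the slopes.
#'
#' @param oxygen_trace Numeric vector aligned to `grid`.
#' @param grid A [time_grid()].
#' @param theta Slope threshold; default `0.5 * sd(slopes)`.
#' @return A tibble: `time`, `slope`, `label`.
#' @export
classify_cycle_phases_from_oxygen <- function(oxygen_trace, grid,
                                              theta = NULL) {
  stopifnot(inherits(grid, "time_grid"))
  x <- as.numeric(oxygen_trace)
  if (length(x) != length(grid$times)) {
    stop("oxygen trace is not aligned to the grid", call. = FALSE)
  }
  d <- diff(x)
  s <- c(d, d[length(d)])
  if (sd(s) == 0 && is.null(theta)) {
    warning("constant oxygen trace: labelling every time point R/C",
            call. = FALSE)
    theta <- Inf
  }
  if (is.null(theta)) theta <- 0.5 * sd(s)
  label <- dplyr::case_when(
    s < -theta ~ "Ox",
    s > theta ~ "R/B",
    TRUE ~ "R/C"
  )
  tibble::tibble(time = grid$times, slope = s, label = label)
}
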