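#' Specification for a synthetic metabolic-cycle dataset
#'
#' Defines a complete generative model mirroring the structure the
#' analysis assumes: factor activities split into a smooth sinusoidal
#' family and a sharp-spike family with sign-flipped pairs, plus inactive
#' decoy factors; a sparse positive binding matrix; expression generated
#' from the multiplicative model R_i = c * prod_j b_ij^alpha_j with
#' log-scale Gaussian noise and injectable missing values; and a
#' sawtooth-like dissolved-oxygen trace (sharp drop, rise, plateau per
#' cycle).
#'
#' The defaults define the study conditions used throughout the test
#' suite: 200 genes, 13 active factors (5 sine + 4 sign-flipped spike
#' pairs) among 37 decoys, 36 time points covering three 12-sample cycles,
#' log-noise sd 0.15, 2% missing cells.
#'
#' @param n_genes Number of genes (default 200).
#' @param n_sine Number of smooth sinusoidal factors (default 5).
#' @param n_spike_pairs Number of sign-flipped spike-profile pairs
#'   (default 4, i.e. 8 spike factors).
#' @param n_decoy_tfs Number of inactive decoy factors (default 37).
#' @param n_timepoints Number of time points (default 36).
#' @param period_samples Cycle period in samples (default 12).
#' @param sine_amplitudes,sine_phases_deg Per-sine-factor amplitude and
#'   phase (recycled to `n_sine`).
#' @param spike_baseline_amplitude Amplitude of the low sine riding under
#'   each spike profile (default 0.35).
#' @param spike_phases_deg Baseline phases of the spike pairs (recycled).
#' @param spike_amplitude Height of the Gaussian pulse (default 1.2).
#' @param spike_center,spike_width Pulse centre and width in samples
#'   within each cycle (defaults 2 and 0.8).
#' @param targets_per_tf Genes bound by each factor (default 30).
#' @param binding_log_mean,binding_log_sd Parameters of the
#'   truncated-positive normal for target log binding strengths
#'   (defaults 1 and 0.3).
#' @param noise_sd Log-scale expression noise sd (default 0.15).
#' @param missing_frac Fraction of expression cells masked missing
#'   (default 0.02).
#' @param intercept The multiplicative constant c (default 1).
#' @param start_time First time point in minutes (default 3973, with
#'   25-min sampling so that the 12-sample period corresponds to 300 min).
#' @param sampling_interval Minutes between samples (default 25).
#' @param rng_seed Integer seed; every generator is deterministic given it.
#' @return An object of class `synthetic_spec` (a named list).
#' @export
synthetic_spec <- function(n_genes = 200,
                           n_sine = 5,
                           n_spike_pairs = 4,
                           n_decoy_tfs = 37,
                           n_timepoints = 36,
                           period_samples = 12,
                           sine_amplitudes = c(0.50, 0.55, 0.60, 0.65, 0.70),
                           sine_phases_deg = c(200, 215, 225, 240, 255),
                           spike_baseline_amplitude = 0.35,
                           spike_phases_deg = c(10, 25, 40, 55),
                           spike_amplitude = 1.2,
                           spike_center = 2,
                           spike_width = 0.8,
                           targets_per_tf = 30,
                           binding_log_mean = 1,
                           binding_log_sd = 0.3,
                           noise_sd = 0.15,
                           missing_frac = 0.02,
                           intercept = 1,
                           start_time = 3973,
                           sampling_interval = 25,
                           rng_seed = 1L) {
  stopifnot(
    n_genes >= 1, n_timepoints >= 2, period_samples >= 2,
    missing_frac >= 0, missing_frac < 1, noise_sd >= 0,
    targets_per_tf <= n_genes, intercept > 0,
    all(sine_amplitudes >= 0), spike_amplitude >= 0
  )
  if (n_timepoints %% period_samples != 0) {
    warning("n_timepoints is not a multiple of period_samples; ",
            "cycle-based checks will drop the remainder", call. = FALSE)
  }
  structure(
    list(
      n_genes = n_genes, n_sine = n_sine, n_spike_pairs = n_spike_pairs,
      n_decoy_tfs = n_decoy_tfs, n_timepoints = n_timepoints,
      period_samples = period_samples,
      sine_amplitudes = rep_len(sine_amplitudes, max(n_sine, 1)),
      sine_phases_deg = rep_len(sine_phases_deg, max(n_sine, 1)),
      spike_baseline_amplitude = spike_baseline_amplitude,
      spike_phases_deg = rep_len(spike_phases_deg, max(n_spike_pairs, 1)),
      spike_amplitude = spike_amplitude,
      spike_center = spike_center, spike_width = spike_width,
      targets_per_tf = targets_per_tf,
      binding_log_mean = binding_log_mean, binding_log_sd = binding_log_sd,
      noise_sd = noise_sd, missing_frac = missing_frac,
      intercept = intercept,
      start_time = start_time, sampling_interval = sampling_interval,
      rng_seed = as.integer(rng_seed)
    ),
    class = "synthetic_spec"
  )
}

synthetic_tf_ids <- function(spec) {
  sine <- if (spec$n_sine > 0) sprintf("SIN%d", seq_len(spec$n_sine)) else character(0)
  spike <- if (spec$n_spike_pairs > 0) {
    as.vector(t(outer(sprintf("SPK%d", seq_len(spec$n_spike_pairs)),
                      c("p", "n"), paste0)))
  } else character(0)
  decoy <- if (spec$n_decoy_tfs > 0) sprintf("DEC%02d", seq_len(spec$n_decoy_tfs)) else character(0)
  list(sine = sine, spike = spike, decoy = decoy,
       all = c(sine, spike, decoy))
}

synthetic_grid <- function(spec) {
  time_grid(
    spec$start_time + spec$sampling_interval * (seq_len(spec$n_timepoints) - 1),
    period_minutes = spec$sampling_interval * spec$period_samples
  )
}

#' Generate the true factor-activity matrix
#'
#' Sine factors get A sin(2 pi t / P + phi); spike factors a low-amplitude
#' sine plus a Gaussian pulse repeated each cycle, with each pair emitted
#' in both signs (profile and its negation); decoys are identically zero.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `alpha` (factors x time matrix), `grid`, `truth` (tibble
#'   with `tf`, `family` in `{"sine", "spike", "decoy"}`, `sign`,
#'   `phase_deg`, `amplitude`).
#' @export
generate_activities <- function(spec) {
  ids <- synthetic_tf_ids(spec)
  grid <- synthetic_grid(spec)
  P <- spec$period_samples
  t <- seq_len(spec$n_timepoints) - 1
  pos <- t %% P

  rows <- list()
  truth <- list()
  for (i in seq_len(spec$n_sine)) {
    phi <- spec$sine_phases_deg[i]
    rows[[ids$sine[i]]] <-
      spec$sine_amplitudes[i] * sin(2 * pi * t / P + phi * pi / 180)
    truth[[ids$sine[i]]] <- tibble::tibble(
      tf = ids$sine[i], family = "sine", sign = 1,
      phase_deg = phi, amplitude = spec$sine_amplitudes[i]
    )
  }
  if (spec$n_spike_pairs > 0) {
    pulse <- spec$spike_amplitude *
      exp(-(pos - spec$spike_center)^2 / (2 * spec$spike_width^2))
    for (i in seq_len(spec$n_spike_pairs)) {
      phi <- spec$spike_phases_deg[i]
      base <- spec$spike_baseline_amplitude *
        sin(2 * pi * t / P + phi * pi / 180) + pulse
      pos_id <- ids$spike[2 * i - 1]
      neg_id <- ids$spike[2 * i]
      rows[[pos_id]] <- base
      rows[[neg_id]] <- -base
      truth[[pos_id]] <- tibble::tibble(
        tf = pos_id, family = "spike", sign = 1,
        phase_deg = phi, amplitude = spec$spike_amplitude
      )
      truth[[neg_id]] <- tibble::tibble(
        tf = neg_id, family = "spike", sign = -1,
        phase_deg = phi, amplitude = spec$spike_amplitude
      )
    }
  }
  for (id in ids$decoy) {
    rows[[id]] <- rep(0, spec$n_timepoints)
    truth[[id]] <- tibble::tibble(
      tf = id, family = "decoy", sign = 0,
      phase_deg = NA_real_, amplitude = 0
    )
  }
  alpha <- do.call(rbind, rows)
  dimnames(alpha) <- list(names(rows), as.character(grid$times))
  list(alpha = alpha, grid = grid, truth = dplyr::bind_rows(truth))
}

rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > 0
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a sparse positive binding matrix
#'
#' Each factor binds a seeded random target set of `targets_per_tf` genes;
#' targets get b = exp(w) with w drawn from a positive-truncated normal,
#' non-targets sit at the neutral baseline 1.
#'
#' @param spec A [synthetic_spec()].
#' @return A `tfa_binding` object (genes x factors).
#' @export
generate_binding <- function(spec) {
  ids <- synthetic_tf_ids(spec)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  mat <- withr::with_seed(spec$rng_seed + 1L, {
    m <- matrix(1, spec$n_genes, length(ids$all),
                dimnames = list(genes, ids$all))
    for (j in seq_along(ids$all)) {
      targets <- sample.int(spec$n_genes, spec$targets_per_tf)
      m[targets, j] <- exp(rtruncnorm_pos(
        spec$targets_per_tf, spec$binding_log_mean, spec$binding_log_sd
      ))
    }
    m
  })
  binding_matrix(mat)
}

#' Generate expression from the multiplicative model
#'
#' log R_i(t) = log c + sum_j alpha_j(t) log b_ij + eps, with eps Gaussian
#' of sd `noise_sd`; afterwards a seeded random `missing_frac` of cells is
#' masked missing. With `noise_sd = 0` and `missing_frac = 0` the
#' expression reproduces the model exactly.
#'
#' @param binding A `tfa_binding` object.
#' @param activities Output of [generate_activities()] (or a bare factors x
#'   time matrix whose rows match the binding columns).
#' @param spec A [synthetic_spec()].
#' @return A `tfa_expression` object.
#' @export
generate_expression <- function(binding, activities, spec) {
  alpha <- if (is.list(activities) && !is.null(activities$alpha)) {
    activities$alpha
  } else {
    as.matrix(activities)
  }
  grid <- if (is.list(activities) && !is.null(activities$grid)) {
    activities$grid
  } else {
    synthetic_grid(spec)
  }
  B <- binding$values[, rownames(alpha), drop = FALSE]
  log_r <- log(spec$intercept) + log(B) %*% alpha
  vals <- withr::with_seed(spec$rng_seed + 2L, {
    noisy <- log_r
    if (spec$noise_sd > 0) {
      noisy <- noisy + matrix(stats::rnorm(length(log_r), 0, spec$noise_sd),
                              nrow(log_r), ncol(log_r))
    }
    r <- exp(noisy)
    if (spec$missing_frac > 0) {
      n_mask <- round(spec$missing_frac * length(r))
      r[sample.int(length(r), n_mask)] <- NA
    }
    r
  })
  dimnames(vals) <- list(rownames(B), as.character(grid$times))
  expression_matrix(vals, grid)
}

#' Generate a sawtooth-like dissolved-oxygen trace
#'
#' Per cycle: a steep linear drop over ~2 samples (the Ox phase), a linear
#' rise over ~4 samples (R/B), and a plateau for the remainder (R/C),
#' plus optional Gaussian noise. Also returns the construction labels.
#'
#' @param spec A [synthetic_spec()] with `period_samples >= 6`.
#' @param amplitude Peak-to-trough height (default 1).
#' @param noise_sd Additive Gaussian noise sd (default 0).
#' @return A list: `trace` (numeric, length `n_timepoints`), `labels`
#'   (character, the construction truth), `grid`.
#' @export
generate_oxygen <- function(spec, amplitude = 1, noise_sd = 0) {
  P <- spec$period_samples
  if (P < 6) stop("period_samples must be at least 6 for the sawtooth shape",
                  call. = FALSE)
  n_drop <- 2L
  n_rise <- 4L
  n_flat <- P - n_drop - n_rise
  # values at cycle positions; forward differences are negative exactly on
  # the drop samples, positive on the rise samples, zero on the plateau
  cycle <- c(
    amplitude * (1 - seq(0, 1, length.out = n_drop + 1))[seq_len(n_drop)],
    amplitude * seq(0, 1, length.out = n_rise + 1)[seq_len(n_rise)],
    rep(amplitude, n_flat)
  )
  labels_cycle <- c(rep("Ox", n_drop), rep("R/B", n_rise), rep("R/C", n_flat))
  reps <- ceiling(spec$n_timepoints / P)
  trace <- rep(cycle, reps)[seq_len(spec$n_timepoints)]
  labels <- rep(labels_cycle, reps)[seq_len(spec$n_timepoints)]
  if (noise_sd > 0) {
    trace <- withr::with_seed(spec$rng_seed + 3L, {
      trace + stats::rnorm(length(trace), 0, noise_sd)
    })
  }
  list(trace = trace, labels = labels, grid = synthetic_grid(spec))
}

#' Generate a random stable linear system and its trajectory
#'
#' Draws a random square matrix, rescales it to the requested spectral
#' radius, and iterates it from a random start vector, optionally with
#' process noise. Used as ground truth for transition-matrix recovery.
#'
#' @param n_factors System dimension.
#' @param spectral_radius Target spectral radius in (0, 1] (default 0.95).
#' @param n_steps Number of forward steps (default 35, giving 36 columns).
#' @param noise_sd Process noise sd (default 0).
#' @param seed Integer seed.
#' @return A list: `T_true` (matrix), `trajectory` (factors x
#'   `n_steps + 1`).
#' @export
generate_linear_system <- function(n_factors, spectral_radius = 0.95,
                                   n_steps = 35, noise_sd = 0, seed = 1L) {
  stopifnot(spectral_radius > 0, spectral_radius <= 1)
  withr::with_seed(seed, {
    Tm <- matrix(stats::rnorm(n_factors^2), n_factors, n_factors)
    Tm <- Tm * (spectral_radius / max(Mod(eigen(Tm)$values)))
    ids <- sprintf("F%d", seq_len(n_factors))
    dimnames(Tm) <- list(ids, ids)
    traj <- matrix(NA_real_, n_factors, n_steps + 1,
                   dimnames = list(ids, NULL))
    v <- stats::rnorm(n_factors)
    traj[, 1] <- v
    for (s in seq_len(n_steps)) {
      v <- drop(Tm %*% v)
      if (noise_sd > 0) v <- v + stats::rnorm(n_factors, 0, noise_sd)
      traj[, s + 1] <- v
    }
    list(T_true = Tm, trajectory = traj)
  })
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Assembles activities, binding, expression and oxygen from one
#' [synthetic_spec()], deterministically given its seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_dataset`: `expression`
#'   (`tfa_expression`), `binding` (`tfa_binding`), `oxygen` (list from
#'   [generate_oxygen()]), `true_activities` (matrix), `truth` (tibble),
#'   `grid`, `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  act <- generate_activities(spec)
  binding <- generate_binding(spec)
  expr <- generate_expression(binding, act, spec)
  oxy <- generate_oxygen(spec)
  structure(
    list(
      expression = expr, binding = binding, oxygen = oxy,
      true_activities = act$alpha, truth = act$truth,
      grid = act$grid, spec = spec
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d genes x %d time points; %d factors (%d active, %d decoys)\n",
    nrow(x$expression$values), ncol(x$expression$values),
    nrow(x$true_activities),
    sum(x$truth$family != "decoy"), sum(x$truth$family == "decoy")
  ))
  invisible(x)
}
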