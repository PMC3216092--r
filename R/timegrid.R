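#' Time grid for a metabolic-cycle time series
#'
#' Describes the sampling of a time course: the observation times (minutes),
#' the sampling interval (median of successive differences), the cycle period
#' in minutes, and the period expressed in samples. The yeast metabolic cycle
#' oscillates with a period of roughly 300 minutes; the standard chemostat design
#' (36 points spanning 3973--4837 min, ~25-min sampling) gives
#' `period_samples = 12` and covers three full cycles.
#'
#' @param times Numeric vector of observation times in minutes, strictly
#'   increasing, length at least 2.
#' @param period_minutes Cycle period in minutes (default 300).
#' @return An object of class `time_grid`: a list with elements `times`,
#'   `sampling_interval`, `period_minutes` and `period_samples`.
#' @examples
#' grid <- time_grid(seq(3973, 4837, length.out = 36))
#' grid$period_samples  # 12
#' @export
time_grid <- function(times, period_minutes = 300) {
  times <- as.numeric(times)
  if (length(times) < 2) {
    stop("a time grid needs at least two time points", call. = FALSE)
  }
  if (any(!is.finite(times))) {
    stop("time values must be finite numbers", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (period_minutes <= 0) {
    stop("`period_minutes` must be positive", call. = FALSE)
  }
  interval <- median(diff(times))
  ratio <- period_minutes / interval
  lag <- as.integer(round(ratio))
  if (abs(ratio - lag) > 1e-6) {
    warning(sprintf(
      "period (%g min) is not an integer multiple of the sampling interval (%g min); rounding lag to %d samples",
      period_minutes, interval, lag
    ), call. = FALSE)
  }
  if (lag < 2) {
    stop("period must span at least 2 samples on this grid", call. = FALSE)
  }
  structure(
    list(
      times = times,
      sampling_interval = interval,
      period_minutes = period_minutes,
      period_samples = lag
    ),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "<time_grid> %d points, %g-%g min, interval %g min, period %g min (%d samples)\n",
    length(x$times), min(x$times), max(x$times),
    x$sampling_interval, x$period_minutes, x$period_samples
  ))
  invisible(x)
}

#' @export
length.time_grid <- function(x) length(x$times)
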