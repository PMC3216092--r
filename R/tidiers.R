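#' Tidy an activity fit into a long tibble
#'
#' One row per factor per time point with the activity estimate, its
#' standard error and p-value.
#'
#' @param x A `tfa_activity` object.
#' @param ... Unused.
#' @return A tibble: `tf`, `time`, `alpha`, `se`, `p_value`.
#' @export
tidy.tfa_activity <- function(x, ...) {
  times <- x$grid$times
  long <- function(mat, name) {
    tibble::tibble(
      tf = rep(rownames(mat), times = ncol(mat)),
      time = rep(times, each = nrow(mat)),
      value = as.vector(mat)
    ) |>
      stats::setNames(c("tf", "time", name))
  }
  long(x$alpha, "alpha") |>
    dplyr::left_join(long(x$se, "se"), by = c("tf", "time")) |>
    dplyr::left_join(long(x$pvalue, "p_value"), by = c("tf", "time"))
}

#' @rdname tidy.tfa_activity
#' @export
glance.tfa_activity <- function(x, ...) {
  tibble::tibble(
    n_factors = nrow(x$alpha),
    n_timepoints = ncol(x$alpha),
    mean_sigma_final = mean(x$diagnostics$sigma_final, na.rm = TRUE),
    mean_n_genes_used = mean(x$diagnostics$n_genes_used, na.rm = TRUE),
    all_converged = all(x$diagnostics$converged, na.rm = TRUE)
  )
}

#' Tidy an iterative selection result
#'
#' @param x A `tfa_selection` object.
#' @param ... Unused.
#' @return The per-iteration history tibble: `iteration`, `tf`,
#'   `n_significant`, `retained`.
#' @export
tidy.tfa_selection <- function(x, ...) x$history

#' @rdname tidy.tfa_selection
#' @export
glance.tfa_selection <- function(x, ...) {
  tibble::tibble(
    n_iterations = x$n_iterations,
    n_candidates = length(unique(x$history$tf)),
    n_retained = length(x$retained)
  )
}

#' Tidy a transition model into a long entry table
#'
#' @param x A `tfa_transition` object.
#' @param ... Unused.
#' @return A tibble: `from`, `to`, `weight` (entry `T[to, from]`).
#' @export
tidy.tfa_transition <- function(x, ...) {
  tibble::tibble(
    from = rep(colnames(x$T), each = nrow(x$T)),
    to = rep(rownames(x$T), times = ncol(x$T)),
    weight = as.vector(x$T)
  )
}

#' @rdname tidy.tfa_transition
#' @export
glance.tfa_transition <- function(x, ...) {
  tibble::tibble(
    n_factors = length(x$factor_ids),
    constrained = x$constrained,
    frobenius_rss = x$frobenius_rss,
    mean_abs_residual = mean(abs(x$residuals$mean_residual)),
    mean_rmse = mean(x$residuals$rmse),
    spectral_radius = max(Mod(eigen(x$T, only.values = TRUE)$values))
  )
}

#' Tidy a clustering result
#'
#' @param x A `tfa_clustering` object.
#' @param ... Unused.
#' @return A tibble: `tf`, `cluster`.
#' @export
tidy.tfa_clustering <- function(x, ...) {
  tibble::tibble(tf = x$tf_ids, cluster = unname(x$labels[x$tf_ids]))
}

#' @rdname tidy.tfa_clustering
#' @export
glance.tfa_clustering <- function(x, ...) {
  tibble::tibble(
    n_profiles = length(x$tf_ids),
    n_clusters = x$n_clusters,
    metric = x$metric,
    linkage = x$linkage,
    max_merge_height = max(x$hclust$height)
  )
}

#' Tidy a regulatory network
#'
#' @param x A `tfa_network` object.
#' @param ... Unused.
#' @return The edge tibble: `from`, `to`, `weight`, `sign`, `self_loop`,
#'   `tie`.
#' @export
tidy.tfa_network <- function(x, ...) x$edges

#' @rdname tidy.tfa_network
#' @export
glance.tfa_network <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x$edges),
    n_self_loops = sum(x$edges$self_loop),
    n_positive = sum(x$edges$sign > 0),
    n_negative = sum(x$edges$sign < 0),
    threshold = x$threshold
  )
}
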