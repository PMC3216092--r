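#' Run the full metabolic-cycle analysis pipeline
#'
#' Executes the stages in the order of the original analysis: (1) robust
#' per-time-point activity regression with (2) iterative factor selection,
#' (3) periodicity scoring with permutation null and threshold filtering,
#' (4) sine fits, peak phases and oxygen-based cycle-phase labels, (5)
#' hierarchical clustering on |alpha|, (6) time-translation matrices
#' (unconstrained and non-negative) with oxygen attached as an extra
#' factor, and (7) network extraction. All intermediate tables are written
#' as TSV under `out_dir` along with a JSON run manifest (config echo,
#' seed, file hashes). A single seed governs every stochastic step.
#'
#' @param expr A `tfa_expression` object.
#' @param binding A `tfa_binding` object.
#' @param oxygen Raw oxygen trace aligned to the expression grid, or
#'   `NULL` to omit oxygen from the dynamical model.
#' @param config A [tfa_config()] object.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param options A [robust_fit_options()] object.
#' @return A list of class `tfa_pipeline`: `selection`, `periodicity`,
#'   `retained`, `activity` (the retained-set `tfa_activity`),
#'   `sine_fits`, `peak_phases`, `cycle_labels` (or `NULL`), `clustering`,
#'   `transition_unconstrained`, `transition_nonneg`, `network`,
#'   `manifest`.
#' @export
run_pipeline <- function(expr, binding, oxygen = NULL,
                         config = tfa_config(), out_dir = NULL,
                         options = robust_fit_options()) {
  stopifnot(inherits(config, "tfa_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stages <- character(0)
  outputs <- character(0)
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    invisible(path)
  }
  run_stage <- function(name, fn) {
    stages <<- c(stages, name)
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  selection <- run_stage("activities", function() {
    iterative_tf_selection(expr, binding, config, options)
  })
  run_stage("selection", function() {
    emit("selection_history.tsv", function(p) write_tibble_tsv(selection$history, p))
    emit("activities.tsv", function(p) write_matrix_tsv(selection$fit$alpha, p, "tf"))
    emit("activity_se.tsv", function(p) write_matrix_tsv(selection$fit$se, p, "tf"))
    emit("activity_pvalues.tsv", function(p) write_matrix_tsv(selection$fit$pvalue, p, "tf"))
    emit("regression_diagnostics.tsv", function(p) write_tibble_tsv(selection$fit$diagnostics, p))
  })

  periodicity <- run_stage("periodicity", function() {
    res <- score_periodicity(selection$fit, config)
    emit("periodicity.tsv", function(p) write_tibble_tsv(res, p))
    res
  })
  retained <- filter_periodic(periodicity, config$periodicity_threshold)
  if (length(retained) == 0) {
    stop("pipeline stage `phases` cannot run: no factor reached the ",
         "periodicity threshold ", config$periodicity_threshold,
         call. = FALSE)
  }
  activity <- subset_activity(selection$fit, retained)

  phases <- run_stage("phases", function() {
    sines <- fit_sines(activity, phase_grid_step = config$phase_grid_step_degrees)
    peaks <- peak_phases(activity)
    labels <- if (!is.null(oxygen)) {
      classify_cycle_phases_from_oxygen(oxygen, activity$grid)
    } else NULL
    emit("sine_fits.tsv", function(p) write_tibble_tsv(sines, p))
    emit("peak_phases.tsv", function(p) write_tibble_tsv(peaks, p))
    if (!is.null(labels)) {
      emit("cycle_labels.tsv", function(p) write_tibble_tsv(labels, p))
    }
    list(sines = sines, peaks = peaks, labels = labels)
  })

  clustering <- run_stage("clustering", function() {
    cl <- cluster_profiles(activity, n_clusters = min(2, length(retained)))
    emit("clusters.tsv", function(p) write_tibble_tsv(tidy(cl), p))
    cl
  })

  dynamics <- run_stage("dynamics", function() {
    act_dyn <- if (!is.null(oxygen)) attach_oxygen(activity, oxygen) else activity
    unc <- estimate_transition_unconstrained(act_dyn)
    nn <- estimate_transition_nonneg(act_dyn)
    emit("transition_unconstrained.tsv", function(p) write_matrix_tsv(unc$T, p, "factor"))
    emit("transition_nonneg.tsv", function(p) write_matrix_tsv(nn$T, p, "factor"))
    resid <- dplyr::bind_rows(
      dplyr::mutate(unc$residuals, model = "unconstrained"),
      dplyr::mutate(nn$residuals, model = "nonneg")
    )
    emit("model_residuals.tsv", function(p) write_tibble_tsv(resid, p))
    list(unconstrained = unc, nonneg = nn)
  })

  network <- run_stage("network", function() {
    net <- extract_network(dynamics$unconstrained, config$network_threshold)
    emit("edges.tsv", function(p) export_network(net, p, "edgelist"))
    emit("network.graphml", function(p) export_network(net, p, "graphml"))
    emit("network.dot", function(p) export_network(net, p, "dot"))
    net
  })

  manifest <- list(
    tool = "tfcycle",
    version = as.character(utils::packageVersion("tfcycle")),
    seed = config$rng_seed,
    config = unclass(config),
    stages = stages,
    n_candidates = ncol(binding$values),
    n_after_selection = length(selection$retained),
    n_after_periodicity = length(retained),
    n_network_edges = nrow(network$edges),
    outputs = if (length(outputs)) {
      as.list(setNames(unname(tools::md5sum(outputs)), basename(outputs)))
    } else list(),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(
    list(
      selection = selection,
      periodicity = periodicity,
      retained = retained,
      activity = activity,
      sine_fits = phases$sines,
      peak_phases = phases$peaks,
      cycle_labels = phases$labels,
      clustering = clustering,
      transition_unconstrained = dynamics$unconstrained,
      transition_nonneg = dynamics$nonneg,
      network = network,
      manifest = manifest
    ),
    class = "tfa_pipeline"
  )
}

write_tibble_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.tfa_pipeline <- function(x, ...) {
  cat("<tfa_pipeline>\n")
  cat(sprintf("  candidates: %d -> selected: %d -> periodic: %d\n",
              x$manifest$n_candidates, x$manifest$n_after_selection,
              x$manifest$n_after_periodicity))
  cat(sprintf("  network edges: %d\n", nrow(x$network$edges)))
  invisible(x)
}
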