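#' Expression and binding containers
#'
#' `expression_matrix()` wraps a genes x time-points matrix of relative
#' expression values (positive; `NA` marks missing) together with its
#' [time_grid()]. `binding_matrix()` wraps a genes x factors matrix of
#' positive binding coefficients b_ij; non-targets sit at the baseline 1 so
#' that log b = 0 and they contribute nothing to the log-linear model.
#'
#' @param values Numeric matrix. For expression: genes x time points, all
#'   present values > 0. For binding: genes x factors, all values >= `floor`.
#' @param grid A [time_grid()] whose length matches `ncol(values)`.
#' @param floor Smallest permitted binding coefficient (> 0).
#' @return An object of class `tfa_expression` or `tfa_binding`.
#' @name containers
NULL

#' @rdname containers
#' @export
expression_matrix <- function(values, grid) {
  values <- as.matrix(values)
  stopifnot(inherits(grid, "time_grid"))
  if (ncol(values) != length(grid$times)) {
    stop("expression matrix has ", ncol(values), " columns but the grid has ",
         length(grid$times), " time points", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    stop("expression matrix needs gene identifiers as row names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  }
  bad <- !is.na(values) & values <= 0
  if (any(bad)) {
    stop("expression values must be positive or missing; found ",
         sum(bad), " non-positive entries (mark them NA)", call. = FALSE)
  }
  structure(list(values = values, grid = grid), class = "tfa_expression")
}

#' @rdname containers
#' @export
binding_matrix <- function(values, floor = 1e-4) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("binding matrix needs gene row names and factor column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicate identifiers in binding matrix", call. = FALSE)
  }
  if (floor <= 0) stop("`floor` must be positive", call. = FALSE)
  values[is.na(values)] <- 1
  if (any(values < floor)) values[values < floor] <- floor
  structure(list(values = values, floor = floor), class = "tfa_binding")
}

#' @export
print.tfa_expression <- function(x, ...) {
  cat(sprintf("<tfa_expression> %d genes x %d time points (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.tfa_binding <- function(x, ...) {
  cat(sprintf("<tfa_binding> %d genes x %d factors, floor %g\n",
              nrow(x$values), ncol(x$values), x$floor))
  invisible(x)
}

#' @export
dim.tfa_expression <- function(x) dim(x$values)

#' @export
dim.tfa_binding <- function(x) dim(x$values)

read_numeric_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("expected an id column plus data columns in ", path,
                         call. = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

#' Read a gene x time-point expression table
#'
#' Tab-delimited, header row holding time values in minutes, first column
#' gene identifiers. Empty cells, `NA`, and non-positive values are marked
#' missing (the log-linear model is undefined for them); rows with missing
#' values are retained, not dropped, and excluded per time point inside the
#' regression.
#'
#' @param path Path to a TSV file.
#' @param period_minutes Cycle period passed to [time_grid()] (default 300).
#' @return A `tfa_expression` object.
#' @export
read_expression <- function(path, period_minutes = 300) {
  mat <- read_numeric_tsv(path)
  times <- suppressWarnings(as.numeric(colnames(mat)))
  if (any(is.na(times))) {
    stop("expression header must be numeric time values (minutes)",
         call. = FALSE)
  }
  if (ncol(mat) < 2) stop("need at least 2 time points", call. = FALSE)
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate gene identifiers in ", path, call. = FALSE)
  }
  mat[!is.na(mat) & mat <= 0] <- NA
  expression_matrix(mat, time_grid(times, period_minutes = period_minutes))
}

#' Read a gene x factor binding-coefficient table
#'
#' Tab-delimited, genes in rows, transcription factors in columns. The raw
#' numbers may be occupancy ratios (use `transform = "identity"`) or binding
#' p-values (use `transform = "pvalue_to_strength"`, which maps p to
#' 1 / max(p, floor) so that strong binding gets a large coefficient).
#' Missing entries are set to the neutral baseline 1; all stored values are
#' clipped below at `floor`.
#'
#' @param path Path to a TSV file.
#' @param transform `"identity"` or `"pvalue_to_strength"`.
#' @param floor Smallest permitted coefficient after preprocessing.
#' @return A `tfa_binding` object.
#' @export
read_binding <- function(path, transform = c("identity", "pvalue_to_strength"),
                         floor = 1e-4) {
  transform <- match.arg(transform)
  mat <- read_numeric_tsv(path)
  if (transform == "identity") {
    if (any(!is.na(mat) & mat < 0)) {
      stop("negative binding coefficients are not allowed under the identity transform",
           call. = FALSE)
    }
  } else {
    mat[!is.na(mat)] <- 1 / pmax(mat[!is.na(mat)], floor)
  }
  binding_matrix(mat, floor = floor)
}

#' Read a dissolved-oxygen trace and align it to a time grid
#'
#' Two-column TSV (time in minutes, oxygen level). The trace need not be
#' sampled at the expression time points; it is linearly interpolated onto
#' the grid (constant extrapolation at the ends).
#'
#' @param path Path to a two-column TSV file.
#' @param grid The [time_grid()] of the expression data.
#' @return Numeric vector of oxygen levels, one per grid time point.
#' @export
read_oxygen <- function(path, grid) {
  stopifnot(inherits(grid, "time_grid"))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("oxygen file must have time and value columns",
                         call. = FALSE)
  t0 <- as.numeric(df[[1]])
  v0 <- as.numeric(df[[2]])
  if (length(t0) < 2) stop("need at least 2 oxygen samples", call. = FALSE)
  if (any(diff(t0) <= 0)) stop("oxygen times must be strictly increasing",
                               call. = FALSE)
  approx(t0, v0, xout = grid$times, rule = 2)$y
}

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Write and read matrix-shaped tables losslessly
#'
#' `write_matrix_tsv()` writes a numeric matrix as TSV (first column = row
#' id, header = column names) at full double precision so that
#' `read_matrix_tsv()` round-trips it exactly; `NA` marks missing cells.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_name Name for the identifier column.
#' @return `write_matrix_tsv()` returns `path` invisibly;
#'   `read_matrix_tsv()` returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path, id_name = "id") {
  mat <- as.matrix(mat)
  header <- c(id_name, colnames(mat))
  lines <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], fmt_num(mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  read_numeric_tsv(path)
}

#' Pipeline configuration
#'
#' Collects the analysis thresholds in one validated object. Defaults follow
#' the study design: per-time-point significance p < 0.1 at >= 9 of 36 time
#' points for factor retention, periodicity-score threshold 0.44, 1000
#' permutations for the null, 300-min period, network threshold 0.5 on
#' |T| entries, 1-degree phase grid.
#'
#' @param p_threshold Per-time-point p-value cut for counting a factor
#'   significant (default 0.1).
#' @param min_significant_timepoints Minimum number of significant time
#'   points for retention (default 9).
#' @param periodicity_threshold Minimum periodicity score (default 0.44).
#' @param n_permutations Permutations for the periodicity null (default 1000).
#' @param rng_seed Integer seed governing all stochastic steps.
#' @param period_minutes Cycle period in minutes (default 300).
#' @param network_threshold Minimum |T| entry for a network edge (default 0.5).
#' @param phase_grid_step_degrees Sine-fit phase grid step (default 1).
#' @param binding_floor Smallest permitted binding coefficient (default 1e-4).
#' @param center_autocorrelation Mean-center profiles before autocorrelation
#'   (default `FALSE`, matching the raw unscaled convention).
#' @return An object of class `tfa_config` (a named list).
#' @export
tfa_config <- function(p_threshold = 0.1,
                       min_significant_timepoints = 9,
                       periodicity_threshold = 0.44,
                       n_permutations = 1000,
                       rng_seed = 1L,
                       period_minutes = 300,
                       network_threshold = 0.5,
                       phase_grid_step_degrees = 1,
                       binding_floor = 1e-4,
                       center_autocorrelation = FALSE) {
  cfg <- list(
    p_threshold = p_threshold,
    min_significant_timepoints = min_significant_timepoints,
    periodicity_threshold = periodicity_threshold,
    n_permutations = n_permutations,
    rng_seed = as.integer(rng_seed),
    period_minutes = period_minutes,
    network_threshold = network_threshold,
    phase_grid_step_degrees = phase_grid_step_degrees,
    binding_floor = binding_floor,
    center_autocorrelation = isTRUE(center_autocorrelation)
  )
  positive <- c("p_threshold", "periodicity_threshold", "period_minutes",
                "network_threshold", "phase_grid_step_degrees", "binding_floor")
  for (key in positive) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1 ||
        !is.finite(cfg[[key]]) || cfg[[key]] <= 0) {
      stop("config field `", key, "` must be a positive number", call. = FALSE)
    }
  }
  if (cfg$min_significant_timepoints < 1) {
    stop("`min_significant_timepoints` must be at least 1", call. = FALSE)
  }
  if (cfg$n_permutations < 1) {
    stop("`n_permutations` must be at least 1", call. = FALSE)
  }
  structure(cfg, class = "tfa_config")
}

#' Read a YAML pipeline configuration
#'
#' Missing keys take the [tfa_config()] defaults; unknown keys are rejected.
#' An empty file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A `tfa_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(tfa_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(tfa_config, raw)
}

#' @export
print.tfa_config <- function(x, ...) {
  cat("<tfa_config>\n")
  for (key in names(x)) cat(sprintf("  %s: %s\n", key, format(x[[key]])))
  invisible(x)
}
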