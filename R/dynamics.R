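#' Normalize an oxygen trace to activity scale
#'
#' Z-scores the dissolved-oxygen trace and rescales it to the median
#' per-factor standard deviation of the activity rows, so that oxygen can
#' be treated as an additional factor's activity profile side by side with
#' the transcription factors. The result is invariant to affine
#' transformations of the input trace.
#'
#' @param trace Numeric vector aligned to the activity grid.
#' @param activity A `tfa_activity` object (or factors x time matrix)
#'   supplying the target scale.
#' @return Numeric vector, same length as `trace`.
#' @export
normalize_oxygen <- function(trace, activity) {
  x <- as.numeric(trace)
  if (sd(x) == 0) stop("zero-variance oxygen trace cannot be normalized",
                       call. = FALSE)
  mat <- if (inherits(activity, "tfa_activity")) activity$alpha else as.matrix(activity)
  target <- median(apply(mat, 1, sd))
  (x - mean(x)) / sd(x) * target
}

#' Attach a normalized oxygen row to an activity matrix
#'
#' Adds the normalized trace as one more row (named `"O2"` by default) so
#' the dynamical model can include oxygen as an extra factor. The row has
#' no standard errors or p-values (flagged missing).
#'
#' @param activity A `tfa_activity` object.
#' @param trace Raw oxygen trace aligned to the activity grid.
#' @param name Row name for the oxygen factor (default `"O2"`).
#' @return The augmented `tfa_activity` object, with `oxygen_row` set.
#' @export
attach_oxygen <- function(activity, trace, name = "O2") {
  stopifnot(inherits(activity, "tfa_activity"))
  row <- normalize_oxygen(trace, activity)
  if (length(row) != ncol(activity$alpha)) {
    stop("oxygen trace is not aligned to the activity grid", call. = FALSE)
  }
  activity$alpha <- rbind(activity$alpha, row)
  rownames(activity$alpha)[nrow(activity$alpha)] <- name
  blank <- rep(NA_real_, ncol(activity$se))
  activity$se <- rbind(activity$se, blank)
  activity$pvalue <- rbind(activity$pvalue, blank)
  rownames(activity$se)[nrow(activity$se)] <- name
  rownames(activity$pvalue)[nrow(activity$pvalue)] <- name
  activity$oxygen_row <- name
  activity
}

activity_to_matrix <- function(activity) {
  if (inherits(activity, "tfa_activity")) activity$alpha
  else as.matrix(activity)
}

#' Estimate the time-translation matrix
#'
#' Fits the linear dynamical model alpha_(t+1) = T alpha_t by least
#' squares. With columns as time points, A holds the activities excluding
#' the last time point and B those excluding the first; the unconstrained
#' solution minimizes ||B - T A||_F and is computed through the
#' pseudoinverse (identical to the normal-equations solution at full rank,
#' minimum-norm under rank deficiency, with a warning). With
#' `constrained = TRUE` each row of T is fit by non-negative least squares
#' (Lawson-Hanson active set), so every entry of T is >= 0.
#'
#' @param activity A `tfa_activity` object or factors x time matrix
#'   (include oxygen first via [attach_oxygen()] if wanted).
#' @param constrained Require non-negative entries (default `FALSE`).
#' @return An object of class `tfa_transition`: list with `T` (square
#'   matrix, entry `T[k, j]` = effect of factor j at time t on factor k at
#'   t+1), `factor_ids`, `constrained`, `A`, `B`, `residuals` (tibble from
#'   [model_residuals()]), `frobenius_rss` (fit residual
#'   `||B - T A||_F^2`).
#' @export
estimate_transition <- function(activity, constrained = FALSE) {
  M <- activity_to_matrix(activity)
  n_t <- ncol(M)
  n_f <- nrow(M)
  if (n_t - 1 < n_f) {
    warning("fewer time transitions (", n_t - 1, ") than factors (", n_f,
            "); the system is underdetermined", call. = FALSE)
  }
  A <- M[, -n_t, drop = FALSE]
  B <- M[, -1, drop = FALSE]
  if (constrained) {
    Tm <- t(vapply(seq_len(n_f), function(k) {
      pracma::lsqnonneg(t(A), B[k, ])$x
    }, numeric(n_f)))
  } else {
    r <- qr(t(A))$rank
    if (r < n_f) {
      warning("rank-deficient activity matrix (rank ", r, " < ", n_f,
              "); returning the minimum-norm solution", call. = FALSE)
    }
    Tm <- B %*% MASS::ginv(A)
  }
  dimnames(Tm) <- list(rownames(M), rownames(M))
  model <- structure(
    list(
      T = Tm,
      factor_ids = rownames(M),
      constrained = constrained,
      A = A,
      B = B,
      frobenius_rss = sum((B - Tm %*% A)^2)
    ),
    class = "tfa_transition"
  )
  model$residuals <- model_residuals(model, M)
  model
}

#' @rdname estimate_transition
#' @export
estimate_transition_unconstrained <- function(activity) {
  estimate_transition(activity, constrained = FALSE)
}

#' @rdname estimate_transition
#' @export
estimate_transition_nonneg <- function(activity) {
  estimate_transition(activity, constrained = TRUE)
}

#' @export
print.tfa_transition <- function(x, ...) {
  cat(sprintf("<tfa_transition> %d factors, %s, fit RSS %.4g\n",
              length(x$factor_ids),
              if (x$constrained) "non-negative" else "unconstrained",
              x$frobenius_rss))
  invisible(x)
}

#' Simulate a trajectory from a transition model
#'
#' Repeatedly applies the time-translation matrix to a starting activity
#' vector: column s of the result is T^s alpha_0.
#'
#' @param model A `tfa_transition` object (or bare square matrix).
#' @param alpha_0 Starting activity vector, one entry per factor.
#' @param n_steps Number of forward steps.
#' @return Matrix of `n_steps + 1` columns (the first is `alpha_0`).
#' @export
simulate_transition <- function(model, alpha_0, n_steps) {
  Tm <- if (inherits(model, "tfa_transition")) model$T else as.matrix(model)
  v <- as.numeric(alpha_0)
  if (length(v) != nrow(Tm)) stop("alpha_0 length must equal the number of factors",
                                  call. = FALSE)
  out <- matrix(NA_real_, nrow = nrow(Tm), ncol = n_steps + 1)
  rownames(out) <- rownames(Tm)
  out[, 1] <- v
  for (s in seq_len(n_steps)) {
    v <- drop(Tm %*% v)
    out[, s + 1] <- v
  }
  out
}

#' Per-time-point residuals of a transition model
#'
#' Simulates the whole time course from the first observed activity vector
#' and compares it with the observed one, in two conventions: the
#' mean-difference residual (mean activity over factors, observed minus
#' simulated — the convention used when comparing the constrained and
#' unconstrained models) and the per-time-point RMSE over factors as a
#' stricter diagnostic.
#'
#' @param model A `tfa_transition` object.
#' @param activity A `tfa_activity` object or factors x time matrix.
#' @return A tibble: `time_index`, `mean_residual`, `rmse`.
#' @export
model_residuals <- function(model, activity) {
  M <- activity_to_matrix(activity)
  sim <- simulate_transition(model, M[, 1], ncol(M) - 1)
  tibble::tibble(
    time_index = seq_len(ncol(M)),
    mean_residual = colMeans(M) - colMeans(sim),
    rmse = sqrt(colMeans((M - sim)^2))
  )
}

#' Asymptotic oscillation modes of a transition model
#'
#' Eigen-decomposes the time-translation matrix. Each eigenvalue's modulus
#' gives the per-step decay (or growth) of its mode and, for complex
#' pairs, the argument gives the oscillation period in samples
#' (2 pi / |arg lambda|). Modes are reported in order of decreasing
#' modulus, one row per eigenvalue pair (complex conjugates collapsed).
#'
#' @param model A `tfa_transition` object (or bare square matrix).
#' @return A tibble: `mode`, `modulus`, `period_samples` (`Inf` for
#'   non-oscillatory modes), `oscillatory`, `leading_factor` (factor with
#'   the largest loading magnitude in the eigenvector).
#' @export
asymptotic_modes <- function(model) {
  Tm <- if (inherits(model, "tfa_transition")) model$T else as.matrix(model)
  e <- eigen(Tm)
  keep <- !duplicated(signif(Mod(e$values), 12) + 1i * abs(signif(Arg(e$values), 12)))
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  ord <- order(Mod(vals), decreasing = TRUE)
  vals <- vals[ord]
  vecs <- vecs[, ord, drop = FALSE]
  ids <- rownames(Tm)
  tibble::tibble(
    mode = seq_along(vals),
    modulus = Mod(vals),
    period_samples = ifelse(abs(Arg(vals)) > 1e-12,
                            2 * pi / abs(Arg(vals)), Inf),
    oscillatory = abs(Arg(vals)) > 1e-12,
    leading_factor = vapply(seq_along(vals), function(j) {
      if (is.null(ids)) NA_character_
      else ids[which.max(Mod(vecs[, j]))]
    }, character(1))
  )
}

#' Extract the regulatory network from a transition model
#'
#' Every entry of T with magnitude at or above the threshold defines a
#' directed edge j -> k (factor j's activity at time t affecting factor
#' k's at t+1) with the signed entry as weight. When both directions of a
#' factor pair are significant, only the larger-magnitude direction is
#' kept (exact ties keep both, flagged). Self-loops are recorded but
#' excluded from graph exports by default.
#'
#' @param model A `tfa_transition` object (or bare square matrix).
#' @param threshold Minimum |weight| for significance (default 0.5).
#' @param comparator `">="` (inclusive, default) or `">"`.
#' @return An object of class `tfa_network`: list with `edges` (tibble:
#'   `from`, `to`, `weight`, `sign`, `self_loop`, `tie`), `threshold`,
#'   `comparator`.
#' @export
extract_network <- function(model, threshold = 0.5, comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  Tm <- if (inherits(model, "tfa_transition")) model$T else as.matrix(model)
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  ids <- rownames(Tm)
  if (is.null(ids)) ids <- paste0("F", seq_len(nrow(Tm)))
  cmp <- if (comparator == ">=") `>=` else `>`
  hits <- which(cmp(abs(Tm), threshold), arr.ind = TRUE)
  edges <- tibble::tibble(
    from = ids[hits[, "col"]],
    to = ids[hits[, "row"]],
    weight = Tm[hits],
    self_loop = hits[, "row"] == hits[, "col"],
    tie = FALSE
  )
  # pair resolution: for each unordered non-self pair with both directions
  # significant, keep the larger |weight|; exact ties keep both, flagged
  drop <- rep(FALSE, nrow(edges))
  if (nrow(edges) > 1) {
    key <- vapply(seq_len(nrow(edges)), function(i) {
      paste(sort(c(edges$from[i], edges$to[i])), collapse = "\r")
    }, character(1))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k & !edges$self_loop)
      if (length(idx) == 2) {
        w <- abs(edges$weight[idx])
        if (w[1] == w[2]) {
          edges$tie[idx] <- TRUE
        } else {
          drop[idx[which.min(w)]] <- TRUE
        }
      }
    }
  }
  edges <- edges[!drop, , drop = FALSE]
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  edges$sign <- sign(edges$weight)
  structure(
    list(edges = edges, threshold = threshold, comparator = comparator,
         factor_ids = ids),
    class = "tfa_network"
  )
}

#' @export
print.tfa_network <- function(x, ...) {
  cat(sprintf("<tfa_network> %d edges (|T| %s %g; %d self-loops)\n",
              nrow(x$edges), x$comparator, x$threshold,
              sum(x$edges$self_loop)))
  invisible(x)
}

network_export_edges <- function(network, include_self_loops = FALSE) {
  edges <- network$edges
  if (!include_self_loops) edges <- edges[!edges$self_loop, , drop = FALSE]
  edges
}

#' Export a regulatory network to a file
#'
#' Writes the network as an edge-list TSV (lossless; read back with
#' [read_network_tsv()]), GraphML, or DOT. Node ordering is deterministic
#' (sorted factor identifiers). Self-loops are excluded by default.
#'
#' @param network A `tfa_network` object.
#' @param path Output path.
#' @param format `"edgelist"`, `"graphml"` or `"dot"`.
#' @param include_self_loops Include self-loops (default `FALSE`).
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("edgelist", "graphml", "dot"),
                           include_self_loops = FALSE) {
  format <- match.arg(format)
  edges <- network_export_edges(network, include_self_loops)
  if (format == "edgelist") {
    lines <- c(
      "from\tto\tweight\tsign",
      vapply(seq_len(nrow(edges)), function(i) {
        paste(edges$from[i], edges$to[i], fmt_num(edges$weight[i]),
              fmt_num(edges$sign[i]), sep = "\t")
      }, character(1))
    )
    writeLines(lines, path)
    return(invisible(path))
  }
  nodes <- sort(unique(c(edges$from, edges$to)))
  if (length(nodes) == 0) nodes <- character(0)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight", "sign")],
    directed = TRUE,
    vertices = data.frame(name = nodes)
  )
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Read an edge-list TSV back into a network
#'
#' @param path Path written by [export_network()] with
#'   `format = "edgelist"`.
#' @param threshold Threshold to record on the object (default the
#'   smallest |weight| present, or `NA` for an empty file).
#' @return A `tfa_network` object.
#' @export
read_network_tsv <- function(path, threshold = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  edges <- tibble::tibble(
    from = as.character(df$from),
    to = as.character(df$to),
    weight = as.numeric(df$weight),
    self_loop = df$from == df$to,
    tie = FALSE,
    sign = sign(as.numeric(df$weight))
  )
  if (is.null(threshold)) {
    threshold <- if (nrow(edges)) min(abs(edges$weight)) else NA_real_
  }
  structure(
    list(edges = edges, threshold = threshold, comparator = ">=",
         factor_ids = sort(unique(c(edges$from, edges$to)))),
    class = "tfa_network"
  )
}
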