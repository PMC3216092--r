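#' Hierarchically cluster activity profiles on their absolute values
#'
#' Factors are clustered on |alpha| profiles because activators and
#' repressors in the same regulatory group can carry sign-flipped activity
#' curves; taking absolute values first makes a profile and its negation
#' identical, so such pairs merge at height zero. Defaults are Euclidean
#' distance with average linkage.
#'
#' @param activity A `tfa_activity` object or factors x time matrix.
#' @param n_clusters Number of flat clusters to cut (default 2).
#' @param metric A [stats::dist()] method (default `"euclidean"`).
#' @param linkage A [stats::hclust()] method (default `"average"`).
#' @return An object of class `tfa_clustering`: list with `hclust` (the
#'   merge tree), `labels` (named integer vector), `tf_ids`, `n_clusters`,
#'   `metric`, `linkage`.
#' @export
cluster_profiles <- function(activity, n_clusters = 2,
                             metric = "euclidean", linkage = "average") {
  mat <- activity_to_matrix(activity)
  if (n_clusters < 1) stop("`n_clusters` must be at least 1", call. = FALSE)
  if (n_clusters > nrow(mat)) {
    stop("cannot cut ", nrow(mat), " profiles into ", n_clusters,
         " clusters", call. = FALSE)
  }
  d <- dist(abs(mat), method = metric)
  tree <- hclust(d, method = linkage)
  labels <- cutree(tree, k = n_clusters)
  structure(
    list(hclust = tree, labels = labels, tf_ids = rownames(mat),
         n_clusters = n_clusters, metric = metric, linkage = linkage),
    class = "tfa_clustering"
  )
}

#' @export
print.tfa_clustering <- function(x, ...) {
  cat(sprintf("<tfa_clustering> %d profiles, %d clusters (%s, %s linkage)\n",
              length(x$tf_ids), x$n_clusters, x$metric, x$linkage))
  invisible(x)
}

#' Mean absolute-activity curve of a cluster
#'
#' The elementwise mean of the |alpha| rows of the member factors — the
#' single summary curve used to display a cluster of sign-mixed profiles.
#'
#' @param activity A `tfa_activity` object or factors x time matrix.
#' @param member_ids Character vector of member factor identifiers.
#' @return Numeric vector, one value per time point.
#' @export
cluster_mean_profile <- function(activity, member_ids) {
  mat <- activity_to_matrix(activity)
  if (length(member_ids) == 0) stop("empty member set", call. = FALSE)
  missing_ids <- setdiff(member_ids, rownames(mat))
  if (length(missing_ids)) {
    stop("unknown factors: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  colMeans(abs(mat[member_ids, , drop = FALSE]))
}
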