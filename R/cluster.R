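## DBSCAN clustering of reference-channel localizations with the
## cluster-morphology constraints used for RyR2 cluster analysis.

#' Clustering parameters
#'
#' Defaults follow the standard RyR2 analysis: search distance (eps) 100 nm,
#' at least 10 localizations per cluster, cluster span (furthest-pair
#' distance) between 50 and 800 nm inclusive, and in 3-D at most 1,000
#' localizations per cluster. `small_mode` switches to the small-cluster
#' pass: DBSCAN is run with `min_pts = 4` and only clusters of 4-9
#' localizations are retained (span bounds still apply).
#'
#' @param eps DBSCAN search distance, nm.
#' @param min_pts minimum points in a closed eps-neighborhood (the point
#'   itself counts) for a core point. Forced to 4 in `small_mode`.
#' @param span_min,span_max inclusive bounds on cluster span, nm.
#' @param max_locs maximum localizations per cluster, or `Inf` for no limit
#'   (the 2-D default; use 1000 for the 3-D pass, see
#'   [cluster_params_default()]).
#' @param small_mode logical; small-cluster pass (retain 4-9 localizations).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(eps = 100, min_pts = 10, span_min = 50,
                           span_max = 800, max_locs = Inf,
                           small_mode = FALSE) {
  if (small_mode) min_pts <- 4L
  .assert(eps > 0, "eps must be > 0")
  .assert(.is_count(min_pts) && min_pts >= 1, "min_pts must be a count >= 1")
  .assert(span_min >= 0 && span_min < span_max,
          "need 0 <= span_min < span_max")
  .assert(is.infinite(max_locs) || (.is_count(max_locs) &&
                                      max_locs >= min_pts),
          "max_locs must be >= min_pts (or Inf)")
  structure(list(eps = eps, min_pts = as.integer(min_pts),
                 span_min = span_min, span_max = span_max,
                 max_locs = max_locs, small_mode = isTRUE(small_mode)),
            class = "cluster_params")
}

#' Default clustering parameters per dimensionality
#'
#' 2-D: no per-cluster localization cap. 3-D: cap at 1,000 localizations.
#'
#' @param dimensionality 2 or 3.
#' @param small_mode logical, see [cluster_params()].
#' @return A [cluster_params()].
#' @export
cluster_params_default <- function(dimensionality = 2, small_mode = FALSE) {
  cluster_params(max_locs = if (dimensionality == 3) 1000 else Inf,
                 small_mode = small_mode)
}

#' DBSCAN labels with deterministic border assignment
#'
#' Classic DBSCAN with Euclidean distance: a point is core iff its closed
#' eps-neighborhood (itself included) holds at least `min_pts` points;
#' clusters are maximal density-connected sets. Border points join the
#' cluster of the lowest-index core point that reaches them, and labels are
#' contiguous integers `0, 1, ...` in order of each cluster's first core
#' point; noise is `-1`. These tie-break rules make the labeling a pure
#' function of the input order.
#'
#' @param points numeric matrix of coordinates (nm), 2 or 3 columns.
#' @param eps search distance, nm.
#' @param min_pts core-point threshold (the point itself counts).
#' @return Integer vector of labels, one per row of `points`.
#' @export
dbscan_labels <- function(points, eps, min_pts) {
  points <- as.matrix(points)
  if (nrow(points) == 0) return(integer(0))
  .assert(all(is.finite(points)), "coordinates must be finite")
  .assert(eps > 0, "eps must be > 0")
  storage.mode(points) <- "double"
  .dbscan_labels_cpp(points, eps, as.integer(min_pts))
}

#' Cluster span: distance between the furthest two member localizations
#'
#' @param members coordinate matrix (>= 1 row). A single point has span 0.
#' @return Maximum pairwise Euclidean distance, nm.
#' @export
cluster_span <- function(members) {
  members <- as.matrix(members)
  n <- nrow(members)
  .assert(n >= 1, "empty point set")
  if (n == 1) return(0)
  if (ncol(members) == 2 && n > 3) {
    h <- chull(members[, 1], members[, 2])
    members <- members[h, , drop = FALSE]
    n <- nrow(members)
  }
  d2 <- .cross_dist2(members, members)
  sqrt(max(d2))
}

#' Cluster centroid: unweighted per-axis mean of member coordinates
#'
#' @param members coordinate matrix (>= 1 row).
#' @return Numeric vector (x, y\[, z\]) in nm.
#' @export
cluster_centroid <- function(members) {
  members <- as.matrix(members)
  .assert(nrow(members) >= 1, "empty point set")
  colMeans(members)
}

#' Detect reference-channel clusters and apply morphology constraints
#'
#' Runs [dbscan_labels()] on the reference-channel localizations, forms
#' candidate clusters, and discards any candidate whose span falls outside
#' `[span_min, span_max]` or whose localization count exceeds `max_locs`.
#' In `small_mode` only candidates with 4-9 localizations are retained.
#' Per-cluster metrics (count, centroid, span, convex-hull measure) are
#' computed for retained clusters, and `n_clustered_locs` counts retained
#' members only.
#'
#' @param table a [loc_table()] containing *only* reference-channel
#'   localizations (split channels first, e.g. with [channel_table()]).
#' @param params a [cluster_params()].
#' @return A `cluster_set`: list with `clusters` (data frame: id, n_locs,
#'   centroid coordinates, span, hull_measure), `members` (list of row
#'   indices into `table`), `labels` (raw DBSCAN labels), counts and params.
#' @export
build_clusters <- function(table, params = cluster_params()) {
  ch <- attr(table, "channels")
  .assert(!any(table$channel == ch[["partner"]]),
          "table contains partner-channel records; split channels first")
  d <- .loc_dim(table)
  cc <- .loc_coords(table)
  labels <- dbscan_labels(cc, params$eps, params$min_pts)

  ids <- integer(0)
  if (length(labels)) ids <- sort(unique(labels[labels >= 0]))
  rows <- list()
  members <- list()
  for (lab in ids) {
    idx <- which(labels == lab)
    n_locs <- length(idx)
    pts <- cc[idx, , drop = FALSE]
    span <- cluster_span(pts)
    if (span < params$span_min || span > params$span_max) next
    if (n_locs > params$max_locs) next
    if (params$small_mode && (n_locs < 4 || n_locs > 9)) next
    cen <- cluster_centroid(pts)
    rows[[length(rows) + 1L]] <- c(lab, n_locs, cen, span, cluster_hull(pts))
    members[[length(members) + 1L]] <- idx
  }
  cn <- c("label", "n_locs", if (d == 3) c("cx", "cy", "cz") else c("cx", "cy"),
          "span", "hull_measure")
  clusters <- if (length(rows)) {
    df <- as.data.frame(do.call(rbind, rows))
    names(df) <- cn
    df$id <- seq_len(nrow(df))
    df[, c("id", cn)]
  } else {
    df <- as.data.frame(matrix(numeric(), 0, length(cn) + 1))
    names(df) <- c("id", cn)
    df
  }
  structure(list(clusters = clusters, members = members, labels = labels,
                 n_input_locs = nrow(table),
                 n_clustered_locs = if (nrow(clusters))
                   sum(clusters$n_locs) else 0L,
                 dimensionality = d, params = params),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "<cluster_set> %d clusters (%d-D), %d of %d localizations clustered\n",
    nrow(x$clusters), x$dimensionality, x$n_clustered_locs, x$n_input_locs))
  if (nrow(x$clusters)) {
    cat(sprintf("  n_locs: median %.0f [%.0f, %.0f]; span: mean %.0f nm\n",
                median(x$clusters$n_locs), min(x$clusters$n_locs),
                max(x$clusters$n_locs), mean(x$clusters$span)))
  }
  invisible(x)
}

#' Cluster centroids as a matrix
#'
#' @param clusters a `cluster_set`.
#' @return Numeric matrix of centroid coordinates (one row per cluster).
#' @export
cluster_centroids <- function(clusters) {
  cols <- if (clusters$dimensionality == 3) c("cx", "cy", "cz")
          else c("cx", "cy")
  as.matrix(clusters$clusters[, cols, drop = FALSE])
}

#' Serialize a cluster set to CSV
#'
#' One row per retained cluster: id, n_locs, centroid coordinates, span,
#' hull_measure.
#' @param clusters a `cluster_set`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_clusters <- function(clusters, path) {
  write.csv(clusters$clusters, path, row.names = FALSE)
  invisible(path)
}
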