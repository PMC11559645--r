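## Partner-channel colocalization: count partner localizations within a
## fixed search radius (circle in 2-D, sphere in 3-D) of each reference
## cluster centroid.

#' Colocalization parameters
#'
#' @param radius search radius around each cluster centroid, nm
#'   (default 210; boundary inclusive).
#' @param unique_assignment if `TRUE`, each partner localization is counted
#'   for its nearest centroid only (sensitivity analysis); the default
#'   (`FALSE`) counts a localization once per search region containing it,
#'   the literal reading of per-cluster counting.
#' @return A `coloc_params` list.
#' @export
coloc_params <- function(radius = 210, unique_assignment = FALSE) {
  .assert(is.numeric(radius) && radius > 0, "radius must be > 0")
  structure(list(radius = radius,
                 unique_assignment = isTRUE(unique_assignment)),
            class = "coloc_params")
}

#' Count partner localizations around each cluster centroid
#'
#' For every retained cluster, counts partner-channel localizations with
#' Euclidean distance `<= radius` from the centroid. Overlapping search
#' regions double-count shared localizations unless
#' `params$unique_assignment` is set.
#'
#' @param clusters a `cluster_set` (see [build_clusters()]).
#' @param partner_points coordinate matrix of partner-channel
#'   localizations, or a partner-channel [loc_table()].
#' @param params a [coloc_params()].
#' @return A `coloc_result`: list with `per_cluster_counts` (aligned with
#'   cluster order), `empty_fraction` (% clusters with count 0),
#'   `mean_count`, `ratio_per_cluster` (partner count / reference n_locs),
#'   `mean_ratio`, `ratio_of_means`, `partner_in_search_fraction` (% of all
#'   partner localizations inside the union of search regions) and
#'   `n_partner_total`. With zero clusters the fractions are `NA` and
#'   `defined` is `FALSE`.
#' @export
count_partners <- function(clusters, partner_points,
                           params = coloc_params()) {
  if (inherits(partner_points, "loc_table")) {
    .assert(.loc_dim(partner_points) == clusters$dimensionality,
            "partner table dimensionality mismatch")
    partner_points <- .loc_coords(partner_points)
  }
  partner_points <- as.matrix(partner_points)
  if (nrow(partner_points))
    .assert(ncol(partner_points) == clusters$dimensionality,
            "partner points must share the clusters' dimensionality")
  n_clust <- nrow(clusters$clusters)
  n_partner <- nrow(partner_points)

  if (n_clust == 0) {
    return(structure(list(per_cluster_counts = integer(0),
                          empty_fraction = NA_real_, mean_count = NA_real_,
                          ratio_per_cluster = numeric(0),
                          mean_ratio = NA_real_, ratio_of_means = NA_real_,
                          partner_in_search_fraction = NA_real_,
                          n_partner_total = n_partner,
                          radius = params$radius, defined = FALSE),
                     class = "coloc_result"))
  }

  cen <- cluster_centroids(clusters)
  r2 <- params$radius^2
  counts <- integer(n_clust)
  inside_any <- logical(n_partner)
  if (n_partner > 0) {
    ## chunk over clusters to bound the distance-matrix size
    chunk <- max(1L, floor(4e6 / n_partner))
    for (s in seq(1L, n_clust, by = chunk)) {
      e <- min(n_clust, s + chunk - 1L)
      d2 <- .cross_dist2(cen[s:e, , drop = FALSE], partner_points)
      within <- d2 <= r2
      if (params$unique_assignment) {
        ## nearest centroid (global) wins; resolve after the loop
        counts[s:e] <- 0L
      } else {
        counts[s:e] <- as.integer(rowSums(within))
      }
      inside_any <- inside_any | colSums(within) > 0
    }
    if (params$unique_assignment) {
      d2all <- .cross_dist2(partner_points, cen)
      nearest <- max.col(-d2all, ties.method = "first")
      ok <- d2all[cbind(seq_len(n_partner), nearest)] <= r2
      tab <- tabulate(nearest[ok], nbins = n_clust)
      counts <- as.integer(tab)
    }
  }
  ratio <- counts / clusters$clusters$n_locs
  structure(list(per_cluster_counts = counts,
                 empty_fraction = 100 * mean(counts == 0),
                 mean_count = mean(counts),
                 ratio_per_cluster = ratio,
                 mean_ratio = mean(ratio),
                 ratio_of_means = sum(counts) / sum(clusters$clusters$n_locs),
                 partner_in_search_fraction =
                   if (n_partner > 0) 100 * mean(inside_any) else NA_real_,
                 n_partner_total = n_partner,
                 radius = params$radius, defined = TRUE),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d clusters, radius %g nm\n",
              length(x$per_cluster_counts), x$radius))
  if (isTRUE(x$defined)) {
    cat(sprintf("  mean partner count %.2f; empty clusters %.1f%%; %s\n",
                x$mean_count, x$empty_fraction,
                if (is.na(x$partner_in_search_fraction)) "no partner points"
                else sprintf("%.1f%% of partner locs in search regions",
                             x$partner_in_search_fraction)))
  } else cat("  undefined (zero clusters)\n")
  invisible(x)
}

#' Percentage of clusters with no partner localization
#'
#' @param result a `coloc_result` from [count_partners()].
#' @return `100 * #\{count == 0\} / #clusters`.
#' @export
empty_cluster_percentage <- function(result) {
  .assert(length(result$per_cluster_counts) >= 1,
          "undefined for zero clusters")
  100 * mean(result$per_cluster_counts == 0)
}
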