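## Nearest-neighbor distances between cluster centroids, size-binned
## summaries and NND frequency distributions.

#' Nearest-neighbor distances between cluster centroids
#'
#' For each cluster, the Euclidean distance from its centroid to the
#' nearest other cluster centroid within the same ROI.
#'
#' @param clusters a `cluster_set` with at least 2 clusters.
#' @return An `nnd_result`: list with `per_cluster_nnd` (aligned with
#'   cluster order), `mean_nnd` and `median_nnd`, all in nm.
#' @export
nearest_neighbor_distances <- function(clusters) {
  cen <- cluster_centroids(clusters)
  n <- nrow(cen)
  .assert(n >= 2, "need at least 2 clusters for NND")
  d2 <- .cross_dist2(cen, cen)
  diag(d2) <- Inf
  nnd <- sqrt(apply(d2, 1, min))
  structure(list(per_cluster_nnd = nnd, mean_nnd = mean(nnd),
                 median_nnd = median(nnd)),
            class = "nnd_result")
}

#' @export
print.nnd_result <- function(x, ...) {
  cat(sprintf("<nnd_result> %d clusters: mean %.1f nm, median %.1f nm\n",
              length(x$per_cluster_nnd), x$mean_nnd, x$median_nnd))
  invisible(x)
}

#' Binning specification for size and NND histograms
#'
#' Cluster sizes are binned by localization count in half-open bins of
#' `size_bin_width` starting at 0 up to `size_bin_max`; NNDs in half-open
#' bins of `nnd_bin_width` up to `nnd_bin_max`. Values beyond the maximum
#' go to an overflow bin (default) or are excluded.
#'
#' @param size_bin_width bin width in localizations (default 25).
#' @param size_bin_max upper edge of the last regular bin (default 400).
#' @param size_overflow `"overflow-bin"` (default) or `"exclude"`.
#' @param nnd_bin_width NND bin width, nm (default 100).
#' @param nnd_bin_max upper edge of the last regular NND bin (default 2000).
#' @return A `bin_spec` list.
#' @export
bin_spec <- function(size_bin_width = 25, size_bin_max = 400,
                     size_overflow = c("overflow-bin", "exclude"),
                     nnd_bin_width = 100, nnd_bin_max = 2000) {
  size_overflow <- match.arg(size_overflow)
  .assert(size_bin_width > 0 && nnd_bin_width > 0, "bin widths must be > 0")
  .assert(size_bin_max %% size_bin_width == 0,
          "size_bin_max must be a multiple of size_bin_width")
  .assert(nnd_bin_max %% nnd_bin_width == 0,
          "nnd_bin_max must be a multiple of nnd_bin_width")
  structure(list(size_bin_width = size_bin_width,
                 size_bin_max = size_bin_max, size_overflow = size_overflow,
                 nnd_bin_width = nnd_bin_width, nnd_bin_max = nnd_bin_max),
            class = "bin_spec")
}

## half-open bin index: values in [k*w, (k+1)*w) -> k+1; >= vmax -> overflow
.bin_index <- function(values, width, vmax) {
  k <- floor(values / width) + 1L
  nreg <- vmax / width
  k[values >= vmax] <- nreg + 1L
  as.integer(k)
}

.bin_labels <- function(width, vmax) {
  nreg <- vmax / width
  lo <- (seq_len(nreg) - 1L) * width
  c(sprintf("[%g,%g)", lo, lo + width), sprintf("%g+", vmax))
}

#' Size-binned cluster summaries
#'
#' Bins retained clusters by localization count (half-open bins) and
#' reports, per bin, the cluster count and the mean partner count and/or
#' mean NND when supplied. Empty bins carry count 0 and `NA` means.
#'
#' @param clusters a `cluster_set`.
#' @param partner optional `coloc_result` aligned with the cluster order.
#' @param nnd optional `nnd_result` aligned with the cluster order.
#' @param spec a [bin_spec()].
#' @return Data frame: bin label, lower/upper edge, n_clusters,
#'   mean_partner, mean_nnd.
#' @export
bin_by_cluster_size <- function(clusters, partner = NULL, nnd = NULL,
                                spec = bin_spec()) {
  sizes <- clusters$clusters$n_locs
  n <- length(sizes)
  if (!is.null(partner))
    .assert(length(partner$per_cluster_counts) == n,
            "partner counts do not match cluster count")
  if (!is.null(nnd))
    .assert(length(nnd$per_cluster_nnd) == n,
            "NND values do not match cluster count")
  nreg <- spec$size_bin_max / spec$size_bin_width
  nbin <- nreg + 1L
  idx <- if (n) .bin_index(sizes, spec$size_bin_width, spec$size_bin_max)
         else integer(0)
  keep <- rep(TRUE, n)
  if (spec$size_overflow == "exclude") keep <- idx <= nreg
  idx <- idx[keep]
  counts <- tabulate(idx, nbins = nbin)
  mean_in_bin <- function(values) {
    vapply(seq_len(nbin), function(b) {
      v <- values[keep][idx == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  lab <- .bin_labels(spec$size_bin_width, spec$size_bin_max)
  out <- data.frame(
    bin = lab,
    lower = c((seq_len(nreg) - 1L) * spec$size_bin_width, spec$size_bin_max),
    upper = c(seq_len(nreg) * spec$size_bin_width, Inf),
    n_clusters = counts)
  out$mean_partner <- if (is.null(partner)) NA_real_
                      else mean_in_bin(partner$per_cluster_counts)
  out$mean_nnd <- if (is.null(nnd)) NA_real_
                  else mean_in_bin(nnd$per_cluster_nnd)
  if (spec$size_overflow == "exclude") out <- out[seq_len(nreg), ]
  out
}

#' Relative frequency distribution of NNDs
#'
#' Half-open NND bins of `nnd_bin_width` up to `nnd_bin_max` plus an
#' overflow bin; frequencies sum to 1 over all clusters. The modal bin is
#' attached as attribute `modal_bin` (lowest bin wins ties).
#'
#' @param nnd an `nnd_result` with at least one value.
#' @param spec a [bin_spec()].
#' @return Data frame: bin label, lower/upper edge, count, frequency; with
#'   attribute `modal_bin` (the label of the most populated bin).
#' @export
nnd_frequency_distribution <- function(nnd, spec = bin_spec()) {
  values <- nnd$per_cluster_nnd
  .assert(length(values) >= 1, "need at least one NND value")
  nreg <- spec$nnd_bin_max / spec$nnd_bin_width
  nbin <- nreg + 1L
  idx <- .bin_index(values, spec$nnd_bin_width, spec$nnd_bin_max)
  counts <- tabulate(idx, nbins = nbin)
  lab <- .bin_labels(spec$nnd_bin_width, spec$nnd_bin_max)
  out <- data.frame(
    bin = lab,
    lower = c((seq_len(nreg) - 1L) * spec$nnd_bin_width, spec$nnd_bin_max),
    upper = c(seq_len(nreg) * spec$nnd_bin_width, Inf),
    count = counts,
    frequency = counts / sum(counts))
  attr(out, "modal_bin") <- lab[which.max(counts)]
  out
}
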