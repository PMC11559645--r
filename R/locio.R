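## Localization tables -------------------------------------------------------
##
## A `loc_table` is a data frame with one row per localization (blink event)
## and columns x, y (z for 3-D) in nanometres, channel, frame and fit_p
## (the per-localization fit-quality p-value from the instrument's Gaussian
## fit; NA when the source did not export one). Two attributes carry the
## table-level contract: `dimensionality` (2 or 3) and `channels`, a named
## two-element character vector declaring which channel label is the
## reference protein (RyR2) and which the colocalization partner
## (Jph2 or CaV1.2). `metadata` holds cell/animal/group identifiers.

#' Construct a localization table
#'
#' @param coords numeric matrix or data frame of coordinates in nm, with 2
#'   (x, y) or 3 (x, y, z) columns.
#' @param channel character vector of channel labels, one per localization.
#' @param channels named character vector `c(reference = , partner = )`
#'   declaring the two channel labels. Defaults to
#'   `c(reference = "reference", partner = "partner")`.
#' @param frame optional non-negative integer frame indices.
#' @param fit_p optional fit-quality p-values in `[0, 1]` (NA allowed).
#' @param metadata named list of table-level identifiers (cell, animal,
#'   group, ...).
#' @return A `loc_table`: data frame with columns x, y (z), channel, frame,
#'   fit_p and attributes `dimensionality`, `channels`, `metadata`.
#' @export
loc_table <- function(coords, channel,
                      channels = c(reference = "reference",
                                   partner = "partner"),
                      frame = NULL, fit_p = NULL, metadata = list()) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (nrow(coords) > 0) storage.mode(coords) <- "double"
  d <- ncol(coords)
  .assert(d %in% c(2L, 3L), "coords must have 2 or 3 columns, got %d", d)
  n <- nrow(coords)
  .assert(n == 0 || all(is.finite(coords)),
          "all coordinates must be finite numbers")
  channel <- as.character(channel)
  .assert(length(channel) == n, "channel must have one entry per row")
  .assert(is.character(channels) && length(channels) == 2 &&
            setequal(names(channels), c("reference", "partner")) &&
            channels[["reference"]] != channels[["partner"]],
          "channels must be c(reference = , partner = ) with distinct labels")
  .assert(n == 0 || all(channel %in% channels),
          "channel labels must be drawn from the declared two-element set")
  if (is.null(frame)) frame <- rep(NA_integer_, n)
  frame <- as.integer(frame)
  .assert(length(frame) == n, "frame must have one entry per row")
  .assert(all(is.na(frame) | frame >= 0), "frame indices must be >= 0")
  if (is.null(fit_p)) fit_p <- rep(NA_real_, n)
  fit_p <- as.double(fit_p)
  .assert(length(fit_p) == n, "fit_p must have one entry per row")
  .assert(all(is.na(fit_p) | (fit_p >= 0 & fit_p <= 1)),
          "fit_p must lie in [0, 1]")

  df <- data.frame(x = if (n) coords[, 1] else double(),
                   y = if (n) coords[, 2] else double())
  if (d == 3L) df$z <- if (n) coords[, 3] else double()
  df$channel <- channel
  df$frame <- frame
  df$fit_p <- fit_p
  structure(df,
            dimensionality = d,
            channels = channels,
            metadata = metadata,
            class = c("loc_table", "data.frame"))
}

#' @export
print.loc_table <- function(x, ...) {
  ch <- attr(x, "channels")
  cat(sprintf("<loc_table> %d localizations, %d-D\n", nrow(x),
              attr(x, "dimensionality")))
  cat(sprintf("  reference channel: %s (%d), partner channel: %s (%d)\n",
              ch[["reference"]], sum(x$channel == ch[["reference"]]),
              ch[["partner"]], sum(x$channel == ch[["partner"]])))
  md <- attr(x, "metadata")
  if (length(md))
    cat("  metadata:", paste(names(md), unlist(md), sep = "=",
                             collapse = ", "), "\n")
  if (nrow(x)) print(head(as.data.frame(x), 4L))
  invisible(x)
}

.loc_dim <- function(table) attr(table, "dimensionality")

.coord_cols <- function(table) {
  if (.loc_dim(table) == 3L) c("x", "y", "z") else c("x", "y")
}

.loc_coords <- function(table) {
  as.matrix(as.data.frame(table)[, .coord_cols(table), drop = FALSE])
}

## rebuild a loc_table from a row subset, preserving attributes
.loc_subset <- function(table, keep, coords = NULL) {
  df <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(df) <- NULL
  cc <- if (is.null(coords)) as.matrix(df[, .coord_cols(table), drop = FALSE])
        else coords
  loc_table(cc, df$channel, channels = attr(table, "channels"),
            frame = df$frame, fit_p = df$fit_p,
            metadata = attr(table, "metadata"))
}

#' Extract one channel of a localization table
#'
#' @param table a [loc_table()].
#' @param role `"reference"` or `"partner"`.
#' @return A `loc_table` holding only that channel's localizations.
#' @export
channel_table <- function(table, role = c("reference", "partner")) {
  role <- match.arg(role)
  lab <- attr(table, "channels")[[role]]
  .loc_subset(table, table$channel == lab)
}

## Dialects -------------------------------------------------------------------

#' Column-name dialect for reading localization CSVs
#'
#' Maps the mandatory (x, y, channel) and optional (z, frame, fit_p) fields
#' onto the column names used by a particular exporter, and declares the
#' coordinate unit.
#'
#' @param x,y,z,channel,frame,fit_p column names in the source file; set a
#'   field to `NULL` if absent. `channel` may instead be supplied as a
#'   constant via `channel_value` when the file holds a single channel.
#' @param unit `"nm"`, `"um"` or `"px"`; coordinates are converted to nm.
#' @param pixel_size pixel size in nm, required when `unit = "px"`.
#' @param channel_value constant channel label used when the file has no
#'   channel column.
#' @return A `loc_dialect` list.
#' @export
loc_dialect <- function(x = "x_nm", y = "y_nm", z = "z_nm",
                        channel = "channel", frame = "frame",
                        fit_p = "fit_p", unit = c("nm", "um", "px"),
                        pixel_size = NULL, channel_value = NULL) {
  unit <- match.arg(unit)
  if (unit == "px")
    .assert(is.numeric(pixel_size) && pixel_size > 0,
            "pixel_size (nm) is required for unit = 'px'")
  structure(list(x = x, y = y, z = z, channel = channel, frame = frame,
                 fit_p = fit_p, unit = unit, pixel_size = pixel_size,
                 channel_value = channel_value),
            class = "loc_dialect")
}

#' ThunderSTORM-style dialect (`x [nm]`, `y [nm]`, `z [nm]`, `frame`)
#'
#' ThunderSTORM exports are single-channel; supply the channel label via
#' `channel_value`.
#' @param channel_value channel label to assign to every row.
#' @return A `loc_dialect`.
#' @export
dialect_thunderstorm <- function(channel_value = "reference") {
  loc_dialect(x = "x [nm]", y = "y [nm]", z = "z [nm]", channel = NULL,
              frame = "frame", fit_p = NULL, unit = "nm",
              channel_value = channel_value)
}

.unit_factor <- function(dialect) {
  switch(dialect$unit, nm = 1, um = 1000, px = dialect$pixel_size)
}

## Reading and writing --------------------------------------------------------

#' Read a localization table from CSV
#'
#' @param path CSV file path.
#' @param dialect a [loc_dialect()]; the default reads the canonical format
#'   written by [write_localizations()].
#' @param channels named vector `c(reference = , partner = )` declaring the
#'   channel roles, or `NULL` to infer the two-element label set from the
#'   file (first-seen label becomes the reference; declare explicitly
#'   whenever the roles matter downstream).
#' @param metadata passed to [loc_table()].
#' @return A [loc_table()]; row order of the file is preserved. An empty
#'   file (header only) yields an empty table.
#' @export
read_localizations <- function(path, dialect = loc_dialect(),
                               channels = NULL, metadata = list()) {
  .assert(file.exists(path), "file not found: %s", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("x", "y")) {
    .assert(!is.null(dialect[[col]]) && dialect[[col]] %in% names(raw),
            "missing mandatory column '%s' (dialect field '%s') in %s",
            if (is.null(dialect[[col]])) "<unmapped>" else dialect[[col]],
            col, path)
  }
  if (is.null(dialect$channel_value)) {
    .assert(!is.null(dialect$channel) && dialect$channel %in% names(raw),
            "missing mandatory column '%s' (dialect field 'channel') in %s",
            if (is.null(dialect$channel)) "<unmapped>" else dialect$channel,
            path)
  }
  n <- nrow(raw)
  has_z <- !is.null(dialect$z) && dialect$z %in% names(raw) &&
    (n == 0 || !all(is.na(raw[[dialect$z]])))
  getnum <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & is.na(v))
    .assert(length(bad) == 0,
            "non-numeric %s coordinate in %s at data row %d",
            what, path, if (length(bad)) bad[1] else 0L)
    v
  }
  f <- .unit_factor(dialect)
  xs <- getnum(dialect$x, "x") * f
  ys <- getnum(dialect$y, "y") * f
  bad <- which(is.na(xs) | is.na(ys))
  .assert(length(bad) == 0, "missing coordinate in %s at data row %d",
          path, if (length(bad)) bad[1] else 0L)
  coords <- cbind(x = xs, y = ys)
  if (has_z) {
    zs <- getnum(dialect$z, "z") * f
    .assert(!anyNA(zs), "missing z coordinate in %s", path)
    coords <- cbind(coords, z = zs)
  }
  channel <- if (!is.null(dialect$channel_value))
    rep(dialect$channel_value, n)
  else as.character(raw[[dialect$channel]])
  frame <- if (!is.null(dialect$frame) && dialect$frame %in% names(raw))
    as.integer(raw[[dialect$frame]]) else NULL
  fit_p <- if (!is.null(dialect$fit_p) && dialect$fit_p %in% names(raw))
    as.numeric(raw[[dialect$fit_p]]) else NULL
  if (n == 0) coords <- matrix(numeric(), 0, if (has_z) 3 else 2)
  if (is.null(channels)) {
    labs <- unique(channel)
    .assert(length(labs) <= 2, "more than two channel labels in %s", path)
    channels <- c(reference = if (length(labs) >= 1) labs[1] else "reference",
                  partner = if (length(labs) == 2) labs[2] else "partner")
    if (channels[["reference"]] == "partner")
      channels[["reference"]] <- "reference"   # degenerate single-label case
  }
  loc_table(coords, channel, channels = channels, frame = frame,
            fit_p = fit_p, metadata = metadata)
}

#' Write a localization table as canonical CSV
#'
#' Canonical headers are `x_nm, y_nm, z_nm, channel, frame, fit_p`
#' (no `z_nm` column for 2-D tables). [read_localizations()] with the
#' default dialect inverts it.
#'
#' @param table a [loc_table()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_localizations <- function(table, path) {
  df <- as.data.frame(table)
  out <- data.frame(x_nm = df$x, y_nm = df$y)
  if (.loc_dim(table) == 3L) out$z_nm <- df$z
  out$channel <- df$channel
  out$frame <- df$frame
  out$fit_p <- df$fit_p
  ## full precision so the round trip is exact for decimal-representable text
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out)) {
    cols <- lapply(out, function(v) {
      if (is.numeric(v)) {
        s <- formatC(v, format = "g", digits = 17)
        s[is.na(v)] <- ""
        trimws(s)
      } else as.character(v)
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

## Fit-quality filtering -------------------------------------------------------

#' Fit-quality filter parameters
#'
#' The instrument assigns each localization a p-value from the chi-square
#' assessment of its Gaussian fit; localizations of poor resolution get low
#' values. The standard protocol keeps partner-channel localizations with
#' p in \[0.25, 1\] and leaves the reference channel unfiltered.
#'
#' @param p_min,p_max inclusive bounds on fit_p (defaults 0.25, 1.0).
#' @param channels_filtered channel *roles* the filter applies to
#'   (default `"partner"`).
#' @return A `qc_params` list.
#' @export
qc_params <- function(p_min = 0.25, p_max = 1.0,
                      channels_filtered = "partner") {
  .assert(is.numeric(p_min) && is.numeric(p_max) &&
            p_min >= 0 && p_min <= p_max && p_max <= 1,
          "need 0 <= p_min <= p_max <= 1")
  .assert(all(channels_filtered %in% c("reference", "partner")),
          "channels_filtered must name channel roles")
  structure(list(p_min = p_min, p_max = p_max,
                 channels_filtered = channels_filtered),
            class = "qc_params")
}

#' Filter localizations by fit quality
#'
#' Localizations in filtered channels are retained iff
#' `p_min <= fit_p <= p_max` (both ends inclusive); a missing fit_p in a
#' filtered channel removes the record. Other channels pass unchanged.
#'
#' @param table a [loc_table()].
#' @param qc a [qc_params()].
#' @return The filtered `loc_table`, with attribute `qc_removed`: a named
#'   integer vector of removed counts per channel label.
#' @export
filter_by_fit_quality <- function(table, qc = qc_params()) {
  ch <- attr(table, "channels")
  filtered_labels <- unname(ch[qc$channels_filtered])
  in_filtered <- table$channel %in% filtered_labels
  ok <- !is.na(table$fit_p) & table$fit_p >= qc$p_min & table$fit_p <= qc$p_max
  keep <- !in_filtered | ok
  removed <- vapply(unname(ch), function(lab)
    sum(!keep & table$channel == lab), integer(1))
  out <- .loc_subset(table, keep)
  attr(out, "qc_removed") <- removed
  out
}

## Regions of interest ---------------------------------------------------------

#' Analysis region of interest
#'
#' An axis-aligned box of fixed measure: the standard analysis uses
#' 3.0e8 nm^2 in 2-D and 3.0e11 nm^3 in 3-D. Intervals are half-open,
#' `[origin, origin + extent)`, so tiled ROIs never double-count.
#'
#' @param origin numeric vector (x, y\[, z\]) in nm.
#' @param extent strictly positive numeric vector (dx, dy\[, dz\]) in nm.
#' @param target_measure expected area (2-D) or volume (3-D); the product of
#'   extents must match it within 1% relative. `NULL` skips the check.
#' @return An `roi_spec`.
#' @export
roi_spec <- function(origin, extent, target_measure = NULL) {
  .assert(length(origin) %in% c(2L, 3L) && length(extent) == length(origin),
          "origin and extent must both have length 2 or 3")
  .assert(all(is.finite(origin)) && all(is.finite(extent)) && all(extent > 0),
          "extents must be strictly positive finite numbers")
  measure <- prod(extent)
  if (!is.null(target_measure)) {
    .assert(abs(measure - target_measure) <= 0.01 * target_measure,
            "product of extents (%.4g) differs from target measure (%.4g) by more than 1%%",
            measure, target_measure)
  }
  structure(list(origin = as.double(origin), extent = as.double(extent),
                 measure = measure, dimensionality = length(origin)),
            class = "roi_spec")
}

#' Default ROI geometry
#'
#' 2-D: a square of side 17,320 nm (area 3.0e8 nm^2). 3-D: a box of
#' 14,142 x 14,142 x 1,500 nm (volume 3.0e11 nm^3); the 1,500 nm z extent
#' matches the short axial capture range of astigmatic 3-D STORM.
#'
#' @param dimensionality 2 or 3.
#' @param origin box origin, default the coordinate origin.
#' @return An [roi_spec()].
#' @export
roi_spec_default <- function(dimensionality = 2, origin = NULL) {
  if (dimensionality == 2) {
    if (is.null(origin)) origin <- c(0, 0)
    roi_spec(origin, c(17320, 17320), target_measure = 3.0e8)
  } else {
    if (is.null(origin)) origin <- c(0, 0, 0)
    roi_spec(origin, c(14142, 14142, 1500), target_measure = 3.0e11)
  }
}

#' Crop a localization table to an ROI
#'
#' Retains localizations with `origin <= coord < origin + extent` on every
#' axis and re-expresses coordinates relative to the ROI origin.
#'
#' @param table a [loc_table()].
#' @param roi an [roi_spec()] of matching dimensionality.
#' @return The cropped `loc_table` (coordinates relative to the ROI origin).
#' @export
crop_roi <- function(table, roi) {
  d <- .loc_dim(table)
  .assert(roi$dimensionality == d,
          "ROI is %d-D but table is %d-D", roi$dimensionality, d)
  cc <- .loc_coords(table)
  keep <- rep(TRUE, nrow(cc))
  for (a in seq_len(d)) {
    keep <- keep & cc[, a] >= roi$origin[a] &
      cc[, a] < roi$origin[a] + roi$extent[a]
  }
  shifted <- sweep(cc[keep, , drop = FALSE], 2, roi$origin, "-")
  .loc_subset(table, keep, coords = shifted)
}

#' Propose analysis ROIs by reference-density grid search
#'
#' A deterministic stand-in for manual ROI placement: candidate origins on a
#' regular grid are scored by contained reference-channel localization
#' count; ROIs are selected greedily (highest count first), must be mutually
#' disjoint, and must keep `margin` clearance from the table's bounding box.
#' Grid ties break toward the lowest origin coordinates.
#'
#' @param table a [loc_table()] (non-empty).
#' @param spec ROI template ([roi_spec()]); placed copies keep its extent.
#' @param n number of ROIs (default 2).
#' @param margin clearance from the bounding-box edge, nm.
#' @param step grid step in nm (default extent/20 per axis).
#' @return List of `n` [roi_spec()]s.
#' @export
propose_rois <- function(table, spec, n = 2, margin = 0, step = NULL) {
  .assert(nrow(table) > 0, "table is empty")
  d <- .loc_dim(table)
  .assert(spec$dimensionality == d, "ROI template dimensionality mismatch")
  ref <- channel_table(table, "reference")
  cc <- .loc_coords(ref)
  lo <- apply(.loc_coords(table), 2, min)
  hi <- apply(.loc_coords(table), 2, max)
  avail <- hi - lo - 2 * margin - spec$extent
  .assert(all(avail >= 0),
          "ROI extent plus margins does not fit inside the bounding box")
  if (is.null(step)) step <- spec$extent / 20
  step <- rep(step, length.out = d)
  grids <- lapply(seq_len(d), function(a) {
    g <- seq(lo[a] + margin, lo[a] + margin + avail[a], by = step[a])
    if (g[length(g)] < lo[a] + margin + avail[a])
      g <- c(g, lo[a] + margin + avail[a])
    g
  })
  cand <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  ## candidate order = lowest origin first (expand.grid varies first axis
  ## fastest); stable greedy selection then breaks ties deterministically
  ord <- do.call(order, lapply(rev(seq_len(d)), function(a) cand[, a]))
  cand <- cand[ord, , drop = FALSE]
  counts <- vapply(seq_len(nrow(cand)), function(i) {
    inside <- rep(TRUE, nrow(cc))
    for (a in seq_len(d)) {
      inside <- inside & cc[, a] >= cand[i, a] &
        cc[, a] < cand[i, a] + spec$extent[a]
    }
    sum(inside)
  }, integer(1))
  chosen <- list()
  taken <- matrix(numeric(), 0, d)
  ok <- rep(TRUE, nrow(cand))
  for (k in seq_len(n)) {
    idx <- which(ok)
    .assert(length(idx) > 0, "geometry cannot fit %d disjoint ROIs", n)
    best <- idx[which.max(counts[idx])]
    org <- cand[best, ]
    chosen[[k]] <- roi_spec(org, spec$extent)
    ## disqualify overlapping candidates
    for (i in which(ok)) {
      overlaps <- all(abs(cand[i, ] - org) < spec$extent)
      if (overlaps) ok[i] <- FALSE
    }
  }
  chosen
}
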