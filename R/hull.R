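## Convex-hull measures of a cluster's member localizations.
## 2-D: polygon area via grDevices::chull + the shoelace formula.
## 3-D: volume via an incremental convex hull (visible-face deletion over a
## horizon, faces re-oriented against an interior point). Degenerate inputs
## (collinear in 2-D, coplanar or < 4 affinely independent points in 3-D)
## have measure 0 by convention.

.hull_area_2d <- function(pts) {
  if (nrow(pts) < 3) return(0)
  h <- chull(pts[, 1], pts[, 2])
  if (length(h) < 3) return(0)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

.hull_volume_3d <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4) return(0)
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1)
  tol <- 1e-9 * scale

  cross3 <- function(u, v) {
    c(u[2] * v[3] - u[3] * v[2],
      u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])
  }

  ## initial simplex: two extreme points, then max-area, then max-volume
  d0 <- .cross_dist2(pts[1, , drop = FALSE], pts)[1, ]
  i2 <- which.max(d0)
  if (d0[i2] <= tol^2) return(0)
  d1 <- .cross_dist2(pts[i2, , drop = FALSE], pts)[1, ]
  i1 <- which.max(pmin(d0, d1) + pmax(d0, d1))  # farthest pair heuristic
  a <- pts[i2, ]; b <- pts[i1, ]
  ab <- b - a
  cr <- t(apply(pts, 1, function(p) cross3(ab, p - a)))
  area2 <- rowSums(cr * cr)
  i3 <- which.max(area2)
  if (sqrt(area2[i3]) <= tol * scale) return(0)   # all collinear
  cpt <- pts[i3, ]
  nrm <- cross3(ab, cpt - a)
  vol6 <- abs(as.vector(pts %*% nrm) - sum(nrm * a))
  i4 <- which.max(vol6)
  if (vol6[i4] <= tol * scale^2) return(0)        # all coplanar
  dpt <- pts[i4, ]

  verts <- rbind(a, b, cpt, dpt)
  interior <- colMeans(verts)

  ## faces stored as index triples into `verts`; orientation fixed so the
  ## interior point lies on the negative side
  mk_face <- function(i, j, k) {
    v1 <- verts[i, ]; v2 <- verts[j, ]; v3 <- verts[k, ]
    nn <- cross3(v2 - v1, v3 - v1)
    if (sum(nn * (interior - v1)) > 0) {
      tmp <- j; j <- k; k <- tmp
      nn <- -nn
    }
    list(idx = c(i, j, k), normal = nn, off = sum(nn * verts[i, ]))
  }
  faces <- list(mk_face(1, 2, 3), mk_face(1, 2, 4),
                mk_face(1, 3, 4), mk_face(2, 3, 4))

  rest <- setdiff(seq_len(n), c(which.max(d0), i1, i3, i4))
  for (pi in rest) {
    p <- pts[pi, ]
    vis <- vapply(faces, function(f)
      sum(f$normal * p) - f$off > tol * sqrt(sum(f$normal^2)), logical(1))
    if (!any(vis)) next
    ## horizon: edges of visible faces not shared by two visible faces
    edges <- do.call(rbind, lapply(faces[vis], function(f) {
      i <- f$idx
      rbind(sort(c(i[1], i[2])), sort(c(i[2], i[3])), sort(c(i[1], i[3])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    if (nrow(horizon) == 0) next   # numerically flush point; skip
    verts <- rbind(verts, p)
    vi <- nrow(verts)
    faces <- faces[!vis]
    for (e in seq_len(nrow(horizon))) {
      faces[[length(faces) + 1L]] <- mk_face(horizon[e, 1], horizon[e, 2], vi)
    }
  }

  vol <- 0
  for (f in faces) {
    v1 <- verts[f$idx[1], ]; v2 <- verts[f$idx[2], ]; v3 <- verts[f$idx[3], ]
    vol <- vol + sum(cross3(v2 - v1, v3 - v1) * (v1 - interior)) / 6
  }
  abs(vol)
}

#' Convex-hull measure of a point set
#'
#' Area (nm^2) of the 2-D convex hull or volume (nm^3) of the 3-D convex
#' hull; this is the "cluster volume created by connecting the perimeter
#' localizations". Degenerate sets return 0.
#'
#' @param members numeric matrix of member coordinates (nm), one row per
#'   localization, 2 or 3 columns.
#' @return A single non-negative number.
#' @export
cluster_hull <- function(members) {
  members <- as.matrix(members)
  .assert(nrow(members) >= 1, "empty point set")
  if (ncol(members) == 2) .hull_area_2d(members)
  else if (ncol(members) == 3) .hull_volume_3d(members)
  else stop("members must have 2 or 3 columns")
}
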