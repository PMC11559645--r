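## Independent brute-force oracles. These deliberately share no code with
## the package internals: dense distance matrices, explicit loops, and (for
## the 3-D hull) exhaustive facet enumeration.

## Brute-force DBSCAN by literal density reachability:
## core = closed eps-neighborhood (self included) >= min_pts; clusters are
## connected components of the core-core eps graph; border points join the
## lowest-index core point within eps; labels numbered by first core index.
oracle_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(pts))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  labels <- rep(-1L, n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] >= 0) next
    ## flood fill over cores
    comp <- i
    repeat {
      grow <- which(core & labels < 0 &
                      apply(nb[, comp, drop = FALSE], 1, any))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    labels[comp] <- lab
    lab <- lab + 1L
  }
  for (j in which(!core)) {
    cands <- which(core & nb[j, ])
    if (length(cands)) labels[j] <- labels[min(cands)]
  }
  labels
}

oracle_span <- function(pts) {
  n <- nrow(pts)
  if (n == 1) return(0)
  best <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    best <- max(best, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  }
  best
}

oracle_nnd <- function(cen) {
  n <- nrow(cen)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      best <- min(best, sqrt(sum((cen[i, ] - cen[j, ])^2)))
    }
    out[i] <- best
  }
  out
}

oracle_count_partners <- function(cen, partner, radius) {
  out <- integer(nrow(cen))
  for (i in seq_len(nrow(cen))) {
    cnt <- 0L
    for (j in seq_len(nrow(partner))) {
      if (sqrt(sum((cen[i, ] - partner[j, ])^2)) <= radius) cnt <- cnt + 1L
    }
    out[i] <- cnt
  }
  out
}

## Exhaustive-facet 3-D convex hull volume for points in general position:
## every triple whose plane has all remaining points strictly on one side is
## a hull facet; the volume is the sum of signed tetrahedra against the
## point cloud's mean.
oracle_hull_volume <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  vol <- 0
  scale <- max(dist(pts))
  tol <- 1e-9 * scale
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c3 <- pts[k, ]
    nn <- cross3(b - a, c3 - a)
    nl <- sqrt(sum(nn^2))
    if (nl < tol * scale) next
    s <- as.vector(pts %*% nn) - sum(nn * a)
    pos <- any(s > tol * nl); neg <- any(s < -tol * nl)
    if (pos && neg) next            # not a facet
    ## orient outward (all other points on negative side)
    if (pos) nn <- -nn
    vol <- vol + sum(nn * (a - ctr)) / 6
  }
  abs(vol)
}

## closed-form one-way ANOVA F from sums of squares
oracle_anova_F <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

## label-invariant comparison of two clusterings (noise must agree exactly)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  ok <- a != -1L
  ta <- paste(a[ok]); tb <- paste(b[ok])
  m1 <- tapply(tb, ta, function(v) length(unique(v)))
  m2 <- tapply(ta, tb, function(v) length(unique(v)))
  all(m1 == 1) && all(m2 == 1)
}
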