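## Seed plumbing -------------------------------------------------------------

## Every stochastic stage draws from its own substream, derived
## deterministically from (seed, stage label), so that stages can be
## reproduced in isolation and adding draws to one stage does not perturb
## the next. The mix is a 32-bit FNV-style hash kept inside R's integer range.
.substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 131 + ch) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

## Evaluate expr with a local RNG state seeded from (seed, label); the
## caller's .Random.seed is restored afterwards.
.with_seed <- function(seed, label, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(.substream_seed(seed, label))
  expr
}

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

## Pairwise squared distances from each row of `a` to each row of `b`
## (both matrices with matching column count). Returns |a| x |b| matrix.
.cross_dist2 <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
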