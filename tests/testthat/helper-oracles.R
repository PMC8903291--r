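# Shared test helpers: independent oracles and matching utilities.

# Greedy one-to-one matching of detections to ground-truth positions.
# Returns tp/fp/fn counts and matched distances.
match_detections <- function(det, truth, max_dist_px = 3) {
  used <- rep(FALSE, nrow(det))
  tp <- 0L; fn <- 0L; dists <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    if (nrow(det) == 0L) { fn <- fn + 1L; next }
    d <- sqrt((det$y - truth$y[i])^2 + (det$x - truth$x[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= max_dist_px) {
      tp <- tp + 1L; used[j] <- TRUE; dists <- c(dists, d[j])
    } else {
      fn <- fn + 1L
    }
  }
  list(tp = tp, fn = fn, fp = sum(!used), dists = dists)
}

# Brute-force Pearson correlation straight from the covariance definition.
pearson_bruteforce <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) /
    sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# Brute-force grayscale opening with a spherical-cap structuring element,
# written independently of the package implementation (plain double loop).
opening_bruteforce <- function(img, radius, scale = 0.5) {
  r <- ceiling(radius)
  off <- seq(-r, r)
  d2 <- outer(off^2, off^2, "+")
  on <- d2 <= radius^2
  h <- matrix(0, length(off), length(off))
  h[on] <- scale * sqrt(radius^2 - d2[on])
  ny <- nrow(img); nx <- ncol(img)
  er <- matrix(NA_real_, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    best <- Inf
    for (i in seq_along(off)) for (j in seq_along(off)) {
      if (!on[i, j]) next
      yy <- y + off[i]; xx <- x + off[j]
      if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
      v <- img[yy, xx] - h[i, j]
      if (v < best) best <- v
    }
    er[y, x] <- best
  }
  di <- matrix(NA_real_, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    best <- -Inf
    for (i in seq_along(off)) for (j in seq_along(off)) {
      if (!on[i, j]) next
      yy <- y + off[i]; xx <- x + off[j]
      if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
      v <- er[yy, xx] + h[i, j]
      if (v > best) best <- v
    }
    di[y, x] <- best
  }
  di
}

# One-phase association evaluated directly (independent of fit_recovery).
one_phase <- function(t, Y0, P, K) Y0 + (P - Y0) * (1 - exp(-K * t))

# 95% binomial confidence half-width (normal approximation).
binom_ci_halfwidth <- function(p, n) 1.96 * sqrt(p * (1 - p) / n)
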