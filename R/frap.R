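#' Raw FRAP trace
#'
#' Per-frame mean ROI intensities for the three ROIs a FRAP analysis needs:
#' the bleached granule, an unbleached reference granule and a diffuse
#' cytoplasmic background region, together with the number of pre-bleach
#' frames.
#'
#' @param times_s strictly increasing frame times (s).
#' @param bleached,unbleached,background per-frame mean ROI intensities.
#' @param n_pre number of pre-bleach frames (>= 1; the standard protocol
#'   uses 2).
#' @return object of class `frap_trace`.
#' @export
frap_trace <- function(times_s, bleached, unbleached, background, n_pre) {
  n <- length(times_s)
  stopifnot(length(bleached) == n, length(unbleached) == n,
            length(background) == n, n_pre >= 1, n_pre < n,
            all(diff(times_s) > 0))
  structure(list(times_s = as.numeric(times_s),
                 bleached = as.numeric(bleached),
                 unbleached = as.numeric(unbleached),
                 background = as.numeric(background),
                 n_pre = as.integer(n_pre)),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("frap_trace: %d frames (%d pre-bleach), t = %.4g..%.4g s\n",
              length(x$times_s), x$n_pre, min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' Extract FRAP traces from a movie
#'
#' Computes the per-frame spatial mean inside the bleached, unbleached and
#' background ROIs. With `follow = TRUE` the two granule ROIs are
#' re-centered each frame on the local background-subtracted intensity
#' centroid within `search_radius_px` of the previous center, mirroring the
#' manual practice of moving the ROI when a granule drifts in x/y. Frames
#' where a granule ROI's mean falls below the background mean are flagged
#' for exclusion (granule dropped out of the focal plane).
#'
#' @param stack single-channel [ImageStack] movie.
#' @param rois named list with `bleached`, `unbleached`, `background`
#'   [roi]s.
#' @param n_pre number of pre-bleach frames.
#' @param follow re-center granule ROIs per frame?
#' @param search_radius_px centroid search radius for `follow`.
#' @return a [frap_trace] with an `excluded` attribute (logical per frame).
#' @export
extract_traces <- function(stack, rois, n_pre = 2L, follow = FALSE,
                           search_radius_px = 5) {
  stopifnot(inherits(stack, "ImageStack"),
            all(c("bleached", "unbleached", "background") %in% names(rois)))
  d <- dim(stack$pixels)
  if (d[3L] != 1L) stop("extract_traces expects a single-channel stack")
  nt <- d[1L]
  vals <- matrix(NA_real_, nt, 3L,
                 dimnames = list(NULL, c("bleached", "unbleached",
                                         "background")))
  centers <- list(bleached = rois$bleached$center,
                  unbleached = rois$unbleached$center)
  for (t in seq_len(nt)) {
    img <- stack_frame(stack, t = t)
    bgv <- roi_mean(img, rois$background)
    for (nm in c("bleached", "unbleached")) {
      r0 <- rois[[nm]]
      if (r0$kind != "circle") {
        vals[t, nm] <- roi_mean(img, r0)
        next
      }
      ctr <- centers[[nm]]
      if (follow && t > 1L) {
        ctr <- refine_center(img, ctr, r0$radius + search_radius_px, bgv)
        centers[[nm]] <- ctr
      }
      vals[t, nm] <- roi_mean(img, roi_circle(ctr, r0$radius, r0$label))
    }
    vals[t, "background"] <- bgv
  }
  excluded <- vals[, "bleached"] < vals[, "background"] |
    vals[, "unbleached"] < vals[, "background"]
  tr <- frap_trace(frame_times(stack), vals[, "bleached"],
                   vals[, "unbleached"], vals[, "background"], n_pre)
  attr(tr, "excluded") <- excluded
  tr
}

# Background-subtracted intensity centroid within a circular search window.
refine_center <- function(img, center, radius, bg) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- max(1L, floor(center[1L] - radius))
  y1 <- min(ny, ceiling(center[1L] + radius))
  x0 <- max(1L, floor(center[2L] - radius))
  x1 <- min(nx, ceiling(center[2L] + radius))
  sub <- img[y0:y1, x0:x1, drop = FALSE]
  yy <- matrix(y0:y1, nrow(sub), ncol(sub))
  xx <- matrix(x0:x1, nrow(sub), ncol(sub), byrow = TRUE)
  inside <- (yy - center[1L])^2 + (xx - center[2L])^2 <= radius^2
  w <- pmax(0, sub - bg) * inside
  if (sum(w) <= 0) return(center)
  c(sum(yy * w), sum(xx * w)) / sum(w)
}

#' Double-normalize a FRAP trace (PCV -> CAI -> BCFI -> FCV)
#'
#' The four-step correction: (1) the photobleach correction value
#' `PCV_t = mean(unbleached over pre-frames) / unbleached_t` measures and
#' inverts shared acquisition photobleaching; (2) the corrected average
#' intensity `CAI_t = bleached_t * PCV_t`; (3) the background-corrected
#' fluorescence intensity `BCFI_t = CAI_t - background_t`; (4) the final
#' corrected value `FCV_t = 100 * BCFI_t / BCFI_init`, where `BCFI_init` is
#' the mean BCFI over the pre-bleach frames, giving a recovery curve in
#' percent of pre-bleach intensity.
#'
#' @param raw a [frap_trace].
#' @return object of class `frap_norm`: data.frame-like list with
#'   `times_s`, `is_pre`, `pcv`, `cai`, `bcfi`, `fcv` and `n_pre`.
#' @export
normalize_trace <- function(raw) {
  stopifnot(inherits(raw, "frap_trace"))
  if (any(raw$unbleached <= 0)) {
    stop("division error: unbleached trace must be strictly positive")
  }
  pre <- seq_len(raw$n_pre)
  pcv <- mean(raw$unbleached[pre]) / raw$unbleached
  cai <- raw$bleached * pcv
  bcfi <- cai - raw$background
  bcfi_init <- mean(bcfi[pre])
  if (bcfi_init <= 0) {
    stop("normalization error: mean pre-bleach BCFI is ",
         format(bcfi_init), " (<= 0); check ROI placement and background")
  }
  fcv <- 100 * bcfi / bcfi_init
  structure(list(times_s = raw$times_s,
                 is_pre = seq_along(raw$times_s) <= raw$n_pre,
                 pcv = pcv, cai = cai, bcfi = bcfi, fcv = fcv,
                 n_pre = raw$n_pre),
            class = "frap_norm")
}

#' @export
print.frap_norm <- function(x, ...) {
  cat(sprintf("frap_norm: %d frames (%d pre), pre-bleach FCV mean %.6g\n",
              length(x$fcv), x$n_pre, mean(x$fcv[x$is_pre])))
  invisible(x)
}

#' @export
as.data.frame.frap_norm <- function(x, ...) {
  data.frame(time_s = x$times_s, is_pre = x$is_pre, pcv = x$pcv,
             cai = x$cai, bcfi = x$bcfi, fcv = x$fcv)
}

#' Fit a one-phase association recovery curve
#'
#' Least-squares fit of `Y(t) = Y0 + (P - Y0) * (1 - exp(-K (t - t0)))` to
#' the post-bleach normalized recovery, with `t0` the time of the first
#' post-bleach frame. The fit is solved by variable projection — for each
#' candidate rate `K` the model is linear in `(Y0, P - Y0)` — on a log-space
#' rate grid, then refined with `minpack.lm::nlsLM` under the bounds
#' `K` in `(1e-6, 10]` 1/s and `P - Y0 >= 0`. Reports the half-time
#' `t_half = log(2)/K` and the bleach-depth-normalized mobile fraction
#' `Fm = (P - Y0) / (100 - Y0)`. Non-convergence never raises: the
#' best-effort grid solution is returned with `converged = FALSE`.
#'
#' @param norm a [frap_norm], or a numeric vector of FCV values (then
#'   `times_s` and `n_pre` must be given).
#' @param times_s frame times, if `norm` is a bare vector.
#' @param n_pre number of pre-bleach frames, if `norm` is a bare vector.
#' @return object of class `frap_fit` with `Y0`, `P`, `K`, `t_half_s`,
#'   `Fm`, `rss`, `converged` and `flags`.
#' @export
fit_recovery <- function(norm, times_s = NULL, n_pre = NULL) {
  if (inherits(norm, "frap_norm")) {
    fcv <- norm$fcv; times_s <- norm$times_s; n_pre <- norm$n_pre
  } else {
    fcv <- as.numeric(norm)
    stopifnot(!is.null(times_s), !is.null(n_pre))
  }
  post <- (n_pre + 1L):length(fcv)
  if (length(post) < 10L) stop("need >= 10 post-bleach frames to fit")
  y <- fcv[post]
  tt <- times_s[post] - times_s[post[1L]]

  # variable projection: linear in (Y0, A) given K
  rss_k <- function(k) {
    xb <- 1 - exp(-k * tt)
    f <- stats::lm.fit(cbind(1, xb), y)
    c(sum(f$residuals^2), f$coefficients)
  }
  kgrid <- 10^seq(-5, 1, length.out = 121L)
  grid <- vapply(kgrid, rss_k, numeric(3L))
  best <- which.min(grid[1L, ])
  k0 <- kgrid[best]
  y0_0 <- grid[2L, best]
  a0 <- max(0, grid[3L, best])
  flags <- character(0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Y0 + A * (1 - exp(-K * tt)),
      start = list(Y0 = y0_0, A = a0, K = k0),
      lower = c(Y0 = -50, A = 0, K = 1e-6),
      upper = c(Y0 = 200, A = 200, K = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    Y0 <- y0_0; A <- a0; K <- max(1e-6, min(10, k0))
    rss <- grid[1L, best]
    converged <- FALSE
    flags <- c(flags, "nls_failed_grid_fallback")
  } else {
    cf <- stats::coef(fit)
    Y0 <- cf[["Y0"]]; A <- cf[["A"]]; K <- cf[["K"]]
    rss <- sum(stats::residuals(fit)^2)
    converged <- fit$convInfo$isConv %||% TRUE
  }
  P <- Y0 + A
  Fm <- if (abs(100 - Y0) < 1e-12) NA_real_ else (P - Y0) / (100 - Y0)
  if (!is.na(Fm) && Fm > 1.05) flags <- c(flags, "mobile_fraction_overshoot")
  if (!is.na(Fm) && Fm > 1.05) Fm <- min(Fm, 1.05)
  structure(list(Y0 = unname(Y0), P = unname(P), K = unname(K),
                 t_half_s = log(2) / unname(K), Fm = unname(Fm),
                 rss = rss, converged = isTRUE(converged), flags = flags),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "frap_fit: Y0 = %.4g%%, plateau = %.4g%%, K = %.4g /s\n          t1/2 = %.4g s, mobile fraction = %.4g  (converged: %s)\n",
    x$Y0, x$P, x$K, x$t_half_s, x$Fm, x$converged))
  invisible(x)
}

#' @export
as.data.frame.frap_fit <- function(x, ...) {
  data.frame(Y0 = x$Y0, P = x$P, K = x$K, t_half_s = x$t_half_s, Fm = x$Fm,
             rss = x$rss, converged = x$converged)
}

#' Summarize a batch of FRAP experiments
#'
#' Normalizes and fits every trace, then reports per-group mean and
#' standard error of the mobile fraction and half-time, plus the mean
#' recovery curve with per-timepoint SE. For a single-trace group the SE is
#' reported as 0 and flagged.
#'
#' @param traces list of [frap_trace] objects.
#' @param groups character vector of group labels, one per trace (default:
#'   one group).
#' @return list with `fits` (per-trace data.frame), `summary` (per-group
#'   data.frame with `n`, `Fm_mean`, `Fm_se`, `t_half_mean`, `t_half_se`,
#'   `se_defined`) and `curves` (per-group mean FCV curve with SE).
#' @export
frap_batch <- function(traces, groups = NULL) {
  stopifnot(length(traces) >= 1L)
  if (is.null(groups)) groups <- rep("all", length(traces))
  stopifnot(length(groups) == length(traces))
  fits <- vector("list", length(traces))
  norms <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    norms[[i]] <- normalize_trace(traces[[i]])
    f <- fit_recovery(norms[[i]])
    fits[[i]] <- cbind(data.frame(trace = i, group = groups[i]),
                       as.data.frame(f))
  }
  fits <- do.call(rbind, fits)
  se <- function(x) if (length(x) < 2L) 0 else stats::sd(x) / sqrt(length(x))
  summ <- do.call(rbind, lapply(split(fits, fits$group), function(g) {
    data.frame(group = g$group[1L], n = nrow(g),
               Fm_mean = mean(g$Fm), Fm_se = se(g$Fm),
               t_half_mean = mean(g$t_half_s), t_half_se = se(g$t_half_s),
               se_defined = nrow(g) >= 2L)
  }))
  rownames(summ) <- NULL
  curves <- do.call(rbind, lapply(split(seq_along(traces), groups),
                                  function(idx) {
    fcv <- do.call(rbind, lapply(norms[idx], function(n) n$fcv))
    data.frame(group = groups[idx[1L]], time_s = norms[[idx[1L]]]$times_s,
               fcv_mean = colMeans(fcv),
               fcv_se = apply(fcv, 2L, se))
  }))
  rownames(curves) <- NULL
  list(fits = fits, summary = summ, curves = curves)
}
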