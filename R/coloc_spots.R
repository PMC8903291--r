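#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a single-plane image as the grayscale
#' morphological opening with a spherical-cap structuring element of the
#' given radius (the morphological formulation of the classic rolling-ball
#' algorithm: a ball rolled under the intensity surface) and subtracts it,
#' clipping at zero. Structures wider than the ball survive in the
#' background; structures narrower than the ball (spots, granules) survive
#' in the output.
#'
#' @param image numeric matrix or single-plane [ImageStack].
#' @param radius_px ball radius in pixels (default 50).
#' @param intensity_scale intensity units per pixel of ball height: the
#'   cap height is `intensity_scale * sqrt(radius^2 - d^2)`. The default
#'   0.5 keeps the cap shallow so that structures much narrower than the
#'   ball are preserved to within a few percent and the operator is
#'   idempotent to about 1 percent.
#' @return background-subtracted matrix with attribute `background`.
#' @export
rolling_ball_subtract <- function(image, radius_px = 50,
                                  intensity_scale = 0.5) {
  if (inherits(image, "ImageStack")) image <- stack_frame(image)
  if (radius_px <= 0) stop("parameter error: radius_px must be > 0")
  r <- ceiling(radius_px)
  off <- seq(-r, r)
  d2 <- outer(off^2, off^2, "+")
  se_on <- d2 <= radius_px^2
  se <- matrix(0, length(off), length(off))
  se[se_on] <- intensity_scale * (sqrt(radius_px^2 - d2[se_on]))
  # replicate-pad by the radius so the ball is fully supported at the
  # image border (otherwise the background dips within r of the edge)
  ny <- nrow(image); nx <- ncol(image)
  iy <- c(rep(1L, r), seq_len(ny), rep(ny, r))
  ix <- c(rep(1L, r), seq_len(nx), rep(nx, r))
  padded <- image[iy, ix]
  bg <- cpp_morph(cpp_morph(padded, se, se_on, TRUE), se, se_on, FALSE)
  bg <- bg[r + seq_len(ny), r + seq_len(nx)]
  out <- image - bg
  out[out < 0] <- 0
  attr(out, "background") <- bg
  out
}

#' Pearson colocalization coefficient
#'
#' Standard Pearson correlation of the two channels over the pixels inside
#' the ROI (all pixels, no intensity thresholding). Zero variance in either
#' channel makes the coefficient undefined; it is returned as `NA` with a
#' flag rather than an error.
#'
#' @param channel_a,channel_b numeric matrices of equal shape.
#' @param roi optional `Roi` or logical matrix restricting the analysis
#'   (default: whole image).
#' @return list of class `coloc_result`: `pearson_r`, `n_pixels`,
#'   `undefined` flag.
#' @export
pearson_coloc <- function(channel_a, channel_b, roi = NULL) {
  stopifnot(identical(dim(channel_a), dim(channel_b)))
  m <- if (is.null(roi)) {
    matrix(TRUE, nrow(channel_a), ncol(channel_a))
  } else if (inherits(roi, "Roi")) {
    roi_mask(roi, dim(channel_a))
  } else {
    roi
  }
  if (!any(m)) stop("empty ROI")
  a <- channel_a[m]; b <- channel_b[m]
  undefined <- stats::sd(a) == 0 || stats::sd(b) == 0
  r <- if (undefined) NA_real_ else stats::cor(a, b)
  structure(list(pearson_r = r, n_pixels = sum(m), undefined = undefined),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result: Pearson r = %s over %d px%s\n",
              format(x$pearson_r, digits = 4), x$n_pixels,
              if (x$undefined) " (undefined: zero variance)" else ""))
  invisible(x)
}

#' Detect diffraction-limited spots
#'
#' Laplacian-of-Gaussian filtering at the point-spread sigma, local maxima
#' above `threshold_factor` times the robust sigma (MAD) of the filtered
#' image, then sub-pixel refinement by least-squares 2-D Gaussian fit in a
#' 7 x 7 window (falling back to the intensity-weighted centroid if the fit
#' fails). Two spots closer than about twice the PSF sigma merge into one
#' detection — a documented limitation shared with any single-scale
#' blob detector.
#'
#' @param image numeric matrix or [ImageStack] (z is max-projected, first
#'   frame/channel used).
#' @param psf_sigma_px expected spot sigma in pixels.
#' @param threshold_factor detection threshold in robust sigmas of the LoG
#'   response (default 5).
#' @return data.frame with sub-pixel `y`, `x`, `response` (LoG peak) and
#'   `fit_ok`.
#' @export
detect_spots <- function(image, psf_sigma_px = 1.3, threshold_factor = 5) {
  if (inherits(image, "ImageStack")) {
    d <- dim(image$pixels)
    image <- matrix(apply(image$pixels[1L, , 1L, , , drop = FALSE],
                          c(4L, 5L), max), d[4L], d[5L])
  }
  lg <- log_filter(image, psf_sigma_px)
  sigma_r <- stats::mad(lg)
  thr <- threshold_factor * sigma_r
  ny <- nrow(lg); nx <- ncol(lg)
  # local maxima over the 8-neighbourhood
  is_max <- lg > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    shifted <- shift_mat(lg, dy, dx, fill = -Inf)
    is_max <- is_max & (lg >= shifted)
  }
  is_max[c(1L, ny), ] <- FALSE
  is_max[, c(1L, nx)] <- FALSE
  peaks <- which(is_max, arr.ind = TRUE)
  if (nrow(peaks) == 0L) {
    return(data.frame(y = numeric(0), x = numeric(0), response = numeric(0),
                      fit_ok = logical(0)))
  }
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    py <- unname(peaks[i, 1L]); px <- unname(peaks[i, 2L])
    ref <- gauss_refine(image, py, px, psf_sigma_px)
    data.frame(y = ref[1L], x = ref[2L], response = lg[py, px],
               fit_ok = ref[3L] == 1)
  })
  df <- do.call(rbind, out)
  df[order(-df$response), ]
}

# negated LoG ("mexican hat") response, positive for bright blobs;
# scale-normalized by sigma^2
log_filter <- function(image, sigma) {
  hw <- max(3L, ceiling(4 * sigma))
  off <- seq(-hw, hw)
  g <- exp(-off^2 / (2 * sigma^2))
  g <- g / sum(g)
  r2 <- outer(off^2, off^2, "+")
  k <- outer(g, g)
  lap <- k * (r2 - 2 * sigma^2) / sigma^4
  lap <- lap - mean(lap)      # zero response on constant images
  conv2_replicate(image, -lap * sigma^2)
}

# 2-D convolution with replicated edges, via EBImage FFT filtering
conv2_replicate <- function(image, kernel) {
  hw <- (dim(kernel) - 1L) / 2L
  padded <- image[c(rep(1L, hw[1L]), seq_len(nrow(image)),
                    rep(nrow(image), hw[1L])),
                  c(rep(1L, hw[2L]), seq_len(ncol(image)),
                    rep(ncol(image), hw[2L]))]
  flt <- EBImage::filter2(padded, kernel, boundary = "circular")
  flt[hw[1L] + seq_len(nrow(image)), hw[2L] + seq_len(ncol(image))]
}

shift_mat <- function(m, dy, dx, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  ok_y <- ys >= 1L & ys <= ny; ok_x <- xs >= 1L & xs <= nx
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

# sub-pixel localization: 2-D Gaussian LS fit in a 7x7 window
gauss_refine <- function(image, py, px, sigma) {
  hw <- 3L
  y0 <- max(1L, py - hw); y1 <- min(nrow(image), py + hw)
  x0 <- max(1L, px - hw); x1 <- min(ncol(image), px + hw)
  win <- image[y0:y1, x0:x1]
  yy <- as.vector(row(win)) + y0 - 1L
  xx <- as.vector(col(win)) + x0 - 1L
  vv <- as.vector(win)
  df <- data.frame(v = vv, y = yy, x = xx)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ b + a * exp(-((y - cy)^2 + (x - cx)^2) / (2 * s^2)),
      data = df,
      start = list(b = min(vv), a = max(vv) - min(vv),
                   cy = py, cx = px, s = sigma),
      lower = c(b = 0, a = 0, cy = py - 2, cx = px - 2, s = 0.3 * sigma),
      upper = c(b = Inf, a = Inf, cy = py + 2, cx = px + 2,
                s = 3 * sigma),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    return(c(cf[["cy"]], cf[["cx"]], 1))
  }
  w <- pmax(0, vv - stats::median(vv))
  if (sum(w) == 0) return(c(py, px, 0))
  c(sum(yy * w) / sum(w), sum(xx * w) / sum(w), 0)
}

#' Assign spots to soma / neurite compartments
#'
#' Each spot is labeled by the mask containing its rounded pixel
#' coordinate; the soma wins ties where the masks overlap. Spots outside
#' both masks are labeled `outside` and excluded from the neurite
#' fraction, which is `n_neurite / (n_neurite + n_soma)`.
#'
#' @param spots data.frame with `y`, `x` (from [detect_spots()]).
#' @param soma_mask,neurite_mask label matrices (non-zero = in
#'   compartment).
#' @return list with `spots` (adds `compartment`), `counts` (named vector)
#'   and `neurite_fraction`.
#' @export
assign_compartments <- function(spots, soma_mask, neurite_mask) {
  stopifnot(identical(dim(soma_mask), dim(neurite_mask)))
  ny <- nrow(soma_mask); nx <- ncol(soma_mask)
  comp <- character(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    yy <- round(spots$y[i]); xx <- round(spots$x[i])
    comp[i] <- if (yy < 1 || yy > ny || xx < 1 || xx > nx) {
      "outside"
    } else if (soma_mask[yy, xx] != 0) {
      "soma"
    } else if (neurite_mask[yy, xx] != 0) {
      "neurite"
    } else "outside"
  }
  spots$compartment <- comp
  counts <- c(soma = sum(comp == "soma"), neurite = sum(comp == "neurite"),
              outside = sum(comp == "outside"))
  nf <- if (counts[["soma"]] + counts[["neurite"]] == 0) NA_real_ else
    counts[["neurite"]] / (counts[["soma"]] + counts[["neurite"]])
  list(spots = spots, counts = counts, neurite_fraction = nf)
}
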