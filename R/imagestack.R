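#' Calibrated multi-dimensional image stack
#'
#' The common container for all image data in rnpquant. Pixels are stored as
#' a 5-D array indexed `(t, z, c, y, x)`; missing axes get length 1 so a
#' plain 2-D image becomes a `1 x 1 x 1 x ny x nx` stack. Spatial calibration
#' is carried with the pixels so every downstream measurement can report
#' micrometres and seconds.
#'
#' Conventions: pixel coordinates are 1-based in R code with `(y, x)` axis
#' order and pixel centers at integer coordinates; all micrometre distances
#' derive from `pixel_size_um`.
#'
#' @param pixels numeric array: 2-D `(y, x)`, 3-D `(t, y, x)` or 5-D
#'   `(t, z, c, y, x)` of non-negative intensities.
#' @param pixel_size_um pixel size in micrometres per pixel (> 0).
#' @param frame_interval_s time between frames in seconds; required
#'   (positive) when the stack has more than one frame.
#' @param z_step_um z-spacing in micrometres (optional).
#' @return an object of class `ImageStack`.
#' @export
ImageStack <- function(pixels, pixel_size_um, frame_interval_s = NA_real_,
                       z_step_um = NA_real_) {
  nd <- length(dim(pixels))
  if (is.null(dim(pixels)) || !nd %in% c(2L, 3L, 5L)) {
    stop("pixels must be a 2-D (y,x), 3-D (t,y,x) or 5-D (t,z,c,y,x) array")
  }
  if (nd == 2L) {
    dim(pixels) <- c(1L, 1L, 1L, dim(pixels))
  } else if (nd == 3L) {
    d <- dim(pixels)
    pixels <- array(pixels, c(d[1L], 1L, 1L, d[2L], d[3L]))
  }
  if (any(pixels < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  storage.mode(pixels) <- "double"
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0")
  }
  if (dim(pixels)[1L] > 1L &&
      (is.na(frame_interval_s) || frame_interval_s <= 0)) {
    stop("frame_interval_s must be > 0 for a multi-frame stack")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s, z_step_um = z_step_um),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "ImageStack: t=%d z=%d c=%d y=%d x=%d | %.4g um/px, dt=%s s\n",
    d[1], d[2], d[3], d[4], d[5], x$pixel_size_um,
    format(x$frame_interval_s)))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$pixels)

#' Extract one 2-D plane from a stack
#'
#' @param stack an [ImageStack].
#' @param t,z,c 1-based frame, slice and channel indices.
#' @return numeric matrix `(y, x)`.
#' @export
stack_frame <- function(stack, t = 1L, z = 1L, c = 1L) {
  stopifnot(inherits(stack, "ImageStack"))
  stack$pixels[t, z, c, , , drop = TRUE] -> m
  d <- dim(stack$pixels)
  matrix(m, d[4L], d[5L])
}

#' Number of frames in a stack
#' @param stack an [ImageStack].
#' @export
n_frames <- function(stack) dim(stack$pixels)[1L]

#' Frame acquisition times of a stack
#' @param stack an [ImageStack].
#' @return numeric vector of times in seconds, starting at 0.
#' @export
frame_times <- function(stack) {
  (seq_len(n_frames(stack)) - 1L) * stack$frame_interval_s
}

# Page order of the multi-page TIFF representation: axes listed fastest-last,
# i.e. page index runs c fastest, then z, then t.
stack_axes_default <- "tzc"

#' Write an image stack as multi-page TIFF plus a JSON sidecar
#'
#' Pages are written in `t, z, c` order (channel fastest). A sidecar file
#' `<path>.json` records the axis order, shape, calibration and bit depth so
#' [read_stack()] can reconstruct the stack without guessing. Integer-valued
#' stacks within `[0, 65535]` are stored losslessly as 16-bit; anything else
#' is stored as 32-bit float.
#'
#' @param stack an [ImageStack].
#' @param path output TIFF path.
#' @param bits 16 (integer data) or 32 (float). Default picks automatically.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = NULL) {
  stopifnot(inherits(stack, "ImageStack"))
  px <- stack$pixels
  d <- dim(px)
  integerish <- all(px == round(px)) && max(px) <= 65535
  if (is.null(bits)) bits <- if (integerish) 16L else 32L
  if (bits == 16L && !integerish) {
    stop("16-bit output requires integer intensities in [0, 65535]")
  }
  pages <- vector("list", d[1L] * d[2L] * d[3L])
  k <- 0L
  for (t in seq_len(d[1L])) for (z in seq_len(d[2L])) for (ch in seq_len(d[3L])) {
    k <- k + 1L
    m <- matrix(px[t, z, ch, , ], d[4L], d[5L])
    pages[[k]] <- if (bits == 16L) m / 65535 else m
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  meta <- list(axes = stack_axes_default,
               shape = list(t = d[1L], z = d[2L], c = d[3L],
                            y = d[4L], x = d[5L]),
               pixel_size_um = stack$pixel_size_um,
               frame_interval_s = stack$frame_interval_s,
               z_step_um = stack$z_step_um,
               bits = bits)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read an image stack from TIFF (+ optional JSON sidecar)
#'
#' If `<path>.json` exists it supplies the non-spatial axis order (any
#' permutation of `"tzc"`), shape and calibration; the metadata is honoured
#' even when it disagrees with naive page order. Without a sidecar, pages
#' are interpreted as frames (`t`) and calibration must come from `config`.
#'
#' @param path TIFF file path.
#' @param config optional [run_config()] list supplying
#'   `pixel_size_um` / `frame_interval_s` / `z_step_um` overrides.
#' @return an [ImageStack].
#' @export
read_stack <- function(path, config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path,
                                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1L] else p  # drop RGB-style channels
  })
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  px_um <- meta$pixel_size_um %||% config$pixel_size_um
  dt_s <- meta$frame_interval_s %||% config$frame_interval_s %||% NA_real_
  dz_um <- meta$z_step_um %||% config$z_step_um %||% NA_real_
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  if (is.null(meta)) {
    shape <- c(t = length(pages), z = 1L, c = 1L)
    axes <- stack_axes_default
  } else {
    shape <- c(t = meta$shape$t, z = meta$shape$z, c = meta$shape$c)
    axes <- meta$axes
    if (prod(shape) != length(pages)) {
      stop("sidecar shape does not match page count in ", path)
    }
  }
  if (is.null(px_um)) {
    stop("no pixel_size_um in metadata and no config override for ", path)
  }
  if (shape[["t"]] > 1L && (is.na(dt_s) || is.null(dt_s))) {
    stop("no frame_interval_s in metadata and no config override for ", path)
  }
  ax <- strsplit(axes, "")[[1L]]
  if (!setequal(ax, c("t", "z", "c"))) stop("sidecar axes must permute 'tzc'")
  arr <- array(NA_real_, c(shape[["t"]], shape[["z"]], shape[["c"]], ny, nx))
  # page index runs over ax with the last axis fastest
  n1 <- shape[[ax[1L]]]; n2 <- shape[[ax[2L]]]; n3 <- shape[[ax[3L]]]
  k <- 0L
  idx <- c(t = 1L, z = 1L, c = 1L)
  for (i1 in seq_len(n1)) for (i2 in seq_len(n2)) for (i3 in seq_len(n3)) {
    k <- k + 1L
    idx[ax] <- c(i1, i2, i3)
    arr[idx[["t"]], idx[["z"]], idx[["c"]], , ] <- pages[[k]]
  }
  ImageStack(arr, pixel_size_um = as.numeric(px_um),
             frame_interval_s = as.numeric(dt_s),
             z_step_um = as.numeric(dz_um))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
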