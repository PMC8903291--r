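#' Detect granules in a single-plane image
#'
#' Granules are punctate regions of intensity above the diffuse cytoplasmic
#' background. The background statistic is robust: the threshold is
#' `median + k_sigma * sigma_MAD` of the cytoplasm within the cell mask,
#' re-estimated once after excluding a first round of detections (so bright
#' granules do not inflate the background estimate). Pixels above threshold
#' are grouped into 8-connected components; components smaller than
#' `min_area_px` pixels or whose bounding box cannot contain a 3 x 3 square
#' are discarded, implementing the "at least 3 x 3 pixels" rule.
#'
#' @param image single-plane [ImageStack] or numeric matrix.
#' @param cell_mask logical matrix (or `Roi`) delimiting the cell.
#' @param k_sigma threshold multiplier over the MAD-based sigma (default 3).
#' @param min_area_px minimum component area (default 9 = 3 x 3).
#' @param pixel_size_um spatial calibration; taken from the stack if given.
#' @return data.frame of granule records: `id`, centroid `y`/`x` (px),
#'   `area_px`, `area_um2`, `perimeter_px` (crack-edge count),
#'   `circularity`, `mean_intensity`. Attribute `label_image` holds the
#'   labeled component matrix, `threshold` the final threshold.
#' @export
detect_granules <- function(image, cell_mask, k_sigma = 3, min_area_px = 9L,
                            pixel_size_um = NULL) {
  if (inherits(image, "ImageStack")) {
    d <- dim(image$pixels)
    if (d[1L] != 1L || d[2L] != 1L || d[3L] != 1L) {
      stop("detect_granules expects a single-plane, single-channel image")
    }
    if (is.null(pixel_size_um)) pixel_size_um <- image$pixel_size_um
    image <- stack_frame(image)
  }
  if (inherits(cell_mask, "Roi")) cell_mask <- roi_mask(cell_mask, dim(image))
  if (!any(cell_mask)) stop("geometry error: empty cell mask")
  if (is.null(pixel_size_um)) pixel_size_um <- NA_real_

  thr <- robust_threshold(image[cell_mask], k_sigma)
  lab1 <- cpp_label(image > thr & cell_mask, 8L)
  # one re-estimation pass excluding first-round detections (dilated 1 px)
  det <- dilate1(lab1 > 0)
  bgpx <- image[cell_mask & !det]
  if (length(bgpx) >= 25L) thr <- robust_threshold(bgpx, k_sigma)
  lab <- cpp_label(image > thr & cell_mask, 8L)

  recs <- component_stats(image, lab, min_area_px, pixel_size_um)
  attr(recs, "label_image") <- lab
  attr(recs, "threshold") <- thr
  recs
}

robust_threshold <- function(px, k_sigma) {
  stats::median(px) + k_sigma * stats::mad(px)
}

dilate1 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-ny, ]
  out[-ny, ] <- out[-ny, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nx]
  out[, -nx] <- out[, -nx] | m[, -1]
  out
}

# Per-component area, centroid, crack perimeter, circularity, intensity.
#
# perimeter_px counts exposed pixel edges (the crack boundary), so a
# w x h rectangle scores 2(w + h). Circularity is computed on the convex
# hull of the component's pixel centers, 4*pi*A_hull / P_hull^2: the hull
# is insensitive to single-pixel boundary noise, a digital disk scores ~1
# and a 3:1 elongated blob ~0.66. Concave shapes are rounded by the hull,
# which biases circularity upward for strongly branched blobs (documented
# limitation; the elongated amorphic phenotype stays well below 0.8).
component_stats <- function(image, lab, min_area_px, pixel_size_um) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  out <- list()
  for (id in ids) {
    m <- lab == id
    area <- sum(m)
    if (area < min_area_px) next
    ys <- row(m)[m]; xs <- col(m)[m]
    # bounding box must fit a 3 x 3 square
    if (diff(range(ys)) < 2L || diff(range(xs)) < 2L) next
    per <- crack_perimeter(m)
    hull <- hull_geometry(ys, xs)
    out[[length(out) + 1L]] <- data.frame(
      id = id,
      y = sum(ys * image[m]) / sum(image[m]),
      x = sum(xs * image[m]) / sum(image[m]),
      area_px = area,
      area_um2 = area * pixel_size_um^2,
      perimeter_px = per,
      circularity = 4 * pi * hull$area / hull$perimeter^2,
      mean_intensity = mean(image[m]))
  }
  if (length(out) == 0L) {
    return(data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                      area_px = integer(0), area_um2 = numeric(0),
                      perimeter_px = numeric(0), circularity = numeric(0),
                      mean_intensity = numeric(0)))
  }
  df <- do.call(rbind, out)
  df$id <- seq_len(nrow(df))
  df
}

# convex hull (of pixel centers, padded by half-pixel cross extent) area
# and Euclidean perimeter
hull_geometry <- function(ys, xs) {
  # represent each pixel by its 4 edge midpoints so a 1-px-wide line still
  # has nonzero hull area and a disk's hull radius is not half a pixel low
  py <- c(ys + 0.5, ys - 0.5, ys, ys)
  px <- c(xs, xs, xs + 0.5, xs - 0.5)
  h <- grDevices::chull(px, py)
  hy <- py[h]; hx <- px[h]
  n <- length(h)
  nxt <- c(seq_len(n)[-1L], 1L)
  area <- abs(sum(hx * hy[nxt] - hx[nxt] * hy)) / 2
  perim <- sum(sqrt((hy[nxt] - hy)^2 + (hx[nxt] - hx)^2))
  list(area = area, perimeter = perim)
}

# number of foreground pixel edges facing background or the image border
crack_perimeter <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  up <- rbind(FALSE, m[-ny, , drop = FALSE])
  down <- rbind(m[-1, , drop = FALSE], FALSE)
  left <- cbind(FALSE, m[, -nx, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], FALSE)
  sum(m & !up) + sum(m & !down) + sum(m & !left) + sum(m & !right)
}

#' Classify granule morphology
#'
#' Adds a `morphology` column: `circular` if circularity is at least
#' `circ_threshold`, else `amorphic`. The circularity statistic is
#' `4 * pi * area / perimeter^2` with the Cauchy-corrected perimeter (see
#' [detect_granules()]), so an ideal disk scores ~1 and elongated blobs
#' (axis ratio >= 3) score well below 0.8.
#'
#' @param records granule data.frame from [detect_granules()].
#' @param circ_threshold circularity cut (default 0.8).
#' @return `records` with an added `morphology` factor.
#' @export
granule_morphometrics <- function(records, circ_threshold = 0.8) {
  records$morphology <- ifelse(records$circularity >= circ_threshold,
                               "circular", "amorphic")
  records
}

#' Per-cell granule summaries and cohort statistics
#'
#' For each cell: granule count, cell area from the longest-axis diameter
#' (`area = pi (d/2)^2`), granule density per square micrometre, and a
#' cell-level morphology call — a cell is `amorphic` if it formed any
#' number of amorphic granules, else `circular` (no granules: `none`).
#' Cohort statistics report the percentage of cells with at least one
#' granule (replicate-wise mean +/- SE when `replicates` is given) and the
#' percentage of granule-forming cells classed amorphic.
#'
#' @param detections list of per-cell granule data.frames (with
#'   `morphology` where available).
#' @param diameters_um numeric vector of per-cell longest-axis diameters.
#' @param replicates optional replicate label per cell.
#' @return list with `cells` (per-cell data.frame) and `cohort` (one-row
#'   data.frame).
#' @export
summarize_cells <- function(detections, diameters_um, replicates = NULL) {
  stopifnot(length(detections) == length(diameters_um))
  n_cells <- length(detections)
  if (is.null(replicates)) replicates <- rep(1L, n_cells)
  cells <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    det <- detections[[i]]
    n <- nrow(det)
    d <- diameters_um[i]
    area <- pi * (d / 2)^2
    morph <- if (n == 0L) {
      "none"
    } else if (!is.null(det$morphology) && any(det$morphology == "amorphic")) {
      "amorphic"
    } else "circular"
    data.frame(cell = i, replicate = replicates[i], has_granules = n > 0L,
               n_granules = n, cell_diameter_um = d, cell_area_um2 = area,
               granules_per_um2 = n / area, morphology = morph)
  }))
  pct_by_rep <- vapply(split(cells$has_granules, cells$replicate),
                       function(x) 100 * mean(x), numeric(1L))
  forming <- cells[cells$has_granules, , drop = FALSE]
  se <- function(x) if (length(x) < 2L) 0 else stats::sd(x) / sqrt(length(x))
  cohort <- data.frame(
    n_cells = n_cells,
    pct_with_granules = 100 * mean(cells$has_granules),
    pct_with_granules_se = se(pct_by_rep),
    pct_forming_amorphic = if (nrow(forming) == 0L) NA_real_ else
      100 * mean(forming$morphology == "amorphic"),
    mean_granules_per_um2 = mean(cells$granules_per_um2[cells$has_granules]))
  list(cells = cells, cohort = cohort)
}

#' Distance of granules from the cell body
#'
#' The soma is approximated by a tightly drawn circle; each granule's
#' distance is the Euclidean distance from its centroid to the circle
#' center, converted to micrometres, minus the soma radius (floored at 0).
#' Granules at least `distal_um` from the soma edge are flagged distal.
#'
#' @param centroids matrix/data.frame with columns `y`, `x` (px).
#' @param soma circle [roi] (center + radius in px).
#' @param pixel_size_um spatial calibration.
#' @param distal_um distal cut-off (default 10).
#' @return data.frame with `distance_um` and logical `distal`.
#' @export
soma_distance <- function(centroids, soma, pixel_size_um, distal_um = 10) {
  stopifnot(inherits(soma, "Roi"), soma$kind == "circle")
  centroids <- as.data.frame(centroids)
  d_px <- sqrt((centroids$y - soma$center[1L])^2 +
               (centroids$x - soma$center[2L])^2)
  dist_um <- pmax(0, d_px * pixel_size_um - soma$radius * pixel_size_um)
  data.frame(distance_um = dist_um, distal = dist_um >= distal_um)
}
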