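#' Regions of interest
#'
#' ROIs come in three kinds: `circle` (center + radius), `polygon` (closed
#' vertex list) and `polyline` (open path, used for neurite axes). All
#' coordinates are pixel coordinates in `(y, x)` order with pixel centers at
#' integer positions. A pixel belongs to an ROI if its center lies inside
#' the shape, boundary inclusive.
#'
#' @param center numeric `(y, x)` center in pixels.
#' @param radius circle radius in pixels (> 0).
#' @param vertices numeric matrix with columns `(y, x)`.
#' @param label text label.
#' @return an object of class `Roi`.
#' @name roi
NULL

#' @rdname roi
#' @export
roi_circle <- function(center, radius, label = "") {
  stopifnot(length(center) == 2L, radius > 0)
  structure(list(kind = "circle", center = as.numeric(center),
                 radius = as.numeric(radius), label = label),
            class = "Roi")
}

#' @rdname roi
#' @export
roi_polygon <- function(vertices, label = "") {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  structure(list(kind = "polygon", vertices = vertices, label = label),
            class = "Roi")
}

#' @rdname roi
#' @export
roi_polyline <- function(vertices, label = "") {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 2L)
  structure(list(kind = "polyline", vertices = vertices, label = label),
            class = "Roi")
}

#' @export
print.Roi <- function(x, ...) {
  cat(sprintf("Roi <%s> '%s'\n", x$kind, x$label))
  invisible(x)
}

# Even-odd rule point-in-polygon, vectorized over query points.
# Points exactly on an edge count as inside (boundary inclusive).
points_in_polygon <- function(py, px, vy, vx) {
  n <- length(vy)
  inside <- rep(FALSE, length(py))
  on_edge <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; xi <- vx[i]; yj <- vy[j]; xj <- vx[j]
    # boundary check: point on segment (i,j)
    dx <- xj - xi; dy <- yj - yi
    seg_len2 <- dx * dx + dy * dy
    if (seg_len2 > 0) {
      tt <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / seg_len2))
      d2 <- (xi + tt * dx - px)^2 + (yi + tt * dy - py)^2
      on_edge <- on_edge | d2 < 1e-18
    }
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Rasterize an ROI to a logical mask
#'
#' @param roi an `Roi` (circle or polygon).
#' @param dim image dimensions `c(ny, nx)`.
#' @return logical matrix; `TRUE` where the pixel center is inside the ROI.
#' @export
roi_mask <- function(roi, dim) {
  stopifnot(inherits(roi, "Roi"))
  ny <- dim[1L]; nx <- dim[2L]
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  if (roi$kind == "circle") {
    m <- (yy - roi$center[1L])^2 + (xx - roi$center[2L])^2 <= roi$radius^2
  } else if (roi$kind == "polygon") {
    m <- matrix(points_in_polygon(as.vector(yy), as.vector(xx),
                                  roi$vertices[, 1L], roi$vertices[, 2L]),
                ny, nx)
  } else {
    stop("cannot rasterize a polyline to an area mask")
  }
  m
}

#' Mean intensity inside an ROI
#'
#' @param img numeric matrix `(y, x)`.
#' @param roi an `Roi`.
#' @return scalar mean of pixels whose centers fall inside the ROI.
#' @export
roi_mean <- function(img, roi) {
  m <- roi_mask(roi, dim(img))
  if (!any(m)) stop("ROI covers no pixel centers (outside image?)")
  mean(img[m])
}

#' Read and write ROI sets as JSON
#'
#' The on-disk schema is `{"rois": [{"kind": "circle", "center": [y, x],
#' "radius": r, "label": "..."}, {"kind": "polygon", "vertices":
#' [[y, x], ...], "label": "..."}, ...]}`.
#'
#' @param rois list of `Roi` objects.
#' @param path JSON file path.
#' @return `read_rois`: named list of `Roi` (names from labels);
#'   `write_rois`: `path` invisibly.
#' @export
write_rois <- function(rois, path) {
  enc <- lapply(rois, function(r) {
    if (r$kind == "circle") {
      list(kind = "circle", center = r$center, radius = r$radius,
           label = r$label)
    } else {
      list(kind = r$kind,
           vertices = lapply(seq_len(nrow(r$vertices)),
                             function(i) as.numeric(r$vertices[i, ])),
           label = r$label)
    }
  })
  jsonlite::write_json(list(rois = enc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  doc <- jsonlite::read_json(path)
  rois <- lapply(doc$rois, function(r) {
    if (r$kind == "circle") {
      roi_circle(unlist(r$center), r$radius, r$label %||% "")
    } else {
      v <- do.call(rbind, lapply(r$vertices, unlist))
      if (r$kind == "polygon") roi_polygon(v, r$label %||% "")
      else roi_polyline(v, r$label %||% "")
    }
  })
  names(rois) <- vapply(rois, function(r) r$label, character(1L))
  rois
}
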