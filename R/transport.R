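#' Transport analysis configuration
#'
#' @param v_min_um_s minimum speed separating stationary from motile
#'   granules; defaults to 0.138 um/s, the pixel size per second of the
#'   acquisition it mirrors.
#' @param dt_s frame interval; defaults to 4.84 s (484 s over 100 frames).
#' @param pixel_size_um pixel size along the neurite axis.
#' @param min_track_frames tracks shorter than this are dropped by
#'   [link_tracks()].
#' @param max_jump_factor linking gate in units of `v_min_um_s * dt_s`
#'   (default 5, comfortably above typical run speeds of 3-4x the floor).
#' @return list of class `transport_config`.
#' @export
transport_config <- function(v_min_um_s = 0.138, dt_s = 4.84,
                             pixel_size_um = 0.138,
                             min_track_frames = 5L,
                             max_jump_factor = 5) {
  stopifnot(v_min_um_s > 0, dt_s > 0)
  structure(list(v_min_um_s = v_min_um_s, dt_s = dt_s,
                 pixel_size_um = pixel_size_um,
                 min_track_frames = min_track_frames,
                 max_jump_factor = max_jump_factor),
            class = "transport_config")
}

#' Build a kymograph along a neurite
#'
#' The movie is max-projected over z per frame, the neurite polyline is
#' sampled at one-pixel arc-length steps (soma end first), and each
#' position's intensity is the maximum over `width_px` samples taken
#' perpendicular to the path (bilinear interpolation). Rows are positions
#' (soma at row 1), columns are frames.
#'
#' @param movie an [ImageStack].
#' @param neurite polyline [roi] traced soma-to-tip.
#' @param width_px perpendicular averaging width (odd; default 5).
#' @return numeric matrix (positions x frames) with attribute
#'   `arc_length_um`.
#' @export
build_kymograph <- function(movie, neurite, width_px = 5L) {
  stopifnot(inherits(movie, "ImageStack"), inherits(neurite, "Roi"),
            neurite$kind == "polyline")
  v <- neurite$vertices
  seg <- diff(v)
  seg_len <- sqrt(rowSums(seg^2))
  if (sum(seg_len) < 2) stop("geometry error: polyline shorter than 2 px")
  total <- sum(seg_len)
  arc <- seq(0, total, by = 1)
  # map arc positions to (y, x) and unit tangents
  cum <- c(0, cumsum(seg_len))
  pts <- matrix(NA_real_, length(arc), 2L)
  tan_ <- matrix(NA_real_, length(arc), 2L)
  for (i in seq_along(arc)) {
    k <- max(1L, min(nrow(seg), findInterval(arc[i], cum,
                                             rightmost.closed = TRUE)))
    u <- (arc[i] - cum[k]) / seg_len[k]
    pts[i, ] <- v[k, ] + u * seg[k, ]
    tan_[i, ] <- seg[k, ] / seg_len[k]
  }
  normal <- cbind(-tan_[, 2L], tan_[, 1L])
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2)
  nt <- n_frames(movie)
  d <- dim(movie$pixels)
  kymo <- matrix(NA_real_, length(arc), nt)
  for (t in seq_len(nt)) {
    img <- matrix(apply(movie$pixels[t, , , , , drop = FALSE], c(4L, 5L),
                        max), d[4L], d[5L])
    vals <- matrix(-Inf, length(arc), length(offs))
    for (j in seq_along(offs)) {
      qy <- pts[, 1L] + offs[j] * normal[, 1L]
      qx <- pts[, 2L] + offs[j] * normal[, 2L]
      vals[, j] <- bilinear(img, qy, qx)
    }
    kymo[, t] <- apply(vals, 1L, max, na.rm = TRUE)
  }
  attr(kymo, "arc_length_um") <- arc * movie$pixel_size_um
  kymo
}

# bilinear interpolation at fractional (y, x); NA outside the image
bilinear <- function(img, qy, qx) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- floor(qy); x0 <- floor(qx)
  fy <- qy - y0; fx <- qx - x0
  y0 <- pmin(pmax(y0, 1L), ny); x0 <- pmin(pmax(x0, 1L), nx)
  y1 <- pmin(y0 + 1L, ny); x1 <- pmin(x0 + 1L, nx)
  out <- (1 - fy) * (1 - fx) * img[cbind(y0, x0)] +
    (1 - fy) * fx * img[cbind(y0, x1)] +
    fy * (1 - fx) * img[cbind(y1, x0)] +
    fy * fx * img[cbind(y1, x1)]
  out[qy < 0.5 | qy > ny + 0.5 | qx < 0.5 | qx > nx + 0.5] <- NA_real_
  out
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour linking of along-axis positions frame to
#' frame: each detection in frame `f + 1` is linked to the closest
#' unclaimed track end within
#' `max_jump_um = max(max_jump_factor * v_min * dt, 2 px)`;
#' assignments are made in order of increasing distance, so crossing
#' tracks resolve to the minimal total jump (documented, not guaranteed
#' correct). Unlinked detections start new tracks; tracks shorter than
#' `cfg$min_track_frames` frames are dropped.
#'
#' @param detections data.frame with `frame` and `s_um` (along-axis
#'   position).
#' @param cfg a [transport_config()].
#' @return data.frame `id, frame, time_s, s_um`.
#' @export
link_tracks <- function(detections, cfg = transport_config()) {
  stopifnot(all(c("frame", "s_um") %in% names(detections)))
  max_jump <- max(cfg$max_jump_factor * cfg$v_min_um_s * cfg$dt_s,
                  2 * cfg$pixel_size_um)
  frames <- sort(unique(detections$frame))
  track_pos <- numeric(0)   # last position per open track
  track_frame <- integer(0) # last frame per open track
  track_id <- integer(0)
  next_id <- 0L
  out <- list()
  for (f in frames) {
    pos <- detections$s_um[detections$frame == f]
    assigned <- rep(NA_integer_, length(pos))
    open <- which(track_frame == f - 1L)
    if (length(open) > 0L && length(pos) > 0L) {
      dmat <- abs(outer(track_pos[open], pos, "-"))
      cand <- which(dmat <= max_jump, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        cand <- cand[order(dmat[cand]), , drop = FALSE]
        used_tr <- logical(length(open)); used_det <- logical(length(pos))
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1L]; j <- cand[r, 2L]
          if (!used_tr[i] && !used_det[j]) {
            used_tr[i] <- TRUE; used_det[j] <- TRUE
            assigned[j] <- track_id[open[i]]
          }
        }
      }
    }
    for (j in seq_along(pos)) {
      if (is.na(assigned[j])) {
        next_id <- next_id + 1L
        assigned[j] <- next_id
        track_pos <- c(track_pos, pos[j])
        track_frame <- c(track_frame, f)
        track_id <- c(track_id, next_id)
      } else {
        k <- match(assigned[j], track_id)
        track_pos[k] <- pos[j]
        track_frame[k] <- f
      }
      out[[length(out) + 1L]] <- data.frame(
        id = assigned[j], frame = f, time_s = (f - 1L) * cfg$dt_s,
        s_um = pos[j])
    }
  }
  tracks <- do.call(rbind, out)
  keep <- names(which(table(tracks$id) >= cfg$min_track_frames))
  tracks <- tracks[tracks$id %in% as.integer(keep), , drop = FALSE]
  tracks[order(tracks$id, tracks$frame), ]
}

#' Classify tracks as stationary, anterograde or retrograde
#'
#' A track is stationary if its mean frame-to-frame speed
#' `mean(|ds|) / dt` is below `cfg$v_min_um_s`; otherwise it is anterograde
#' if its net displacement (end minus start, positive away from the soma)
#' is positive and retrograde if negative. A motile-speed tie at exactly
#' zero net displacement is broken to stationary and flagged. Per track the
#' function reports the motile velocity (mean `|ds|/dt` over frames moving
#' at or above `v_min`), the whole-track mean speed, signed net
#' displacement, cumulative path length, and descriptive burst frames
#' (instantaneous speed above 3x the track median).
#'
#' @param tracks data.frame `id, frame, time_s, s_um` (>= 5 frames per
#'   track).
#' @param cfg a [transport_config()].
#' @return list with `tracks` (per-track data.frame: `class`,
#'   `velocity_um_s`, `mean_speed_um_s`, `net_displacement_um`,
#'   `path_length_um`, `n_burst_frames`, `flagged`) and `cohort`
#'   (class fractions, per-direction velocity mean +/- SE, motile path
#'   length mean +/- SE).
#' @export
classify_tracks <- function(tracks, cfg = transport_config()) {
  per <- lapply(split(tracks, tracks$id), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 5L) stop("tracks must have >= 5 frames (track ",
                            tr$id[1L], ")")
    ds <- diff(tr$s_um)
    dt <- diff(tr$time_s)
    sp <- abs(ds) / dt
    mean_speed <- mean(sp)
    net <- tr$s_um[nrow(tr)] - tr$s_um[1L]
    flagged <- FALSE
    if (mean_speed < cfg$v_min_um_s) {
      cl <- "stationary"
    } else if (net > 0) {
      cl <- "anterograde"
    } else if (net < 0) {
      cl <- "retrograde"
    } else {
      cl <- "stationary"; flagged <- TRUE
    }
    motile <- sp >= cfg$v_min_um_s
    vel <- if (any(motile)) mean(sp[motile]) else NA_real_
    med <- stats::median(sp)
    data.frame(id = tr$id[1L], n_frames = nrow(tr), class = cl,
               velocity_um_s = vel, mean_speed_um_s = mean_speed,
               net_displacement_um = net, path_length_um = sum(abs(ds)),
               n_burst_frames = if (med > 0) sum(sp > 3 * med) else 0L,
               flagged = flagged)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  se <- function(x) if (length(x) < 2L) 0 else stats::sd(x) / sqrt(length(x))
  frac <- function(cl) mean(per$class == cl)
  motile <- per[per$class != "stationary", , drop = FALSE]
  dir_stats <- function(cl) {
    v <- per$velocity_um_s[per$class == cl]
    c(mean = if (length(v)) mean(v) else NA_real_, se = se(v))
  }
  av <- dir_stats("anterograde"); rv <- dir_stats("retrograde")
  cohort <- data.frame(
    n_tracks = nrow(per),
    frac_stationary = frac("stationary"),
    frac_anterograde = frac("anterograde"),
    frac_retrograde = frac("retrograde"),
    anterograde_velocity_mean = av[["mean"]],
    anterograde_velocity_se = av[["se"]],
    retrograde_velocity_mean = rv[["mean"]],
    retrograde_velocity_se = rv[["se"]],
    motile_path_length_mean = if (nrow(motile)) mean(motile$path_length_um)
                              else NA_real_,
    motile_path_length_se = se(motile$path_length_um),
    motile_net_displacement_mean =
      if (nrow(motile)) mean(abs(motile$net_displacement_um)) else NA_real_)
  list(tracks = per, cohort = cohort)
}
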