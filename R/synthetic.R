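#' Synthetic microscopy generators
#'
#' Every input modality the pipeline consumes can be simulated with a known
#' ground truth, so each analysis stage is testable by parameter recovery.
#' All generators take an explicit integer `seed`, use one local RNG per
#' call (the caller's RNG state is untouched) and are bit-reproducible:
#' identical parameters + seed give identical output.
#'
#' The camera model everywhere is Poisson shot noise on the expected signal
#' plus additive Gaussian read noise, rounded to integer counts and clipped
#' at zero. The signal-to-noise ratio `snr` of a fluorescent object is
#' defined as `(peak - background) / sd(background)` with
#' `sd(background) = sqrt(background_level + read_noise_sd^2)`.
#'
#' @name synthetic
NULL

# ---- shared rendering helpers -------------------------------------------

# Add elliptical Gaussian spots to an image. spots: data.frame with
# y, x (pixel coords, may be fractional), amplitude, sigma_major,
# sigma_minor, theta (radians, major-axis direction).
render_spots <- function(img, spots) {
  ny <- nrow(img); nx <- ncol(img)
  for (i in seq_len(nrow(spots))) {
    s <- spots[i, ]
    ext <- ceiling(4 * s$sigma_major)
    y0 <- max(1L, floor(s$y - ext)); y1 <- min(ny, ceiling(s$y + ext))
    x0 <- max(1L, floor(s$x - ext)); x1 <- min(nx, ceiling(s$x + ext))
    if (y0 > y1 || x0 > x1) next
    yy <- matrix(y0:y1, y1 - y0 + 1L, x1 - x0 + 1L) - s$y
    xx <- matrix(x0:x1, y1 - y0 + 1L, x1 - x0 + 1L, byrow = TRUE) - s$x
    u <- cos(s$theta) * yy + sin(s$theta) * xx   # along major axis
    v <- -sin(s$theta) * yy + cos(s$theta) * xx
    img[y0:y1, x0:x1] <- img[y0:y1, x0:x1] +
      s$amplitude * exp(-(u^2 / (2 * s$sigma_major^2) +
                          v^2 / (2 * s$sigma_minor^2)))
  }
  img
}

# Poisson shot noise + Gaussian read noise, integer counts clipped at 0.
# With shot_noise = FALSE and zero read noise the expected signal is
# returned untouched (noise-free scenes for exactness tests).
camera_noise <- function(signal, read_noise_sd, shot_noise = TRUE) {
  if (!shot_noise && read_noise_sd == 0) return(signal)
  n <- length(signal)
  obs <- if (shot_noise) stats::rpois(n, lambda = as.vector(signal))
         else as.vector(signal)
  obs <- obs + stats::rnorm(n, 0, read_noise_sd)
  matrix(pmax(0, round(obs)), nrow(signal), ncol(signal))
}

# Rejection-sampled non-overlapping centers inside a disk.
# exclusion[i] is the half-distance granule i needs to its neighbours.
place_in_disk <- function(n, center, radius, exclusion, max_tries = 2000L) {
  ys <- numeric(0); xs <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- radius * sqrt(stats::runif(1))
      a <- stats::runif(1, 0, 2 * pi)
      y <- center[1L] + r * sin(a); x <- center[2L] + r * cos(a)
      if (i == 1L ||
          all(sqrt((ys - y)^2 + (xs - x)^2) >=
              exclusion[seq_len(i - 1L)] + exclusion[i])) {
        ys <- c(ys, y); xs <- c(xs, x); placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("packing error: could not place ", n,
           " non-overlapping granules after ", max_tries, " tries each")
    }
  }
  cbind(y = ys, x = xs)
}

# ---- granule scenes ------------------------------------------------------

#' Simulate a single-plane cell with punctate granules
#'
#' Renders a circular cell (uniform diffuse cytoplasm over a darker
#' extracellular background) containing `n_granules` non-overlapping
#' granules. Circular granules are isotropic Gaussian spots; amorphic
#' granules are elongated anisotropic Gaussians with major/minor axis
#' ratio >= 3, drawn at a random orientation.
#'
#' @param n_granules number of granules (>= 0).
#' @param cell_diameter_um cell diameter along its longest axis.
#' @param granule_radius_um_mean,granule_radius_um_sd radius distribution;
#'   the rendered Gaussian sigma is `radius / 2` (so ~95% of the intensity
#'   falls within the nominal radius).
#' @param amorphic_fraction fraction of granules rendered as elongated
#'   blobs (rounded to a whole count).
#' @param snr peak signal-to-noise ratio over the cytoplasm (see
#'   [synthetic]).
#' @param pixel_size_um pixel size; default matches imaging where
#'   3 px = 0.252 um.
#' @param cytoplasm_level,outside_level expected counts inside/outside the
#'   cell.
#' @param read_noise_sd camera read noise (counts).
#' @param seed integer seed.
#' @return list with `stack` ([ImageStack], one plane), `cell_mask`
#'   (logical matrix), `cell_roi` (circle [roi]), and `truth` (generator
#'   name, parameters, and a per-granule data.frame with center, radius,
#'   sigmas, orientation and morphology class).
#' @export
gen_granule_scene <- function(n_granules = 12L, cell_diameter_um = 10,
                              granule_radius_um_mean = 0.3,
                              granule_radius_um_sd = 0.05,
                              amorphic_fraction = 0, snr = 10,
                              pixel_size_um = 0.084,
                              cytoplasm_level = 200, outside_level = 20,
                              read_noise_sd = 3, seed = 1L) {
  stopifnot(n_granules >= 0, amorphic_fraction >= 0, amorphic_fraction <= 1)
  params <- list(n_granules = n_granules, cell_diameter_um = cell_diameter_um,
                 granule_radius_um_mean = granule_radius_um_mean,
                 granule_radius_um_sd = granule_radius_um_sd,
                 amorphic_fraction = amorphic_fraction, snr = snr,
                 pixel_size_um = pixel_size_um,
                 cytoplasm_level = cytoplasm_level,
                 outside_level = outside_level,
                 read_noise_sd = read_noise_sd, seed = seed)
  with_seed(seed, {
    cell_r_px <- cell_diameter_um / 2 / pixel_size_um
    margin <- 10
    side <- ceiling(2 * (cell_r_px + margin))
    ctr <- c(side, side) / 2 + 0.5
    cell_roi <- roi_circle(ctr, cell_r_px, "cell")
    cell_mask <- roi_mask(cell_roi, c(side, side))

    n_amorphic <- round(amorphic_fraction * n_granules)
    cls <- rep("circular", n_granules)
    if (n_amorphic > 0) cls[sample(n_granules, n_amorphic)] <- "amorphic"
    radius_um <- pmax(0.15, stats::rnorm(n_granules, granule_radius_um_mean,
                                         granule_radius_um_sd))
    sig_minor <- radius_um / 2 / pixel_size_um
    ratio <- ifelse(cls == "amorphic", stats::runif(n_granules, 3, 4), 1)
    sig_major <- sig_minor * ratio
    theta <- ifelse(cls == "amorphic", stats::runif(n_granules, 0, pi), 0)
    amp <- snr * sqrt(cytoplasm_level + read_noise_sd^2)

    truth <- data.frame(id = seq_len(n_granules))[seq_len(n_granules), ,
                                                  drop = FALSE]
    if (n_granules > 0) {
      # anisotropy-aware exclusion: pairwise center distances of
      # excl_i + excl_j keep above-threshold supports from merging even
      # when elongated blobs point at each other
      excl <- sig_major + 2 * sig_minor + 1
      pos <- place_in_disk(n_granules, ctr,
                           max(1, cell_r_px - max(excl) - 2), excl)
      truth <- data.frame(id = seq_len(n_granules), y = pos[, "y"],
                          x = pos[, "x"], radius_um = radius_um,
                          sigma_minor_px = sig_minor,
                          sigma_major_px = sig_major, theta = theta,
                          class = cls, amplitude = amp)
    } else {
      truth <- data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                          radius_um = numeric(0), sigma_minor_px = numeric(0),
                          sigma_major_px = numeric(0), theta = numeric(0),
                          class = character(0), amplitude = numeric(0))
    }
    signal <- matrix(outside_level, side, side)
    signal[cell_mask] <- cytoplasm_level
    signal <- render_spots(signal, truth)
    img <- camera_noise(signal, read_noise_sd)
    list(stack = ImageStack(img, pixel_size_um = pixel_size_um),
         cell_mask = cell_mask, cell_roi = cell_roi,
         truth = list(generator = "granule_scene", params = params,
                      granules = truth, seed = seed))
  })
}

# ---- FRAP traces ---------------------------------------------------------

#' Simulate a FRAP experiment as mean-ROI intensity traces
#'
#' The bleached-granule truth signal is 100 (arbitrary pre-bleach units)
#' for the `n_pre` pre-bleach frames; after the bleach it follows the
#' one-phase association `S(t) = Y0 + (P - Y0) * (1 - exp(-K (t - t0)))`
#' with `Y0 = 100 (1 - bleach_depth)`, plateau `P = Y0 + Fm (100 - Y0)` and
#' rate `K = log(2) / t_half_s`. Both the bleached and the unbleached
#' reference trace are multiplied by a shared per-frame acquisition
#' photobleaching decay `d^i` with `d = 1 - drift_per_frame` (the artifact
#' the photobleach-correction step cancels), then offset by
#' `background_level` and perturbed by Gaussian noise. The background trace
#' is constant at `background_level` plus noise.
#'
#' @param Fm mobile fraction in `[0, 1]`.
#' @param t_half_s recovery half-time (s).
#' @param bleach_depth fraction of the pre-bleach signal removed by the
#'   bleach (1 = complete bleach).
#' @param drift_per_frame per-frame acquisition photobleaching in `[0, 1)`.
#' @param background_level additive constant background (default 0; see the
#'   methods vignette for why a nonzero value plus nonzero drift makes the
#'   correction approximate rather than exact).
#' @param noise_sd Gaussian noise sd on every trace (pre-bleach units).
#' @param n_pre,n_post pre-/post-bleach frame counts.
#' @param dt_s frame interval (default 1.0878 s).
#' @param seed integer seed.
#' @return list with `trace` (a [frap_trace]) and `truth` (true signal
#'   `S`, true parameters including `Y0`, `P`, `K`).
#' @export
gen_frap_trace <- function(Fm, t_half_s, bleach_depth = 1,
                           drift_per_frame = 0, background_level = 0,
                           noise_sd = 0, n_pre = 2L, n_post = 200L,
                           dt_s = 1.0878, seed = 1L) {
  stopifnot(Fm >= 0, Fm <= 1, t_half_s > 0, bleach_depth >= 0,
            bleach_depth <= 1, drift_per_frame >= 0, drift_per_frame < 1,
            n_pre >= 1, n_post >= 1)
  n <- n_pre + n_post
  times <- (seq_len(n) - 1L) * dt_s
  t0 <- times[n_pre + 1L]
  Y0 <- 100 * (1 - bleach_depth)
  P <- Y0 + Fm * (100 - Y0)
  K <- log(2) / t_half_s
  S <- c(rep(100, n_pre),
         Y0 + (P - Y0) * (1 - exp(-K * (times[(n_pre + 1L):n] - t0))))
  d <- (1 - drift_per_frame)^(seq_len(n) - 1L)
  with_seed(seed, {
    bleached <- S * d + background_level + stats::rnorm(n, 0, noise_sd)
    unbleached <- 100 * d + background_level + stats::rnorm(n, 0, noise_sd)
    background <- background_level + stats::rnorm(n, 0, noise_sd)
    trace <- frap_trace(times_s = times, bleached = bleached,
                        unbleached = unbleached, background = background,
                        n_pre = n_pre)
    list(trace = trace,
         truth = list(generator = "frap_trace", S = S, Y0 = Y0, P = P, K = K,
                      params = list(Fm = Fm, t_half_s = t_half_s,
                                    bleach_depth = bleach_depth,
                                    drift_per_frame = drift_per_frame,
                                    background_level = background_level,
                                    noise_sd = noise_sd, n_pre = n_pre,
                                    n_post = n_post, dt_s = dt_s,
                                    seed = seed)))
  })
}

#' Render a FRAP trace as a small synthetic movie
#'
#' Builds an image time series with a bleached granule, an unbleached
#' reference granule and diffuse background whose mean-ROI traces equal the
#' analytic traces of [gen_frap_trace()], for end-to-end tests of
#' [extract_traces()].
#'
#' @inheritParams gen_frap_trace
#' @param granule_sigma_px Gaussian radius of the rendered granules.
#' @param drift_px_per_frame slow (y, x) drift applied to both granules, to
#'   exercise ROI following.
#' @param pixel_size_um spatial calibration of the rendered movie.
#' @return list with `stack`, `rois` (bleached/unbleached/background), the
#'   underlying `trace` and `truth`.
#' @export
gen_frap_movie <- function(Fm, t_half_s, bleach_depth = 1,
                           drift_per_frame = 0, background_level = 20,
                           noise_sd = 0, n_pre = 2L, n_post = 60L,
                           dt_s = 1.0878, granule_sigma_px = 2.5,
                           drift_px_per_frame = c(0, 0),
                           pixel_size_um = 0.084, seed = 1L) {
  sim <- gen_frap_trace(Fm, t_half_s, bleach_depth, drift_per_frame,
                        background_level = 0, noise_sd = 0,
                        n_pre = n_pre, n_post = n_post, dt_s = dt_s,
                        seed = seed)
  n <- n_pre + n_post
  side <- 64L
  pos_b <- c(20, 20); pos_u <- c(44, 44)
  frames <- array(0, c(n, 1L, 1L, side, side))
  d <- (1 - drift_per_frame)^(seq_len(n) - 1L)
  with_seed(seed, {
    for (i in seq_len(n)) {
      off <- (i - 1L) * drift_px_per_frame
      spots <- data.frame(
        y = c(pos_b[1L] + off[1L], pos_u[1L] + off[1L]),
        x = c(pos_b[2L] + off[2L], pos_u[2L] + off[2L]),
        amplitude = c(sim$truth$S[i] * d[i], 100 * d[i]),
        sigma_major = granule_sigma_px, sigma_minor = granule_sigma_px,
        theta = 0)
      img <- render_spots(matrix(background_level, side, side), spots)
      if (noise_sd > 0) img <- img + stats::rnorm(side * side, 0, noise_sd)
      frames[i, 1L, 1L, , ] <- pmax(0, img)
    }
  })
  r <- 1.2 * granule_sigma_px
  rois <- list(bleached = roi_circle(pos_b, r, "bleached"),
               unbleached = roi_circle(pos_u, r, "unbleached"),
               background = roi_circle(c(54, 10), 4, "background"))
  list(stack = ImageStack(frames, pixel_size_um = pixel_size_um,
                          frame_interval_s = dt_s),
       rois = rois, trace = sim$trace, truth = sim$truth)
}

# ---- neurite transport ---------------------------------------------------

#' Simulate neurite transport tracks (and optionally a movie)
#'
#' Positions are 1-D along-axis coordinates in micrometres from the soma,
#' increasing away from the cell body. Stationary granules jitter with a
#' sub-threshold amplitude; motile granules alternate runs (probability
#' `p_move` per frame, directed at the track's run speed) with stationary
#' pauses, so whole-track mean speeds sit between the jitter floor and the
#' run speed, as in real kymographs. A random subset of motile tracks gets
#' one contiguous burst of rapid movement (`burst_multiplier` times the run
#' speed).
#'
#' Class counts are fixed to `round(fraction * n_tracks)` (largest-remainder
#' apportionment) so the generated class composition is exactly known.
#'
#' @param n_tracks number of tracks.
#' @param fractions named fractions for `stationary`, `anterograde`,
#'   `retrograde`; must sum to 1.
#' @param speed_um_s_mean,speed_um_s_sd run-speed distribution of motile
#'   granules.
#' @param p_move per-frame probability a motile granule is running.
#' @param burst_prob probability a motile track contains a burst.
#' @param burst_multiplier,burst_duration_frames burst speed multiplier and
#'   length.
#' @param jitter_um_s mean jitter speed of stationary phases (well below
#'   the 0.138 um/s classification floor).
#' @param neurite_length_um length of the neurite.
#' @param n_frames,dt_s frames and frame interval (defaults 100 frames,
#'   4.84 s = 484 s total).
#' @param pixel_size_um pixel size, used when rendering the movie.
#' @param movie if `TRUE`, also render the tracks as a Gaussian-spot movie
#'   along a straight horizontal neurite.
#' @param snr,background_level,read_noise_sd movie rendering parameters.
#' @param seed integer seed.
#' @return list with `tracks` (data.frame `id, frame, time_s, s_um`),
#'   `truth` (per-track class, run speed, burst frames, exact class
#'   fractions), and optionally `stack` + `neurite_roi`.
#' @export
gen_transport_tracks <- function(n_tracks = 100L,
                                 fractions = c(stationary = 0.7,
                                               anterograde = 0.2,
                                               retrograde = 0.1),
                                 speed_um_s_mean = 0.5, speed_um_s_sd = 0.1,
                                 p_move = 0.5, burst_prob = 0.1,
                                 burst_multiplier = 3,
                                 burst_duration_frames = 5L,
                                 jitter_um_s = 0.06,
                                 neurite_length_um = 150,
                                 n_frames = 100L, dt_s = 4.84,
                                 pixel_size_um = 0.138, movie = FALSE,
                                 snr = 10, background_level = 50,
                                 read_noise_sd = 2, seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, n_tracks >= 1, n_frames >= 2)
  fr <- fractions[c("stationary", "anterograde", "retrograde")]
  # largest-remainder apportionment to integer counts
  raw <- fr * n_tracks
  cnt <- floor(raw)
  rem <- n_tracks - sum(cnt)
  if (rem > 0) {
    order_rem <- order(raw - cnt, decreasing = TRUE)
    cnt[order_rem[seq_len(rem)]] <- cnt[order_rem[seq_len(rem)]] + 1L
  }
  classes <- rep(names(cnt), cnt)
  L <- neurite_length_um
  with_seed(seed, {
    classes <- sample(classes)
    sd_jit <- jitter_um_s * dt_s * sqrt(pi / 2)
    rows <- vector("list", n_tracks)
    tr_truth <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      cl <- classes[i]
      speed <- max(0.25, stats::rnorm(1, speed_um_s_mean, speed_um_s_sd))
      start <- switch(cl,
        stationary = stats::runif(1, 5, L - 5),
        anterograde = stats::runif(1, 2, 0.15 * L),
        retrograde = stats::runif(1, 0.85 * L, L - 2))
      jit <- stats::rnorm(n_frames - 1L, 0, sd_jit)
      if (cl == "stationary") {
        steps <- jit
        burst_frames <- integer(0)
      } else {
        dir <- if (cl == "anterograde") 1 else -1
        moving <- stats::runif(n_frames - 1L) < p_move
        mult <- rep(1, n_frames - 1L)
        burst_frames <- integer(0)
        if (stats::runif(1) < burst_prob) {
          b0 <- sample(max(1L, n_frames - 1L - burst_duration_frames), 1L)
          burst_frames <- b0:(b0 + burst_duration_frames - 1L)
          mult[burst_frames] <- burst_multiplier
          moving[burst_frames] <- TRUE
        }
        steps <- ifelse(moving, dir * speed * mult * dt_s, jit)
      }
      s <- pmin(L, pmax(0, start + cumsum(c(0, steps))))
      rows[[i]] <- data.frame(id = i, frame = seq_len(n_frames),
                              time_s = (seq_len(n_frames) - 1L) * dt_s,
                              s_um = s)
      tr_truth[[i]] <- data.frame(id = i, class = cl, speed_um_s = speed,
                                  n_burst_frames = length(burst_frames))
    }
    tracks <- do.call(rbind, rows)
    truth_df <- do.call(rbind, tr_truth)
    out <- list(tracks = tracks,
                truth = list(generator = "transport_tracks",
                             tracks = truth_df,
                             fractions = cnt / n_tracks,
                             params = list(n_tracks = n_tracks,
                                           fractions = fr,
                                           speed_um_s_mean = speed_um_s_mean,
                                           speed_um_s_sd = speed_um_s_sd,
                                           p_move = p_move,
                                           burst_prob = burst_prob,
                                           jitter_um_s = jitter_um_s,
                                           n_frames = n_frames, dt_s = dt_s,
                                           seed = seed)))
    if (movie) {
      nx <- ceiling(L / pixel_size_um) + 10L
      ny <- 15L
      amp <- snr * sqrt(background_level + read_noise_sd^2)
      frames <- array(0, c(n_frames, 1L, 1L, ny, nx))
      for (f in seq_len(n_frames)) {
        pos <- tracks$s_um[tracks$frame == f] / pixel_size_um + 5
        spots <- data.frame(y = 8, x = pos, amplitude = amp,
                            sigma_major = 1.5, sigma_minor = 1.5, theta = 0)
        frames[f, 1L, 1L, , ] <-
          camera_noise(render_spots(matrix(background_level, ny, nx), spots),
                       read_noise_sd)
      }
      out$stack <- ImageStack(frames, pixel_size_um = pixel_size_um,
                              frame_interval_s = dt_s)
      out$neurite_roi <- roi_polyline(rbind(c(8, 5), c(8, nx - 5)),
                                      "neurite")
    }
    out
  })
}

# ---- two-channel colocalization scenes ----------------------------------

#' Simulate a two-channel granule scene with tunable overlap
#'
#' `n_shared` granules appear at identical coordinates in both channels;
#' `n_only_a` / `n_only_b` granules are channel-specific. Noise is drawn
#' independently per channel.
#'
#' @param n_shared,n_only_a,n_only_b granule counts (>= 0).
#' @param shot_noise apply Poisson shot noise? Set `FALSE` together with
#'   `read_noise_sd = 0` for exactly noise-free channels.
#' @inheritParams gen_granule_scene
#' @return list with `stack` (2-channel [ImageStack]), `cell_mask`,
#'   `cell_roi` and `truth` (positions plus channel membership).
#' @export
gen_two_channel_scene <- function(n_shared = 10L, n_only_a = 5L,
                                  n_only_b = 5L, snr = 10,
                                  cell_diameter_um = 10,
                                  granule_radius_um_mean = 0.3,
                                  pixel_size_um = 0.084,
                                  cytoplasm_level = 200, outside_level = 20,
                                  read_noise_sd = 3, shot_noise = TRUE,
                                  seed = 1L) {
  stopifnot(n_shared >= 0, n_only_a >= 0, n_only_b >= 0)
  n <- n_shared + n_only_a + n_only_b
  with_seed(seed, {
    cell_r_px <- cell_diameter_um / 2 / pixel_size_um
    side <- ceiling(2 * (cell_r_px + 10))
    ctr <- c(side, side) / 2 + 0.5
    cell_roi <- roi_circle(ctr, cell_r_px, "cell")
    cell_mask <- roi_mask(cell_roi, c(side, side))
    sig <- granule_radius_um_mean / 2 / pixel_size_um
    amp <- snr * sqrt(cytoplasm_level + read_noise_sd^2)
    membership <- rep(c("shared", "a_only", "b_only"),
                      c(n_shared, n_only_a, n_only_b))
    if (n > 0) {
      pos <- place_in_disk(n, ctr, max(1, cell_r_px - 3 * sig - 2),
                           rep(3 * sig + 1, n))
      truth <- data.frame(id = seq_len(n), y = pos[, "y"], x = pos[, "x"],
                          membership = membership)
    } else {
      truth <- data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                          membership = character(0))
    }
    base <- matrix(outside_level, side, side)
    base[cell_mask] <- cytoplasm_level
    mk <- function(keep) {
      sp <- truth[truth$membership %in% keep, , drop = FALSE]
      spd <- data.frame(y = sp$y, x = sp$x, amplitude = amp,
                        sigma_major = sig, sigma_minor = sig, theta = 0)
      camera_noise(render_spots(base, spd), read_noise_sd, shot_noise)
    }
    a <- mk(c("shared", "a_only"))
    b <- mk(c("shared", "b_only"))
    px <- array(0, c(1L, 1L, 2L, side, side))
    px[1, 1, 1, , ] <- a
    px[1, 1, 2, , ] <- b
    list(stack = ImageStack(px, pixel_size_um = pixel_size_um),
         cell_mask = cell_mask, cell_roi = cell_roi,
         truth = list(generator = "two_channel_scene", granules = truth,
                      seed = seed))
  })
}

# ---- smFISH spot scenes --------------------------------------------------

#' Simulate a single-molecule FISH scene with soma and neurite masks
#'
#' Diffraction-limited spots (isotropic Gaussians of `psf_sigma_px`) are
#' placed inside a circular soma and along straight neurites radiating from
#' it. Soma and neurite masks are returned as label images; the truth
#' records every spot's compartment.
#'
#' @param n_soma,n_neurite spot counts per compartment.
#' @param soma_radius_um soma radius.
#' @param n_neurites number of neurites.
#' @param neurite_length_um,neurite_width_um neurite geometry.
#' @param psf_sigma_px point-spread sigma in pixels.
#' @param snr spot peak SNR over background.
#' @param pixel_size_um pixel size.
#' @param background_level,read_noise_sd camera model parameters.
#' @param min_sep_px minimum pairwise spot separation (rejection sampled);
#'   about 3 PSF sigmas by default so every truth spot is resolvable.
#'   Real smFISH images do contain unresolvable pairs; see the spot-merge
#'   limitation of [detect_spots()].
#' @param seed integer seed.
#' @return list with `stack`, `soma_mask`, `neurite_mask` (0/1 label
#'   matrices) and `truth` (spot coordinates + compartment).
#' @export
gen_spot_scene <- function(n_soma = 20L, n_neurite = 5L, soma_radius_um = 5,
                           n_neurites = 2L, neurite_length_um = 30,
                           neurite_width_um = 1, psf_sigma_px = 1.3,
                           snr = 8, pixel_size_um = 0.117,
                           background_level = 100, read_noise_sd = 2,
                           min_sep_px = 4, seed = 1L) {
  stopifnot(n_soma >= 0, n_neurite >= 0, n_neurites >= 1)
  with_seed(seed, {
    r_px <- soma_radius_um / pixel_size_um
    len_px <- neurite_length_um / pixel_size_um
    w_px <- neurite_width_um / pixel_size_um
    side <- ceiling(2 * (r_px + len_px + 8))
    ctr <- c(side, side) / 2 + 0.5
    ang <- stats::runif(n_neurites, 0, 2 * pi)
    yy <- matrix(seq_len(side), side, side)
    xx <- matrix(seq_len(side), side, side, byrow = TRUE)
    soma_mask <- (yy - ctr[1])^2 + (xx - ctr[2])^2 <= r_px^2
    neurite_mask <- matrix(FALSE, side, side)
    seg <- vector("list", n_neurites)
    for (k in seq_len(n_neurites)) {
      p0 <- ctr + r_px * c(sin(ang[k]), cos(ang[k]))
      p1 <- ctr + (r_px + len_px) * c(sin(ang[k]), cos(ang[k]))
      seg[[k]] <- rbind(p0, p1)
      # distance from every pixel center to the segment
      d <- p1 - p0
      tt <- pmin(1, pmax(0, ((yy - p0[1]) * d[1] + (xx - p0[2]) * d[2]) /
                              sum(d^2)))
      d2 <- (p0[1] + tt * d[1] - yy)^2 + (p0[2] + tt * d[2] - xx)^2
      neurite_mask <- neurite_mask | d2 <= (w_px / 2)^2
    }
    neurite_mask <- neurite_mask & !soma_mask
    spots <- data.frame(y = numeric(0), x = numeric(0),
                        compartment = character(0))
    add_spot <- function(draw, compartment, n) {
      for (i in seq_len(n)) {
        for (try in 1:500) {
          p <- draw()
          if (nrow(spots) == 0L ||
              min(sqrt((spots$y - p[1])^2 + (spots$x - p[2])^2)) >=
                min_sep_px) break
          if (try == 500) stop("packing error: spots too dense for ",
                               "min_sep_px = ", min_sep_px)
        }
        spots[nrow(spots) + 1L, ] <<- list(p[1], p[2], compartment)
      }
    }
    add_spot(function() {
      rr <- (r_px - 3) * sqrt(stats::runif(1))
      aa <- stats::runif(1, 0, 2 * pi)
      c(ctr[1] + rr * sin(aa), ctr[2] + rr * cos(aa))
    }, "soma", n_soma)
    add_spot(function() {
      k <- sample(n_neurites, 1)
      u <- stats::runif(1, 4, len_px - 3)   # arc position past soma
      off <- stats::runif(1, -w_px / 5, w_px / 5)
      ydir <- sin(ang[k]); xdir <- cos(ang[k])
      c(ctr[1] + (r_px + u) * ydir - off * xdir,
        ctr[2] + (r_px + u) * xdir + off * ydir)
    }, "neurite", n_neurite)
    amp <- snr * sqrt(background_level + read_noise_sd^2)
    signal <- matrix(background_level, side, side)
    if (nrow(spots) > 0) {
      spd <- data.frame(y = spots$y, x = spots$x, amplitude = amp,
                        sigma_major = psf_sigma_px,
                        sigma_minor = psf_sigma_px, theta = 0)
      signal <- render_spots(signal, spd)
    }
    img <- camera_noise(signal, read_noise_sd)
    list(stack = ImageStack(img, pixel_size_um = pixel_size_um),
         soma_mask = soma_mask * 1L, neurite_mask = neurite_mask * 1L,
         truth = list(generator = "spot_scene", spots = spots, seed = seed))
  })
}

# ---- dual-luciferase plates ---------------------------------------------

#' Simulate a dual-luciferase reporter plate
#'
#' Each well's Renilla (RLuc) reading is drawn around `rluc_mean`; the
#' firefly (FLuc) reading is `RLuc * baseline_ratio / fold` times
#' multiplicative log-normal noise with coefficient of variation
#' `noise_cv`. The control construct has fold = 1, so noise-free
#' normalized ratios equal `1 / fold` exactly.
#'
#' @param true_fold named vector of repression folds per construct; must
#'   include the control (fold 1).
#' @param control name of the control construct.
#' @param rluc_mean mean RLuc luminescence.
#' @param baseline_ratio FLuc/RLuc ratio of the unrepressed control.
#' @param noise_cv multiplicative noise CV (0 = noise-free).
#' @param n_technical technical replicates per construct per plate.
#' @param n_plates independent experiments.
#' @param seed integer seed.
#' @return list with `wells` (data.frame `plate, construct, replicate,
#'   fluc, rluc`), `control`, and `truth` (the fold vector).
#' @export
gen_plate <- function(true_fold = c(control = 1, reporter = 4),
                      control = "control", rluc_mean = 1e6,
                      baseline_ratio = 0.5, noise_cv = 0.1,
                      n_technical = 3L, n_plates = 1L, seed = 1L) {
  stopifnot(control %in% names(true_fold), all(true_fold > 0),
            n_technical >= 1, n_plates >= 1)
  sdl <- sqrt(log(1 + noise_cv^2))
  lnoise <- function(n) {
    if (noise_cv == 0) rep(1, n) else stats::rlnorm(n, -sdl^2 / 2, sdl)
  }
  with_seed(seed, {
    wells <- expand.grid(replicate = seq_len(n_technical),
                         construct = names(true_fold),
                         plate = seq_len(n_plates),
                         stringsAsFactors = FALSE)[, c("plate", "construct",
                                                       "replicate")]
    nw <- nrow(wells)
    wells$rluc <- rluc_mean * lnoise(nw)
    wells$fluc <- wells$rluc * baseline_ratio /
      true_fold[wells$construct] * lnoise(nw)
    list(wells = wells, control = control,
         truth = list(generator = "plate", fold = true_fold, seed = seed))
  })
}
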