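make_track <- function(id, s, dt = 4.84) {
  data.frame(id = id, frame = seq_along(s),
             time_s = (seq_along(s) - 1) * dt, s_um = s)
}

test_that("the speed floor separates slow jitter from directed motion", {
  dt <- 4.84
  # |step| = 0.10 um/s * dt, alternating direction: mean speed 0.10 < 0.138
  jitter <- make_track(1, 20 + cumsum(c(0, rep(c(1, -1), 10) * 0.10 * dt)))
  # constant 0.50 um/s away from the soma
  run <- make_track(2, 5 + (0:20) * 0.50 * dt)
  res <- classify_tracks(rbind(jitter, run))
  expect_equal(res$tracks$class, c("stationary", "anterograde"))
  expect_equal(res$tracks$velocity_um_s[2], 0.5, tolerance = 1e-9)
  expect_equal(res$tracks$path_length_um[2], 0.5 * 20 * dt)
  expect_equal(res$tracks$net_displacement_um[2], 0.5 * 20 * dt)

  # frozen track
  frozen <- make_track(3, rep(12, 15))
  expect_equal(classify_tracks(frozen)$tracks$class, "stationary")

  # toward the soma
  retro <- make_track(4, 60 - (0:20) * 0.3 * dt)
  expect_equal(classify_tracks(retro)$tracks$class, "retrograde")
})

test_that("class fractions sum to one and a zero-net motile tie is flagged stationary", {
  dt <- 4.84
  zigzag <- make_track(1, 30 + cumsum(c(0, rep(c(2, -2), 8))))  # net 0, fast
  res <- classify_tracks(zigzag)
  expect_equal(res$tracks$class, "stationary")
  expect_true(res$tracks$flagged)
  expect_equal(res$cohort$frac_stationary + res$cohort$frac_anterograde +
                 res$cohort$frac_retrograde, 1)
})

test_that("classification recovers generated class fractions and run speeds", {
  sim <- gen_transport_tracks(n_tracks = 100,
                              fractions = c(stationary = 0.7,
                                            anterograde = 0.2,
                                            retrograde = 0.1),
                              speed_um_s_mean = 0.5, burst_prob = 0,
                              seed = 11)
  res <- classify_tracks(sim$tracks)
  co <- res$cohort
  expect_lt(abs(co$frac_stationary - 0.7), binom_ci_halfwidth(0.7, 100))
  expect_lt(abs(co$frac_anterograde - 0.2), binom_ci_halfwidth(0.2, 100))
  expect_lt(abs(co$frac_retrograde - 0.1), binom_ci_halfwidth(0.1, 100))
  expect_lt(abs(co$anterograde_velocity_mean - 0.5) / 0.5, 0.1)

  # all-stationary degenerate case
  allst <- gen_transport_tracks(
    n_tracks = 20, fractions = c(stationary = 1, anterograde = 0,
                                 retrograde = 0), seed = 3)
  expect_equal(classify_tracks(allst$tracks)$cohort$frac_stationary, 1)
})

test_that("reversing time swaps anterograde and retrograde but not stationary", {
  sim <- gen_transport_tracks(n_tracks = 30, seed = 8)
  fwd <- classify_tracks(sim$tracks)
  rev_tracks <- do.call(rbind, lapply(split(sim$tracks, sim$tracks$id),
                                      function(tr) {
    tr$s_um <- rev(tr$s_um)
    tr
  }))
  bwd <- classify_tracks(rev_tracks)
  swap <- c(stationary = "stationary", anterograde = "retrograde",
            retrograde = "anterograde")
  expect_equal(bwd$tracks$class, unname(swap[fwd$tracks$class]))
})

test_that("link_tracks joins per-frame detections into the generating tracks", {
  sim <- gen_transport_tracks(n_tracks = 1, burst_prob = 0, seed = 3)
  linked <- link_tracks(sim$tracks[, c("frame", "s_um")])
  expect_equal(length(unique(linked$id)), 1L)

  # two well-separated slow granules: two tracks, no identity switches
  dt <- 4.84
  a <- make_track(1, 10 + (0:19) * 0.05 * dt)
  b <- make_track(2, 40 + (0:19) * -0.05 * dt)
  det <- rbind(a, b)[, c("frame", "s_um")]
  linked2 <- link_tracks(det)
  expect_equal(length(unique(linked2$id)), 2L)
  for (gid in unique(linked2$id)) {
    s <- linked2$s_um[linked2$id == gid]
    expect_true(all(abs(diff(s)) < 1))  # never jumps to the other granule
  }

  # sub-minimum-length fragments are dropped
  short <- data.frame(frame = 1:3, s_um = c(5, 5.1, 5.2))
  expect_equal(nrow(link_tracks(short)), 0L)
})

test_that("kymographs map a moving granule to a line of the generating slope", {
  sim <- gen_transport_tracks(n_tracks = 1,
                              fractions = c(stationary = 0, anterograde = 1,
                                            retrograde = 0),
                              p_move = 1, burst_prob = 0, movie = TRUE,
                              seed = 5)
  ky <- build_kymograph(sim$stack, sim$neurite_roi)
  expect_equal(ncol(ky), 100)
  # the ridge position per frame tracks the true position
  ridge_px <- apply(ky, 2, which.max)
  true_px <- sim$tracks$s_um / sim$stack$pixel_size_um
  fit <- stats::lm(ridge_px ~ true_px)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.02)

  # a static granule is a constant-row ridge
  sim2 <- gen_transport_tracks(n_tracks = 1,
                               fractions = c(stationary = 1,
                                             anterograde = 0,
                                             retrograde = 0),
                               jitter_um_s = 0, movie = TRUE, seed = 6)
  ky2 <- build_kymograph(sim2$stack, sim2$neurite_roi)
  # camera noise can move the argmax a pixel or two on the flat-top spot
  expect_lte(diff(range(apply(ky2, 2, which.max))), 2)

  expect_error(build_kymograph(sim$stack,
                               roi_polyline(rbind(c(8, 5), c(8, 5.5)))),
               "geometry error")
})
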