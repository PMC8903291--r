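test_that("Pearson identities and the 3x3 closed-form example hold", {
  a <- matrix(as.numeric(1:9), 3, 3)
  expect_equal(pearson_coloc(a, a)$pearson_r, 1)
  expect_equal(pearson_coloc(a, max(a) - a)$pearson_r, -1)
  # closed form for x = 1..9, y = x^2: cov = 66.67, var_x = 6.67,
  # var_y = 700.89 -> r = 0.9753
  r <- pearson_coloc(a, a^2)$pearson_r
  expect_equal(r, pearson_bruteforce(as.vector(a), as.vector(a)^2))
  expect_equal(round(r, 4), 0.9753)

  flat <- matrix(5, 3, 3)
  res <- pearson_coloc(a, flat)
  expect_true(res$undefined)
  expect_true(is.na(res$pearson_r))
})

test_that("Pearson is invariant under positive affine transforms of either channel", {
  set.seed(4)
  a <- matrix(runif(100), 10, 10)
  b <- matrix(runif(100), 10, 10)
  r0 <- pearson_coloc(a, b)$pearson_r
  expect_equal(pearson_coloc(3.7 * a + 11, b)$pearson_r, r0,
               tolerance = 1e-12)
  expect_equal(pearson_coloc(a, 0.2 * b + 5)$pearson_r, r0,
               tolerance = 1e-12)
})

test_that("colocalization tracks the shared-granule fraction", {
  # fully shared, noise-free scene: identical channels
  sc <- gen_two_channel_scene(n_shared = 10, n_only_a = 0, n_only_b = 0,
                              read_noise_sd = 0, shot_noise = FALSE,
                              seed = 1)
  r1 <- pearson_coloc(stack_frame(sc$stack, c = 1),
                      stack_frame(sc$stack, c = 2))$pearson_r
  expect_equal(r1, 1, tolerance = 1e-6)

  # disjoint singles: near-zero correlation across seeds
  rs <- vapply(1:20, function(s) {
    d <- gen_two_channel_scene(n_shared = 0, n_only_a = 8, n_only_b = 8,
                               snr = 10, seed = s)
    pearson_coloc(stack_frame(d$stack, c = 1), stack_frame(d$stack, c = 2),
                  d$cell_mask)$pearson_r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)

  # monotone increase with the shared fraction at fixed totals
  shared_counts <- c(0, 4, 8, 12, 16)
  rbar <- vapply(shared_counts, function(k) {
    mean(vapply(1:5, function(s) {
      d <- gen_two_channel_scene(n_shared = k, n_only_a = 16 - k,
                                 n_only_b = 16 - k, seed = 100 + s)
      pearson_coloc(stack_frame(d$stack, c = 1),
                    stack_frame(d$stack, c = 2), d$cell_mask)$pearson_r
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rbar) > 0))
})

test_that("rolling-ball subtraction matches a brute-force opening oracle", {
  set.seed(9)
  img <- matrix(runif(400, 10, 30), 20, 20)
  img[8:12, 8:12] <- img[8:12, 8:12] + 50
  out <- rolling_ball_subtract(img, radius_px = 4)
  # oracle replicates the same border padding, then opens by brute force
  pidx_y <- c(rep(1, 4), 1:20, rep(20, 4))
  padded <- img[pidx_y, pidx_y]
  bg <- opening_bruteforce(padded, 4)[4 + (1:20), 4 + (1:20)]
  oracle <- img - bg
  oracle[oracle < 0] <- 0
  expect_equal(unclass(out), oracle, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(rolling_ball_subtract(img, 0), "parameter error")
})

test_that("rolling ball removes flat/ramp backgrounds but preserves narrow peaks", {
  expect_equal(max(abs(rolling_ball_subtract(matrix(7, 40, 40), 10))), 0)

  side <- 80
  spot <- rnpquant:::render_spots(
    matrix(10, side, side),
    data.frame(y = 40, x = 40, amplitude = 50, sigma_major = 2,
               sigma_minor = 2, theta = 0))
  rb <- rolling_ball_subtract(spot, 25)
  expect_lt(abs(max(rb) - 50) / 50, 0.05)  # peak preserved, offset gone

  ramp <- outer(seq(0, 20, length.out = side), rep(1, side))
  expect_lt(max(abs(rolling_ball_subtract(ramp, 25))) / 20, 0.05)

  rb2 <- rolling_ball_subtract(rb, 25)
  expect_lt(max(abs(rb2 - rb)) / max(rb), 0.011)  # idempotent on spots
})

test_that("spot detection is quiet on noise and accurate on generated scenes", {
  false_spots <- vapply(1:20, function(s) {
    sc <- gen_spot_scene(n_soma = 0, n_neurite = 0, seed = s)
    nrow(detect_spots(sc$stack))
  }, numeric(1))
  expect_lte(mean(false_spots), 1)

  sc <- gen_spot_scene(n_soma = 25, n_neurite = 0, snr = 8, seed = 2)
  det <- detect_spots(sc$stack)
  expect_equal(nrow(det), 25L)
  m <- match_detections(det, sc$truth$spots, max_dist_px = 2)
  expect_equal(m$tp, 25L)
  expect_lt(sqrt(mean(m$dists^2)), 0.5)  # sub-pixel localization
})

test_that("two overlapping spots merge into at least one detection", {
  sigma <- 1.3
  img <- rnpquant:::render_spots(
    matrix(100, 40, 40),
    data.frame(y = c(20, 20), x = c(19, 19 + 2 * sigma), amplitude = 80,
               sigma_major = sigma, sigma_minor = sigma, theta = 0))
  det <- detect_spots(img, psf_sigma_px = sigma)
  expect_gte(nrow(det), 1L)
  expect_lte(nrow(det), 2L)
})

test_that("compartment assignment applies soma precedence and computes the fraction", {
  soma <- matrix(0L, 10, 10); soma[1:5, ] <- 1L
  neur <- matrix(0L, 10, 10); neur[5:8, ] <- 1L  # row 5 overlaps soma
  spots <- data.frame(y = c(2, 5, 7, 20), x = c(3, 3, 3, 3))
  asg <- assign_compartments(spots, soma, neur)
  expect_equal(asg$spots$compartment,
               c("soma", "soma", "neurite", "outside"))
  expect_equal(asg$neurite_fraction, 1 / 3)

  all_soma <- assign_compartments(data.frame(y = c(2, 3), x = c(2, 3)),
                                  soma, neur)
  expect_equal(all_soma$neurite_fraction, 0)
})

test_that("the generated neurite fraction is recovered across seeds", {
  fracs <- vapply(1:10, function(s) {
    sc <- gen_spot_scene(n_soma = 20, n_neurite = 5, snr = 8, seed = s)
    det <- detect_spots(sc$stack)
    assign_compartments(det, sc$soma_mask, sc$neurite_mask)$neurite_fraction
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.2), binom_ci_halfwidth(0.2, 250))
})
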