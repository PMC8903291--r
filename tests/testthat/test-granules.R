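test_that("detection obeys the minimum 3x3 size rule", {
  img <- matrix(10, 40, 40)
  img[10:11, 10:11] <- 200           # bright but only 2x2
  mask <- matrix(TRUE, 40, 40)
  expect_equal(nrow(detect_granules(img, mask, pixel_size_um = 1)), 0L)

  img[20:22, 20:22] <- 200           # 3x3 passes
  det <- detect_granules(img, mask, pixel_size_um = 1)
  expect_equal(nrow(det), 1L)
  expect_equal(det$area_px, 9L)
  # a 2 x 8 ribbon fails the bounding-box rule despite area >= 9
  img2 <- matrix(10, 40, 40)
  img2[5:6, 10:17] <- 200
  expect_equal(nrow(detect_granules(img2, mask, pixel_size_um = 1)), 0L)
})

test_that("blank noise scenes yield essentially no detections", {
  hits <- 0L
  for (s in 1:20) {
    sc <- gen_granule_scene(n_granules = 0, seed = s)
    d <- detect_granules(sc$stack, sc$cell_mask)
    if (nrow(d) > 0L) hits <- hits + 1L
  }
  expect_lt(hits / 20, 0.05)
})

test_that("detection recovers generated granules with high precision and recall", {
  tp <- 0L; fp <- 0L; fn <- 0L; dists <- numeric(0)
  for (s in 1:20) {
    sc <- gen_granule_scene(n_granules = 12, snr = 8, seed = s)
    d <- detect_granules(sc$stack, sc$cell_mask)
    m <- match_detections(d, sc$truth$granules)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    dists <- c(dists, m$dists)
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tp / (tp + fp), 0.95)
  expect_lt(max(dists), 1)  # centroids within 1 px of truth
})

test_that("detection count is invariant to a uniform intensity offset", {
  sc <- gen_granule_scene(n_granules = 10, seed = 9)
  img <- stack_frame(sc$stack)
  d0 <- detect_granules(img, sc$cell_mask, pixel_size_um = 0.084)
  d1 <- detect_granules(img + 500, sc$cell_mask, pixel_size_um = 0.084)
  expect_equal(nrow(d1), nrow(d0))
  expect_equal(d1$area_px, d0$area_px)
})

test_that("morphometrics match closed-form shapes", {
  mask <- matrix(TRUE, 30, 30)
  # rasterized disk, radius 6
  img <- matrix(0, 30, 30)
  img[outer(-14:15, -14:15, function(y, x) y^2 + x^2 <= 36)] <- 100
  d <- detect_granules(img, mask, pixel_size_um = 1)
  expect_equal(d$area_px, 113L)       # |{(y,x): y^2+x^2 <= 36}|
  expect_equal(d$perimeter_px, 52)    # crack edges of the digital disk
  expect_gt(d$circularity, 0.9)       # hull circularity of a disk ~ 1
  expect_equal(granule_morphometrics(d)$morphology, "circular")

  # 2 x 8 rectangle: crack perimeter 2*(2+8) = 20, elongated -> amorphic
  m <- matrix(FALSE, 12, 18)
  m[6:7, 6:13] <- TRUE
  expect_equal(rnpquant:::crack_perimeter(m), 20)
  hull <- rnpquant:::hull_geometry(row(m)[m], col(m)[m])
  circ <- 4 * pi * hull$area / hull$perimeter^2
  expect_lt(circ, 0.8)
  # closed form: hull is the rectangle with corners chamfered by the
  # half-pixel cross extent: area 16 - 0.5, perimeter 16 + 2*sqrt(2)
  expect_equal(hull$area, 15.5)
  expect_equal(hull$perimeter, 16 + 2 * sqrt(2))
})

test_that("generated amorphic blobs are classified amorphic, circular circular", {
  n_am <- 0L; tot_am <- 0L
  for (s in 1:15) {
    sc <- gen_granule_scene(n_granules = 5, cell_diameter_um = 14,
                            amorphic_fraction = 1, snr = 10, seed = s)
    d <- granule_morphometrics(detect_granules(sc$stack, sc$cell_mask))
    tot_am <- tot_am + nrow(d)
    n_am <- n_am + sum(d$morphology == "amorphic")
  }
  expect_gte(n_am / tot_am, 0.9)

  n_ci <- 0L; tot_ci <- 0L
  for (s in 1:15) {
    sc <- gen_granule_scene(n_granules = 8, amorphic_fraction = 0,
                            snr = 10, seed = s)
    d <- granule_morphometrics(detect_granules(sc$stack, sc$cell_mask))
    tot_ci <- tot_ci + nrow(d)
    n_ci <- n_ci + sum(d$morphology == "circular")
  }
  expect_gte(n_ci / tot_ci, 0.9)
})

test_that("per-cell summaries follow the diameter-derived area arithmetic", {
  det30 <- data.frame(id = 1:30, morphology = rep("circular", 30))
  out <- summarize_cells(list(det30), diameters_um = 10)
  expect_equal(out$cells$cell_area_um2, pi * 25)
  expect_equal(round(out$cells$cell_area_um2, 2), 78.54)
  expect_equal(round(out$cells$granules_per_um2, 3), 0.382)

  # density scales as 1/d^2 for the same detections
  out2 <- summarize_cells(list(det30), diameters_um = 20)
  expect_equal(out$cells$granules_per_um2 / out2$cells$granules_per_um2, 4)

  # no granules anywhere -> 0% forming
  empty <- data.frame(id = integer(0), morphology = character(0))
  res <- summarize_cells(rep(list(empty), 100), rep(10, 100))
  expect_equal(res$cohort$pct_with_granules, 0)

  # one amorphic granule makes the whole cell amorphic
  mixed <- data.frame(id = 1:3,
                      morphology = c("circular", "amorphic", "circular"))
  res2 <- summarize_cells(list(mixed, det30), c(10, 10))
  expect_equal(res2$cells$morphology, c("amorphic", "circular"))
  expect_equal(res2$cohort$pct_forming_amorphic, 50)
})

test_that("cohort granule-forming percentage recovers a generative rate", {
  set.seed(31)
  p_true <- 0.65
  cells <- lapply(1:300, function(i) {
    if (runif(1) < p_true) data.frame(id = 1, morphology = "circular")
    else data.frame(id = integer(0), morphology = character(0))
  })
  res <- summarize_cells(cells, rep(10, 300),
                         replicates = rep(1:3, each = 100))
  expect_lt(abs(res$cohort$pct_with_granules / 100 - p_true),
            binom_ci_halfwidth(p_true, 300))
})

test_that("soma distances subtract the soma radius and apply the 10-um rule", {
  soma <- roi_circle(c(50, 50), 5, "soma")  # radius 5 px = 5 um at 1 um/px
  pts <- data.frame(y = c(50, 50, 50), x = c(50, 63, 66))
  d <- soma_distance(pts, soma, pixel_size_um = 1)
  expect_equal(d$distance_um, c(0, 8, 11))
  expect_equal(d$distal, c(FALSE, FALSE, TRUE))
})
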