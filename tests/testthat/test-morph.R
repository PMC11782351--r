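# Segmentation and morphometrics: Otsu against exhaustive search,
# particle filtering, watershed tolerance semantics, closed-form shape
# metrics, and the agreement statistic.

test_that("Otsu matches exhaustive between-class-variance search", {
  set.seed(5)
  for (i in 1:20) {
    img <- matrix(c(rnorm(200, 0.3, 0.05), rnorm(200, 0.7, 0.08)), 20, 20)
    expect_equal(otsu_threshold(img), otsu_bruteforce(img),
                 tolerance = 1e-12)
  }
})

test_that("Otsu separates a two-delta histogram and rejects constants", {
  img <- matrix(rep(c(0.2, 0.8), each = 50), 10, 10)
  thr <- otsu_threshold(img)
  expect_gt(thr, 0.2); expect_lt(thr, 0.8)
  expect_error(otsu_threshold(matrix(1, 5, 5)), "constant")
})

test_that("particle extraction is 8-connected with size and border rules", {
  m <- matrix(0, 20, 20)
  m[3:6, 3:6] <- 1          # interior blob, 16 px
  m[10:15, 10:15] <- 1      # interior blob, 36 px
  lab <- segment_particles(m, min_area_px = 1, exclude_border = FALSE)
  expect_equal(max(lab), 2)
  # diagonal touch merges under 8-connectivity
  d <- matrix(0, 10, 10); d[3, 3] <- 1; d[4, 4] <- 1
  expect_equal(max(segment_particles(d, min_area_px = 1,
                                     exclude_border = FALSE)), 1)
  # small blob removed
  expect_equal(max(segment_particles(m, min_area_px = 20,
                                     exclude_border = FALSE)), 1)
  # border blob removed
  b <- m; b[1, 10:13] <- 1; b[2, 10:13] <- 1
  lab_b <- segment_particles(b, min_area_px = 1, exclude_border = TRUE)
  expect_equal(max(lab_b), 2)
})

test_that("watershed tolerance merges shallow basins", {
  # two dark basins separated by a ridge of depth ~0.5
  g <- expand.grid(r = 1:40, c = 1:40)
  img <- matrix(0.5, 40, 40)
  img <- img - 0.45 * exp(-((g$r - 20)^2 + (g$c - 10)^2) / 30) -
    0.45 * exp(-((g$r - 20)^2 + (g$c - 30)^2) / 30)
  img <- matrix(img, 40, 40)
  lab_lo <- marker_watershed(img, tolerance = 0.1, gradient_radius_px = 0)
  expect_equal(max(lab_lo), 2)
  expect_true(all(lab_lo > 0))                 # labels partition the image
  expect_warning(lab_hi <- marker_watershed(img, tolerance = 0.6,
                                            gradient_radius_px = 0),
                 "single region")
  expect_equal(max(lab_hi), 1)
})

test_that("region count is non-increasing over a tolerance sweep", {
  for (sd in 1:5) {
    s <- generate_scene(scene_spec(width_px = 96, height_px = 96,
                                   n_cells = 4, lobe_amplitude = 2,
                                   seed = sd))
    counts <- vapply(c(0.01, 0.05, 0.2), function(tol)
      max(suppressWarnings(marker_watershed(s$channels$membrane,
                                            tolerance = tol,
                                            gradient_radius_px = 0))),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("shape metrics match closed forms on rasterized primitives", {
  disk <- raster_disk(100)
  md <- measure_cells(disk, 1)
  expect_lt(abs(md$circularity - 1), 0.05)
  expect_gt(md$solidity, 0.99)

  rect <- raster_rect(50, 100)
  mr <- measure_cells(rect, 1)
  expect_equal(mr$solidity, 1)
  expect_equal(mr$area_um2, 5000)
  expect_lt(abs(mr$aspect_ratio - 2), 0.02)

  sq <- raster_rect(50, 50)
  ms <- measure_cells(sq, 1)
  expect_lt(abs(ms$circularity - pi / 4), 0.02)
})

test_that("pixel size scales areas and perimeters correctly", {
  disk <- raster_disk(30)
  m1 <- measure_cells(disk, 1)
  m2 <- measure_cells(disk, 0.5)
  expect_equal(m2$area_um2, m1$area_um2 * 0.25)
  expect_equal(m2$perimeter_um, m1$perimeter_um * 0.5)
  expect_equal(m2$circularity, m1$circularity)
})

test_that("solidity never exceeds 1 and watershed output is a partition", {
  for (sd in 1:4) {
    s <- generate_scene(scene_spec(n_cells = 8, lobe_amplitude = 5,
                                   seed = sd))
    mc <- measure_cells(s$labels, 0.56)
    expect_true(all(mc$solidity <= 1 + 1e-12))
    expect_true(all(mc$circularity > 0 & mc$circularity <= 1.05))
    expect_true(all(mc$aspect_ratio >= 1))
  }
})

test_that("agreement reproduces analytic R-squared for a linear model", {
  expect_equal(suppressWarnings(    # lm warns on an exact fit
    agreement(data.frame(id = 1:5, v = 1:5),
              data.frame(id = 1:5, v = 1:5), "v"))$r_squared, 1)
  expect_error(agreement(data.frame(id = 1:5, v = 1:5),
                         data.frame(id = 1:5, v = rep(2, 5)), "v"),
               "zero variance")
  # y = 2x + noise: E[R^2] ~ 4 var(x) / (4 var(x) + sigma^2)
  set.seed(9)
  x <- runif(200, 0, 1); sigma <- 0.4
  y <- 2 * x + rnorm(200, 0, sigma)
  r2 <- agreement(data.frame(id = 1:200, v = x),
                  data.frame(id = 1:200, v = y), "v")$r_squared
  expected <- 4 * var(x) / (4 * var(x) + sigma^2)
  expect_lt(abs(r2 - expected), 0.1)
})

test_that("by2 scenes with doubled elongation measure higher aspect ratio", {
  ar_of <- function(e, sd) {
    s <- generate_scene(scene_spec(width_px = 192, height_px = 96,
                                   n_cells = 3, shape_model = "by2_file",
                                   elongation = e, seed = sd))
    measure_cells(s$labels, 0.56)$aspect_ratio
  }
  ar1 <- unlist(lapply(1:5, function(sd) ar_of(1.5, sd)))
  ar2 <- unlist(lapply(1:5, function(sd) ar_of(3, sd)))
  expect_lt(wilcox.test(ar2, ar1, alternative = "greater")$p.value, 0.01)
})
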