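# Synthetic scene generator: determinism, ground-truth consistency,
# and the geometric properties downstream modules rely on.

test_that("scenes are bit-identical under the same spec and seed", {
  for (model in c("pavement", "by2_file", "chloroplast_field")) {
    spec <- scene_spec(width_px = 96, height_px = 96, n_cells = 4,
                       shape_model = model, lobe_amplitude = 2, seed = 3)
    expect_identical(generate_scene(spec), generate_scene(spec))
  }
  vs <- generate_viability_set(3, seed = 11)
  expect_identical(vs, generate_viability_set(3, seed = 11))
})

test_that("pavement scenes carry exactly n_cells labels with full support", {
  s <- generate_scene(scene_spec(width_px = 160, height_px = 160,
                                 n_cells = 20, shape_model = "pavement",
                                 lobe_amplitude = 2, seed = 1))
  expect_setequal(unique(as.integer(s$labels)), 1:20)
  expect_true(all(tabulate(s$labels[s$labels > 0]) > 0))
  expect_true(all(s$brightfield >= 0 & s$brightfield <= 1))
  for (ch in s$channels) expect_true(all(ch >= 0 & ch <= 1))
})

test_that("infeasible placements raise an error naming the spec", {
  spec <- scene_spec(width_px = 64, height_px = 64, n_cells = 40,
                     pixel_size_um = 0.28,
                     shape_model = "chloroplast_field", seed = 2)
  expect_error(generate_scene(spec), "cannot place")
})

test_that("membrane channel mass concentrates near label boundaries", {
  for (seed in 1:3) {
    s <- generate_scene(scene_spec(n_cells = 8, lobe_amplitude = 3,
                                   seed = seed))
    bnd <- vstain:::boundary_mask(s$labels)
    dm <- as.matrix(EBImage::distmap(matrix(as.numeric(!bnd),
                                            nrow(bnd), ncol(bnd))))
    frac <- sum(s$channels$membrane[dm <= 2]) / sum(s$channels$membrane)
    expect_gt(frac, 0.95)
  }
})

test_that("unlobed pavement cells are convex (solidity >= 0.98)", {
  s <- generate_scene(scene_spec(width_px = 128, height_px = 128,
                                 n_cells = 8, shape_model = "pavement",
                                 lobe_amplitude = 0, seed = 2))
  mc <- measure_cells(s$labels, 1)
  expect_true(all(mc$solidity >= 0.98))
})

test_that("mean solidity is non-increasing in lobe amplitude", {
  mean_sol <- vapply(c(0, 3, 6), function(a) {
    mean(vapply(1:4, function(sd) {
      s <- generate_scene(scene_spec(width_px = 128, height_px = 128,
                                     n_cells = 8, lobe_amplitude = a,
                                     seed = sd))
      mean(measure_cells(s$labels, 1)$solidity)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sol) <= 0))
})

test_that("time-lapse truth speeds follow from centroid displacements", {
  spec <- scene_spec(width_px = 192, height_px = 192, pixel_size_um = 0.28,
                     n_cells = 5, shape_model = "chloroplast_field",
                     seed = 4)
  tl <- generate_timelapse(spec, n_frames = 10,
                           speed_model = list(mean_um_s = 2, sd = 0.5,
                                              direction_persistence = 0.8))
  expect_length(tl$frames, 10)
  expect_equal(dim(tl$speeds_um_s), c(5, 9))
  for (i in 1:5) {
    expect_equal(nrow(tl$tracks[[i]]), 10)
    d <- sqrt(rowSums(diff(tl$tracks[[i]])^2)) * 0.28 / tl$dt_s
    expect_equal(d, tl$speeds_um_s[i, ], tolerance = 1e-12)
  }
})

test_that("constant-speed time-lapse records exactly that speed", {
  spec <- scene_spec(width_px = 256, height_px = 256, pixel_size_um = 0.28,
                     n_cells = 8, shape_model = "chloroplast_field",
                     seed = 5)
  tl <- generate_timelapse(spec, n_frames = 6,
                           speed_model = list(mean_um_s = 1, sd = 0,
                                              direction_persistence = 1))
  # stalled excluded-volume steps record 0; all moving steps are exact
  sp <- tl$speeds_um_s
  expect_true(all(abs(sp - 1) < 1e-9 | sp == 0))
  expect_gt(mean(abs(sp - 1) < 1e-9), 0.9)
})

test_that("truth speeds of a stochastic walk match the requested mean", {
  spec <- scene_spec(width_px = 320, height_px = 320, pixel_size_um = 0.28,
                     n_cells = 30, shape_model = "chloroplast_field",
                     seed = 6)
  tl <- generate_timelapse(spec, n_frames = 6,
                           speed_model = list(mean_um_s = 2, sd = 0.5,
                                              direction_persistence = 0.5))
  sp <- tl$speeds_um_s[tl$speeds_um_s > 0]   # drop rare stalled steps
  se <- sd(sp) / sqrt(length(sp))
  expect_lt(abs(mean(sp) - 2), 3 * se + 0.05)
})

test_that("negative speed spread is rejected", {
  spec <- scene_spec(width_px = 128, height_px = 128, pixel_size_um = 0.28,
                     n_cells = 3, shape_model = "chloroplast_field",
                     seed = 1)
  expect_error(generate_timelapse(spec, 5,
                                  speed_model = list(mean_um_s = 1, sd = -1,
                                                     direction_persistence = 0.5)),
               "non-negative")
})

test_that("viability sets are balanced, labeled and class-distinct", {
  vs <- generate_viability_set(10, seed = 7)
  expect_length(vs, 20)
  labs <- vapply(vs, `[[`, "", "label")
  expect_equal(sum(labs == "living"), 10)
  expect_equal(sum(labs == "dead"), 10)
  expect_true(all(vapply(vs, function(cr) is.matrix(cr$brightfield) &&
                           is.matrix(cr$membrane), logical(1))))
})

test_that("dead crops carry more co-occurrence contrast than living", {
  vs <- generate_viability_set(50, seed = 8)
  labs <- vapply(vs, `[[`, "", "label")
  cfg <- glcm_config()
  con <- vapply(vs, function(cr)
    unname(haralick_features(glcm(cr$brightfield, cfg))["contrast_d1"]),
    numeric(1))
  expect_gt(mean(con[labs == "dead"]), mean(con[labs == "living"]))
})
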