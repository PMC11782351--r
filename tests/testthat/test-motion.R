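# Centroid extraction, gated greedy linking, and speed recovery.

test_that("centroids of isolated disks are recovered to sub-pixel accuracy", {
  frame <- matrix(0, 64, 64)
  g <- vstain:::coord_grid(64, 64)
  frame[( (g$x - 20.5)^2 + (g$y - 31.5)^2 ) <= 25] <- 1
  cents <- extract_centroids(frame)
  expect_equal(nrow(cents), 1)
  expect_lt(abs(cents$x_px - 20.5), 0.5)
  expect_lt(abs(cents$y_px - 31.5), 0.5)
  frame[( (g$x - 50)^2 + (g$y - 12)^2 ) <= 25] <- 1
  expect_equal(nrow(extract_centroids(frame)), 2)
  expect_warning(e <- extract_centroids(matrix(0.3, 32, 32)), "constant")
  expect_equal(nrow(e), 0)
})

test_that("generator frames yield one centroid per object within 1 px", {
  s <- generate_scene(scene_spec(width_px = 192, height_px = 192,
                                 pixel_size_um = 0.28, n_cells = 6,
                                 shape_model = "chloroplast_field",
                                 seed = 3))
  cents <- extract_centroids(s$channels$chloroplast, min_area_px = 10)
  expect_equal(nrow(cents), 6)
  for (i in seq_len(6)) {
    d <- sqrt((cents$x_px - s$truth$cx_px[i])^2 +
                (cents$y_px - s$truth$cy_px[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("two well-separated movers are tracked exactly", {
  frames <- lapply(0:4, function(t)
    data.frame(x_px = c(10 + 2 * t, 60 - 2 * t), y_px = c(10, 60)))
  tracks <- link_tracks(frames, max_disp_px = 5, dt_s = 0.5,
                        pixel_size_um = 0.28)
  expect_length(tracks, 2)
  for (tr in tracks) {
    expect_equal(tr$frames, 1:5)
    expect_equal(tr$speeds_um_s, rep(2 * 0.28 / 0.5, 4))
  }
})

test_that("a 1 px step at 0.28 um/px and 0.5 s gives 0.56 um/s", {
  frames <- list(data.frame(x_px = 5, y_px = 5),
                 data.frame(x_px = 6, y_px = 5))
  tr <- link_tracks(frames, max_disp_px = 3, dt_s = 0.5,
                    pixel_size_um = 0.28)
  expect_equal(tr[[1]]$speeds_um_s, 0.56)
})

test_that("jumps beyond the gate terminate the track and start a new one", {
  frames <- list(data.frame(x_px = 10, y_px = 10),
                 data.frame(x_px = 40, y_px = 40))
  tracks <- link_tracks(frames, max_disp_px = 5, dt_s = 0.5,
                        pixel_size_um = 1)
  expect_length(tracks, 2)
  expect_equal(tracks[[1]]$frames, 1L)
  expect_equal(tracks[[2]]$frames, 2L)
})

test_that("linking is exact whenever spacing exceeds twice the step", {
  # exhaustive over seeded configurations: objects on a jittered grid,
  # random small steps, spacing > 2 * max displacement
  for (sd in 1:10) {
    set.seed(sd)
    n <- 9
    base <- expand.grid(x = c(15, 45, 75), y = c(15, 45, 75))
    base <- base + matrix(runif(2 * n, -3, 3), n, 2)
    steps <- matrix(runif(2 * n, -3, 3), n, 2)   # |step| <= 4.3 < 15/2
    frames <- list(data.frame(x_px = base$x, y_px = base$y),
                   data.frame(x_px = base$x + steps[, 1],
                              y_px = base$y + steps[, 2]))
    tracks <- link_tracks(frames, max_disp_px = 7, dt_s = 1,
                          pixel_size_um = 1)
    expect_length(tracks, n)
    got <- t(vapply(tracks, function(tr) c(tr$x_px[2], tr$y_px[2]),
                    numeric(2)))
    ord <- order(vapply(tracks, function(tr) tr$x_px[1] * 1e3 + tr$y_px[1],
                        numeric(1)))
    want_ord <- order(base$x * 1e3 + base$y)
    expect_equal(got[ord, 1], (base$x + steps[, 1])[want_ord])
  }
})

test_that("speeds are invariant under global scene translation", {
  set.seed(2)
  pos <- data.frame(x_px = runif(5, 20, 80), y_px = runif(5, 20, 80))
  mv <- data.frame(x_px = pos$x_px + runif(5, -2, 2),
                   y_px = pos$y_px + runif(5, -2, 2))
  t1 <- link_tracks(list(pos, mv), max_disp_px = 6, dt_s = 0.5,
                    pixel_size_um = 0.28)
  shift <- function(df) data.frame(x_px = df$x_px + 11, y_px = df$y_px - 7)
  t2 <- link_tracks(list(shift(pos), shift(mv)), max_disp_px = 6,
                    dt_s = 0.5, pixel_size_um = 0.28)
  s1 <- sort(unlist(lapply(t1, `[[`, "speeds_um_s")))
  s2 <- sort(unlist(lapply(t2, `[[`, "speeds_um_s")))
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("speed agreement is perfect for exact detections and null for shuffled", {
  spec <- scene_spec(width_px = 256, height_px = 256, pixel_size_um = 0.28,
                     n_cells = 10, shape_model = "chloroplast_field",
                     seed = 12)
  tl <- generate_timelapse(spec, 8,
                           speed_model = list(mean_um_s = 2, sd = 0.5,
                                              direction_persistence = 0.8))
  perfect <- lapply(seq_along(tl$tracks), function(i) {
    m <- tl$tracks[[i]]
    list(id = i, frames = seq_len(nrow(m)), x_px = m[, 1], y_px = m[, 2],
         speeds_um_s = sqrt(rowSums(diff(m)^2)) * 0.28 / tl$dt_s)
  })
  expect_equal(suppressWarnings(speed_agreement(tl, perfect))$r_squared, 1,
               tolerance = 1e-9)   # lm warns on an exact fit
  # jittered detections still recover speeds faithfully
  set.seed(1)
  jit <- lapply(perfect, function(tr) {
    tr$x_px <- tr$x_px + rnorm(length(tr$x_px), 0, 0.1)
    tr$y_px <- tr$y_px + rnorm(length(tr$y_px), 0, 0.1)
    tr$speeds_um_s <- sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2) * 0.28 / 0.5
    tr
  })
  expect_gt(speed_agreement(tl, jit)$r_squared, 0.9)
  # shuffled pairing destroys the agreement
  shuf <- lapply(seq_along(perfect), function(i) {
    tr <- perfect[[i]]
    tr$speeds_um_s <- perfect[[(i %% length(perfect)) + 1]]$speeds_um_s
    tr
  })
  expect_lt(speed_agreement(tl, shuf)$r_squared, 0.3)
})
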