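# RCA-UNet: architecture contracts, analytic gradients against finite
# differences, normalization, training behaviour, serialization and
# tiled inference.

small_cfg <- function(...) {
  model_config(depth = 2, base_channels = 4, attention_reduction_r = 2,
               patch_size_px = 16, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(model_config(depth = 3, patch_size_px = 20),
               "divisible")
  expect_error(model_config(depth = 2, base_channels = 2,
                            attention_reduction_r = 64,
                            patch_size_px = 16),
               "attention_reduction_r")
})

test_that("the network maps an image to a same-shape single channel", {
  m <- build_model(small_cfg(seed = 3))
  x <- array(vstain:::with_seed(7, rnorm(64 * 64)), c(64, 64, 1, 1))
  y <- vstain:::unet_forward(m$params, x)$y
  expect_equal(dim(y), c(64, 64, 1, 1))
  expect_true(all(is.finite(y)))
})

test_that("attention gates lie strictly inside (0, 1), even on zero input", {
  pars <- vstain:::with_seed(1, vstain:::ca_init(8L, 2L))
  g <- vstain:::ca_gate(pars, matrix(0, 1, 8))$g
  expect_true(all(g > 0 & g < 1))
})

test_that("identical config and seed give identical initial predictions", {
  x <- vstain:::with_seed(5, matrix(runif(32 * 32), 32, 32))
  p1 <- predict_stain(build_model(small_cfg(seed = 8)), x,
                      allow_untrained = TRUE)
  p2 <- predict_stain(build_model(small_cfg(seed = 8)), x,
                      allow_untrained = TRUE)
  expect_identical(p1, p2)
})

test_that("backpropagated gradients match central finite differences", {
  m <- build_model(small_cfg(seed = 3))
  x <- array(vstain:::with_seed(7, rnorm(16 * 16)), c(16, 16, 1, 1))
  t4 <- array(vstain:::with_seed(8, rnorm(16 * 16)), c(16, 16, 1, 1))
  fw <- vstain:::unet_forward(m$params, x, keep_cache = TRUE)
  grads <- vstain:::unet_backward(m$params, fw, 2 * (fw$y - t4) / length(t4))
  lossfun <- function(params)
    mean((vstain:::unet_forward(params, x)$y - t4)^2)
  paths <- list(c("enc", "1", "conv1", "W"), c("enc", "2", "conv2", "b"),
                c("bott", "att", "W1"), c("dec", "1", "proj", "W"),
                c("dec", "2", "att", "b2"), c("head", "W"))
  eps <- 1e-6
  set.seed(1)
  for (path in paths) {
    pluck <- function(L) { for (k in path) {
      L <- L[[if (grepl("^[0-9]+$", k)) as.integer(k) else k]] }; L }
    poke <- function(L, i, v, depth = 1) {
      k <- path[depth]; k2 <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
      if (depth == length(path)) { L[[k2]][i] <- L[[k2]][i] + v; L }
      else { L[[k2]] <- poke(L[[k2]], i, v, depth + 1); L }
    }
    g0 <- pluck(grads)
    for (i in sample(length(g0), 2)) {
      num <- (lossfun(poke(m$params, i, eps)) -
                lossfun(poke(m$params, i, -eps))) / (2 * eps)
      expect_lt(abs(num - g0[i]) / max(1e-8, abs(num) + abs(g0[i])), 1e-4)
    }
  }
})

test_that("percentile normalization maps the stated range and clips", {
  img <- matrix(seq(0, 1, length.out = 100), 10, 10)
  n <- normalize_percentile(img)
  expect_lt(min(n), 0.02); expect_gt(max(n), 0.98)
  expect_error(normalize_percentile(matrix(0.5, 5, 5)), "degenerate")
  hot <- matrix(runif(400, 0.4, 0.6), 20, 20); hot[1, 1] <- 50
  expect_equal(max(normalize_percentile(hot)), 1)  # hot pixel clipped
})

test_that("the identity task is learned quickly", {
  set.seed(1)
  pairs <- lapply(1:50, function(i) {
    m <- vstain:::blur_gauss(matrix(runif(32 * 32), 32, 32), 2)
    m <- (m - min(m)) / (max(m) - min(m))
    list(m, m)
  })
  cfg <- model_config(depth = 2, base_channels = 8,
                      attention_reduction_r = 4, patch_size_px = 32,
                      epochs = 5, batch_size = 4, seed = 2)
  fit <- train_model(build_model(cfg), pairs)
  expect_length(fit$history, 5)
  expect_true(all(is.finite(fit$history)))
  expect_lt(tail(fit$history, 1), 0.1 * fit$history[1])
})

test_that("training rejects malformed pair lists", {
  m <- build_model(small_cfg(seed = 1))
  expect_error(train_model(m, list()), "length")
  bad <- list(list(matrix(0.5 + runif(256) / 10, 16, 16), matrix(0, 8, 8)))
  expect_error(train_model(m, bad), "shapes differ")
  small <- list(list(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8)))
  expect_error(train_model(m, small), "smaller than patch_size")
})

test_that("save -> load -> predict is bit-identical", {
  set.seed(3)
  pairs <- lapply(1:10, function(i) {
    m <- matrix(runif(256), 16, 16); list(m, sqrt(m))
  })
  fit <- train_model(build_model(small_cfg(epochs = 2, seed = 4)), pairs)
  img <- matrix(runif(1024), 32, 32)
  p0 <- predict_stain(fit, img)
  dir <- withr::local_tempdir()
  save_model(fit, dir)
  fit2 <- load_model(dir)
  expect_identical(predict_stain(fit2, img), p0)
})

test_that("tiled prediction equals the whole-image pass", {
  m <- build_model(small_cfg(seed = 9))
  img <- vstain:::with_seed(3, matrix(runif(256 * 256), 256, 256))
  whole <- predict_stain(m, img, tile_px = Inf, allow_untrained = TRUE)
  tiled <- predict_stain(m, img, tile_px = 128, allow_untrained = TRUE)
  expect_lt(max(abs(whole - tiled)), 1e-3)
  expect_equal(dim(tiled), dim(img))
})

test_that("non-multiple sizes are padded and tiny images rejected", {
  m <- build_model(small_cfg(seed = 9))
  img <- vstain:::with_seed(4, matrix(runif(50 * 70), 50, 70))
  p <- predict_stain(m, img, allow_untrained = TRUE)
  expect_equal(dim(p), c(50, 70))
  expect_error(predict_stain(m, matrix(0.5, 2, 2), allow_untrained = TRUE),
               "smaller than the minimum tile")
  expect_error(predict_stain(m, img), "untrained")
})

test_that("multiplex prediction stacks one channel per model", {
  ma <- build_model(small_cfg(seed = 1), channel_name = "membrane")
  mb <- build_model(small_cfg(seed = 2), channel_name = "nucleus")
  mc <- build_model(small_cfg(seed = 3), channel_name = "vacuole")
  img <- vstain:::with_seed(5, matrix(runif(64 * 64), 64, 64))
  out <- predict_multiplex(list(ma, mb, mc), img, allow_untrained = TRUE)
  expect_named(out, c("membrane", "nucleus", "vacuole"))
  expect_true(all(vapply(out, function(p) all(dim(p) == c(64, 64)),
                         logical(1))))
})
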