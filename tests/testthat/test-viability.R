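# GLCM construction and Haralick statistics against brute-force oracles;
# random-forest classifier behaviour.

test_that("a constant image yields a single-entry matrix with ASM 1", {
  m <- glcm(matrix(0.5, 16, 16), glcm_config(levels = 8))
  P <- m$d1$a0
  expect_equal(sum(P), 1, tolerance = 1e-9)
  expect_equal(sum(P > 0), 1)
  f <- haralick_features(m)
  expect_equal(unname(f["asm_d1"]), 1)
  expect_equal(unname(f["contrast_d1"]), 0)
})

test_that("co-occurrence counts equal exhaustive pair counting", {
  set.seed(3)
  cfg <- glcm_config(levels = 4, angles_deg = c(0, 45, 90, 135))
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  for (i in 1:10) {
    img <- matrix(runif(64), 8, 8)
    q <- vstain:::quantize_levels(img, 4L)
    got <- glcm(img, cfg)
    for (a in names(offs)) {
      want <- glcm_bruteforce(q, 4L, offs[[a]][1], offs[[a]][2])
      expect_equal(got$d1[[paste0("a", a)]], want, tolerance = 1e-12)
    }
  }
})

test_that("symmetrized matrices equal their transpose and sum to one", {
  set.seed(4)
  for (i in 1:5) {
    m <- glcm(matrix(runif(256), 16, 16), glcm_config(levels = 16))
    for (P in m$d1) {
      expect_equal(P, t(P))
      expect_equal(sum(P), 1, tolerance = 1e-9)
    }
  }
})

test_that("closed forms hold for simple matrices", {
  # uniform 2x2: ASM = 1/4, entropy = ln 4
  u <- vstain:::haralick_one(matrix(0.25, 2, 2))
  expect_equal(unname(u["asm"]), 0.25)
  expect_equal(unname(u["entropy"]), log(4))
  # diagonal matrix: zero contrast
  d <- vstain:::haralick_one(diag(4) / 4)
  expect_equal(unname(d["contrast"]), 0)
  expect_error(vstain:::haralick_one(matrix(1, 3, 3)), "not normalized")
})

test_that("all 13 statistics match the straight-from-formula oracle", {
  set.seed(7)
  for (i in 1:25) {
    img <- matrix(runif(14 * 11), 14, 11)
    P <- glcm(img, glcm_config(levels = 6, angles_deg = 0))$d1$a0
    expect_equal(unname(vstain:::haralick_one(P)),
                 unname(haralick_bruteforce(P)), tolerance = 1e-10)
    expect_true(all(is.finite(vstain:::haralick_one(P))))
  }
})

test_that("offsets larger than the image are rejected", {
  expect_error(glcm(matrix(runif(9), 3, 3),
                    glcm_config(levels = 4, distances = 5)), "offset")
})

test_that("the forest fits a separable toy problem and is seeded", {
  set.seed(5)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 4), 50, 2))
  y <- rep(c("a", "b"), each = 50)
  fit <- train_classifier(x, y, n_trees = 100, seed = 3)
  expect_equal(mean(predict(fit, as.data.frame(x)) == y), 1)
  fit2 <- train_classifier(x, y, n_trees = 100, seed = 3)
  xt <- matrix(rnorm(40, 2), 20, 2)
  expect_identical(predict(fit, as.data.frame(xt)),
                   predict(fit2, as.data.frame(xt)))
  expect_error(train_classifier(x, rep("a", 100)), "two classes")
})

test_that("evaluation reports coherent confusion counts and accuracies", {
  set.seed(6)
  x_tr <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 3), 100, 2))
  y_tr <- rep(c("living", "dead"), each = 100)
  x_te <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 3), 30, 2))
  y_te <- rep(c("living", "dead"), each = 30)
  ev <- evaluate_classifier(x_tr, y_tr, x_te, y_te, seeds = 1:3,
                            n_trees = 100)
  expect_equal(sum(ev$confusion), 60)
  expect_equal(ev$mean, mean(ev$accuracies))
  expect_equal(unname(ev$accuracies[1]),
               sum(diag(ev$confusion)) / sum(ev$confusion))
  # a leaked label column forces perfect accuracy
  leak_tr <- cbind(x_tr, as.numeric(y_tr == "dead"))
  leak_te <- cbind(x_te, as.numeric(y_te == "dead"))
  ev2 <- evaluate_classifier(leak_tr, y_tr, leak_te, y_te, seeds = 1,
                             n_trees = 50)
  expect_equal(ev2$mean, 1)
})
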