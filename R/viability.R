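# Texture-based live/dead classification: gray-level co-occurrence
# matrices, the 13 classical Haralick statistics, and a random-forest
# classifier over them.

#' GLCM configuration
#'
#' @param levels Gray levels after quantization (default 64).
#' @param distances Pixel offsets (default 1).
#' @param angles_deg Offset directions in degrees (default 0, 45, 90,
#'   135).
#' @param symmetric Add the transposed counts (default TRUE).
#' @param normalize Scale each matrix to sum 1 (default TRUE).
#' @param robust_range Quantize over the 1-99 intensity percentiles
#'   instead of min-max (default FALSE).
#' @return Object of class `glcm_config`.
#' @export
glcm_config <- function(levels = 64L, distances = 1L,
                        angles_deg = c(0, 45, 90, 135),
                        symmetric = TRUE, normalize = TRUE,
                        robust_range = FALSE) {
  stopifnot(levels >= 2, all(distances >= 1))
  structure(list(levels = as.integer(levels),
                 distances = as.integer(distances),
                 angles_deg = angles_deg, symmetric = symmetric,
                 normalize = normalize, robust_range = robust_range),
            class = "glcm_config")
}

quantize_levels <- function(image, levels, robust = FALSE) {
  v <- image
  rng <- if (robust) stats::quantile(v, c(0.01, 0.99)) else range(v)
  if (diff(rng) <= 0) return(matrix(1L, nrow(image), ncol(image)))
  q <- as.integer((v - rng[1L]) / (rng[2L] - rng[1L]) * levels) + 1L
  q[q < 1L] <- 1L; q[q > levels] <- levels
  matrix(q, nrow(image), ncol(image))
}

# Row/column offset of a GLCM angle at distance d; angles follow the
# usual convention (0 deg = horizontal neighbour to the right, 45 deg =
# up-right, y axis pointing down).
angle_offset <- function(angle_deg, d) {
  switch(as.character(angle_deg %% 180),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported GLCM angle: ", angle_deg))
}

#' Gray-level co-occurrence matrices of an image
#'
#' For each (distance, angle) pair, counts co-occurrences of quantized
#' gray levels at that offset; optionally symmetrized and normalized to
#' sum 1.
#'
#' @param image Numeric matrix.
#' @param cfg A [glcm_config()].
#' @return Nested list: `matrices[[distance]][[angle]]`, each a
#'   `levels x levels` matrix, with the config attached as attribute
#'   `"cfg"`.
#' @export
glcm <- function(image, cfg = glcm_config()) {
  stopifnot(inherits(cfg, "glcm_config"))
  if (any(dim(image) <= max(cfg$distances))) {
    stop("image smaller than the largest co-occurrence offset")
  }
  q <- quantize_levels(image, cfg$levels, cfg$robust_range)
  L <- cfg$levels
  h <- nrow(q); w <- ncol(q)
  out <- lapply(cfg$distances, function(d) {
    ms <- lapply(cfg$angles_deg, function(a) {
      off <- angle_offset(a, d)
      r0 <- max(1L, 1L - off[1L]); r1 <- min(h, h - off[1L])
      c0 <- max(1L, 1L - off[2L]); c1 <- min(w, w - off[2L])
      i <- q[r0:r1, c0:c1]
      j <- q[(r0 + off[1L]):(r1 + off[1L]), (c0 + off[2L]):(c1 + off[2L])]
      m <- matrix(tabulate(i + L * (j - 1L), L * L), L, L)
      if (cfg$symmetric) m <- m + t(m)
      if (cfg$normalize) m <- m / sum(m)
      m
    })
    names(ms) <- paste0("a", cfg$angles_deg)
    ms
  })
  names(out) <- paste0("d", cfg$distances)
  attr(out, "cfg") <- cfg
  out
}

# The 13 Haralick statistics of one normalized co-occurrence matrix.
haralick_one <- function(P) {
  if (abs(sum(P) - 1) > 1e-6) stop("co-occurrence matrix is not normalized")
  L <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  lev <- seq_len(L)
  mx <- sum(lev * px); my <- sum(lev * py)
  sx <- sqrt(sum((lev - mx)^2 * px)); sy <- sqrt(sum((lev - my)^2 * py))
  pxy_sum <- vapply(2:(2 * L), function(k) sum(P[(i + j) == k]), numeric(1))
  k_sum <- 2:(2 * L)
  pxy_dif <- vapply(0:(L - 1L), function(k) sum(P[abs(i - j) == k]),
                    numeric(1))
  k_dif <- 0:(L - 1L)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sx > 0 && sy > 0) {
    (sum(i * j * P) - mx * my) / (sx * sy)
  } else 0
  variance <- sum((i - mx)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_avg <- sum(k_sum * pxy_sum)
  sum_ent <- ent(pxy_sum)
  sum_var <- sum((k_sum - sum_avg)^2 * pxy_sum)
  entropy <- ent(P)
  dif_avg <- sum(k_dif * pxy_dif)
  dif_var <- sum((k_dif - dif_avg)^2 * pxy_dif)
  dif_ent <- ent(pxy_dif)
  hx <- ent(px); hy <- ent(py)
  hxy <- entropy
  pq <- outer(px, py)
  pos <- P > 0 & pq > 0
  hxy1 <- -sum(P[pos] * log(pq[pos]))
  hxy2 <- -sum(pq[pq > 0] * log(pq[pq > 0]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = sum_ent, entropy = entropy,
    difference_variance = dif_var, difference_entropy = dif_ent,
    imc1 = imc1, imc2 = imc2)
}

#' Haralick feature vector from co-occurrence matrices
#'
#' Computes the 13 classical statistics (angular second moment, contrast,
#' correlation, sum-of-squares variance, inverse difference moment, sum
#' average, sum variance, sum entropy, entropy, difference variance,
#' difference entropy, and the two information measures of correlation)
#' per matrix, averaged over angles; one block per distance.
#'
#' @param matrices Result of [glcm()] (normalized).
#' @return Named numeric vector, `13 * n_distances` long.
#' @export
haralick_features <- function(matrices) {
  blocks <- lapply(names(matrices), function(dn) {
    f <- rowMeans(vapply(matrices[[dn]], haralick_one, numeric(13)))
    names(f) <- paste0(names(f), "_", dn)
    f
  })
  unlist(blocks)
}

#' Haralick features of a set of crops
#'
#' @param crops List of numeric matrices.
#' @param cfg A [glcm_config()].
#' @return Matrix, one row per crop.
#' @export
texture_features <- function(crops, cfg = glcm_config()) {
  t(vapply(crops, function(m) haralick_features(glcm(m, cfg)),
           numeric(13L * length(cfg$distances))))
}

#' Train a random-forest live/dead classifier
#'
#' Bootstrap-aggregated trees with `sqrt(p)` candidate features per split
#' (the randomForest package defaults), seeded for reproducibility.
#'
#' @param features Numeric matrix (rows = samples).
#' @param labels Factor or character class labels (2 classes, >= 10
#'   samples each).
#' @param n_trees Ensemble size (default 500).
#' @param seed Integer seed.
#' @return A `randomForest` model.
#' @export
train_classifier <- function(features, labels, n_trees = 500L, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least two classes")
  if (min(table(labels)) < 10L) stop("need at least 10 samples per class")
  with_seed(seed,
            randomForest::randomForest(x = as.data.frame(features),
                                       y = labels, ntree = n_trees))
}

#' Multi-seed evaluation of the live/dead classifier
#'
#' Retrains the forest once per seed on the fixed training split and
#' evaluates on the fixed held-out split (the data split itself is not
#' re-randomized, only the forest). Reports per-seed accuracies, their
#' mean and SD, and the confusion matrix of the first seed (rows = true,
#' columns = predicted).
#'
#' @param train_features,train_labels Training split.
#' @param test_features,test_labels Held-out split (disjoint by
#'   construction).
#' @param seeds Integer vector of forest seeds.
#' @param n_trees Trees per forest.
#' @return List of class `eval_report`: `accuracies`, `mean`, `sd`,
#'   `confusion`, `n_test`.
#' @export
evaluate_classifier <- function(train_features, train_labels,
                                test_features, test_labels,
                                seeds = 1:10, n_trees = 500L) {
  test_labels <- factor(test_labels)
  if (!all(levels(factor(train_labels)) == levels(test_labels))) {
    stop("train and test label sets differ")
  }
  accs <- numeric(length(seeds))
  confusion <- NULL
  for (k in seq_along(seeds)) {
    fit <- train_classifier(train_features, train_labels,
                            n_trees = n_trees, seed = seeds[k])
    pred <- stats::predict(fit, as.data.frame(test_features))
    accs[k] <- mean(pred == test_labels)
    if (k == 1L) confusion <- table(true = test_labels, predicted = pred)
  }
  structure(list(accuracies = accs, mean = mean(accs),
                 sd = if (length(accs) > 1L) stats::sd(accs) else 0,
                 confusion = confusion, n_test = length(test_labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f +/- %.3f over %d seeds (n_test = %d)\n",
              x$mean, x$sd, length(x$accuracies), x$n_test))
  print(x$confusion)
  invisible(x)
}
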