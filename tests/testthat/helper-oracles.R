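# Independent oracles and raster fixtures shared across tests. All are
# deliberately naive (loops, exhaustive search, straight-from-formula) so
# they stay independent of the implementation paths they check.

# Exhaustive Otsu: try every 256-bin cut, maximize between-class variance
# computed directly from the two class populations.
otsu_bruteforce <- function(image, n_bins = 256L) {
  v <- as.vector(image)
  lo <- min(v); hi <- max(v)
  idx <- pmin(as.integer((v - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  best <- -Inf; best_k <- NA
  for (k in seq_len(n_bins - 1L)) {
    g0 <- idx <= k; g1 <- !g0
    if (!any(g0) || !any(g1)) next
    w0 <- mean(g0)
    bcv <- w0 * (1 - w0) * (mean(idx[g0]) - mean(idx[g1]))^2
    if (bcv > best + 1e-12) { best <- bcv; best_k <- k }
  }
  lo + (hi - lo) * best_k / n_bins
}

# Naive GLCM: loop over every pixel pair at the requested offset.
glcm_bruteforce <- function(q, levels, dr, dc, symmetric = TRUE) {
  h <- nrow(q); w <- ncol(q)
  m <- matrix(0, levels, levels)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
      m[q[r, c], q[r2, c2]] <- m[q[r, c], q[r2, c2]] + 1
    }
  }
  if (symmetric) m <- m + t(m)
  m / sum(m)
}

# The 13 Haralick statistics written directly from their definitions with
# explicit loops (no vectorized reuse of the package code).
haralick_bruteforce <- function(P) {
  L <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mx <- sum((1:L) * px); my <- sum((1:L) * py)
  sx <- sqrt(sum(((1:L) - mx)^2 * px)); sy <- sqrt(sum(((1:L) - my)^2 * py))
  f1 <- f2 <- f4 <- f5 <- f9 <- 0; fcor <- 0
  pxy_sum <- numeric(2L * L - 1L); pxy_dif <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    f1 <- f1 + p^2
    f2 <- f2 + (i - j)^2 * p
    f4 <- f4 + (i - mx)^2 * p
    f5 <- f5 + p / (1 + (i - j)^2)
    if (p > 0) f9 <- f9 - p * log(p)
    fcor <- fcor + i * j * p
    pxy_sum[i + j - 1L] <- pxy_sum[i + j - 1L] + p
    pxy_dif[abs(i - j) + 1L] <- pxy_dif[abs(i - j) + 1L] + p
  }
  f3 <- if (sx > 0 && sy > 0) (fcor - mx * my) / (sx * sy) else 0
  ks <- 2:(2 * L); kd <- 0:(L - 1L)
  ps <- pxy_sum; pd <- pxy_dif
  f6 <- sum(ks * ps)
  f7 <- sum((ks - f6)^2 * ps)
  f8 <- -sum(ps[ps > 0] * log(ps[ps > 0]))
  da <- sum(kd * pd)
  f10 <- sum((kd - da)^2 * pd)
  f11 <- -sum(pd[pd > 0] * log(pd[pd > 0]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    q <- px[i] * py[j]
    if (q > 0) {
      hxy2 <- hxy2 - q * log(q)
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log(q)
    }
  }
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f9))))
  c(asm = f1, contrast = f2, correlation = f3, variance = f4, idm = f5,
    sum_average = f6, sum_variance = f7, sum_entropy = f8, entropy = f9,
    difference_variance = f10, difference_entropy = f11,
    imc1 = f12, imc2 = f13)
}

# Rasterized shapes on pixel-centre grids.
raster_disk <- function(r, pad = 10L) {
  n <- 2L * r + 2L * pad + 1L
  c0 <- pad + r + 1L
  outer(1:n, 1:n, function(i, j) as.integer((i - c0)^2 + (j - c0)^2 <= r^2))
}

raster_rect <- function(h, w, pad = 10L) {
  m <- matrix(0L, h + 2L * pad, w + 2L * pad)
  m[pad + 1:h, pad + 1:w] <- 1L
  m
}

# Selection-count TOS evaluated straight from the stated piecewise
# formulas (no clipping shortcuts).
tos_log_reference <- function(n12, n1, n2, N) {
  E <- n1 * n2 / N
  M <- min(n1, n2)
  m <- max(0, n1 + n2 - N)
  if (n12 >= E) {
    log(max(n12, 0.5) / max(E, 0.5)) / log(M / max(E, 0.5))
  } else {
    log(max(n12, 0.5) / E) / log(E / max(m, 0.5))
  }
}
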