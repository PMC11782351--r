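# Minimal CPU tensor engine for the RCA-UNet.
#
# Feature maps are 4-D arrays (H, W, B, C); flattening the first three
# dimensions gives the matrix view (H*W*B) x C used for BLAS matrix
# products. 3x3 convolutions run through an im2col gather with a
# precomputed index vector, so forward and backward are single indexed
# subsets plus one matrix multiplication each. Everything is double
# precision and deterministic given the seed.

nn_env <- new.env(parent = emptyenv())

# Index vector mapping (out pixel, kernel offset) to padded plane
# positions, cached per geometry. Row order: hw fastest, then batch;
# block order: the 9 kernel offsets.
im2col_index <- function(H, W, B) {
  key <- paste(H, W, B, sep = "x")
  if (!is.null(nn_env[[key]])) return(nn_env[[key]])
  Hp <- H + 2L; Wp <- W + 2L
  ii <- rep.int(seq_len(H), W)            # out row per (hw)
  jj <- rep(seq_len(W), each = H)
  bb <- rep(seq_len(B), each = H * W)
  ii <- rep.int(ii, B); jj <- rep.int(jj, B)
  idx <- vector("list", 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    idx[[k]] <- (ii + 1L + di) + Hp * (jj + dj) + Hp * Wp * (bb - 1L)
  }
  out <- unlist(idx, use.names = FALSE)
  nn_env[[key]] <- out
  out
}

pad_plane <- function(x) {
  d <- dim(x)                              # (H, W, B, C)
  xp <- array(0, c(d[1L] + 2L, d[2L] + 2L, d[3L], d[4L]))
  xp[2L:(d[1L] + 1L), 2L:(d[2L] + 1L), , ] <- x
  dim(xp) <- c((d[1L] + 2L) * (d[2L] + 2L) * d[3L], d[4L])
  xp
}

conv3_init <- function(cin, cout) {
  w <- matrix(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
              9L * cin, cout)
  list(W = w, b = numeric(cout))
}

conv1_init <- function(cin, cout, zero = FALSE) {
  w <- if (zero) matrix(0, cin, cout) else
    matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout)
  list(W = w, b = numeric(cout))
}

# 3x3 same-padding convolution. Weight rows are ordered offset-fastest
# within input channel, matching the im2col column order. With
# `keep_cols = TRUE` the im2col matrix is cached for the backward pass.
conv3_forward <- function(pars, x, keep_cols = FALSE) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; B <- d[3L]; C <- d[4L]
  idx <- im2col_index(H, W, B)
  P <- pad_plane(x)
  cols <- P[idx, , drop = FALSE]           # (9*HWB) x C, offset-major blocks
  dim(cols) <- c(H * W * B, 9L * C)
  y <- cols %*% pars$W
  y <- y + rep(pars$b, each = nrow(y))
  dim(y) <- c(H, W, B, ncol(pars$W))
  if (keep_cols) list(y = y, cols = cols) else y
}

# Input gradients are the correlation of dy with the spatially flipped
# kernel (single gather + GEMM); weight gradients reuse the cached
# im2col matrix from the forward pass.
conv3_backward <- function(pars, cols, x_dim, dy) {
  H <- x_dim[1L]; W <- x_dim[2L]; B <- x_dim[3L]; C <- x_dim[4L]
  HWB <- H * W * B
  cout <- ncol(pars$W)
  dyM <- dy; dim(dyM) <- c(HWB, cout)
  dW <- crossprod(cols, dyM)
  db <- colSums(dyM)
  Wa <- pars$W; dim(Wa) <- c(9L, C, cout)
  Wrot <- aperm(Wa[9:1, , , drop = FALSE], c(1L, 3L, 2L))
  dim(Wrot) <- c(9L * cout, C)
  idx <- im2col_index(H, W, B)
  Pdy <- pad_plane(dy)
  cols_dy <- Pdy[idx, , drop = FALSE]
  dim(cols_dy) <- c(HWB, 9L * cout)
  dx <- cols_dy %*% Wrot
  dim(dx) <- c(H, W, B, C)
  list(dx = dx, grads = list(W = dW, b = db))
}

conv1_forward <- function(pars, x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1L] * d[2L] * d[3L], d[4L])
  y <- xm %*% pars$W
  y <- y + rep(pars$b, each = nrow(y))
  dim(y) <- c(d[1L], d[2L], d[3L], ncol(pars$W))
  y
}

conv1_backward <- function(pars, x, dy) {
  d <- dim(x)
  n <- d[1L] * d[2L] * d[3L]
  xm <- x; dim(xm) <- c(n, d[4L])
  dyM <- dy; dim(dyM) <- c(n, ncol(pars$W))
  dx <- dyM %*% t(pars$W)
  dim(dx) <- d
  list(dx = dx,
       grads = list(W = crossprod(xm, dyM), b = colSums(dyM)))
}

relu <- function(x) { x[x < 0] <- 0; x }

maxpool2_forward <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1L], 2L); jo <- seq(1L, d[2L], 2L)
  s <- list(x[io, jo, , , drop = FALSE], x[io + 1L, jo, , , drop = FALSE],
            x[io, jo + 1L, , , drop = FALSE], x[io + 1L, jo + 1L, , , drop = FALSE])
  y <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
  list(y = y, slices = s)
}

maxpool2_backward <- function(cache, x_dim, dy) {
  y <- cache$y
  dx <- array(0, x_dim)
  io <- seq(1L, x_dim[1L], 2L); jo <- seq(1L, x_dim[2L], 2L)
  di <- c(0L, 1L, 0L, 1L); dj <- c(0L, 0L, 1L, 1L)
  taken <- array(FALSE, dim(y))
  for (k in 1:4) {
    m <- (cache$slices[[k]] == y) & !taken   # first-max tie rule
    taken <- taken | m
    dx[io + di[k], jo + dj[k], , ] <- as.vector(dy * m)
  }
  dx
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
    drop = FALSE]
}

upsample2_backward <- function(dy) {
  d <- dim(dy)
  io <- seq(1L, d[1L], 2L); jo <- seq(1L, d[2L], 2L)
  dy[io, jo, , , drop = FALSE] + dy[io + 1L, jo, , , drop = FALSE] +
    dy[io, jo + 1L, , , drop = FALSE] + dy[io + 1L, jo + 1L, , , drop = FALSE]
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- c(a, b)
  dim(out) <- c(da[1L], da[2L], da[3L], da[4L] + db[4L])
  out
}

# Channel attention: spatial global average per channel -> bottleneck of
# width C/r -> sigmoid gate scaling each channel.
ca_init <- function(C, r) {
  Cr <- max(1L, C %/% r)
  list(W1 = matrix(stats::rnorm(Cr * C, 0, sqrt(2 / C)), Cr, C),
       b1 = numeric(Cr),
       W2 = matrix(stats::rnorm(C * Cr, 0, sqrt(1 / Cr)), C, Cr),
       b2 = numeric(C))
}

# Gate values (B x C) from pooled channel means (B x C).
ca_gate <- function(pars, S) {
  z <- S %*% t(pars$W1) + rep(pars$b1, each = nrow(S))
  u <- relu(z)
  a <- u %*% t(pars$W2) + rep(pars$b2, each = nrow(S))
  list(g = 1 / (1 + exp(-a)), z = z, u = u)
}

ca_forward <- function(pars, x, gate_override = NULL) {
  d <- dim(x); HW <- d[1L] * d[2L]; B <- d[3L]; C <- d[4L]
  xm <- x; dim(xm) <- c(HW, B * C)
  S <- matrix(colMeans(xm), B, C)
  if (is.null(gate_override)) {
    gt <- ca_gate(pars, S)
    g <- gt$g
  } else {
    gt <- NULL
    g <- gate_override
    if (is.null(dim(g))) g <- matrix(g, B, C, byrow = TRUE)
  }
  ym <- xm * rep(as.vector(g), each = HW)
  dim(ym) <- d
  list(y = ym, S = S, gate = gt, g = g)
}

ca_backward <- function(pars, x, cache, dy) {
  d <- dim(x); HW <- d[1L] * d[2L]; B <- d[3L]; C <- d[4L]
  xm <- x; dim(xm) <- c(HW, B * C)
  dym <- dy; dim(dym) <- c(HW, B * C)
  g <- cache$g
  dxm <- dym * rep(as.vector(g), each = HW)
  dg <- matrix(colSums(dym * xm), B, C)
  gt <- cache$gate
  dpre <- dg * g * (1 - g)
  dW2 <- crossprod(dpre, gt$u)
  db2 <- colSums(dpre)
  du <- dpre %*% pars$W2
  dz <- du * (gt$z > 0)
  dW1 <- crossprod(dz, cache$S)
  db1 <- colSums(dz)
  dS <- dz %*% pars$W1
  dxm <- dxm + rep(as.vector(dS), each = HW) / HW
  dim(dxm) <- d
  list(dx = dxm, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# Residual channel attention block: conv3 -> ReLU -> conv3 -> channel
# attention -> residual addition of the (projected) block input.
rca_init <- function(cin, cout, r) {
  list(conv1 = conv3_init(cin, cout),
       conv2 = conv3_init(cout, cout),
       att = ca_init(cout, r),
       proj = if (cin != cout) conv1_init(cin, cout) else NULL)
}

rca_forward <- function(pars, x, gate_override = NULL, pregate_only = FALSE,
                        keep_cache = FALSE) {
  f1 <- conv3_forward(pars$conv1, x, keep_cols = keep_cache)
  h1 <- if (keep_cache) f1$y else f1
  a1 <- relu(h1)
  f2 <- conv3_forward(pars$conv2, a1, keep_cols = keep_cache)
  h2 <- if (keep_cache) f2$y else f2
  if (pregate_only) return(list(pregate = h2))
  ca <- ca_forward(pars$att, h2, gate_override)
  skip <- if (is.null(pars$proj)) x else conv1_forward(pars$proj, x)
  list(y = ca$y + skip, x = x, h1 = h1, h2 = h2, ca = ca,
       cols1 = if (keep_cache) f1$cols, cols2 = if (keep_cache) f2$cols)
}

rca_backward <- function(pars, cache, dy) {
  grads <- list()
  if (is.null(pars$proj)) {
    dx_skip <- dy
    grads$proj <- NULL
  } else {
    pb <- conv1_backward(pars$proj, cache$x, dy)
    dx_skip <- pb$dx
    grads$proj <- pb$grads
  }
  cb <- ca_backward(pars$att, cache$h2, cache$ca, dy)
  grads$att <- cb$grads
  d2 <- dim(cache$h1)
  c2 <- conv3_backward(pars$conv2, cache$cols2, d2, cb$dx)
  grads$conv2 <- c2$grads
  da1 <- c2$dx * (cache$h1 > 0)
  c1 <- conv3_backward(pars$conv1, cache$cols1, dim(cache$x), da1)
  grads$conv1 <- c1$grads
  list(dx = c1$dx + dx_skip,
       grads = grads[c("conv1", "conv2", "att", "proj")])
}

# ---- Adam over a nested parameter list ------------------------------------

adam_init <- function(params) {
  if (is.numeric(params)) return(list(m = params * 0, v = params * 0))
  lapply(params, function(p) if (is.null(p)) NULL else adam_init(p))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.numeric(p)) {
      m <- beta1 * s$m + (1 - beta1) * g
      v <- beta2 * s$v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      return(list(p = p - lr * mh / (sqrt(vh) + eps),
                  s = list(m = m, v = v)))
    }
    out_p <- p; out_s <- s
    for (nm in names(p)) {
      if (is.null(p[[nm]])) next
      r <- walk(p[[nm]], g[[nm]], s[[nm]])
      out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
    }
    list(p = out_p, s = out_s)
  }
  walk(params, grads, state)
}
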