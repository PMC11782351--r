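# Virtual staining: RCA-UNet image-to-image regression.
#
# A UNet whose convolution blocks are residual channel attention (RCA)
# blocks: two 3x3 convolutions with a ReLU between them, a channel
# attention gate (global average pooling -> bottleneck of width C/r ->
# sigmoid, scaling each channel), and a residual addition of the block
# input. The encoder has `depth` levels (RCA block then 2x max pooling,
# channels doubling per level), a bottleneck RCA block, and a symmetric
# decoder with 2x nearest-neighbour upsampling and skip concatenation,
# closed by a 1-channel linear 1x1 head.

#' RCA-UNet model configuration
#'
#' @param depth Encoder levels (default 4; small experiments use 2).
#' @param base_channels Channels at the first level (default 16).
#' @param attention_reduction_r Channel-attention bottleneck reduction
#'   (default 16); must not exceed `base_channels * 2^depth`.
#' @param patch_size_px Training patch side; must be divisible by
#'   `2^depth` (default 128).
#' @param loss `"mse"` or `"mae"` (default `"mse"`).
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs Training epochs (default 10).
#' @param batch_size Patches per step (default 8).
#' @param augment Random 8-fold dihedral augmentation (default TRUE).
#' @param seed Seed for weight init, patch sampling and augmentation.
#' @return Object of class `model_config`.
#' @export
model_config <- function(depth = 4L, base_channels = 16L,
                         attention_reduction_r = 16L, patch_size_px = 128L,
                         loss = c("mse", "mae"), learning_rate = 1e-3,
                         epochs = 10L, batch_size = 8L, augment = TRUE,
                         seed = 1L) {
  loss <- match.arg(loss)
  depth <- as.integer(depth)
  if (patch_size_px %% 2^depth != 0) {
    stop("patch_size_px must be divisible by 2^depth")
  }
  if (attention_reduction_r > base_channels * 2^depth) {
    stop("attention_reduction_r must not exceed base_channels * 2^depth")
  }
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 attention_reduction_r = as.integer(attention_reduction_r),
                 patch_size_px = as.integer(patch_size_px), loss = loss,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), augment = augment,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build an (untrained) RCA-UNet
#'
#' @param config A [model_config()].
#' @param channel_name Name of the fluorescence channel the model will be
#'   trained to predict.
#' @return Object of class `trained_model` with seeded initial weights,
#'   `trained = FALSE` and identity normalization.
#' @export
build_model <- function(config, channel_name = "stain") {
  stopifnot(inherits(config, "model_config"))
  d <- config$depth; base <- config$base_channels
  r <- config$attention_reduction_r
  params <- with_seed(config$seed, {
    enc <- vector("list", d)
    cin <- 1L
    for (i in seq_len(d)) {
      cout <- base * 2^(i - 1L)
      enc[[i]] <- rca_init(cin, cout, r)
      cin <- cout
    }
    bott <- rca_init(base * 2^(d - 1L), base * 2^d, r)
    dec <- vector("list", d)
    for (i in rev(seq_len(d))) {
      cin_i <- base * 2^i + base * 2^(i - 1L)   # upsampled + skip
      dec[[i]] <- rca_init(cin_i, base * 2^(i - 1L), r)
    }
    list(enc = enc, bott = bott, dec = dec,
         head = conv1_init(base, 1L, zero = TRUE))
  })
  structure(list(params = params, config = config,
                 channel_name = channel_name,
                 norm = list(input = c(0, 1), target = c(0, 1)),
                 trained = FALSE, history = NULL),
            class = "trained_model")
}

# Full forward pass. `gates` optionally fixes the attention gates (a list
# indexed by attention-layer order: enc 1..d, bottleneck, dec d..1).
# With `keep_cache = TRUE` all intermediates are retained for backward.
unet_forward <- function(params, x, gates = NULL, keep_cache = FALSE) {
  d <- length(params$enc)
  caches <- list(enc = vector("list", d), pool = vector("list", d),
                 dec = vector("list", d))
  skips <- vector("list", d)
  gi <- 0L
  gate_for <- function() {
    gi <<- gi + 1L
    if (is.null(gates)) NULL else gates[[gi]]
  }
  cur <- x
  pool_dims <- vector("list", d)
  for (i in seq_len(d)) {
    cc <- rca_forward(params$enc[[i]], cur, gate_override = gate_for(),
                      keep_cache = keep_cache)
    if (keep_cache) caches$enc[[i]] <- cc
    skips[[i]] <- cc$y
    pool_dims[[i]] <- dim(cc$y)
    mp <- maxpool2_forward(cc$y)
    if (keep_cache) caches$pool[[i]] <- mp
    cur <- mp$y
  }
  cb <- rca_forward(params$bott, cur, gate_override = gate_for(),
                    keep_cache = keep_cache)
  if (keep_cache) caches$bott <- cb
  cur <- cb$y
  for (i in rev(seq_len(d))) {
    up <- upsample2(cur)
    cat_in <- concat_c(up, skips[[i]])
    cc <- rca_forward(params$dec[[i]], cat_in, gate_override = gate_for(),
                      keep_cache = keep_cache)
    if (keep_cache) caches$dec[[i]] <- cc
    cur <- cc$y
  }
  y <- conv1_forward(params$head, cur)
  list(y = y, caches = if (keep_cache) c(caches, list(
         skips = skips, pool_dims = pool_dims, head_in = cur)) else NULL)
}

unet_backward <- function(params, fw, dy) {
  d <- length(params$enc)
  caches <- fw$caches
  grads <- list(enc = vector("list", d), dec = vector("list", d))
  hb <- conv1_backward(params$head, caches$head_in, dy)
  grads$head <- hb$grads
  dcur <- hb$dx
  dskips <- vector("list", d)
  for (i in seq_len(d)) {            # decoder blocks, shallow to deep
    rb <- rca_backward(params$dec[[i]], caches$dec[[i]], dcur)
    grads$dec[[i]] <- rb$grads
    dcat <- rb$dx
    nc_up <- dim(dcat)[4L] - dim(caches$skips[[i]])[4L]
    dup <- dcat[, , , seq_len(nc_up), drop = FALSE]
    dskips[[i]] <- dcat[, , , nc_up + seq_len(dim(caches$skips[[i]])[4L]),
                        drop = FALSE]
    dcur <- upsample2_backward(dup)
  }
  rb <- rca_backward(params$bott, caches$bott, dcur)
  grads$bott <- rb$grads
  dcur <- rb$dx
  for (i in rev(seq_len(d))) {       # encoder blocks, deep to shallow
    dpooled <- maxpool2_backward(caches$pool[[i]], caches$pool_dims[[i]], dcur)
    dblock <- dpooled + dskips[[i]]
    rb <- rca_backward(params$enc[[i]], caches$enc[[i]], dblock)
    grads$enc[[i]] <- rb$grads
    dcur <- rb$dx
  }
  grads
}

#' Percentile normalization of an image
#'
#' Affine map sending the `low_pct` and `high_pct` intensity percentiles
#' to 0 and 1, clipped to `[0, 1]`.
#'
#' @param image Numeric matrix.
#' @param low_pct,high_pct Percentiles (default 1 and 99).
#' @param bounds Optional precomputed `c(lo, hi)` intensity bounds
#'   (bypasses the percentile computation).
#' @return Normalized matrix; attribute `"bounds"` carries `c(lo, hi)`.
#' @export
normalize_percentile <- function(image, low_pct = 1, high_pct = 99,
                                 bounds = NULL) {
  stopifnot(low_pct < high_pct)
  if (is.null(bounds)) {
    bounds <- unname(stats::quantile(image, c(low_pct, high_pct) / 100))
  }
  if (diff(bounds) <= .Machine$double.eps) {
    stop("degenerate intensity range: image is (near-)constant")
  }
  out <- clip01((image - bounds[1L]) / (bounds[2L] - bounds[1L]))
  attr(out, "bounds") <- bounds
  out
}

dihedral <- function(m, k) {
  # the 8 symmetries of the square, k in 1..8
  if (k > 4L) m <- t(m)
  k <- ((k - 1L) %% 4L) + 1L
  switch(k, m,
         m[rev(seq_len(nrow(m))), , drop = FALSE],
         m[, rev(seq_len(ncol(m))), drop = FALSE],
         m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE])
}

#' Train an RCA-UNet on bright-field / fluorescence pairs
#'
#' Minimizes the configured loss over seeded random patches (resampled
#' each epoch) with optional 8-fold dihedral augmentation, using Adam.
#' Inputs and targets are percentile-normalized with bounds pooled over
#' the training set; the bounds are stored on the model and reapplied at
#' prediction time. Deterministic given the config seed under a fixed
#' BLAS thread policy.
#'
#' @param model A model from [build_model()].
#' @param pairs List of `list(input, target)` matrices (same shape within
#'   a pair, at least `patch_size_px` on each side).
#' @param epochs,learning_rate,batch_size Optional overrides of the
#'   model's config.
#' @return The trained model; `$history` holds the per-epoch mean
#'   training loss.
#' @export
train_model <- function(model, pairs, epochs = NULL, learning_rate = NULL,
                        batch_size = NULL) {
  stopifnot(inherits(model, "trained_model"), length(pairs) >= 1)
  cfg <- model$config
  if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
  if (!is.null(learning_rate)) cfg$learning_rate <- learning_rate
  if (!is.null(batch_size)) cfg$batch_size <- as.integer(batch_size)
  ps <- cfg$patch_size_px
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (!all(dim(p[[1L]]) == dim(p[[2L]]))) {
      stop(sprintf("pair %d: input and target shapes differ", i))
    }
    if (any(dim(p[[1L]]) < ps)) {
      stop(sprintf("pair %d: images smaller than patch_size_px = %d", i, ps))
    }
  }
  in_bounds <- pooled_bounds(lapply(pairs, `[[`, 1L))
  tg_bounds <- pooled_bounds(lapply(pairs, `[[`, 2L))
  xs <- lapply(pairs, function(p)
    normalize_percentile(p[[1L]], bounds = in_bounds))
  ts <- lapply(pairs, function(p)
    normalize_percentile(p[[2L]], bounds = tg_bounds))

  n <- length(pairs)
  params <- model$params
  state <- adam_init(params)
  history <- numeric(cfg$epochs)
  step <- 0L
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        sel <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        B <- length(sel)
        x4 <- array(0, c(ps, ps, B, 1L))
        t4 <- array(0, c(ps, ps, B, 1L))
        for (k in seq_len(B)) {
          xi <- xs[[sel[k]]]; ti <- ts[[sel[k]]]
          r0 <- sample.int(nrow(xi) - ps + 1L, 1L)
          c0 <- sample.int(ncol(xi) - ps + 1L, 1L)
          xp <- xi[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L)]
          tp <- ti[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L)]
          if (cfg$augment) {
            dk <- sample.int(8L, 1L)
            xp <- dihedral(xp, dk); tp <- dihedral(tp, dk)
          }
          x4[, , k, 1L] <- xp; t4[, , k, 1L] <- tp
        }
        fw <- unet_forward(params, x4, keep_cache = TRUE)
        resid <- fw$y - t4
        if (cfg$loss == "mse") {
          loss <- mean(resid^2)
          dy <- 2 * resid / length(resid)
        } else {
          loss <- mean(abs(resid))
          dy <- sign(resid) / length(resid)
        }
        grads <- unet_backward(params, fw, dy)
        step <- step + 1L
        upd <- adam_step(params, grads, state, cfg$learning_rate, step)
        params <- upd$p; state <- upd$s
        losses <- c(losses, loss)
      }
      history[ep] <- mean(losses)
    }
  })
  model$params <- params
  model$config <- cfg
  model$norm <- list(input = in_bounds, target = tg_bounds)
  model$trained <- TRUE
  model$history <- history
  model
}

# Pooled 1/99 percentile bounds over a list of images (subsampled for
# large sets; deterministic).
pooled_bounds <- function(imgs, low_pct = 1, high_pct = 99) {
  v <- unlist(lapply(imgs, function(m) {
    x <- as.vector(m)
    if (length(x) > 16384L) x[seq(1L, length(x), length.out = 16384L)] else x
  }), use.names = FALSE)
  b <- unname(stats::quantile(v, c(low_pct, high_pct) / 100))
  if (diff(b) <= .Machine$double.eps) stop("degenerate training intensities")
  b
}

#' Predict a virtual-stain channel from a bright-field image
#'
#' Applies the model's stored input normalization, pads the image to a
#' multiple of `2^depth` (edge replication), and runs the network. Images
#' larger than `tile_px` are processed in overlapping tiles whose channel
#' attention gates are synchronized to the whole-image statistics, so a
#' tiled prediction is identical to the single-pass prediction up to
#' floating-point rounding.
#'
#' @param model A `trained_model`.
#' @param image Numeric matrix, at least `2^depth` on each side.
#' @param tile_px Tile side (multiple of `2^depth`); `Inf` disables
#'   tiling (default 256).
#' @param allow_untrained Permit prediction from seeded initial weights
#'   (default FALSE).
#' @return Matrix of the predicted channel (normalized target units),
#'   same shape as `image`.
#' @export
predict_stain <- function(model, image, tile_px = 256L,
                          allow_untrained = FALSE) {
  stopifnot(inherits(model, "trained_model"), is.matrix(image))
  if (!model$trained && !allow_untrained) {
    stop("model is untrained; pass allow_untrained = TRUE to use initial weights")
  }
  d <- model$config$depth
  f <- 2^d
  if (any(dim(image) < f)) {
    stop(sprintf("image smaller than the minimum tile (%d px)", f))
  }
  x <- if (model$trained) {
    normalize_percentile(image, bounds = model$norm$input)
  } else image
  H <- nrow(x); W <- ncol(x)
  Hp <- ceiling(H / f) * f; Wp <- ceiling(W / f) * f
  xp <- matrix(0, Hp, Wp)
  xp[seq_len(H), seq_len(W)] <- x
  if (Hp > H) xp[(H + 1L):Hp, seq_len(W)] <- x[rep(H, Hp - H), , drop = FALSE]
  if (Wp > W) xp[, (W + 1L):Wp] <- xp[, rep(W, Wp - W), drop = FALSE]

  if (max(Hp, Wp) <= tile_px) {
    x4 <- array(xp, c(Hp, Wp, 1L, 1L))
    y <- unet_forward(model$params, x4)$y
    return(matrix(y[, , 1L, 1L], Hp, Wp)[seq_len(H), seq_len(W)])
  }
  predict_tiled(model, xp, tile_px)[seq_len(H), seq_len(W)]
}

# Gate-synchronized tiled inference. The attention gates are global
# statistics; computing them per tile would make the output depend on the
# tiling. Instead the gates are resolved sequentially: for attention
# layer k, all tiles are run with layers < k fixed, the pre-gate features
# are pooled over each tile's owned (partition) region, and the gate is
# computed from the combined global mean. A final pass stitches the owned
# regions, which then agree with a whole-image pass wherever the overlap
# exceeds the receptive field.
predict_tiled <- function(model, xp, tile_px) {
  d <- model$config$depth
  f <- 2^d
  tile_px <- as.integer(min(tile_px, max(dim(xp))))
  if (tile_px %% f != 0) tile_px <- (tile_px %/% f) * f
  overlap <- max(4L * f, 32L)
  overlap <- (overlap %/% f) * f
  Hp <- nrow(xp); Wp <- ncol(xp)
  starts <- function(total) {
    if (total <= tile_px) return(0L)
    stride <- tile_px - overlap
    s <- seq(0L, total - tile_px, by = stride)
    if (s[length(s)] != total - tile_px) s <- c(s, total - tile_px)
    as.integer(s)
  }
  s_r <- starts(Hp); s_c <- starts(Wp)
  tiles <- expand.grid(r = s_r, c = s_c)
  tile_h <- min(tile_px, Hp); tile_w <- min(tile_px, Wp)
  # owned region of each tile: midpoints between neighbouring starts,
  # snapped to multiples of 2^depth
  own_range <- function(s, tile_len, total) {
    lo <- hi <- integer(length(s))
    for (i in seq_along(s)) {
      lo[i] <- if (i == 1L) 0L else
        (((s[i - 1L] + tile_len + s[i]) %/% 2L) %/% f) * f
      hi[i] <- if (i == length(s)) total else
        (((s[i] + tile_len + s[i + 1L]) %/% 2L) %/% f) * f
    }
    list(lo = lo, hi = hi)
  }
  own_r <- own_range(s_r, tile_h, Hp)
  own_c <- own_range(s_c, tile_w, Wp)
  n_gates <- 2L * d + 1L
  gate_scale <- c(2^(seq_len(d) - 1L), 2^d, rev(2^(seq_len(d) - 1L)))
  gates <- vector("list", n_gates)
  get_tile <- function(t) {
    r <- tiles$r[t]; c <- tiles$c[t]
    array(xp[(r + 1L):(r + tile_h), (c + 1L):(c + tile_w)],
          c(tile_h, tile_w, 1L, 1L))
  }
  for (k in seq_len(n_gates)) {
    sc <- gate_scale[k]
    acc <- NULL; npix <- 0
    for (t in seq_len(nrow(tiles))) {
      pre <- unet_forward_pregate(model$params, get_tile(t), gates, k)
      ri <- match(tiles$r[t], s_r); ci <- match(tiles$c[t], s_c)
      rlo <- (own_r$lo[ri] - tiles$r[t]) %/% sc + 1L
      rhi <- (own_r$hi[ri] - tiles$r[t]) %/% sc
      clo <- (own_c$lo[ci] - tiles$c[t]) %/% sc + 1L
      chi <- (own_c$hi[ci] - tiles$c[t]) %/% sc
      sub <- pre[rlo:rhi, clo:chi, 1L, , drop = FALSE]
      sums <- colSums(matrix(sub, (rhi - rlo + 1L) * (chi - clo + 1L),
                             dim(pre)[4L]))
      acc <- if (is.null(acc)) sums else acc + sums
      npix <- npix + (rhi - rlo + 1L) * (chi - clo + 1L)
    }
    pars_k <- gate_params(model$params, k)
    gates[[k]] <- ca_gate(pars_k$att, matrix(acc / npix, 1L))$g
  }
  out <- matrix(0, Hp, Wp)
  for (t in seq_len(nrow(tiles))) {
    y <- unet_forward(model$params, get_tile(t), gates = gates)$y
    ri <- match(tiles$r[t], s_r); ci <- match(tiles$c[t], s_c)
    rows <- (own_r$lo[ri] + 1L):own_r$hi[ri]
    cols <- (own_c$lo[ci] + 1L):own_c$hi[ci]
    out[rows, cols] <- y[rows - tiles$r[t], cols - tiles$c[t], 1L, 1L]
  }
  out
}

# Parameters of the k-th attention layer in forward order.
gate_params <- function(params, k) {
  d <- length(params$enc)
  if (k <= d) params$enc[[k]]
  else if (k == d + 1L) params$bott
  else params$dec[[2L * d + 2L - k]]
}

# Forward pass truncated at the k-th attention layer; gates 1..k-1 must
# be fixed. Returns the pre-gate feature tensor of layer k.
unet_forward_pregate <- function(params, x, gates, k) {
  d <- length(params$enc)
  gi <- 0L
  cur <- x
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    gi <- gi + 1L
    if (gi == k) return(rca_forward(params$enc[[i]], cur,
                                    pregate_only = TRUE)$pregate)
    cc <- rca_forward(params$enc[[i]], cur, gate_override = gates[[gi]])
    skips[[i]] <- cc$y
    cur <- maxpool2_forward(cc$y)$y
  }
  gi <- gi + 1L
  if (gi == k) return(rca_forward(params$bott, cur,
                                  pregate_only = TRUE)$pregate)
  cur <- rca_forward(params$bott, cur, gate_override = gates[[gi]])$y
  for (i in rev(seq_len(d))) {
    gi <- gi + 1L
    cat_in <- concat_c(upsample2(cur), skips[[i]])
    if (gi == k) return(rca_forward(params$dec[[i]], cat_in,
                                    pregate_only = TRUE)$pregate)
    cur <- rca_forward(params$dec[[i]], cat_in, gate_override = gates[[gi]])$y
  }
  stop("gate index out of range")
}

#' Save / load a trained model
#'
#' Weights and normalization are serialized losslessly (RDS); the
#' configuration is additionally written as a human-readable JSON
#' sidecar, which is the documented interface of the checkpoint.
#'
#' @param model A `trained_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `save_model` returns `dir` invisibly; `load_model` the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model[c("params", "norm", "trained", "history")],
          file.path(dir, "weights.rds"))
  jsonlite::write_json(
    c(unclass(model$config),
      list(channel_name = model$channel_name, trained = model$trained)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfgj <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- model_config(depth = cfgj$depth, base_channels = cfgj$base_channels,
                      attention_reduction_r = cfgj$attention_reduction_r,
                      patch_size_px = cfgj$patch_size_px, loss = cfgj$loss,
                      learning_rate = cfgj$learning_rate,
                      epochs = cfgj$epochs, batch_size = cfgj$batch_size,
                      augment = cfgj$augment, seed = cfgj$seed)
  w <- readRDS(file.path(dir, "weights.rds"))
  structure(list(params = w$params, config = cfg,
                 channel_name = cfgj$channel_name, norm = w$norm,
                 trained = w$trained, history = w$history),
            class = "trained_model")
}

#' Multiplex virtual staining
#'
#' Applies several single-channel models to one bright-field image.
#'
#' @param models List of `trained_model`s.
#' @param image Bright-field matrix.
#' @param ... Passed to [predict_stain()].
#' @return Named list of predicted channel matrices.
#' @export
predict_multiplex <- function(models, image, ...) {
  out <- lapply(models, predict_stain, image = image, ...)
  names(out) <- vapply(models, `[[`, "", "channel_name")
  out
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("RCA-UNet (%s): depth %d, base %d, %s%s\n",
              x$channel_name, x$config$depth, x$config$base_channels,
              if (x$trained) "trained" else "untrained",
              if (x$trained) sprintf(", final loss %.4g",
                                     utils::tail(x$history, 1)) else ""))
  invisible(x)
}
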