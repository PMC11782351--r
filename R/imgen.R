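# Synthetic microscopy-scene generator.
#
# Produces paired bright-field / fluorescence scenes with exact ground truth
# (label masks, per-cell shape records, organelle positions), standing in for
# raw plant-cell microscopy: puzzle-shaped pavement cells, elongated cell
# files, chloroplast fields and live/dead cell crops. All generators are
# deterministic under their seed and leave the global RNG untouched.

#' Specification of a synthetic scene
#'
#' @param width_px,height_px Canvas size in pixels (both >= 64).
#' @param pixel_size_um Physical pixel size in micrometres. 0.56 suits
#'   BY-2-like suspension cells, 0.28 chloroplast-scale imaging.
#' @param n_cells Number of cells (or chloroplasts for
#'   `shape_model = "chloroplast_field"`).
#' @param shape_model One of `"pavement"` (perturbed Voronoi tessellation
#'   with sinusoidal lobing), `"by2_file"` (a file of elongated cells),
#'   `"chloroplast_field"` (scattered disks), `"viability_crop"` (a single
#'   cell crop; see [generate_viability_set()]).
#' @param lobe_amplitude Boundary waviness of pavement cells in pixels
#'   (>= 0; 0 gives convex Voronoi cells).
#' @param defocus_sigma_px Width of the defocused edge halo
#'   (difference-of-Gaussians scale) in pixels.
#' @param noise_sd Standard deviation of additive Gaussian read noise on
#'   the bright-field image.
#' @param elongation Length-to-width ratio of cells in the `"by2_file"`
#'   model (>= 1).
#' @param seed Integer seed; identical specs regenerate bit-identical
#'   scenes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width_px = 128L, height_px = 128L,
                       pixel_size_um = 0.56, n_cells = 8L,
                       shape_model = c("pavement", "by2_file",
                                       "chloroplast_field", "viability_crop"),
                       lobe_amplitude = 0, defocus_sigma_px = 2,
                       noise_sd = 0.02, elongation = 2.5, seed = 1L) {
  shape_model <- match.arg(shape_model)
  stopifnot(width_px >= 64, height_px >= 64, n_cells >= 1,
            pixel_size_um > 0, lobe_amplitude >= 0,
            defocus_sigma_px >= 0, noise_sd >= 0, elongation >= 1)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 n_cells = as.integer(n_cells),
                 shape_model = shape_model,
                 lobe_amplitude = lobe_amplitude,
                 defocus_sigma_px = defocus_sigma_px,
                 noise_sd = noise_sd,
                 elongation = elongation,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Rejection-sampled point placement with a minimum pairwise distance.
# At most `max_retry` draws per point; overflow is an error, never a
# silent truncation.
place_points <- function(n, width, height, min_dist, margin = 0,
                         max_retry = 200L, what = "object") {
  pts <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      x <- stats::runif(1, 1 + margin, width - margin)
      y <- stats::runif(1, 1 + margin, height - margin)
      if (i == 1L ||
          all((pts[seq_len(i - 1L), 1L] - x)^2 +
              (pts[seq_len(i - 1L), 2L] - y)^2 >= min_dist^2)) {
        pts[i, ] <- c(x, y); ok <- TRUE; break
      }
    }
    if (!ok) {
      stop(sprintf(paste0("cannot place %d %ss on a %dx%d canvas ",
                          "(min distance %.1f px): placement failed at ",
                          "%s %d after %d retries"),
                   n, what, width, height, min_dist, what, i, max_retry))
    }
  }
  pts
}

# Pixel-centre coordinate grids (x = column, y = row, origin top-left).
coord_grid <- function(width, height) {
  list(x = matrix(rep(seq_len(width), each = height), height, width),
       y = matrix(rep(seq_len(height), times = width), height, width))
}

# Boundary pixels of a label image: any pixel with a 4-neighbour carrying a
# different label (the image edge itself is not a boundary).
boundary_mask <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  b <- matrix(FALSE, h, w)
  b[-h, ] <- b[-h, ] | (labels[-h, ] != labels[-1, ])
  b[-1, ] <- b[-1, ] | (labels[-1, ] != labels[-h, ])
  b[, -w] <- b[, -w] | (labels[, -w] != labels[, -1])
  b[, -1] <- b[, -1] | (labels[, -1] != labels[, -w])
  b
}

# Lobed Voronoi tessellation: pixels are assigned to the seed minimising
# distance plus a per-seed sinusoidal term in the polar angle, which bends
# straight Voronoi walls into pavement-cell lobes of roughly
# `lobe_amplitude` pixels.
pavement_labels <- function(spec) {
  w <- spec$width_px; h <- spec$height_px; n <- spec$n_cells
  min_dist <- 0.62 * sqrt(w * h / n)   # even-sized cells, no slivers
  pts <- place_points(n, w, h, min_dist, margin = 2, what = "cell")
  freq <- sample(3:6, n, replace = TRUE)
  phase <- stats::runif(n, 0, 2 * pi)
  g <- coord_grid(w, h)
  best <- matrix(Inf, h, w)
  lab <- matrix(0L, h, w)
  for (i in seq_len(n)) {
    dx <- g$x - pts[i, 1L]; dy <- g$y - pts[i, 2L]
    d <- sqrt(dx^2 + dy^2)
    score <- d + spec$lobe_amplitude * sin(freq[i] * atan2(dy, dx) + phase[i])
    upd <- score < best
    best[upd] <- score[upd]
    lab[upd] <- i
  }
  if (length(setdiff(seq_len(n), unique(as.integer(lab)))) > 0L) {
    stop("pavement tessellation produced an empty cell; ",
         "reduce lobe_amplitude or n_cells for this canvas")
  }
  list(labels = lab, centres = pts)
}

# A horizontal file of elongated cells rendered as abutting superellipses.
by2_labels <- function(spec) {
  w <- spec$width_px; h <- spec$height_px; n <- spec$n_cells
  e <- spec$elongation
  len <- (w - 8) / n                    # x-extent per cell
  hgt <- min(0.55 * h, len / e)         # y-extent from the elongation ratio
  if (len < 8 || hgt < 6) {
    stop(sprintf("cannot place a file of %d cells (elongation %.1f) on a %dx%d canvas",
                 n, e, w, h))
  }
  cy <- h / 2 + stats::runif(1, -0.05, 0.05) * h
  jit_l <- stats::runif(n, 0.92, 1.0)
  jit_h <- stats::runif(n, 0.9, 1.0)
  g <- coord_grid(w, h)
  best <- matrix(Inf, h, w)
  lab <- matrix(0L, h, w)
  centres <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    cx <- 4 + (i - 0.5) * len
    centres[i, ] <- c(cx, cy)
    a <- len * jit_l[i] / 2; b <- hgt * jit_h[i] / 2
    s <- (abs((g$x - cx) / a))^4 + (abs((g$y - cy) / b))^4
    upd <- s <= 1 & s < best
    best[upd] <- s[upd]
    lab[upd] <- i
  }
  if (length(setdiff(seq_len(n), unique(as.integer(lab)))) > 0L) {
    stop("cell file rendering produced an empty cell")
  }
  list(labels = lab, centres = centres)
}

# Scattered non-overlapping chloroplast disks; radii follow the physical
# ~5 um organelle diameter converted through the pixel size.
chloroplast_objects <- function(spec, margin_extra = 3) {
  r_base <- 2.5 / spec$pixel_size_um
  n <- spec$n_cells
  radii <- r_base * stats::runif(n, 0.8, 1.2)
  min_dist <- 2 * max(radii) + 2
  pts <- place_points(n, spec$width_px, spec$height_px, min_dist,
                      margin = max(radii) + margin_extra,
                      what = "chloroplast")
  list(centres = pts, radii = radii)
}

chloroplast_render <- function(spec, centres, radii) {
  w <- spec$width_px; h <- spec$height_px
  g <- coord_grid(w, h)
  lab <- matrix(0L, h, w)
  bestd <- matrix(Inf, h, w)
  chan <- matrix(0, h, w)
  for (i in seq_len(nrow(centres))) {
    d <- sqrt((g$x - centres[i, 1L])^2 + (g$y - centres[i, 2L])^2)
    inside <- d <= radii[i]
    upd <- inside & d < bestd
    bestd[upd] <- d[upd]
    lab[upd] <- i
    chan[inside] <- pmax(chan[inside], 1 - 0.6 * (d[inside] / radii[i])^2)
  }
  # FFT-based blur can leave values a few ulp outside [0,1]
  list(labels = lab, channel = clip01(blur_gauss(chan, 0.7)))
}

# Nucleus centres and radii, one per cell, placed near (jittered) centroids.
nuclei_for_cells <- function(labels, centres) {
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids > 0L]
  out <- matrix(NA_real_, length(ids), 3L)
  area <- tabulate(as.integer(labels)[as.integer(labels) > 0L])
  for (k in seq_along(ids)) {
    i <- ids[k]
    req <- sqrt(area[i] / pi)
    r_n <- max(2, 0.28 * req)
    cx <- centres[i, 1L]; cy <- centres[i, 2L]
    pos <- c(cx, cy)
    for (try in 1:20) {
      cand <- c(cx, cy) + stats::runif(2, -0.25, 0.25) * req
      ri <- round(cand[2L]); ci <- round(cand[1L])
      if (ri >= 1 && ri <= nrow(labels) && ci >= 1 && ci <= ncol(labels) &&
          labels[ri, ci] == i) { pos <- cand; break }
    }
    out[k, ] <- c(pos, r_n)
  }
  out
}

# Fluorescence channels for cell-based scenes. Targets are deterministic
# functions of scene geometry (no unlearnable per-cell brightness), so a
# regression model can in principle recover them from bright-field alone.
cell_channels <- function(labels, nuclei) {
  h <- nrow(labels); w <- ncol(labels)
  bnd <- boundary_mask(labels)
  membrane <- blur_gauss(bnd * 1.0, 0.9)
  membrane <- clip01(membrane / max(membrane))

  g <- coord_grid(w, h)
  nuc <- matrix(0, h, w)
  for (k in seq_len(nrow(nuclei))) {
    d2 <- (g$x - nuclei[k, 1L])^2 + (g$y - nuclei[k, 2L])^2
    nuc <- pmax(nuc, clip01(1 - d2 / nuclei[k, 3L]^2))
  }
  nucleus <- clip01(blur_gauss(nuc, 0.8))

  dist_b <- as.matrix(EBImage::distmap(matrix(as.numeric(!bnd), h, w)))
  vac_core <- (dist_b >= 3) & (labels > 0) & (nuc < 0.15)
  vacuole <- clip01(blur_gauss(vac_core * 0.9, 1.0))

  list(membrane = membrane, nucleus = nucleus, vacuole = vacuole)
}

# Bright-field rendering: interior transmittance below background, a thin
# dark wall line, and a signed difference-of-Gaussians halo around edges
# ("slightly defocused" appearance), organelle-induced transmittance
# shifts, then additive Gaussian read noise, clipped to [0, 1].
render_brightfield <- function(labels, spec, channels = NULL,
                               chloro = NULL) {
  h <- nrow(labels); w <- ncol(labels)
  inside <- labels > 0L
  bf <- 0.92 - 0.07 * inside
  bnd <- boundary_mask(labels) * 1.0
  s1 <- max(spec$defocus_sigma_px, 0.5)
  dog <- blur_gauss(bnd, s1) - blur_gauss(bnd, 2 * s1)
  bf <- bf - 0.30 * blur_gauss(bnd, 0.7) + 0.45 * dog
  if (!is.null(channels)) {
    if (!is.null(channels$nucleus)) bf <- bf - 0.07 * channels$nucleus
    if (!is.null(channels$vacuole)) bf <- bf + 0.05 * channels$vacuole
  }
  if (!is.null(chloro)) bf <- bf - 0.30 * chloro
  if (spec$noise_sd > 0) {
    bf <- bf + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
  }
  clip01(bf)
}

truth_records <- function(labels, spec, radii = NULL) {
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids > 0L]
  g <- coord_grid(ncol(labels), nrow(labels))
  out <- data.frame(id = ids, area_px = NA_real_,
                    cx_px = NA_real_, cy_px = NA_real_)
  for (k in seq_along(ids)) {
    m <- labels == ids[k]
    out$area_px[k] <- sum(m)
    out$cx_px[k] <- mean(g$x[m])
    out$cy_px[k] <- mean(g$y[m])
  }
  if (!is.null(radii)) out$radius_px <- radii[ids]
  out
}

#' Generate one synthetic bright-field / fluorescence scene
#'
#' Renders a label mask for the requested shape model, fluorescence ground
#' truth channels (plasma membrane, nucleus, vacuole or chloroplasts), and
#' a bright-field image with defocused edge halos and read noise. The same
#' spec always regenerates a bit-identical scene.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `scene_pair`: a list with elements
#'   `brightfield` (matrix in `[0,1]`), `channels` (named list of matrices),
#'   `labels` (integer matrix, 0 = background), `truth` (per-object
#'   data.frame with pixel areas and centroids), and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    if (spec$shape_model == "pavement") {
      pv <- pavement_labels(spec)
      nuc <- nuclei_for_cells(pv$labels, pv$centres)
      ch <- cell_channels(pv$labels, nuc)
      bf <- render_brightfield(pv$labels, spec, channels = ch)
      truth <- truth_records(pv$labels, spec)
      truth$nucleus_x <- nuc[, 1L]; truth$nucleus_y <- nuc[, 2L]
    } else if (spec$shape_model == "by2_file") {
      pv <- by2_labels(spec)
      nuc <- nuclei_for_cells(pv$labels, pv$centres)
      ch <- cell_channels(pv$labels, nuc)
      bf <- render_brightfield(pv$labels, spec, channels = ch)
      truth <- truth_records(pv$labels, spec)
      truth$nucleus_x <- nuc[, 1L]; truth$nucleus_y <- nuc[, 2L]
    } else if (spec$shape_model == "chloroplast_field") {
      ob <- chloroplast_objects(spec)
      rd <- chloroplast_render(spec, ob$centres, ob$radii)
      ch <- list(chloroplast = rd$channel)
      bf <- render_brightfield(rd$labels, spec, chloro = rd$channel)
      truth <- truth_records(rd$labels, spec, radii = ob$radii)
      pv <- rd
    } else {
      stop("viability_crop scenes are produced by generate_viability_set()")
    }
    structure(list(brightfield = bf, channels = ch,
                   labels = pv$labels, truth = truth, spec = spec),
              class = "scene_pair")
  })
}

#' Generate a seeded chloroplast time-lapse with ground-truth tracks
#'
#' Chloroplasts follow a correlated random walk with reflecting boundaries;
#' per-interval truth speeds are recorded from the realised centroid
#' displacements converted through the pixel size and frame interval, so
#' they are exact by construction.
#'
#' @param spec A [scene_spec()] with `shape_model = "chloroplast_field"`.
#' @param n_frames Number of frames (>= 2).
#' @param speed_model List with `mean_um_s` (>= 0), `sd` (>= 0) and
#'   `direction_persistence` in `[0, 1]`.
#' @param dt_s Frame interval in seconds (default 0.5).
#' @return An object of class `timelapse_truth`: `frames` (list of
#'   `scene_pair`), `dt_s`, `tracks` (list of `n_frames` x 2 centroid
#'   matrices, px), `speeds_um_s` (objects x intervals matrix), `spec`.
#' @export
generate_timelapse <- function(spec, n_frames,
                               speed_model = list(mean_um_s = 2,
                                                  sd = 0.5,
                                                  direction_persistence = 0.8),
                               dt_s = 0.5) {
  stopifnot(inherits(spec, "scene_spec"),
            spec$shape_model == "chloroplast_field",
            n_frames >= 2, speed_model$mean_um_s >= 0)
  if (is.null(speed_model$sd) || speed_model$sd < 0) {
    stop("speed_model$sd must be non-negative")
  }
  p <- speed_model$direction_persistence
  stopifnot(p >= 0, p <= 1)
  with_seed(spec$seed, {
    ob <- chloroplast_objects(spec, margin_extra = 5)
    n <- spec$n_cells
    margin <- max(ob$radii) + 2
    pos <- ob$centres
    ang <- stats::runif(n, 0, 2 * pi)
    dir <- cbind(cos(ang), sin(ang))
    tracks <- lapply(seq_len(n), function(i) {
      m <- matrix(NA_real_, n_frames, 2L); m[1L, ] <- pos[i, ]; m
    })
    speeds <- matrix(NA_real_, n, n_frames - 1L)
    frames <- vector("list", n_frames)
    render_frame <- function(centres) {
      rd <- chloroplast_render(spec, centres, ob$radii)
      bf <- render_brightfield(rd$labels, spec, chloro = rd$channel)
      structure(list(brightfield = bf,
                     channels = list(chloroplast = rd$channel),
                     labels = rd$labels,
                     truth = truth_records(rd$labels, spec, radii = ob$radii),
                     spec = spec),
                class = "scene_pair")
    }
    frames[[1L]] <- render_frame(pos)
    lo <- 1 + margin
    hix <- spec$width_px - margin
    hiy <- spec$height_px - margin
    for (t in 2:n_frames) {
      u_ang <- stats::runif(n, 0, 2 * pi)
      mix <- p * dir + (1 - p) * cbind(cos(u_ang), sin(u_ang))
      nr <- sqrt(rowSums(mix^2))
      nr[nr == 0] <- 1
      dir <- mix / nr
      sp <- pmax(0, stats::rnorm(n, speed_model$mean_um_s, speed_model$sd))
      step <- sp * dt_s / spec$pixel_size_um
      sep <- 2 * max(ob$radii) + 4   # excluded-volume separation
      for (i in seq_len(n)) {
        d <- dir[i, ] * step[i]
        new <- pos[i, ] + d
        # reflect the step direction off canvas walls (preserves |step|)
        if (new[1L] < lo || new[1L] > hix) { d[1L] <- -d[1L]; dir[i, 1L] <- -dir[i, 1L] }
        if (new[2L] < lo || new[2L] > hiy) { d[2L] <- -d[2L]; dir[i, 2L] <- -dir[i, 2L] }
        new <- pmin(pmax(pos[i, ] + d, lo), c(hix, hiy))
        # excluded volume: organelles never approach closer than their
        # blob support; a blocked step reverses, a doubly blocked one
        # stalls (zero realised displacement, recorded as such)
        other <- pos[-i, , drop = FALSE]
        too_close <- function(p2) any((other[, 1L] - p2[1L])^2 +
                                        (other[, 2L] - p2[2L])^2 < sep^2)
        if (too_close(new)) {
          d <- -d
          dir[i, ] <- -dir[i, ]
          new <- pmin(pmax(pos[i, ] + d, lo), c(hix, hiy))
          if (too_close(new)) new <- pos[i, ]
        }
        speeds[i, t - 1L] <- sqrt(sum((new - pos[i, ])^2)) *
          spec$pixel_size_um / dt_s
        pos[i, ] <- new
        tracks[[i]][t, ] <- new
      }
      frames[[t]] <- render_frame(pos)
    }
    structure(list(frames = frames, dt_s = dt_s, tracks = tracks,
                   speeds_um_s = speeds, spec = spec),
              class = "timelapse_truth")
  })
}

# One living or dead cell crop (bright-field + membrane fluorescence).
#
# Both classes share the same cell-wall geometry: death does not remove
# the wall, so the bright-field outline looks alike. In living cells the
# plasma membrane lines the wall (smooth bright ring in fluorescence,
# quiet interior). In dead cells the protoplast has retracted into a
# shrunken wavy contour with a fragmented membrane and collapse debris --
# obvious in the fluorescence channel, but only a faint, near-noise
# transmittance signature in bright-field.
render_viability_crop <- function(size_px, living, noise_sd) {
  g <- coord_grid(size_px, size_px)
  cx <- size_px / 2 + stats::runif(1, -2, 2)
  cy <- size_px / 2 + stats::runif(1, -2, 2)
  th <- stats::runif(1, -pi / 9, pi / 9)
  xr <- (g$x - cx) * cos(th) + (g$y - cy) * sin(th)
  yr <- -(g$x - cx) * sin(th) + (g$y - cy) * cos(th)
  # cell wall: same size distribution for both classes
  a <- size_px * stats::runif(1, 0.38, 0.44)
  b <- a / stats::runif(1, 1.9, 2.6)
  inside <- (abs(xr / a))^3 + (abs(yr / b))^3 <= 1
  wall_lab <- matrix(0L, size_px, size_px)
  wall_lab[inside] <- 1L
  wall_bnd <- boundary_mask(wall_lab) * 1.0

  speck <- blur_gauss(matrix(stats::runif(size_px^2) < 0.25,
                             size_px, size_px) * 1.0, 0.5)
  speck <- speck - mean(speck)

  if (living) {
    membrane <- blur_gauss(wall_bnd, 0.9)
    speckle_amp <- stats::runif(1, 0, 0.04)
    proto_bnd <- NULL
    # living interior structure: nucleus, transvacuolar strands and
    # granules -- coherent internal contours that are invisible in the
    # membrane stain but show in bright-field, like the collapse contour
    # of dead cells does
    nr <- stats::runif(1, 0.18, 0.26) * a
    ncx <- stats::runif(1, -0.4, 0.4) * a; ncy <- stats::runif(1, -0.4, 0.4) * b
    nd2 <- ((xr - ncx) / nr)^2 + ((yr - ncy) / (nr * stats::runif(1, 0.7, 1)))^2
    organelles <- 0.10 * blur_gauss((nd2 <= 1) * 1.0, 0.8)
    n_str <- sample(1:3, 1)
    strand <- matrix(0, size_px, size_px)
    for (k in seq_len(n_str)) {
      ang_s <- stats::runif(1, 0, 2 * pi)
      tpar <- seq(0, 1, length.out = 80)
      sx <- ncx + tpar * (0.9 * a * cos(ang_s) - ncx) +
        0.08 * a * sin(3 * pi * tpar + stats::runif(1, 0, 2 * pi))
      sy <- ncy + tpar * (0.9 * b * sin(ang_s) - ncy) +
        0.08 * b * sin(2 * pi * tpar + stats::runif(1, 0, 2 * pi))
      ri <- round(cy + (-sx * sin(-th) + sy * cos(-th)))
      ci <- round(cx + (sx * cos(-th) + sy * sin(-th)))
      ok <- ri >= 1 & ri <= size_px & ci >= 1 & ci <= size_px
      strand[cbind(ri[ok], ci[ok])] <- 1
    }
    organelles <- organelles + 0.08 * blur_gauss(strand, 0.7)
    n_gran <- stats::rpois(1, 4)
    for (k in seq_len(n_gran)) {
      gx <- stats::runif(1, -0.8, 0.8) * a; gy <- stats::runif(1, -0.8, 0.8) * b
      gr <- stats::runif(1, 1, 2.2)
      organelles <- organelles +
        stats::runif(1, 0.04, 0.1) * clip01(1 - ((xr - gx)^2 + (yr - gy)^2) / gr^2)
    }
  } else {
    sc <- stats::runif(1, 0.5, 0.7)
    off_x <- stats::runif(1, -0.12, 0.12) * a
    off_y <- stats::runif(1, -0.12, 0.12) * b
    ang <- atan2((yr - off_y) / (b * sc), (xr - off_x) / (a * sc))
    wav <- 1 + 0.18 * sin(3 * ang + stats::runif(1, 0, 2 * pi)) +
      0.10 * sin(5 * ang + stats::runif(1, 0, 2 * pi))
    proto <- ((xr - off_x) / (a * sc))^2 + ((yr - off_y) / (b * sc))^2 <= wav
    proto_lab <- matrix(0L, size_px, size_px)
    proto_lab[proto & inside] <- 1L
    proto_bnd <- boundary_mask(proto_lab) * 1.0
    # collapsed membrane mass: the stain fills the shrunken protoplast
    # (bulk aggregate) with speckled collapse debris on top
    debris <- blur_gauss((speck > stats::quantile(speck, 0.75)) * 1.0, 0.4)
    membrane <- 0.7 * blur_gauss((proto_lab > 0L) * 1.0, 1.0) +
      0.4 * blur_gauss(proto_bnd, 0.9) +
      0.5 * clip01(2 * debris) * (proto_lab > 0L)
    speckle_amp <- stats::runif(1, 0.02, 0.08)
  }
  mx <- max(membrane)
  if (mx > 0) membrane <- membrane / mx
  membrane <- clip01(membrane)

  bf <- 0.92 - 0.06 * inside
  dog <- blur_gauss(wall_bnd, 1.5) - blur_gauss(wall_bnd, 3)
  bf <- bf - 0.28 * blur_gauss(wall_bnd, 0.7) + 0.4 * dog
  if (living) {
    bf <- bf - organelles * inside
  } else {
    bf <- bf - 0.12 * blur_gauss(proto_bnd, 0.8)   # retracted protoplast edge
  }
  bf <- bf + speckle_amp * speck * inside
  # per-crop acquisition nuisances (focus drift, debris, read noise level):
  # they disturb bright-field texture statistics crop to crop but leave
  # the fluorescence target untouched
  n_debris <- stats::rpois(1, 3)
  for (k in seq_len(n_debris)) {
    dcx <- stats::runif(1, 3, size_px - 3); dcy <- stats::runif(1, 3, size_px - 3)
    dr <- stats::runif(1, 1.5, 4)
    damp <- stats::runif(1, -0.08, 0.08)
    bf <- bf + damp * clip01(1 - ((g$x - dcx)^2 + (g$y - dcy)^2) / dr^2)
  }
  focus_sig <- stats::runif(1, 0, 0.8)
  if (focus_sig > 0.05) bf <- blur_gauss(bf, focus_sig)
  noise_eff <- stats::runif(1, 0.4, 1.3) * noise_sd
  bf <- bf + matrix(stats::rnorm(size_px^2, 0, noise_eff), size_px, size_px)
  list(brightfield = clip01(bf), membrane = membrane,
       label = if (living) "living" else "dead")
}

#' Generate a balanced set of living and dead cell crops
#'
#' Living crops show an intact elongated cell with a smooth interior and a
#' continuous, crisp boundary; dead crops a shrunken wavy contour with a
#' fragmented membrane and high-frequency collapse speckle, in both the
#' bright-field and the membrane-fluorescence channel.
#'
#' @param n_per_class Crops per class (>= 2).
#' @param seed Integer seed.
#' @param size_px Crop side length in pixels (default 64).
#' @param noise_sd Bright-field read-noise SD (default 0.05).
#' @return A list of `2 * n_per_class` records, each with `brightfield`,
#'   `membrane` and `label` (`"living"` or `"dead"`), in interleaved
#'   class-balanced order; class `viability_set`.
#' @export
generate_viability_set <- function(n_per_class, seed, size_px = 64L,
                                   noise_sd = 0.03) {
  stopifnot(n_per_class >= 2, size_px >= 32)
  with_seed(seed, {
    out <- vector("list", 2L * n_per_class)
    for (i in seq_len(n_per_class)) {
      out[[2L * i - 1L]] <- render_viability_crop(size_px, TRUE, noise_sd)
      out[[2L * i]] <- render_viability_crop(size_px, FALSE, noise_sd)
    }
    structure(out, class = "viability_set")
  })
}

#' @export
print.scene_pair <- function(x, ...) {
  cat(sprintf("scene_pair: %dx%d px (%.2f um/px), %s, %d objects, channels: %s\n",
              x$spec$width_px, x$spec$height_px, x$spec$pixel_size_um,
              x$spec$shape_model, max(x$labels),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
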