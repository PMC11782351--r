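# Segmentation and per-cell morphometrics.
#
# Otsu binarization plus connected components for particle-style
# measurements, tolerance-based (h-extrema) watershed for membrane images,
# and per-cell shape metrics: area, perimeter, circularity 4*pi*S/L^2,
# solidity (area over convex-hull area) and fitted-ellipse aspect ratio.
#
# Perimeter convention: the outer cell boundary is traced as a sub-pixel
# marching-squares contour (pixel centres at integer coordinates, the 0.5
# iso-level) and lightly smoothed with a 3-point circular moving average,
# which removes the raster staircase so that a digitized disk measures a
# circularity close to 1. Solidity uses the same polygon for both the
# region and its convex hull, so convex rasters measure exactly 1.

#' Otsu threshold of a grayscale image
#'
#' Maximizes between-class variance over a 256-bin histogram of the image
#' range; ties resolve to the lowest qualifying threshold.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param n_bins Histogram resolution (default 256).
#' @return Threshold on the intensity scale of `image`; pixels strictly
#'   above it form the foreground.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.vector(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant image: Otsu threshold undefined")
  idx <- pmin(as.integer((v - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  h <- tabulate(idx, n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  # between-class variance for a cut after bin k (k = 1 .. n_bins - 1)
  k <- seq_len(n_bins - 1L)
  w0 <- omega[k]
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu_t * w0[valid] - mu[k][valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  kk <- which.max(bcv)                      # which.max takes the first tie
  lo + (hi - lo) * kk / n_bins
}

#' Connected-component particle extraction
#'
#' Labels 8-connected foreground components, removes components smaller
#' than `min_area_px`, and (optionally) components touching the image
#' border. Surviving components are relabeled 1..n.
#'
#' @param binary Logical or 0/1 matrix.
#' @param min_area_px Minimum component area in pixels (default 50).
#' @param exclude_border Drop border-touching components (default TRUE).
#' @return Integer label matrix (0 = background).
#' @export
segment_particles <- function(binary, min_area_px = 50L,
                              exclude_border = TRUE) {
  stopifnot(is.matrix(binary))
  lab <- label_components_8(binary)
  filter_labels(lab, min_area_px = min_area_px,
                exclude_border = exclude_border)
}

# 8-connected components via two passes of EBImage's 4-connected bwlabel
# with diagonal merging through union-find.
label_components_8 <- function(binary) {
  b <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  lab <- as.matrix(EBImage::bwlabel(b))
  storage.mode(lab) <- "integer"
  nmax <- max(lab)
  if (nmax <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1L]); b2 <- find(pairs[r, 2L])
      if (a != b2) parent[max(a, b2)] <- min(a, b2)
    }
  }
  root <- vapply(seq_len(nmax), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

# Drop small and/or border-touching labels, relabeling densely.
filter_labels <- function(lab, min_area_px = 0L, exclude_border = FALSE) {
  if (max(lab) == 0L) return(lab)
  keep <- which(tabulate(lab[lab > 0L], max(lab)) >= min_area_px)
  if (exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep <- setdiff(keep, border)
  }
  map <- integer(max(lab))
  map[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

#' Tolerance-based watershed segmentation
#'
#' Segments an image with bright boundaries (such as a membrane stain)
#' into regions. Optionally a morphological gradient (dilation minus
#' erosion over a `(2r+1)`-square) turns step edges into ridges first;
#' for fluorescence membrane images, where the membrane itself is the
#' ridge, use `gradient_radius_px = 0` to flood the intensity directly.
#' Catchment basins whose dynamic (depth relative to the lowest saddle
#' towards a neighbour basin) is below `tolerance` are merged, mirroring
#' h-extrema suppression before flooding. The output labels partition the
#' image: every pixel, including former watershed lines, belongs to a
#' region.
#'
#' @param image Numeric matrix.
#' @param tolerance Basin depth below which regions merge, in the
#'   intensity units of `image` (on 16-bit integer scales the useful range
#'   is roughly 10^2 to 10^4; divide by 65535 for `[0,1]` images).
#' @param gradient_radius_px Radius of the morphological gradient
#'   element; 0 skips the gradient (default 1).
#' @return Integer label matrix; a single region raises a warning.
#' @export
marker_watershed <- function(image, tolerance, gradient_radius_px = 1L) {
  stopifnot(is.matrix(image), tolerance > 0)
  elev <- image
  if (gradient_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(gradient_radius_px) + 1L,
                                shape = "box")
    elev <- as.matrix(EBImage::dilate(image, brush)) -
      as.matrix(EBImage::erode(image, brush))
  }
  inv <- max(elev) - elev + 1e-6          # flood from intensity minima
  lab <- as.matrix(EBImage::watershed(EBImage::as.Image(inv),
                                      tolerance = tolerance, ext = 1L))
  storage.mode(lab) <- "integer"
  if (max(lab) <= 1L) {
    warning("watershed produced a single region (tolerance >= image dynamic?)")
  }
  lab
}

# Outer contour of one label as a closed sub-pixel polygon: the longest
# marching-squares line at the 0.5 iso-level of the padded mask, lightly
# smoothed. Coordinates are (x, y) pixel centres.
label_contour <- function(mask, smooth_w = 3L) {
  h <- nrow(mask); w <- ncol(mask)
  pm <- matrix(0, h + 2L, w + 2L)
  pm[2:(h + 1L), 2:(w + 1L)] <- mask
  cl <- grDevices::contourLines(x = 0:(h + 1L), y = 0:(w + 1L), z = pm,
                                levels = 0.5)
  if (!length(cl)) return(NULL)
  cl <- cl[[which.max(vapply(cl, function(cc) length(cc$x), numeric(1)))]]
  p <- cbind(y = cl$x, x = cl$y)   # contourLines' x runs along rows
  if (all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  p <- smooth_contour(p, smooth_w)
  cbind(x = p[, 2L], y = p[, 1L])
}

#' Per-cell morphometrics from a label mask
#'
#' For every label: area `S` (pixel count times squared pixel size),
#' perimeter `L` from the smoothed sub-pixel contour, circularity
#' `4*pi*S/L^2`, solidity (contour polygon area over its convex hull
#' area; exactly 1 for convex rasters), fitted-ellipse aspect ratio from
#' second central moments, and the intensity-unweighted centroid.
#'
#' @param labels Integer label matrix (0 = background).
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @return A data.frame with one row per label: `id`, `area_um2`,
#'   `perimeter_um`, `circularity`, `solidity`, `aspect_ratio`, `cx_um`,
#'   `cy_um`. Empty label set gives zero rows.
#' @export
measure_cells <- function(labels, pixel_size_um) {
  stopifnot(is.matrix(labels), pixel_size_um > 0)
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids > 0L]
  res <- data.frame(id = integer(0), area_um2 = numeric(0),
                    perimeter_um = numeric(0), circularity = numeric(0),
                    solidity = numeric(0), aspect_ratio = numeric(0),
                    cx_um = numeric(0), cy_um = numeric(0))
  if (!length(ids)) return(res)
  psz <- pixel_size_um
  for (i in ids) {
    m <- labels == i
    S_px <- sum(m)
    idxm <- which(m, arr.ind = TRUE)
    cy <- mean(idxm[, 1L]); cx <- mean(idxm[, 2L])
    p <- label_contour(m * 1.0)
    if (is.null(p)) next
    L <- poly_perimeter(p) * psz
    S <- S_px * psz^2
    # solidity from a more strongly smoothed copy of the same contour:
    # it is a ratio of areas, so extra smoothing of both the region
    # polygon and its hull cancels for convex shapes but suppresses the
    # residual raster zigzag that would otherwise read as concavity
    ps <- label_contour(m * 1.0, smooth_w = 7L)
    A_poly <- poly_area(ps)
    hull <- ps[grDevices::chull(ps), , drop = FALSE]
    solidity <- A_poly / poly_area(hull)
    # fitted-ellipse aspect ratio from second central moments
    dy <- idxm[, 1L] - cy; dx <- idxm[, 2L] - cx
    cxx <- mean(dx^2) + 1 / 12; cyy <- mean(dy^2) + 1 / 12
    cxy <- mean(dx * dy)
    tr <- cxx + cyy; dt <- sqrt(max(0, (cxx - cyy)^2 + 4 * cxy^2))
    l1 <- (tr + dt) / 2; l2 <- (tr - dt) / 2
    ar <- if (l2 > 0) sqrt(l1 / l2) else Inf
    res <- rbind(res, data.frame(
      id = i, area_um2 = S, perimeter_um = L,
      circularity = 4 * pi * S / L^2,
      solidity = min(solidity, 1),
      aspect_ratio = max(1, ar),
      cx_um = cx * psz, cy_um = cy * psz))
  }
  res
}

#' Agreement between two measurement sources
#'
#' Ordinary least-squares coefficient of determination of source B against
#' source A for one metric, with records matched by `id`.
#'
#' @param records_a,records_b Data.frames as returned by
#'   [measure_cells()], or any frames with `id` and the metric column.
#' @param metric Column name to compare.
#' @return List of class `agreement_report`: `metric`, `r_squared`, `n`,
#'   `slope`, `intercept`, and the matched value vectors `a`, `b`.
#' @export
agreement <- function(records_a, records_b, metric) {
  stopifnot(metric %in% names(records_a), metric %in% names(records_b))
  idx <- match(records_a$id, records_b$id)
  keep <- !is.na(idx)
  a <- records_a[[metric]][keep]
  b <- records_b[[metric]][idx[keep]]
  if (length(a) < 3L) stop("need at least 3 matched records")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("zero variance in one source: R^2 undefined")
  }
  fit <- stats::lm(b ~ a)
  structure(list(metric = metric,
                 r_squared = summary(fit)$r.squared,
                 n = length(a),
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 a = a, b = b),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement (%s): R^2 = %.4f over n = %d (slope %.3f)\n",
              x$metric, x$r_squared, x$n, x$slope))
  invisible(x)
}
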