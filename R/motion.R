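# Chloroplast-style object tracking: per-frame centroid extraction,
# greedy nearest-neighbour linking with a distance gate, per-interval
# speeds in micrometres per second.

#' Extract object centroids from one frame
#'
#' Otsu-binarizes the frame, labels 8-connected components of at least
#' `min_area_px` pixels, and returns intensity-weighted centroids.
#'
#' @param frame Numeric matrix (bright objects on dark background).
#' @param min_area_px Minimum object area (default 5).
#' @return Data.frame with `x_px`, `y_px` (pixel-centre coordinates,
#'   origin top-left, x = column); empty with a warning for a constant
#'   frame.
#' @export
extract_centroids <- function(frame, min_area_px = 5L) {
  if (max(frame) == min(frame)) {
    warning("constant frame: no objects detected")
    return(data.frame(x_px = numeric(0), y_px = numeric(0)))
  }
  thr <- otsu_threshold(frame)
  lab <- segment_particles(frame > thr, min_area_px = min_area_px,
                           exclude_border = FALSE)
  n <- max(lab)
  if (n == 0L) return(data.frame(x_px = numeric(0), y_px = numeric(0)))
  idx <- which(lab > 0L, arr.ind = TRUE)
  w <- frame[lab > 0L]
  l <- lab[lab > 0L]
  sw <- tapply(w, l, sum)
  data.frame(
    x_px = as.vector(tapply(w * idx[, 2L], l, sum) / sw),
    y_px = as.vector(tapply(w * idx[, 1L], l, sum) / sw))
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame matching is greedy in ascending distance: candidate
#' pairs within `max_disp_px` are accepted closest-first, each detection
#' and each open track at most once. Unmatched detections start new
#' tracks; unmatched tracks terminate. Speeds are Euclidean displacements
#' converted through the pixel size and frame interval.
#'
#' @param per_frame_centroids List (one element per frame) of data.frames
#'   with `x_px`, `y_px`.
#' @param max_disp_px Linking gate in pixels (default 15).
#' @param dt_s Frame interval in seconds.
#' @param pixel_size_um Pixel size in micrometres.
#' @return List of tracks, each a list with `id`, `frames` (frame
#'   indices), `x_px`, `y_px`, `speeds_um_s` (length `points - 1`).
#' @export
link_tracks <- function(per_frame_centroids, max_disp_px = 15,
                        dt_s = 0.5, pixel_size_um = 1) {
  stopifnot(length(per_frame_centroids) >= 2,
            max_disp_px > 0, dt_s > 0, pixel_size_um > 0)
  tracks <- list()
  open <- integer(0)     # track index per active detection
  prev <- per_frame_centroids[[1L]]
  for (i in seq_len(nrow(prev))) {
    tracks[[i]] <- list(frames = 1L, x = prev$x_px[i], y = prev$y_px[i])
    open[i] <- i
  }
  for (f in 2:length(per_frame_centroids)) {
    cur <- per_frame_centroids[[f]]
    np <- nrow(prev); nc <- nrow(cur)
    assigned_prev <- logical(np); assigned_cur <- logical(nc)
    new_open <- integer(nc)
    if (np > 0L && nc > 0L) {
      dmat <- outer(prev$x_px, cur$x_px, "-")^2 +
        outer(prev$y_px, cur$y_px, "-")^2
      cand <- which(dmat <= max_disp_px^2, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(dmat[cand]), , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          ip <- cand[r, 1L]; ic <- cand[r, 2L]
          if (assigned_prev[ip] || assigned_cur[ic]) next
          assigned_prev[ip] <- TRUE; assigned_cur[ic] <- TRUE
          ti <- open[ip]
          tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f)
          tracks[[ti]]$x <- c(tracks[[ti]]$x, cur$x_px[ic])
          tracks[[ti]]$y <- c(tracks[[ti]]$y, cur$y_px[ic])
          new_open[ic] <- ti
        }
      }
    }
    for (ic in which(!assigned_cur)) {
      ti <- length(tracks) + 1L
      tracks[[ti]] <- list(frames = f, x = cur$x_px[ic], y = cur$y_px[ic])
      new_open[ic] <- ti
    }
    open <- new_open
    prev <- cur
  }
  lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    k <- length(tr$frames)
    sp <- if (k > 1L) {
      sqrt(diff(tr$x)^2 + diff(tr$y)^2) * pixel_size_um /
        (diff(tr$frames) * dt_s)
    } else numeric(0)
    list(id = i, frames = tr$frames, x_px = tr$x, y_px = tr$y,
         speeds_um_s = sp)
  })
}

#' Tracks as a tidy data.frame
#' @param tracks Result of [link_tracks()].
#' @return Data.frame with `track_id`, `frame`, `x_px`, `y_px`,
#'   `speed_um_s` (NA on each track's first point).
#' @export
tracks_to_df <- function(tracks) {
  do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = tr$id, frame = tr$frames,
               x_px = tr$x_px, y_px = tr$y_px,
               speed_um_s = c(NA, tr$speeds_um_s))
  }))
}

#' Agreement of recovered speeds with ground truth
#'
#' Tracks are matched to truth objects by nearest initial position
#' (within `match_gate_px`); per-interval speeds are then paired by frame
#' and summarized by the OLS coefficient of determination. Track stubs of
#' a single point carry no speeds and drop out naturally.
#'
#' @param truth A `timelapse_truth` from [generate_timelapse()].
#' @param tracks Result of [link_tracks()].
#' @param match_gate_px Maximum initial-position distance for matching.
#' @return An `agreement_report` (see [agreement()]) for the speeds.
#' @export
speed_agreement <- function(truth, tracks, match_gate_px = 5) {
  stopifnot(inherits(truth, "timelapse_truth"))
  start_true <- t(vapply(truth$tracks, function(m) m[1L, ], numeric(2)))
  pair_a <- c(); pair_b <- c()
  for (tr in tracks) {
    if (length(tr$frames) < 2L || tr$frames[1L] != 1L) next
    d2 <- (start_true[, 1L] - tr$x_px[1L])^2 +
      (start_true[, 2L] - tr$y_px[1L])^2
    i <- which.min(d2)
    if (d2[i] > match_gate_px^2) next
    for (k in seq_len(length(tr$frames) - 1L)) {
      if (tr$frames[k + 1L] != tr$frames[k] + 1L) next
      pair_a <- c(pair_a, truth$speeds_um_s[i, tr$frames[k]])
      pair_b <- c(pair_b, tr$speeds_um_s[k])
    }
  }
  if (!length(pair_a)) stop("no tracks matched to truth objects")
  agreement(data.frame(id = seq_along(pair_a), speed = pair_a),
            data.frame(id = seq_along(pair_a), speed = pair_b),
            "speed")
}
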