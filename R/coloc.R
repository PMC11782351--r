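# Threshold overlap score (TOS) colocalization.
#
# Two images are compared by selecting, in each, the pixels in the top
# intensity percentile and measuring how strongly the two selections
# overlap relative to chance. The logarithmically rescaled score maps
# complete anticolocalization to -1, independence to 0 and complete
# colocalization to +1. Selection is rank-exact (a fixed pixel count, not
# an intensity cut), which makes the score invariant under any monotone
# intensity transform -- virtual-stain outputs are in arbitrary units, so
# this matters.

#' Select the top intensity percentile of an image
#'
#' Selects exactly `ceiling(t/100 * N)` pixels of highest intensity. Ties
#' at the cut are broken by a fixed total order (intensity descending,
#' then row-major pixel index), so the selected count is exact and the
#' selection deterministic; a constant image triggers a warning but still
#' yields a valid deterministic selection.
#'
#' @param image Numeric matrix.
#' @param t Percentile in `(0, 100]`.
#' @return Logical matrix marking selected pixels.
#' @export
top_percentile_mask <- function(image, t = 1) {
  stopifnot(is.matrix(image), t > 0, t <= 100)
  v <- as.vector(t(image))          # row-major order for the tie rule
  n <- length(v)
  n1 <- ceiling(t / 100 * n)
  if (max(v) == min(v)) {
    warning("constant image: top-percentile selection is arbitrary (deterministic tie rule)")
  }
  ord <- order(-v, seq_len(n))
  sel <- logical(n)
  sel[ord[seq_len(n1)]] <- TRUE
  matrix(sel, nrow(image), ncol(image), byrow = TRUE)
}

#' Threshold overlap score of two images
#'
#' With `n1`, `n2` selected pixels per image, `n12` co-selected, expected
#' overlap `E = n1 n2 / N`, maximum `M = min(n1, n2)` and minimum
#' `m = max(0, n1 + n2 - N)`, the log-rescaled score is
#' `ln(n12/E) / ln(M/E)` at or above `E` and
#' `ln(max(n12, 0.5)/E) / ln(E / max(m, 0.5))` below it, clipped to
#' `[-1, 1]`. A half-pixel floor keeps the score defined when the minimum
#' overlap is zero. The linearly rescaled score is reported alongside.
#'
#' @param image_a,image_b Numeric matrices of identical shape.
#' @param t Selection percentile (default 1, the top 1 percentile).
#' @return A list of class `tos_result` with `N`, `n1`, `n2`, `n12`, `E`,
#'   `M`, `m`, `tos_linear`, `tos_log`, and `floored` (whether the
#'   half-pixel floor was engaged).
#' @export
tos <- function(image_a, image_b, t = 1) {
  stopifnot(is.matrix(image_a), is.matrix(image_b))
  if (!all(dim(image_a) == dim(image_b))) {
    stop("images must have identical dimensions")
  }
  sa <- top_percentile_mask(image_a, t)
  sb <- top_percentile_mask(image_b, t)
  tos_from_masks(sa, sb)
}

# Score from precomputed selection masks (shared by tos() and tests).
tos_from_masks <- function(sel_a, sel_b) {
  N <- length(sel_a)
  n1 <- sum(sel_a); n2 <- sum(sel_b)
  n12 <- sum(sel_a & sel_b)
  tos_from_counts(n12, n1, n2, N)
}

#' Threshold overlap score from selection counts
#'
#' @param n12 Co-selected pixel count.
#' @param n1,n2 Selected counts in each image.
#' @param N Total pixel count.
#' @return A `tos_result` list; see [tos()].
#' @export
tos_from_counts <- function(n12, n1, n2, N) {
  E <- n1 * n2 / N
  M <- min(n1, n2)
  m <- max(0, n1 + n2 - N)
  if (n12 < m || n12 > M) stop("inconsistent overlap counts")
  if (M <= E) {
    stop("degenerate selection: maximum overlap equals expected overlap ",
         "(a selection covers the whole image); TOS undefined")
  }
  floored <- (E < 0.5) || (n12 < E && (n12 < 0.5 || m < 0.5))
  if (n12 >= E) {
    tl <- (n12 - E) / (M - E)
    tg <- log(max(n12, 0.5) / max(E, 0.5)) / log(M / max(E, 0.5))
  } else {
    tl <- (n12 - E) / (E - m)
    tg <- log(max(n12, 0.5) / E) / log(E / max(m, 0.5))
  }
  structure(list(N = N, n1 = n1, n2 = n2, n12 = n12, E = E, M = M, m = m,
                 tos_linear = max(-1, min(1, tl)),
                 tos_log = max(-1, min(1, tg)),
                 floored = floored),
            class = "tos_result")
}

#' Batch TOS over image pairs
#'
#' @param pairs List of two-element lists (or a list of `list(a =, b =)`)
#'   of same-shape matrices.
#' @param t Selection percentile.
#' @return List with `mean`, `sd` (0 for a single pair), `n`, and the
#'   per-pair `tos_log` values.
#' @export
tos_batch <- function(pairs, t = 1) {
  stopifnot(length(pairs) >= 1)
  vals <- vapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    r <- tryCatch(tos(p[[1L]], p[[2L]], t = t),
                  error = function(e) stop(sprintf("pair %d: %s", i,
                                                   conditionMessage(e))))
    r$tos_log
  }, numeric(1))
  list(mean = mean(vals),
       sd = if (length(vals) > 1L) stats::sd(vals) else 0,
       n = length(vals),
       values = vals)
}

#' @export
print.tos_result <- function(x, ...) {
  cat(sprintf("TOS: n1=%d n2=%d n12=%d E=%.3g  log=%.4f linear=%.4f%s\n",
              x$n1, x$n2, x$n12, x$E, x$tos_log, x$tos_linear,
              if (x$floored) " (half-pixel floor engaged)" else ""))
  invisible(x)
}
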