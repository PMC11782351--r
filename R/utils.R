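# Shared helpers: seeded evaluation, image arithmetic, contour geometry.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the default generator, evaluates
#' `expr`, and restores the previous state on exit. All randomness in this
#' package flows through per-call seeds so that no function leaves a trace
#' in the global RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and a stage label
#'
#' A single experiment seed fans out to per-stage seeds by a fixed integer
#' derivation, so individual stages can be rerun in isolation and still
#' match a full pipeline run. Result is always in `[0, 2^31 - 2]`.
#'
#' @param seed Parent integer seed.
#' @param label Character stage label.
#' @return Integer child seed.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Gaussian blur of a matrix image (replicated boundary)
#' @keywords internal
blur_gauss <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma, boundary = "replicate"))
}

# Shoelace area of a closed polygon given as an n x 2 matrix (not repeated).
poly_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Total edge length of a closed polygon.
poly_perimeter <- function(p) {
  q <- rbind(p, p[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(q)^2)))
}

# Circular moving-average smoothing of a closed polygon (window w vertices).
# Tames the staircase of raster contours so perimeter-based metrics match
# their continuous definitions.
smooth_contour <- function(p, w = 3L) {
  n <- nrow(p)
  if (w <= 1L || n <= w) return(p)
  h <- (w - 1L) %/% 2L
  q <- p * 0
  for (k in -h:h) {
    idx <- ((seq_len(n) - 1L + k) %% n) + 1L
    q <- q + p[idx, , drop = FALSE]
  }
  q / w
}
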