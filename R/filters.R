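## Raster filtering primitives (no image-processing package is assumed).
## Padding is nearest-edge (replicate) everywhere, so constant rasters are
## fixed points of the mean filter and background correction maps them to 0.

pad_replicate <- function(x, top, bottom = top, left = top, right = top) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(rep(1L, top), seq_len(nr), rep(nr, bottom))
  ci <- c(rep(1L, left), seq_len(nc), rep(nc, right))
  x[ri, ci, drop = FALSE]
}

#' Uniform (box) mean filter
#'
#' Sliding-window mean with a square window of side `size` pixels and
#' nearest-edge padding, computed with an integral image. For even sizes the
#' window extends one pixel further below/right of the center.
#'
#' @param x numeric matrix.
#' @param size window side in pixels (>= 1).
#' @return matrix of the same shape holding local means.
#' @export
uniform_filter <- function(x, size) {
  stopifnot(is.matrix(x), size >= 1)
  size <- as.integer(size)
  if (size == 1L) return(x)
  lo <- (size - 1L) %/% 2L
  hi <- size - 1L - lo
  nr <- nrow(x); nc <- ncol(x)
  p <- pad_replicate(x, top = lo, bottom = hi, left = lo, right = hi)
  ## integral image with a zero border
  s <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  s[-1L, -1L] <- p
  s <- apply(s, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  i0 <- seq_len(nr); j0 <- seq_len(nc)
  w <- s[i0 + size, j0 + size, drop = FALSE] - s[i0, j0 + size, drop = FALSE] -
    s[i0 + size, j0, drop = FALSE] + s[i0, j0, drop = FALSE]
  w / (size * size)
}

#' Background correction by large-kernel mean subtraction
#'
#' Subtracts the uniformly filtered image (window `filter_size_px`) from the
#' original, removing slowly varying background. Output values can be
#' negative; downstream thresholds are applied to the corrected values.
#'
#' @param channel numeric matrix (one image channel).
#' @param filter_size_px side of the uniform filter window in pixels.
#' @return corrected matrix, same shape.
#' @export
background_correct <- function(channel, filter_size_px) {
  if (filter_size_px < 1) stop("filter size must be >= 1")
  channel - uniform_filter(channel, filter_size_px)
}

#' Gaussian blur
#'
#' Separable Gaussian smoothing with standard deviation `sigma` pixels and
#' nearest-edge padding. The kernel is truncated at 3 sigma.
#'
#' @param x numeric matrix.
#' @param sigma standard deviation in pixels (> 0).
#' @return blurred matrix, same shape.
#' @export
gaussian_blur <- function(x, sigma) {
  stopifnot(is.matrix(x), sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  nr <- nrow(x); nc <- ncol(x)
  p <- pad_replicate(x, top = r)
  tmp <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(k)) {
    tmp <- tmp + k[i] * p[seq_len(nr) + i - 1L, , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * tmp[, seq_len(nc) + i - 1L, drop = FALSE]
  }
  out
}
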