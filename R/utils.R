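#' @keywords internal
"_PACKAGE"

# Coordinate convention used throughout: (row, col), 1-based, origin at the
# top-left pixel of the patch.  Images are plain numeric matrices.

#' Derive a child RNG seed from a parent seed and a stream index
#'
#' Keeps every derived seed strictly below 2^31 so it is a valid R integer.
#'
#' @param seed parent integer seed
#' @param index non-negative stream index
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483629L)
}

#' Evaluate an expression under a fixed RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

#' 1-D Gaussian kernel
#' @keywords internal
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian blur of a matrix (replicated edges)
#' @keywords internal
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  k <- gaussian_kernel(sigma)
  half <- (length(k) - 1L) / 2L
  conv1 <- function(m, kern, half) {
    # convolve along rows (dimension 1) with edge replication
    n <- nrow(m)
    idx <- pmin(pmax(seq_len(n + 2L * half) - half, 1L), n)
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(kern)) {
      out <- out + kern[i] * padded[i:(i + n - 1L), , drop = FALSE]
    }
    out
  }
  mat <- conv1(mat, k, half)
  t(conv1(t(mat), k, half))
}

#' Bilinear resize of a matrix
#'
#' Pixel centres are aligned at the image corners (the first and last
#' samples of input and output coincide), which makes the 2x2 -> 4x4 case
#' directly checkable against the interpolation formula by hand.
#'
#' @param mat numeric matrix
#' @param out_rows,out_cols target size
#' @return resized numeric matrix
#' @export
bilinear_resize <- function(mat, out_rows, out_cols) {
  nr <- nrow(mat); nc <- ncol(mat)
  stopifnot(nr >= 1, nc >= 1, out_rows >= 1, out_cols >= 1)
  map_axis <- function(n_in, n_out) {
    if (n_out == 1L || n_in == 1L) {
      pos <- rep(1, n_out)
    } else {
      pos <- 1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
    }
    lo <- pmin(floor(pos), n_in - ifelse(n_in > 1, 1, 0))
    lo <- pmax(lo, 1)
    frac <- pos - lo
    list(lo = as.integer(lo), hi = as.integer(pmin(lo + 1, n_in)), frac = frac)
  }
  ri <- map_axis(nr, out_rows)
  ci <- map_axis(nc, out_cols)
  a <- mat[ri$lo, ci$lo, drop = FALSE]
  b <- mat[ri$hi, ci$lo, drop = FALSE]
  cc <- mat[ri$lo, ci$hi, drop = FALSE]
  d <- mat[ri$hi, ci$hi, drop = FALSE]
  fr <- matrix(ri$frac, out_rows, out_cols)
  fc <- matrix(ci$frac, out_rows, out_cols, byrow = TRUE)
  a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) + cc * (1 - fr) * fc + d * fr * fc
}

#' Shannon entropy (base 2) of a probability vector, ignoring zeros
#' @keywords internal
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

#' Dice overlap between two binary masks
#' @param a,b logical matrices of equal size
#' @return Dice coefficient in [0, 1]
#' @export
dice_overlap <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
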