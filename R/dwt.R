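# Periodised orthonormal 2-D discrete wavelet transform (Daubechies-4,
# 8-tap filters).  With periodic boundary handling the transform is
# exactly orthonormal, so total coefficient energy equals image energy.

DB4_LO <- c(-0.010597401785069032, 0.032883011666885197,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.63088076792985892,
            0.71484657055291567, 0.23037781330889651)
DB4_HI <- rev(DB4_LO) * c(1, -1, 1, -1, 1, -1, 1, -1)

# One periodised analysis step along columns of x (length must be even).
dwt_step_1d <- function(x) {
  n <- nrow(x)
  taps <- length(DB4_LO)
  idx <- outer(seq(1, n, by = 2), seq_len(taps) - 1L, `+`)
  idx <- (idx - 1L) %% n + 1L
  lo <- hi <- matrix(0, n / 2, ncol(x))
  for (t in seq_len(taps)) {
    xt <- x[idx[, t], , drop = FALSE]
    lo <- lo + DB4_LO[t] * xt
    hi <- hi + DB4_HI[t] * xt
  }
  list(lo = lo, hi = hi)
}

#' Multi-level 2-D discrete wavelet decomposition
#'
#' Periodised Daubechies-4 analysis.  The input is cropped to the largest
#' size divisible by `2^levels` so every level acts on even-length
#' signals and orthonormality (hence energy conservation) is exact on the
#' cropped image.
#'
#' @param image numeric matrix with both sides `>= 2^levels`
#' @param levels number of decomposition levels
#' @return list of subband matrices named `LH1`, `HL1`, `HH1`, ...,
#'   `LL<levels>`
#' @export
dwt2 <- function(image, levels = 2L) {
  if (min(dim(image)) < 2^levels)
    stop("image too small for the requested number of wavelet levels")
  crop <- function(n) (n %/% 2^levels) * 2^levels
  image <- image[seq_len(crop(nrow(image))), seq_len(crop(ncol(image))),
                 drop = FALSE]
  out <- list()
  ll <- image
  for (lev in seq_len(levels)) {
    rows <- dwt_step_1d(ll)
    colL <- dwt_step_1d(t(rows$lo))
    colH <- dwt_step_1d(t(rows$hi))
    out[[paste0("LH", lev)]] <- t(colL$hi)  # low rows / high cols
    out[[paste0("HL", lev)]] <- t(colH$lo)
    out[[paste0("HH", lev)]] <- t(colH$hi)
    ll <- t(colL$lo)
  }
  out[[paste0("LL", levels)]] <- ll
  out
}
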