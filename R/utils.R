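# Shared numerical helpers: separable Gaussian smoothing with edge
# renormalisation, log-sum-exp, and map geometry utilities.

gaussian_kernel_1d <- function(sd_bins, radius = ceiling(4 * sd_bins)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sd_bins^2))
  k / sum(k)
}

conv_1d_cols <- function(M, k) {
  # convolve each column with kernel k (zero padding)
  r <- (length(k) - 1L) / 2L
  n <- nrow(M)
  P <- rbind(matrix(0, r, ncol(M)), M, matrix(0, r, ncol(M)))
  out <- matrix(0, n, ncol(M))
  for (i in seq_along(k)) {
    out <- out + k[i] * P[i:(i + n - 1L), , drop = FALSE]
  }
  out
}

#' Smooth a matrix with a Gaussian kernel
#'
#' Separable 2D Gaussian smoothing. At map edges (and around masked `NA`
#' bins) the kernel is renormalised over the valid bins, so interior mass is
#' preserved and edge bins are not dragged toward zero.
#'
#' @param M Numeric matrix; `NA` entries are treated as masked.
#' @param sd_bins Kernel s.d. in bins.
#' @param renormalize Renormalise over valid bins (default `TRUE`); when
#'   `FALSE`, plain zero-padded convolution (mass-preserving in the
#'   interior).
#' @return Smoothed matrix, `NA` where `M` was `NA`.
#' @export
gaussian_smooth <- function(M, sd_bins, renormalize = TRUE) {
  if (sd_bins <= 0) {
    return(M)
  }
  k <- gaussian_kernel_1d(sd_bins)
  valid <- !is.na(M)
  M0 <- ifelse(valid, M, 0)
  num <- t(conv_1d_cols(t(conv_1d_cols(M0, k)), k))
  if (!renormalize) {
    num[!valid] <- NA_real_
    return(num)
  }
  den <- t(conv_1d_cols(t(conv_1d_cols(valid * 1, k)), k))
  out <- num / pmax(den, .Machine$double.eps)
  out[!valid] <- NA_real_
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

# Bin index of coordinates on a square map with bin size `bin` and origin 0;
# clamped into range.
coord_to_bin <- function(v, bin, n) {
  pmin(pmax(ceiling(v / bin), 1L), n)
}

bin_centers <- function(n, bin) (seq_len(n) - 0.5) * bin

# Translate a map so that the bin containing `at` lands on the origin of a
# (2n-1) x (2n-1) canvas (origin at its centre bin); unfilled bins are NA.
# With clamp = FALSE, reference points outside the map shift content off the
# canvas instead of snapping to the nearest edge bin.
translate_to_origin <- function(M, at, bin, clamp = TRUE) {
  n <- nrow(M)
  if (clamp) {
    ib <- coord_to_bin(at[1], bin, n)
    jb <- coord_to_bin(at[2], bin, n)
  } else {
    ib <- ceiling(at[1] / bin)
    jb <- ceiling(at[2] / bin)
  }
  big <- matrix(NA_real_, 2L * n - 1L, 2L * n - 1L)
  ctr <- n # canvas centre index = origin
  rows <- seq_len(n) - ib + ctr
  cols <- seq_len(n) - jb + ctr
  ok_r <- rows >= 1 & rows <= 2L * n - 1L
  ok_c <- cols >= 1 & cols <= 2L * n - 1L
  big[rows[ok_r], cols[ok_c]] <- M[ok_r, ok_c]
  big
}
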