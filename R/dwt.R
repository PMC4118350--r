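# Minimal periodized discrete wavelet transform with the db4 (8-tap
# Daubechies, 4 vanishing moments) filter pair. Only what the ECG denoiser
# needs: forward/inverse pyramid and universal soft thresholding.

.db4_h <- c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)
.db4_g <- rev(.db4_h) * (-1)^(seq_along(.db4_h) - 1)

.dwt_step <- function(x, h = .db4_h, g = .db4_g) {
  n <- length(x)
  stopifnot(n %% 2L == 0L)
  k <- seq(0L, n - 2L, by = 2L)
  idx <- (outer(k, seq_along(h) - 1L, "+") %% n) + 1L
  xm <- matrix(x[idx], nrow = length(k))
  list(a = as.vector(xm %*% h), d = as.vector(xm %*% g))
}

.idwt_step <- function(a, d, h = .db4_h, g = .db4_g) {
  n <- 2L * length(a)
  x <- numeric(n)
  k2 <- 2L * (seq_along(a) - 1L)
  for (m in seq_along(h)) {
    j <- ((k2 + m - 1L) %% n) + 1L   # distinct for fixed m
    x[j] <- x[j] + h[m] * a + g[m] * d
  }
  x
}

# Forward pyramid; x is padded internally by periodic-style reflection to a
# multiple of 2^levels, the pad is recorded for the inverse.
.dwt <- function(x, levels) {
  n0 <- length(x)
  block <- 2^levels
  pad <- (block - n0 %% block) %% block
  if (pad > 0) x <- c(x, rev(x)[seq_len(pad)])
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- .dwt_step(a)
    details[[l]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, n = n0, pad = pad, levels = levels)
}

.idwt <- function(w) {
  a <- w$approx
  for (l in rev(seq_len(w$levels))) a <- .idwt_step(a, w$details[[l]])
  a[seq_len(w$n)]
}

#' Wavelet soft-threshold denoising (db4)
#'
#' Decomposes the signal with a periodized db4 transform, soft-thresholds all
#' detail levels at the universal threshold `sigma * sqrt(2 log n)` (noise
#' scale `sigma` estimated from the median absolute deviation of the finest
#' detail band), and reconstructs.
#'
#' @param x Numeric signal.
#' @param levels Number of detail levels to threshold (>= 1).
#' @return Denoised signal, same length as `x`.
#' @export
denoise_dwt <- function(x, levels = 1L) {
  stopifnot(levels >= 1L, length(x) >= 2^levels)
  w <- .dwt(x, levels)
  sigma <- stats::median(abs(w$details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  w$details <- lapply(w$details, soft)
  .idwt(w)
}
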