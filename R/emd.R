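#' Empirical mode decomposition
#'
#' Decomposes a series into a small set of oscillatory intrinsic mode
#' functions (IMFs) plus a monotone residue by standard sifting: cubic
#' spline upper/lower envelopes through the local maxima/minima (with
#' mirror extension of the boundary extrema), subtract the envelope
#' mean, and repeat until the Cauchy-type stopping criterion
#' `sum((h_prev - h)^2) / sum(h_prev^2) < sd_stop` or `max_sift` sifts.
#' Decomposition stops when the residue has fewer than two maxima or
#' two minima (monotone trend) or `max_imf` IMFs have been extracted.
#' By construction `rowSums(imfs) + residue` reconstructs the input to
#' floating-point accuracy.
#'
#' @param series Numeric vector (length >= 8).
#' @param max_imf Maximum number of IMFs (default 8).
#' @param max_sift Maximum sifting iterations per IMF (default 10).
#' @param sd_stop Cauchy stopping threshold (default 0.2).
#' @return A list of class `har_imfset` with elements `imfs` (matrix,
#'   one column per IMF; 0 columns when none) and `residue`.
#' @export
#' @examples
#' t <- seq(0, 4, by = 0.01)
#' d <- emd(sin(2 * pi * 10 * t) + sin(2 * pi * t))
#' ncol(d$imfs)
emd <- function(series, max_imf = 8, max_sift = 10, sd_stop = 0.2) {
  v <- as.numeric(series)
  n <- length(v)
  if (n < 8) stop("emd needs a series of length >= 8")
  imfs <- NULL
  residue <- v
  for (k in seq_len(max_imf)) {
    ext <- find_extrema(residue)
    if (length(ext$maxima) < 2 || length(ext$minima) < 2) break
    h <- residue
    for (s in seq_len(max_sift)) {
      env <- envelope_mean(h)
      if (is.null(env)) break
      h_new <- h - env
      crit <- sum((h - h_new)^2) / sum(h^2)
      h <- h_new
      if (!is.finite(crit) || crit < sd_stop) break
    }
    imfs <- cbind(imfs, h)
    residue <- residue - h
  }
  if (is.null(imfs)) imfs <- matrix(numeric(0), nrow = n, ncol = 0)
  colnames(imfs) <- if (ncol(imfs) > 0) paste0("imf", seq_len(ncol(imfs)))
  structure(list(imfs = imfs, residue = residue), class = "har_imfset")
}

#' @export
print.har_imfset <- function(x, ...) {
  cat(sprintf("<har_imfset> %d IMF(s) of length %d\n",
              ncol(x$imfs), length(x$residue)))
  invisible(x)
}

## Interior local extrema via sign changes of the first difference.
## Plateaus count their first sample.
find_extrema <- function(v) {
  n <- length(v)
  d <- diff(v)
  d_sign <- sign(d)
  nz <- which(d_sign != 0)
  maxima <- integer(0); minima <- integer(0)
  if (length(nz) >= 2) {
    for (j in seq_len(length(nz) - 1)) {
      i1 <- nz[j]; i2 <- nz[j + 1]
      if (d_sign[i1] > 0 && d_sign[i2] < 0) maxima <- c(maxima, i1 + 1L)
      if (d_sign[i1] < 0 && d_sign[i2] > 0) minima <- c(minima, i1 + 1L)
    }
  }
  list(maxima = maxima, minima = minima)
}

## Mean of the cubic-spline envelopes with mirror boundary extension;
## NULL when there are not enough extrema to build both envelopes.
envelope_mean <- function(v) {
  n <- length(v)
  ext <- find_extrema(v)
  mx <- ext$maxima; mn <- ext$minima
  if (length(mx) < 2 || length(mn) < 2) return(NULL)
  spline_env <- function(idx) {
    ## mirror up to two boundary extrema across each end
    k <- min(2L, length(idx))
    left <- 2L - rev(idx[seq_len(k)])        # reflect about sample 1
    right <- 2L * n - rev(idx[(length(idx) - k + 1L):length(idx)])
    xs <- c(left, idx, right)
    ys <- c(v[rev(idx[seq_len(k)])], v[idx],
            v[rev(idx[(length(idx) - k + 1L):length(idx)])])
    ord <- order(xs)
    xs <- xs[ord]; ys <- ys[ord]
    keep <- !duplicated(xs)
    stats::splinefun(xs[keep], ys[keep], method = "fmm")(seq_len(n))
  }
  (spline_env(mx) + spline_env(mn)) / 2
}

#' Analytic signal via the Hilbert transform
#'
#' FFT construction of the analytic signal `x + i * H(x)`.
#'
#' @param series Numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(series) {
  v <- as.numeric(series)
  n <- length(v)
  X <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert descriptors of the leading intrinsic mode functions
#'
#' For each of the first `n_imf` IMFs (zero-filled when fewer exist):
#' the energy fraction (IMF energy over total signal energy), the mean
#' instantaneous amplitude, and the mean instantaneous frequency in Hz
#' estimated from consecutive analytic-signal phase differences over
#' interior samples only. Returns `3 * n_imf` values in a fixed order
#' (imf1 energy, amp, freq; imf2 ...).
#'
#' @param series Numeric vector.
#' @param rate Sampling rate in Hz.
#' @param n_imf Number of IMFs summarised (default 3).
#' @return Named numeric vector of length `3 * n_imf`.
#' @export
hht_features <- function(series, rate, n_imf = 3) {
  v <- as.numeric(series)
  out <- numeric(3 * n_imf)
  names(out) <- as.vector(vapply(seq_len(n_imf), function(k)
    paste0("hht_imf", k, "_", c("energy", "amp", "freq")), character(3)))
  total_energy <- sum(v^2)
  if (length(v) < 8 || total_energy == 0) return(out)
  dec <- emd(v)
  k_avail <- min(n_imf, ncol(dec$imfs))
  for (k in seq_len(k_avail)) {
    imf <- dec$imfs[, k]
    z <- analytic_signal(imf)
    amp <- Mod(z)
    dphi <- Arg(z[-1] * Conj(z[-length(z)]))  # phase step in (-pi, pi]
    interior <- if (length(dphi) > 4) dphi[2:(length(dphi) - 1)] else dphi
    out[(k - 1) * 3 + 1] <- sum(imf^2) / total_energy
    out[(k - 1) * 3 + 2] <- mean(amp)
    out[(k - 1) * 3 + 3] <- mean(interior) * rate / (2 * pi)
  }
  out
}
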