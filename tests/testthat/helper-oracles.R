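# Independent brute-force oracles: naive loops and direct formula
# evaluation, no shared code with the package implementations beyond
# base R primitives.

o_mean <- function(v) { s <- 0; for (x in v) s <- s + x; s / length(v) }

o_median <- function(v) {
  s <- sort(v); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

o_std <- function(v) {
  m <- o_mean(v); s <- 0
  for (x in v) s <- s + (x - m)^2
  sqrt(s / (length(v) - 1))
}

o_min <- function(v) { m <- v[1]; for (x in v) if (x < m) m <- x; m }
o_max <- function(v) { m <- v[1]; for (x in v) if (x > m) m <- x; m }

o_energy <- function(v) { s <- 0; for (x in v) s <- s + x * x; s / length(v) }

# linear-interpolation ("type 7") quantile computed from its definition
o_quantile7 <- function(v, p) {
  s <- sort(v); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

o_peaks <- function(v) {
  q1 <- o_quantile7(v, 0.25); q3 <- o_quantile7(v, 0.75)
  below <- c(); above <- c()
  for (x in v) {
    if (x < q1) below <- c(below, x)
    if (x > q3) above <- c(above, x)
  }
  c(neg = if (length(below)) o_min(below) else o_min(v),
    pos = if (length(above)) o_max(above) else o_max(v))
}

o_mode <- function(v) {
  lo <- o_min(v); hi <- o_max(v)
  if (hi == lo) return(lo)
  edges <- seq(lo, hi, length.out = 11)
  counts <- integer(10)
  for (x in v) {
    for (k in 1:10) {
      if (x >= edges[k] && (k == 10 || x < edges[k + 1])) {
        counts[k] <- counts[k] + 1
        break
      }
    }
  }
  best <- 1
  for (k in 2:10) if (counts[k] > counts[best]) best <- k
  (edges[best] + edges[best + 1]) / 2
}

o_zcr <- function(v) {
  last <- 0; cnt <- 0
  for (x in v) {
    sg <- if (x > 0) 1 else if (x < 0) -1 else 0
    if (sg != 0) {
      if (last != 0 && sg != last) cnt <- cnt + 1
      last <- sg
    }
  }
  cnt / (length(v) - 1)
}

o_corr <- function(a, b) {
  ma <- o_mean(a); mb <- o_mean(b)
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(a)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  if (da == 0 || db == 0) 0 else num / sqrt(da * db)
}

o_mag_mean <- function(m) {
  s <- 0
  for (i in seq_len(nrow(m)))
    s <- s + sqrt(m[i, 1]^2 + m[i, 2]^2 + m[i, 3]^2)
  unname(s / nrow(m))
}

o_sma <- function(m, absolute = FALSE) {
  s <- 0
  for (i in seq_len(nrow(m)))
    for (j in 1:3) s <- s + if (absolute) abs(m[i, j]) else m[i, j]
  unname(s / nrow(m))
}

# direct O(n^2) discrete Fourier transform
o_dft <- function(v) {
  n <- length(v)
  out <- complex(n)
  for (k in 0:(n - 1)) {
    acc <- 0 + 0i
    for (j in 0:(n - 1))
      acc <- acc + v[j + 1] * exp(-2i * pi * k * j / n)
    out[k + 1] <- acc
  }
  out
}

o_fundamental <- function(v, rate) {
  n <- length(v)
  w <- numeric(n)
  for (i in 1:n) w[i] <- 0.5 - 0.5 * cos(2 * pi * (i - 1) / (n - 1))
  X <- o_dft((v - o_mean(v)) * w)
  half <- floor(n / 2) + 1
  best <- 2
  for (k in 3:half) if (Mod(X[k])^2 > Mod(X[best])^2) best <- k
  if (Mod(X[best])^2 <= 0) return(0)
  (best - 1) * rate / n
}

o_phase <- function(v, rate) {
  n <- length(v)
  w <- numeric(n)
  for (i in 1:n) w[i] <- 0.5 - 0.5 * cos(2 * pi * (i - 1) / (n - 1))
  Xw <- o_dft((v - o_mean(v)) * w)
  half <- floor(n / 2) + 1
  best <- 2
  for (k in 3:half) if (Mod(Xw[k])^2 > Mod(Xw[best])^2) best <- k
  if (Mod(Xw[best])^2 <= 0) return(0)
  X <- o_dft(v)
  atan2(Im(X[best]), Re(X[best]))
}

o_spectral_entropy <- function(v, rate, band = NULL) {
  n <- length(v)
  if (is.null(band)) band <- c(0, rate / 2)
  X <- o_dft(v)
  half <- floor(n / 2) + 1
  p <- c(); nb <- 0
  for (k in 1:half) {
    f <- (k - 1) * rate / n
    inband <- if (band[1] == 0) f > 0 && f <= band[2]
              else f >= band[1] && f <= band[2]
    if (inband) { nb <- nb + 1; p <- c(p, Mod(X[k])^2) }
  }
  tot <- 0; for (x in p) tot <- tot + x
  if (tot == 0) return(0)
  h <- 0
  for (x in p) { q <- x / tot; if (q > 0) h <- h - q * log(q) }
  h / log(nb)
}

## ---- independent EMD / Hilbert oracle ------------------------------

# interior extrema by explicit scan over runs of equal values
o_extrema <- function(v) {
  n <- length(v)
  maxima <- c(); minima <- c()
  prev_dir <- 0; prev_pos <- NA
  for (i in 1:(n - 1)) {
    d <- v[i + 1] - v[i]
    dir <- if (d > 0) 1 else if (d < 0) -1 else 0
    if (dir == 0) next
    if (prev_dir == 1 && dir == -1) maxima <- c(maxima, prev_pos + 1)
    if (prev_dir == -1 && dir == 1) minima <- c(minima, prev_pos + 1)
    prev_dir <- dir; prev_pos <- i
  }
  list(maxima = maxima, minima = minima)
}

o_envelope <- function(v, idx) {
  n <- length(v)
  k <- min(2, length(idx))
  first <- idx[1:k]; last <- idx[(length(idx) - k + 1):length(idx)]
  xs <- c(); ys <- c()
  for (j in k:1) { xs <- c(xs, 2 - first[j]); ys <- c(ys, v[first[j]]) }
  xs <- c(xs, idx); ys <- c(ys, v[idx])
  for (j in k:1) { xs <- c(xs, 2 * n - last[j]); ys <- c(ys, v[last[j]]) }
  ord <- order(xs)
  xs <- xs[ord]; ys <- ys[ord]
  keep <- !duplicated(xs)
  stats::spline(xs[keep], ys[keep], xout = 1:n, method = "fmm")$y
}

o_emd <- function(v, max_imf = 8, max_sift = 10, sd_stop = 0.2) {
  n <- length(v)
  imfs <- list()
  residue <- v
  for (k in 1:max_imf) {
    ext <- o_extrema(residue)
    if (length(ext$maxima) < 2 || length(ext$minima) < 2) break
    h <- residue
    for (s in 1:max_sift) {
      e <- o_extrema(h)
      if (length(e$maxima) < 2 || length(e$minima) < 2) break
      env <- (o_envelope(h, e$maxima) + o_envelope(h, e$minima)) / 2
      h_new <- h - env
      num <- 0; den <- 0
      for (i in 1:n) { num <- num + (h[i] - h_new[i])^2; den <- den + h[i]^2 }
      h <- h_new
      if (!is.finite(num / den) || num / den < sd_stop) break
    }
    imfs[[k]] <- h
    residue <- residue - h
  }
  list(imfs = imfs, residue = residue)
}

o_analytic <- function(v) {
  n <- length(v)
  X <- o_dft(v)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  Y <- X * h
  out <- complex(n)
  for (j in 0:(n - 1)) {
    acc <- 0 + 0i
    for (k in 0:(n - 1)) acc <- acc + Y[k + 1] * exp(2i * pi * k * j / n)
    out[j + 1] <- acc / n
  }
  out
}

o_hht <- function(v, rate, n_imf = 3) {
  out <- numeric(3 * n_imf)
  tot <- 0; for (x in v) tot <- tot + x * x
  if (length(v) < 8 || tot == 0) return(out)
  dec <- o_emd(v)
  for (k in seq_len(min(n_imf, length(dec$imfs)))) {
    imf <- dec$imfs[[k]]
    z <- o_analytic(imf)
    e <- 0; for (x in imf) e <- e + x * x
    amp <- 0; for (zz in z) amp <- amp + Mod(zz)
    dphi <- numeric(length(z) - 1)
    for (i in 1:(length(z) - 1)) dphi[i] <- Arg(z[i + 1] * Conj(z[i]))
    interior <- if (length(dphi) > 4) dphi[2:(length(dphi) - 1)] else dphi
    mf <- 0; for (x in interior) mf <- mf + x
    mf <- mf / length(interior) * rate / (2 * pi)
    out[(k - 1) * 3 + 1] <- e / tot
    out[(k - 1) * 3 + 2] <- amp / length(z)
    out[(k - 1) * 3 + 3] <- mf
  }
  out
}

# full oracle feature vector in registry order (single frame)
o_extract_all <- function(frame, band = NULL, sma_absolute = FALSE) {
  m <- frame$data; rate <- frame$rate
  per_axis <- function(v) {
    pk <- o_peaks(v)
    c(o_mean(v), o_median(v), o_mode(v), o_std(v), o_std(v)^2,
      o_min(v), o_max(v), pk["neg"], pk["pos"],
      o_zcr(v - o_mean(v)), o_energy(v),
      o_fundamental(v, rate), o_phase(v, rate),
      o_spectral_entropy(v, rate, band),
      o_hht(v, rate))
  }
  unname(c(per_axis(m[, 1]), per_axis(m[, 2]), per_axis(m[, 3]),
           o_mag_mean(m), o_sma(m, sma_absolute),
           o_corr(m[, 1], m[, 2]), o_corr(m[, 2], m[, 3]),
           o_corr(m[, 3], m[, 1])))
}
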