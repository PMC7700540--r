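#' Mean signal vector magnitude
#'
#' Mean over samples of the instantaneous vector magnitude
#' `sqrt(x_i^2 + y_i^2 + z_i^2)`, the distance of each triaxial sample
#' from the origin.
#'
#' @param frame A [har_frame()].
#' @return Scalar.
#' @export
signal_magnitude_mean <- function(frame) {
  stopifnot(inherits(frame, "har_frame"))
  mean(sqrt(rowSums(frame$data^2)))
}

#' Zero crossing rate
#'
#' Fraction of consecutive nonzero-signed samples whose signs differ,
#' normalised by `W - 1` so the value lies in `[0, 1]`. Exact zeros are
#' ignored in the sign sequence. The feature bank applies this to the
#' mean-removed axis signal, since after min-max normalisation a raw
#' signal never changes sign.
#'
#' @param series Numeric vector of length >= 2.
#' @return Scalar in `[0, 1]`.
#' @export
zero_crossing_rate <- function(series) {
  stopifnot(length(series) >= 2)
  s <- sign(series)
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  sum(diff(s) != 0) / (length(series) - 1)
}

#' Negative and positive peak features
#'
#' The negative peak is the minimum over samples strictly below the
#' first quartile; the positive peak is the maximum over samples
#' strictly above the third quartile. Quartiles use linear interpolation
#' (R's default type 7). When a subset is empty (e.g. a constant
#' series) the global minimum/maximum is used.
#'
#' @param series Numeric vector of length >= 4.
#' @return Named vector `c(neg = ..., pos = ...)`.
#' @export
peak_features <- function(series) {
  stopifnot(length(series) >= 4)
  q <- stats::quantile(series, c(0.25, 0.75), names = FALSE, type = 7)
  below <- series[series < q[1]]
  above <- series[series > q[2]]
  c(neg = if (length(below)) min(below) else min(series),
    pos = if (length(above)) max(above) else max(series))
}

#' Elementary per-axis statistics
#'
#' Sample statistics of one axis series: `std_feature` is the sample
#' standard deviation (n - 1 denominator, so a length-1 series is an
#' error), `variance_feature` its square, and the rest are what their
#' names say.
#'
#' @param series Numeric vector.
#' @return Scalar.
#' @export
std_feature <- function(series) {
  if (length(series) < 2)
    stop("standard deviation needs at least 2 samples (n - 1 denominator)")
  stats::sd(series)
}

#' @rdname std_feature
#' @export
variance_feature <- function(series) std_feature(series)^2

#' @rdname std_feature
#' @export
mean_feature <- function(series) mean(series)

#' @rdname std_feature
#' @export
median_feature <- function(series) stats::median(series)

#' @rdname std_feature
#' @export
min_feature <- function(series) min(series)

#' @rdname std_feature
#' @export
max_feature <- function(series) max(series)

#' Histogram mode
#'
#' Centre of the most populated bin of a 10-bin histogram over
#' `[min, max]`; the leftmost such bin wins ties, and a constant series
#' returns the constant.
#'
#' @param series Numeric vector.
#' @return Scalar.
#' @export
mode_feature <- function(series) {
  lo <- min(series); hi <- max(series)
  if (hi == lo) return(lo)
  edges <- seq(lo, hi, length.out = 11L)
  bins <- pmin(pmax(findInterval(series, edges, rightmost.closed = TRUE), 1L), 10L)
  counts <- tabulate(bins, nbins = 10L)
  b <- which.max(counts)  # which.max takes the leftmost maximum
  (edges[b] + edges[b + 1]) / 2
}

#' Signal magnitude area
#'
#' Signed sum of the three axis series, normalised by the window length
#' so the feature is invariant to window size:
#' `(sum(x) + sum(y) + sum(z)) / W`. With `absolute = TRUE` the
#' conventional absolute-value form is used instead.
#'
#' @param frame A [har_frame()].
#' @param absolute Sum `|.|` instead of signed values (default FALSE).
#' @return Scalar.
#' @export
signal_magnitude_area <- function(frame, absolute = FALSE) {
  stopifnot(inherits(frame, "har_frame"))
  d <- if (absolute) abs(frame$data) else frame$data
  sum(d) / nrow(frame$data)
}

#' Signal energy
#'
#' Mean of squared samples.
#'
#' @param series Numeric vector.
#' @return Scalar.
#' @export
signal_energy <- function(series) mean(series^2)

#' Pairwise axis correlations
#'
#' Pearson correlation for each axis pair; 0 (with a warning) when
#' either axis is constant.
#'
#' @param frame A [har_frame()].
#' @return Named vector `c(xy = ..., yz = ..., zx = ...)`.
#' @export
correlation_features <- function(frame) {
  stopifnot(inherits(frame, "har_frame"))
  d <- frame$data
  safe_cor <- function(a, b, nm) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("constant axis: correlation ", nm, " set to 0")
      return(0)
    }
    stats::cor(a, b)
  }
  c(xy = safe_cor(d[, 1], d[, 2], "xy"),
    yz = safe_cor(d[, 2], d[, 3], "yz"),
    zx = safe_cor(d[, 3], d[, 1], "zx"))
}

## Hann-windowed one-sided periodogram of the mean-removed series.
## Returns bin frequencies and powers (DC bin included, power ~0).
periodogram_hann <- function(series, rate) {
  n <- length(series)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  v <- (series - mean(series)) * w
  X <- stats::fft(v)
  k <- seq_len(floor(n / 2) + 1)
  list(freq = (k - 1) * rate / n, power = Mod(X[k])^2, bin = k)
}

#' Fundamental frequency and phase angle
#'
#' `fundamental_frequency` is the argmax of a Hann-windowed
#' periodogram of the mean-removed series, excluding the DC bin,
#' mapped to Hz; a constant (or zero-power) series returns 0 by
#' convention. `phase_angle` is the argument of the raw (unwindowed)
#' FFT coefficient at that bin, in `(-pi, pi]`; 0 for a constant
#' series.
#'
#' @param series Numeric vector of length >= 4.
#' @param rate Sampling rate in Hz.
#' @return Scalar (Hz / radians).
#' @export
fundamental_frequency <- function(series, rate) {
  stopifnot(length(series) >= 4)
  pg <- periodogram_hann(series, rate)
  p <- pg$power[-1]
  if (max(p) <= 0) return(0)
  pg$freq[-1][which.max(p)]
}

#' @rdname fundamental_frequency
#' @export
phase_angle <- function(series, rate) {
  stopifnot(length(series) >= 4)
  pg <- periodogram_hann(series, rate)
  p <- pg$power[-1]
  if (max(p) <= 0) return(0)
  bin <- pg$bin[-1][which.max(p)]
  Arg(stats::fft(as.numeric(series))[bin])
}

#' Normalised spectral entropy
#'
#' Shannon entropy of the power spectral density normalised over a
#' frequency band, divided by `log` of the number of band bins, so the
#' value lies in `[0, 1]`: 0 for a single-bin spectrum, 1 for a flat
#' one. The PSD is the one-sided unwindowed periodogram; the band
#' defaults to `(0, Nyquist]` (the DC bin is excluded whenever
#' `f1 = 0`). Zero-power bins contribute 0; an all-zero band returns 0
#' with a warning.
#'
#' @param series Numeric vector of length >= 4.
#' @param rate Sampling rate in Hz.
#' @param band `c(f1, f2)` in Hz with `0 <= f1 < f2 <= rate / 2`, or
#'   `NULL` for the full band.
#' @return Scalar in `[0, 1]`.
#' @export
spectral_entropy <- function(series, rate, band = NULL) {
  stopifnot(length(series) >= 4)
  n <- length(series)
  X <- stats::fft(as.numeric(series))
  k <- seq_len(floor(n / 2) + 1)
  freq <- (k - 1) * rate / n
  power <- Mod(X[k])^2
  if (is.null(band)) band <- c(0, rate / 2)
  if (band[1] < 0 || band[1] >= band[2] || band[2] > rate / 2 + 1e-9)
    stop("band must satisfy 0 <= f1 < f2 <= Nyquist")
  sel <- if (band[1] == 0) freq > 0 & freq <= band[2]
         else freq >= band[1] & freq <= band[2]
  p <- power[sel]
  n_band <- length(p)
  if (n_band < 2) stop("band must contain at least 2 frequency bins")
  tot <- sum(p)
  if (tot == 0) {
    warning("zero power in band: spectral entropy set to 0")
    return(0)
  }
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(n_band)
}

#' Feature registry
#'
#' The deterministic name, axis and group (`time`, `frequency`,
#' `acoustic`) of every feature produced by [extract_features()], plus
#' the grouped kind used by the per-trial weight reports.
#'
#' @param n_imf Number of IMFs summarised per axis (default 3).
#' @return Data frame with columns `name`, `axis`, `kind`, `group`.
#' @export
har_feature_registry <- function(n_imf = 3) {
  axis_kinds <- c(mean = "time", median = "time", mode = "time",
                  std = "time", var = "time", min = "time", max = "time",
                  peak_neg = "time", peak_pos = "time", zcr = "acoustic",
                  energy = "time", f0 = "frequency", phase = "frequency",
                  specent = "acoustic")
  hht_kinds <- as.vector(vapply(seq_len(n_imf), function(k)
    paste0("hht_imf", k, "_", c("energy", "amp", "freq")), character(3)))
  rows <- list()
  for (ax in c("x", "y", "z")) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0(ax, "_", names(axis_kinds)), axis = ax,
      kind = names(axis_kinds), group = unname(axis_kinds))
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0(ax, "_", hht_kinds), axis = ax,
      kind = hht_kinds, group = "acoustic")
  }
  rows[[length(rows) + 1]] <- data.frame(
    name = c("mag_mean", "sma", "corr_xy", "corr_yz", "corr_zx"),
    axis = "frame",
    kind = c("mag_mean", "sma", "corr", "corr", "corr"),
    group = "time")
  do.call(rbind, rows)
}

#' Extract the multi-fused feature vector of a frame
#'
#' Computes, per axis: mean, median, mode, standard deviation,
#' variance, min, max, negative/positive peaks, zero-crossing rate (on
#' the mean-removed series), signal energy, fundamental frequency,
#' phase angle, spectral entropy, and the Hilbert descriptors of the
#' first `n_imf` IMFs; per frame: the mean vector magnitude, signal
#' magnitude area and the three pairwise axis correlations. Names and
#' order follow [har_feature_registry()].
#'
#' @param frame A [har_frame()].
#' @param config A [har_config()] (band, SMA mode, number of IMFs).
#' @return Named numeric vector of class `har_features` with
#'   attributes `label` and `groups`.
#' @export
extract_features <- function(frame, config = har_config()) {
  stopifnot(inherits(frame, "har_frame"))
  rate <- frame$rate
  per_axis <- function(v) {
    pk <- peak_features(v)
    c(mean = mean(v), median = stats::median(v), mode = mode_feature(v),
      std = std_feature(v), var = variance_feature(v),
      min = min(v), max = max(v),
      peak_neg = unname(pk["neg"]), peak_pos = unname(pk["pos"]),
      zcr = zero_crossing_rate(v - mean(v)),
      energy = signal_energy(v),
      f0 = fundamental_frequency(v, rate),
      phase = phase_angle(v, rate),
      specent = spectral_entropy(v, rate, config$band),
      hht_features(v, rate, config$n_imf))
  }
  vals <- c(
    stats::setNames(per_axis(frame$data[, 1]),
                    paste0("x_", names(per_axis_names(config$n_imf)))),
    stats::setNames(per_axis(frame$data[, 2]),
                    paste0("y_", names(per_axis_names(config$n_imf)))),
    stats::setNames(per_axis(frame$data[, 3]),
                    paste0("z_", names(per_axis_names(config$n_imf)))),
    mag_mean = signal_magnitude_mean(frame),
    sma = signal_magnitude_area(frame, config$sma_absolute),
    stats::setNames(correlation_features(frame),
                    c("corr_xy", "corr_yz", "corr_zx")))
  reg <- har_feature_registry(config$n_imf)
  vals <- vals[reg$name]
  structure(vals, label = frame$label,
            groups = stats::setNames(reg$group, reg$name),
            class = c("har_features", "numeric"))
}

## canonical per-axis feature name order (named logical used only for
## its names)
per_axis_names <- function(n_imf = 3) {
  nm <- c("mean", "median", "mode", "std", "var", "min", "max",
          "peak_neg", "peak_pos", "zcr", "energy", "f0", "phase",
          "specent",
          as.vector(vapply(seq_len(n_imf), function(k)
            paste0("hht_imf", k, "_", c("energy", "amp", "freq")),
            character(3))))
  stats::setNames(rep(TRUE, length(nm)), nm)
}

#' Build a feature table from frames
#'
#' Applies [extract_features()] to each frame and assembles a data
#' frame with one row per frame plus a `label` column.
#'
#' @param frames List of [har_frame()]s.
#' @param config A [har_config()].
#' @return Data frame (feature columns + `label`).
#' @export
har_feature_table <- function(frames, config = har_config()) {
  if (length(frames) == 0) stop("no frames to extract features from")
  rows <- lapply(frames, extract_features, config = config)
  tab <- as.data.frame(do.call(rbind, lapply(rows, as.numeric)))
  names(tab) <- names(rows[[1]])
  tab$label <- vapply(rows, function(r) attr(r, "label"), "")
  tab
}

#' Concatenate per-sensor feature vectors
#'
#' For synchronised multi-sensor recordings: concatenates the feature
#' vectors of aligned frames from several sensors, prefixing each
#' sensor's names with its placement (e.g. `wrist_x_mean`).
#'
#' @param feature_list Named list of `har_features` vectors; names
#'   default to each frame's placement.
#' @return A single named numeric vector.
#' @export
combine_sensor_features <- function(feature_list) {
  nms <- names(feature_list)
  if (is.null(nms)) nms <- paste0("s", seq_along(feature_list))
  out <- unlist(lapply(seq_along(feature_list), function(i)
    stats::setNames(as.numeric(feature_list[[i]]),
                    paste0(nms[i], "_", names(feature_list[[i]])))))
  out
}
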