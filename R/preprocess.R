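#' Third-order median filter
#'
#' Removes impulsive noise with a per-axis running median of order 3,
#' with edge replication (end samples pass through unchanged, the exact
#' behaviour of an order-3 median on an edge-replicated series). Output
#' length equals input length and values stay within the per-axis input
#' range.
#'
#' @param stream A [har_stream()].
#' @return The filtered [har_stream()].
#' @export
median_filter3 <- function(stream) {
  stopifnot(inherits(stream, "har_stream"))
  n <- nrow(stream$data)
  if (n < 3) return(stream)
  out <- apply(stream$data, 2, function(v) stats::runmed(v, 3, endrule = "keep"))
  stream_with_data(stream, out)
}

#' Centred moving-average filter
#'
#' Smooths each axis with a centred mean of odd width and edge
#' replication, so constant signals are unchanged and the output range
#' never exceeds the input range. A causal variant (mean of the current
#' and `width - 1` preceding samples) is available for pipelines that
#' compensate filter delay explicitly.
#'
#' @param stream A [har_stream()].
#' @param width Odd positive window width (`width <= length`).
#' @param causal If `TRUE`, apply the causal variant (introduces a
#'   group delay of `(width - 1) / 2` samples; see
#'   [compensate_delay()]).
#' @return The smoothed [har_stream()].
#' @export
moving_average <- function(stream, width = 5, causal = FALSE) {
  stopifnot(inherits(stream, "har_stream"))
  n <- nrow(stream$data)
  if (width < 1 || width %% 2 == 0) stop("width must be a positive odd integer")
  if (width > n) stop("width exceeds stream length")
  if (width == 1) return(stream)
  half <- (width - 1) / 2
  smooth_axis <- function(v) {
    if (causal) {
      padded <- c(rep(v[1], width - 1), v)
      out <- stats::filter(padded, rep(1 / width, width), sides = 1)
      as.numeric(out[width:(width + n - 1)])
    } else {
      padded <- c(rep(v[1], half), v, rep(v[n], half))
      out <- stats::filter(padded, rep(1 / width, width), sides = 2)
      as.numeric(out[(half + 1):(half + n)])
    }
  }
  stream_with_data(stream, apply(stream$data, 2, smooth_axis))
}

#' Compensate the group delay of a causal smoothing filter
#'
#' A causal moving average of width `w` delays the signal by
#' `(w - 1) / 2` samples; this advances it back, replicating the final
#' sample at the tail. With the default centred filter the smoothing is
#' already zero-phase and this is the identity.
#'
#' @param stream A [har_stream()].
#' @param width Width used by the causal smoothing filter.
#' @param causal Whether the smoothing filter was causal; if `FALSE`
#'   (the default pipeline), nothing is done.
#' @return The delay-compensated [har_stream()].
#' @export
compensate_delay <- function(stream, width = 5, causal = FALSE) {
  stopifnot(inherits(stream, "har_stream"))
  if (!causal || width <= 1) return(stream)
  shift <- (width - 1) / 2
  n <- nrow(stream$data)
  if (shift >= n) return(stream)
  idx <- pmin(seq_len(n) + shift, n)
  stream_with_data(stream, stream$data[idx, , drop = FALSE])
}

#' Min-max normalisation
#'
#' Maps each axis affinely so that the training minimum goes to 0 and
#' the training maximum to 1, removing negative values before feature
#' extraction. When `extremes` is supplied (a stored training pass),
#' out-of-range values clamp to `[0, 1]`. A constant axis maps to all
#' zeros with a warning.
#'
#' @param stream A [har_stream()].
#' @param extremes Optional 2x3 matrix (rows `min`, `max`; columns
#'   x/y/z) of stored training extremes. When absent the stream's own
#'   extremes are used.
#' @return The normalised [har_stream()] with attribute `"extremes"`
#'   (the 2x3 matrix used).
#' @export
normalize_minmax <- function(stream, extremes = NULL) {
  stopifnot(inherits(stream, "har_stream"))
  own <- is.null(extremes)
  if (own) {
    extremes <- rbind(min = apply(stream$data, 2, min),
                      max = apply(stream$data, 2, max))
  } else {
    extremes <- as.matrix(extremes)
    if (any(extremes[1, ] > extremes[2, ]))
      stop("supplied extremes have min > max")
  }
  out <- stream$data
  for (ax in 1:3) {
    lo <- extremes[1, ax]; hi <- extremes[2, ax]
    if (hi == lo) {
      warning("constant axis ", c("x", "y", "z")[ax],
              ": normalised to all zeros")
      out[, ax] <- 0
    } else {
      out[, ax] <- pmin(pmax((stream$data[, ax] - lo) / (hi - lo), 0), 1)
    }
  }
  res <- stream_with_data(stream, out)
  attr(res, "extremes") <- extremes
  res
}

#' Frame a stream into overlapped sliding windows
#'
#' Splits a stream into fixed-length windows of `round(window_seconds *
#' rate)` samples advancing by `max(1, floor(W * (1 - overlap_ratio)))`
#' samples; the trailing partial window is discarded.
#'
#' @param stream A [har_stream()].
#' @param window_seconds Window duration in seconds (`W >= 2` samples).
#' @param overlap_ratio Overlap fraction in `[0, 1)`.
#' @return A list of [har_frame()]s (possibly empty).
#' @export
#' @examples
#' s <- generate_stream(activity_spec("walk", 1.5), 10, rate = 100, seed = 1)
#' length(frame_stream(s, 2, 0.6))  # step 80: 11 frames
frame_stream <- function(stream, window_seconds = 2, overlap_ratio = 0.6) {
  stopifnot(inherits(stream, "har_stream"))
  if (overlap_ratio < 0 || overlap_ratio >= 1)
    stop("overlap_ratio must lie in [0, 1)")
  W <- round(window_seconds * stream$rate)
  if (W < 2) stop("window must contain at least 2 samples")
  n <- nrow(stream$data)
  if (n < W) return(list())
  step <- max(1, floor(W * (1 - overlap_ratio)))
  starts <- seq(1L, n - W + 1L, by = step)
  lapply(starts, function(s0)
    har_frame(stream$data[s0:(s0 + W - 1L), , drop = FALSE],
              start_index = s0, rate = stream$rate, label = stream$label,
              sensor = stream$sensor, placement = stream$placement,
              subject = stream$subject))
}

#' Preprocess a stream with the standard pipeline
#'
#' Applies, in order: third-order median filter, moving average (with
#' delay compensation when causal), and per-stream min-max
#' normalisation.
#'
#' @param stream A [har_stream()].
#' @param config A [har_config()].
#' @param extremes Optional stored normalisation extremes (see
#'   [normalize_minmax()]).
#' @return The preprocessed [har_stream()].
#' @export
preprocess_stream <- function(stream, config = har_config(),
                              extremes = NULL) {
  s <- median_filter3(stream)
  s <- moving_average(s, config$ma_width, causal = config$causal_ma)
  s <- compensate_delay(s, config$ma_width, causal = config$causal_ma)
  normalize_minmax(s, extremes)
}
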