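#' Construct a triaxial signal stream
#'
#' A `har_stream` holds one sensor's uniformly sampled triaxial series
#' plus its metadata: sampling rate, sensor kind, body placement,
#' subject and (optionally) the activity label.
#'
#' @param data Numeric matrix with columns `x`, `y`, `z` (one row per
#'   sample), or a data frame coercible to one.
#' @param rate Sampling rate in Hz (> 0).
#' @param sensor One of `"accelerometer"`, `"gyroscope"`,
#'   `"magnetometer"`.
#' @param placement One of `"wrist"`, `"chest"`, `"thigh"`, `"waist"`,
#'   `"pocket"`, `"unspecified"`.
#' @param subject Subject identifier (character).
#' @param label Activity label, or `NA` when unlabelled.
#' @return An object of class `har_stream`.
#' @export
#' @examples
#' s <- har_stream(cbind(x = sin(1:100 / 10), y = 0, z = 9.8), rate = 50)
#' s
har_stream <- function(data, rate,
                       sensor = c("accelerometer", "gyroscope",
                                  "magnetometer"),
                       placement = c("unspecified", "wrist", "chest",
                                     "thigh", "waist", "pocket"),
                       subject = "unknown", label = NA_character_) {
  data <- as.matrix(data)
  if (ncol(data) != 3) stop("stream data must have 3 columns (x, y, z)")
  colnames(data) <- c("x", "y", "z")
  storage.mode(data) <- "double"
  if (nrow(data) < 1) stop("stream must contain at least one sample")
  if (!all(is.finite(data))) stop("stream samples must be finite")
  if (!is.numeric(rate) || rate <= 0) stop("sampling rate must be > 0")
  structure(list(data = data, rate = as.numeric(rate),
                 sensor = match.arg(sensor),
                 placement = match.arg(placement),
                 subject = as.character(subject),
                 label = as.character(label)),
            class = "har_stream")
}

#' @export
print.har_stream <- function(x, ...) {
  cat(sprintf("<har_stream> %d samples @ %g Hz | %s @ %s | subject %s | label %s\n",
              nrow(x$data), x$rate, x$sensor, x$placement, x$subject,
              if (is.na(x$label)) "<none>" else x$label))
  invisible(x)
}

#' @export
length.har_stream <- function(x) nrow(x$data)

## Clone a stream with new sample data, keeping metadata.
stream_with_data <- function(stream, data) {
  out <- stream
  colnames(data) <- c("x", "y", "z")
  out$data <- data
  out
}

#' Construct a window frame
#'
#' A fixed-length segment of a stream produced by overlapped framing;
#' the unit of feature extraction.
#'
#' @param data Numeric matrix (W rows, columns x/y/z).
#' @param start_index 1-based sample offset of the first row in the
#'   source stream.
#' @param rate Sampling rate in Hz.
#' @param label Activity label or `NA`.
#' @param sensor,placement,subject Source metadata.
#' @return An object of class `har_frame`.
#' @export
har_frame <- function(data, start_index = 1L, rate = 100,
                      label = NA_character_, sensor = "accelerometer",
                      placement = "unspecified", subject = "unknown") {
  data <- as.matrix(data)
  colnames(data) <- c("x", "y", "z")
  storage.mode(data) <- "double"
  if (nrow(data) < 2) stop("a frame needs at least 2 samples")
  if (!all(is.finite(data))) stop("frame values must be finite")
  structure(list(data = data, start_index = as.integer(start_index),
                 rate = as.numeric(rate), label = as.character(label),
                 sensor = sensor, placement = placement,
                 subject = subject),
            class = "har_frame")
}

#' @export
print.har_frame <- function(x, ...) {
  cat(sprintf("<har_frame> W=%d @ %g Hz from sample %d | label %s\n",
              nrow(x$data), x$rate, x$start_index,
              if (is.na(x$label)) "<none>" else x$label))
  invisible(x)
}
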