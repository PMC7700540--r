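#' Run configuration
#'
#' Bundles every tunable of the pipeline: sampling rate, window geometry,
#' filter widths, normalisation mode, feature toggles and the genetic
#' algorithm settings. Defaults are the pipeline's standard operating
#' point: 100 Hz sampling, a 60% overlapping sliding window, a
#' third-order median filter plus a width-5 centred moving average, and a
#' GA with mutation rate 0.05.
#'
#' @param sampling_rate Sampling rate in Hz used when a stream does not
#'   carry its own (default 100).
#' @param window_seconds Window duration in seconds (default 2).
#' @param overlap_ratio Fraction of a window shared with its successor,
#'   in `[0, 1)` (default 0.6).
#' @param ma_width Odd width of the centred moving-average filter
#'   (default 5 samples).
#' @param causal_ma Logical; if `TRUE` the moving average is causal and
#'   [compensate_delay()] advances the signal by `(width - 1) / 2`
#'   samples. Default `FALSE` (centred, zero phase).
#' @param sma_absolute Logical; if `TRUE` the signal magnitude area sums
#'   absolute axis values instead of signed ones (default `FALSE`).
#' @param band Spectral-entropy band as `c(f1, f2)` in Hz, or `NULL` for
#'   the full band up to Nyquist (default).
#' @param n_imf Number of intrinsic mode functions summarised by the
#'   Hilbert descriptors (default 3).
#' @param ga List of genetic-algorithm settings: `population` (30),
#'   `generations` (50), `crossover_prob` (0.8), `mutation_rate` (0.05),
#'   `elitism` (1), `patience` (10, generations without improvement
#'   before stopping), `tournament` (3).
#' @param split_fraction Training fraction for the evaluation protocol
#'   (default 0.7).
#' @param similarity Template-matching similarity, `"cosine"` or
#'   `"euclidean"` (default cosine).
#' @param seed Integer seed recorded with the run.
#'
#' @return An object of class `har_config` (a validated list).
#' @export
#' @examples
#' cfg <- har_config(window_seconds = 2, overlap_ratio = 0.6)
#' cfg$ga$mutation_rate
har_config <- function(sampling_rate = 100,
                       window_seconds = 2,
                       overlap_ratio = 0.6,
                       ma_width = 5,
                       causal_ma = FALSE,
                       sma_absolute = FALSE,
                       band = NULL,
                       n_imf = 3,
                       ga = list(),
                       split_fraction = 0.7,
                       similarity = c("cosine", "euclidean"),
                       seed = 1L) {
  ga_defaults <- list(population = 30L, generations = 50L,
                      crossover_prob = 0.8, mutation_rate = 0.05,
                      elitism = 1L, patience = 10L, tournament = 3L)
  ga <- utils::modifyList(ga_defaults, as.list(ga))
  stopifnot(sampling_rate > 0, window_seconds > 0)
  if (overlap_ratio < 0 || overlap_ratio >= 1)
    stop("overlap_ratio must lie in [0, 1)")
  if (ga$mutation_rate < 0 || ga$mutation_rate > 1)
    stop("mutation_rate must lie in [0, 1]")
  if (ma_width < 1 || ma_width %% 2 == 0)
    stop("ma_width must be a positive odd integer")
  cfg <- list(sampling_rate = sampling_rate,
              window_seconds = window_seconds,
              overlap_ratio = overlap_ratio,
              ma_width = as.integer(ma_width),
              causal_ma = isTRUE(causal_ma),
              sma_absolute = isTRUE(sma_absolute),
              band = band,
              n_imf = as.integer(n_imf),
              ga = ga,
              split_fraction = split_fraction,
              similarity = match.arg(similarity),
              seed = as.integer(seed))
  class(cfg) <- "har_config"
  cfg
}

#' Read or write a run configuration as YAML/JSON
#'
#' @param path File path; `.yaml`/`.yml` is parsed as YAML, anything
#'   else as JSON.
#' @param config A [har_config()] object (for writing).
#' @return `read_har_config()` returns a `har_config`;
#'   `write_har_config()` returns `path` invisibly.
#' @export
read_har_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(har_config, raw[intersect(names(raw), names(formals(har_config)))])
}

#' @rdname read_har_config
#' @export
write_har_config <- function(config, path) {
  stopifnot(inherits(config, "har_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                            null = "null")
  invisible(path)
}

#' @export
print.har_config <- function(x, ...) {
  cat("<har_config>\n")
  cat(sprintf("  rate %g Hz, window %g s, overlap %.0f%%, ma width %d%s\n",
              x$sampling_rate, x$window_seconds, 100 * x$overlap_ratio,
              x$ma_width, if (x$causal_ma) " (causal)" else ""))
  cat(sprintf("  GA: pop %d, <=%d generations, crossover %.2f, mutation %.2f, patience %d\n",
              x$ga$population, x$ga$generations, x$ga$crossover_prob,
              x$ga$mutation_rate, x$ga$patience))
  invisible(x)
}
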