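#' Read raw comma-separated sensor logs (WISDM dialect)
#'
#' Parses text lines of the form
#' `user,activity,timestamp,x,y,z;` — the dialect used by public
#' smartphone-accelerometer collections such as WISDM. The trailing
#' semicolon and trailing commas are tolerated; blank and corrupt lines
#' (wrong field count, non-numeric x/y/z) are skipped and counted.
#'
#' Records are grouped into streams wherever the subject or label
#' changes, or the timestamp gap exceeds 10 times the median gap (a new
#' recording session). The per-stream sampling rate is inferred from the
#' median timestamp gap, read as nanoseconds; when timestamps are zero
#' or duplicated the configured rate is used instead.
#'
#' @param path Path to the raw text file.
#' @param config A [har_config()]; supplies the fallback sampling rate.
#' @param sensor,placement Metadata attached to every stream.
#' @return A list of [har_stream()] objects with attributes
#'   `n_skipped` (corrupt line count) and `n_records`.
#' @export
read_wisdm_raw <- function(path, config = har_config(),
                           sensor = "accelerometer",
                           placement = "unspecified") {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  ## strip trailing ';' and any trailing commas
  lines <- sub(";\\s*$", "", lines)
  lines <- sub(",+$", "", lines)
  keep <- nzchar(lines)
  n_skipped <- 0L
  recs <- vector("list", length(lines))
  n <- 0L
  for (ln in lines[keep]) {
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) != 6) { n_skipped <- n_skipped + 1L; next }
    xyz <- suppressWarnings(as.numeric(parts[4:6]))
    ts <- suppressWarnings(as.numeric(parts[3]))
    if (anyNA(xyz) || !all(is.finite(xyz)) || is.na(ts) || ts < 0) {
      n_skipped <- n_skipped + 1L; next
    }
    n <- n + 1L
    recs[[n]] <- list(subject = parts[1], label = parts[2], ts = ts,
                      x = xyz[1], y = xyz[2], z = xyz[3])
  }
  n_skipped <- n_skipped + sum(!keep)
  if (n == 0L) stop("no parseable records in ", path)
  recs <- recs[seq_len(n)]
  subj <- vapply(recs, `[[`, "", "subject")
  lab <- vapply(recs, `[[`, "", "label")
  ts <- vapply(recs, `[[`, 0, "ts")
  xyz <- t(vapply(recs, function(r) c(r$x, r$y, r$z), numeric(3)))

  ## split on subject/label change or large timestamp gap
  gaps <- diff(ts)
  med_gap <- stats::median(gaps[gaps > 0])
  boundary <- c(FALSE,
                subj[-1] != subj[-n] | lab[-1] != lab[-n] |
                  (is.finite(med_gap) & gaps > 10 * med_gap))
  grp <- cumsum(boundary) + 1L
  streams <- lapply(split(seq_len(n), grp), function(idx) {
    g <- diff(ts[idx])
    g <- g[g > 0]
    rate <- if (length(g) > 0 && stats::median(g) > 0)
      1e9 / stats::median(g)
    else config$sampling_rate
    har_stream(xyz[idx, , drop = FALSE], rate = rate, sensor = sensor,
               placement = placement, subject = subj[idx[1]],
               label = lab[idx[1]])
  })
  streams <- unname(streams)
  attr(streams, "n_skipped") <- n_skipped
  attr(streams, "n_records") <- n
  streams
}

#' Read generic CSV IMU data
#'
#' Reads a CSV with a header containing at least `x`, `y`, `z` columns;
#' optional columns `t`, `sensor`, `placement`, `subject`, `label`
#' supply metadata, otherwise config defaults apply. Consecutive rows
#' sharing the same label (and subject) form one stream.
#'
#' @inheritParams read_wisdm_raw
#' @return A list of [har_stream()] objects.
#' @export
read_csv_imu <- function(path, config = har_config(),
                         sensor = "accelerometer",
                         placement = "unspecified") {
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stop("CSV must contain x,y,z columns; found: ",
         paste(names(df), collapse = ", "))
  lab <- if ("label" %in% names(df)) as.character(df$label)
         else rep(NA_character_, nrow(df))
  subj <- if ("subject" %in% names(df)) as.character(df$subject)
          else rep("unknown", nrow(df))
  key <- paste(ifelse(is.na(lab), "<na>", lab), subj)
  boundary <- c(FALSE, key[-1] != key[-nrow(df)])
  grp <- cumsum(boundary) + 1L
  rate <- config$sampling_rate
  if ("t" %in% names(df)) {
    dt <- diff(df$t)
    dt <- dt[dt > 0]
    if (length(dt) > 0 && stats::median(dt) > 0) rate <- 1 / stats::median(dt)
  }
  unname(lapply(split(seq_len(nrow(df)), grp), function(idx) {
    har_stream(as.matrix(df[idx, need]), rate = rate,
               sensor = if ("sensor" %in% names(df)) df$sensor[idx[1]] else sensor,
               placement = if ("placement" %in% names(df)) df$placement[idx[1]] else placement,
               subject = subj[idx[1]], label = lab[idx[1]])
  }))
}

#' Write/read a feature table as CSV
#'
#' The table is a data frame of numeric feature columns plus a `label`
#' column; round-trips preserve feature order, labels and values to at
#' least 12 significant digits.
#'
#' @param table Data frame of features with a `label` column (as
#'   produced by [har_feature_table()]).
#' @param path Output CSV path.
#' @return `read_feature_table()` returns the data frame;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  num <- setdiff(names(table), "label")
  if (!all(vapply(table[num], is.numeric, TRUE)))
    stop("feature columns must be numeric")
  out <- table
  for (nm in num) out[[nm]] <- formatC(table[[nm]], digits = 15,
                                       format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  for (nm in setdiff(names(df), "label")) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Write a stream collection in the raw comma-separated dialect
#'
#' Inverse of [read_wisdm_raw()]: emits `user,activity,timestamp,x,y,z;`
#' lines with synthetic nanosecond timestamps at each stream's rate.
#'
#' @param streams List of [har_stream()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wisdm_raw <- function(streams, path) {
  con <- file(path, "w")
  on.exit(close(con))
  t0 <- 0
  for (s in streams) {
    n <- nrow(s$data)
    ts <- t0 + round(seq(0, by = 1e9 / s$rate, length.out = n))
    lines <- sprintf("%s,%s,%.0f,%.10g,%.10g,%.10g;",
                     s$subject, s$label, ts,
                     s$data[, 1], s$data[, 2], s$data[, 3])
    writeLines(lines, con)
    t0 <- ts[n] + 100 * 1e9 / s$rate  # gap forces a session boundary
  }
  invisible(path)
}
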