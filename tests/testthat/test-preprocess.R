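as_stream <- function(v, rate = 10) {
  har_stream(cbind(x = v, y = v, z = v), rate = rate)
}

test_that("order-3 median filter removes isolated impulses", {
  expect_equal(median_filter3(as_stream(c(5, 5, 5, 5)))$data[, 1],
               c(5, 5, 5, 5))
  expect_equal(median_filter3(as_stream(c(0, 0, 9, 0, 0)))$data[, 1],
               c(0, 0, 0, 0, 0))
  ## oracle: explicit sort of each edge-replicated 3-window
  v <- c(1, 100, 2, 3, 2)
  ora <- vapply(seq_along(v), function(i) {
    w <- v[pmax(1, pmin(length(v), (i - 1):(i + 1)))]
    sort(w)[2]
  }, 0)
  expect_equal(median_filter3(as_stream(v))$data[, 1], ora)
  expect_equal(ora, c(1, 2, 3, 2, 2))
})

test_that("moving average is a centred mean with edge replication", {
  expect_equal(moving_average(as_stream(c(4, 7, 1)), 1)$data[, 1],
               c(4, 7, 1))
  ## oracle: direct windowed means (0+0+3)/3, (0+3+0)/3, (3+0+0)/3
  expect_equal(moving_average(as_stream(c(0, 3, 0)), 3)$data[, 1],
               c(1, 1, 1))
  expect_equal(moving_average(as_stream(rep(2.5, 9)), 5)$data[, 1],
               rep(2.5, 9))
  expect_error(moving_average(as_stream(1:10), 4), "odd")
  expect_error(moving_average(as_stream(1:3), 5), "length")
})

test_that("filters never widen the per-axis range", {
  for (s in 1:5) {
    set.seed(s)
    v <- rnorm(100)
    st <- as_stream(v)
    for (out in list(median_filter3(st), moving_average(st, 7))) {
      expect_gte(min(out$data[, 1]), min(v))
      expect_lte(max(out$data[, 1]), max(v))
    }
  }
})

test_that("delay compensation realigns the causal moving average", {
  st <- as_stream(sin(2 * pi * 3 * (0:99) / 100))
  centred <- compensate_delay(st, 5, causal = FALSE)
  expect_identical(centred$data, st$data)
  expect_identical(compensate_delay(st, 1, causal = TRUE)$data, st$data)
  smoothed <- moving_average(st, 5, causal = TRUE)
  fixed <- compensate_delay(smoothed, 5, causal = TRUE)
  ## oracle: cross-correlation argmax lag vs the input is 0 afterwards
  lag_of <- function(a, b) {
    lags <- -10:10
    cc <- vapply(lags, function(L) {
      i <- seq_along(a)
      j <- i + L
      ok <- j >= 1 & j <= length(b)
      cor(a[i[ok]], b[j[ok]])
    }, 0)
    lags[which.max(cc)]
  }
  expect_equal(lag_of(st$data[, 1], fixed$data[, 1]), 0)
  expect_equal(lag_of(st$data[, 1], smoothed$data[, 1]), 2)
})

test_that("min-max normalisation maps extremes, clamps and warns", {
  st <- as_stream(c(2, 4, 6))
  out <- normalize_minmax(st)
  expect_equal(out$data[, 1], c(0, 0.5, 1))
  w <- testthat::capture_warnings(
    out2 <- normalize_minmax(as_stream(c(3, 3, 3))))
  expect_length(w, 3)  # all three axes constant
  expect_match(w, "constant", all = TRUE)
  expect_equal(out2$data[, 1], c(0, 0, 0))
  ext <- rbind(min = rep(0, 3), max = rep(4, 3))
  out3 <- normalize_minmax(as_stream(c(-1, 7)), ext)
  expect_equal(out3$data[, 1], c(0, 1))
  expect_error(normalize_minmax(st, rbind(rep(5, 3), rep(1, 3))),
               "min > max")
  ## idempotent when re-applied with unit extremes
  unit <- rbind(min = rep(0, 3), max = rep(1, 3))
  again <- normalize_minmax(stream_norm <- out, unit)
  expect_equal(again$data, out$data, tolerance = 1e-12)
})

test_that("framing counts and contents follow the step rule", {
  st <- make_stream(1, n = 1000, rate = 100)
  frames <- frame_stream(st, window_seconds = 1, overlap_ratio = 0.6)
  ## oracle: enumerated start indices 1, 41, ..., 881
  expect_length(frames, 23)
  expect_equal(vapply(frames, `[[`, 0L, "start_index"),
               as.integer(seq(1, 881, by = 40)))
  expect_equal(frames[[2]]$data, st$data[41:140, ],
               ignore_attr = "dimnames")

  expect_length(frame_stream(make_stream(2, n = 99, rate = 100), 1, 0.5), 0)
  expect_error(frame_stream(st, 0.001, 0), "at least 2")
  ## overlap 0 tiles the stream: concatenation rebuilds the prefix
  tiles <- frame_stream(st, 1, 0)
  expect_length(tiles, 10)
  rebuilt <- do.call(rbind, lapply(tiles, `[[`, "data"))
  expect_equal(rebuilt, st$data[1:1000, ], ignore_attr = "dimnames")
})

test_that("frames inherit label and metadata", {
  st <- make_stream(3, n = 300, rate = 50, label = "walk", subject = "s7")
  fr <- frame_stream(st, 2, 0.5)
  expect_equal(fr[[1]]$label, "walk")
  expect_equal(fr[[1]]$subject, "s7")
  expect_equal(nrow(fr[[1]]$data), 100)
})
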