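test_that("vector magnitude and magnitude area follow their formulas", {
  zero <- har_frame(matrix(0, 10, 3))
  expect_equal(signal_magnitude_mean(zero), 0)
  expect_equal(signal_magnitude_area(zero), 0)
  f345 <- har_frame(matrix(rep(c(3, 4, 0), each = 8), 8))
  expect_equal(signal_magnitude_mean(f345), 5)
  f <- har_frame(cbind(c(1, 1), c(2, 2), c(3, 3)))
  expect_equal(signal_magnitude_area(f), 6)
  fr <- make_frame(21)
  expect_equal(signal_magnitude_mean(fr), o_mag_mean(fr$data),
               tolerance = 1e-12)
  expect_equal(signal_magnitude_area(fr), o_sma(fr$data),
               tolerance = 1e-12)
  expect_equal(signal_magnitude_area(fr, absolute = TRUE),
               o_sma(fr$data, absolute = TRUE), tolerance = 1e-12)
})

test_that("zero crossing rate counts sign changes over W - 1", {
  expect_equal(zero_crossing_rate(c(1, 2, 3, 0.5)), 0)
  expect_equal(zero_crossing_rate(rep(c(1, -1), 4)), 1)
  set.seed(4)
  v <- rnorm(50)
  expect_equal(zero_crossing_rate(v), o_zcr(v), tolerance = 1e-12)
})

test_that("peak features use interpolated quartiles with fallback", {
  expect_equal(peak_features(1:8), c(neg = 1, pos = 8))
  expect_equal(peak_features(rep(2, 6)), c(neg = 2, pos = 2))
  expect_equal(peak_features(c(-5, 0, 0, 0, 0, 5)), c(neg = -5, pos = 5))
  set.seed(5)
  v <- rnorm(64)
  expect_equal(peak_features(v), o_peaks(v), tolerance = 1e-12)
})

test_that("basic statistics match their definitions", {
  expect_equal(std_feature(c(2, 2, 2)), 0)
  expect_equal(std_feature(1:4), sqrt(5 / 3))
  expect_error(std_feature(3), "at least 2")
  expect_equal(variance_feature(1:4), 5 / 3)
  set.seed(6)
  v <- rnorm(40)
  expect_equal(mean_feature(v), o_mean(v), tolerance = 1e-12)
  expect_equal(median_feature(v), o_median(v), tolerance = 1e-12)
  expect_lte(min_feature(v), median_feature(v))
  expect_lte(median_feature(v), max_feature(v))
})

test_that("histogram mode picks the leftmost fullest bin", {
  expect_equal(mode_feature(rep(4.2, 5)), 4.2)
  v <- c(0, 0, 0, 1)
  expect_equal(mode_feature(v), 0.05)  # centre of bin [0, 0.1)
  set.seed(7)
  v <- c(rnorm(80, 0, 0.3), rnorm(40, 3, 0.3))
  expect_equal(mode_feature(v), o_mode(v), tolerance = 1e-12)
})

test_that("energy and correlations behave at the boundaries", {
  expect_equal(signal_energy(c(1, -1, 1, -1)), 1)
  x <- rnorm(30)
  f <- har_frame(cbind(x, 2 * x + 1, rev(x)))
  expect_equal(unname(correlation_features(f)["xy"]), 1, tolerance = 1e-12)
  f2 <- har_frame(cbind(x, x, rep(5, 30)))
  w <- testthat::capture_warnings(cc <- correlation_features(f2))
  expect_length(w, 2)  # yz and zx both degenerate
  expect_match(w, "constant", all = TRUE)
  expect_equal(unname(cc["yz"]), 0)
  expect_equal(unname(cc["zx"]), 0)
})

test_that("fundamental frequency and phase angle recover a sinusoid", {
  t <- (0:199) / 100
  expect_equal(fundamental_frequency(sin(2 * pi * 2 * t), 100), 2,
               tolerance = 0.5)
  ## integer number of periods: zero-phase cosine has phase ~ 0
  expect_lt(abs(phase_angle(cos(2 * pi * 2 * t), 100)), 0.1)
  expect_equal(fundamental_frequency(rep(3, 16), 100), 0)
  expect_equal(phase_angle(rep(3, 16), 100), 0)
})

test_that("spectral entropy spans [0, 1] with closed-form anchors", {
  t <- (0:31) / 32
  ## all power in one bin
  expect_equal(spectral_entropy(sin(2 * pi * 4 * t), 32), 0,
               tolerance = 1e-9)
  ## flat spectrum: a unit impulse has equal power in every bin
  impulse <- c(1, rep(0, 31))
  expect_equal(spectral_entropy(impulse, 32), 1, tolerance = 1e-9)
  ## equal power in exactly 2 of 4 band bins -> log 2 / log 4 = 0.5
  t8 <- (0:7) / 8
  two <- sin(2 * pi * 1 * t8) + sin(2 * pi * 2 * t8)
  expect_equal(spectral_entropy(two, 8), 0.5, tolerance = 1e-9)
  expect_warning(z <- spectral_entropy(rep(0, 16), 32), "zero power")
  expect_equal(z, 0)
  expect_error(spectral_entropy(rnorm(16), 32, band = c(10, 5)), "band")
})

test_that("extract_features returns the full named registry vector", {
  fr <- make_frame(1)
  v <- extract_features(fr)
  reg <- har_feature_registry()
  expect_length(v, 74)
  expect_identical(names(v), reg$name)
  expect_false(anyDuplicated(names(v)) > 0)
  expect_true(all(is.finite(v)))
  expect_setequal(unique(attr(v, "groups")),
                  c("time", "frequency", "acoustic"))
  ## purity: identical frames give identical vectors
  expect_identical(as.numeric(v), as.numeric(extract_features(fr)))
})

test_that("feature table assembles rows with labels", {
  frames <- lapply(1:4, make_frame, label = "walk")
  tab <- har_feature_table(frames)
  expect_equal(dim(tab), c(4, 75))
  expect_equal(tab$label, rep("walk", 4))
})

test_that("multi-sensor concatenation prefixes placements", {
  f1 <- extract_features(make_frame(1))
  f2 <- extract_features(make_frame(2))
  out <- combine_sensor_features(list(wrist = f1, chest = f2))
  expect_length(out, 148)
  expect_true("wrist_x_mean" %in% names(out))
  expect_true("chest_z_specent" %in% names(out))
})

test_that("amplitude equivariance holds across the feature bank", {
  scale_keys <- c("mean", "std", "min", "max", "peak_neg", "peak_pos")
  for (s in c(11, 12, 13)) {
    fr <- make_frame(s)
    c0 <- 3.7
    fr2 <- har_frame(fr$data * c0, rate = fr$rate)
    a <- extract_features(fr); b <- extract_features(fr2)
    for (ax in c("x", "y", "z")) {
      for (k in scale_keys)
        expect_equal(b[[paste0(ax, "_", k)]],
                     c0 * a[[paste0(ax, "_", k)]], tolerance = 1e-9)
      expect_equal(b[[paste0(ax, "_energy")]],
                   c0^2 * a[[paste0(ax, "_energy")]], tolerance = 1e-9)
      for (k in c("zcr", "specent", "f0"))
        expect_equal(b[[paste0(ax, "_", k)]], a[[paste0(ax, "_", k)]],
                     tolerance = 1e-9)
      expect_equal(b[[paste0(ax, "_hht_imf1_energy")]],
                   a[[paste0(ax, "_hht_imf1_energy")]], tolerance = 1e-4)
    }
    expect_equal(b[["mag_mean"]], c0 * a[["mag_mean"]], tolerance = 1e-9)
    expect_equal(b[["sma"]], c0 * a[["sma"]], tolerance = 1e-9)
    for (k in c("corr_xy", "corr_yz", "corr_zx"))
      expect_equal(b[[k]], a[[k]], tolerance = 1e-9)
  }
})

test_that("bounded features stay in range on random suites", {
  for (s in 31:40) {
    fr <- make_frame(s)
    v <- extract_features(fr)
    for (ax in c("x", "y", "z")) {
      expect_gte(v[[paste0(ax, "_zcr")]], 0)
      expect_lte(v[[paste0(ax, "_zcr")]], 1)
      expect_gte(v[[paste0(ax, "_specent")]], 0)
      expect_lte(v[[paste0(ax, "_specent")]], 1)
    }
    for (k in c("corr_xy", "corr_yz", "corr_zx"))
      expect_lte(abs(v[[k]]), 1 + 1e-12)
  }
})
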