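fft_amplitude <- function(x, fs, freq) {
  n <- length(x)
  2 * Mod(stats::fft(x))[round(freq * n / fs) + 1] / n
}

test_that("high-pass filter removes DC and stroking, keeps burst band", {
  fs <- 20
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  expect_lt(max(abs(highpass(rep(2.5, 600), fs, 3))), 1e-6)

  slow <- sin(2 * pi * 1 * t)
  out <- highpass(slow, fs, 3)
  expect_lt(fft_amplitude(out, fs, 1) / fft_amplitude(slow, fs, 1), 0.10)

  fast <- sin(2 * pi * 6 * t)
  out6 <- highpass(fast, fs, 3)
  expect_gt(fft_amplitude(out6, fs, 6) / fft_amplitude(fast, fs, 6), 0.90)

  expect_error(highpass(slow, fs, 10), "Nyquist")
})

test_that("moving variance matches hand arithmetic and excludes edge windows", {
  expect_equal(moving_variance(c(1, 1, 1, 3), 4), c(NA, 1, NA, NA))
  expect_true(all(moving_variance(rep(4.2, 50), 30) %in% c(0, NA)))
  expect_equal(sum(!is.na(moving_variance(rnorm(50), 30))), 50 - 30 + 1)
  expect_error(moving_variance(1:10, 1), "at least 2")
  expect_true(all(is.na(moving_variance(rnorm(5), 10))))
})

test_that("moving variance agrees with the brute-force oracle", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    w <- sample(2:min(n, 40), 1)
    x <- rnorm(n, sd = runif(1, 0.1, 3))
    expect_equal(moving_variance(x, w), brute_moving_variance(x, w),
                 tolerance = 1e-10)
  }
})

test_that("variance peaks are strict local maxima above threshold", {
  expect_identical(find_variance_peaks(rep(0.05, 20), 0.1), integer(0))
  bump <- c(0, 0.05, 0.2, 0.5, 0.2, 0.05, 0)
  expect_identical(find_variance_peaks(bump, 0.1), 4L)
  two <- c(0, 0.3, 0.05, 0.4, 0)
  expect_identical(find_variance_peaks(two, 0.1), c(2L, 4L))
  # plateau reports its first sample
  plat <- c(0, 0.3, 0.3, 0.3, 0.1, 0)
  expect_identical(find_variance_peaks(plat, 0.1), 2L)
  # NA positions never hold peaks
  expect_identical(find_variance_peaks(c(NA, 0.5, NA), 0.1), 2L)
})

test_that("peak finding agrees with the brute-force oracle", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(3:60, 1)
    v <- round(runif(n, 0, 1), sample(1:2, 1))  # quantized -> plateaus
    v[runif(n) < 0.1] <- NA
    thr <- runif(1, 0, 0.8)
    expect_identical(find_variance_peaks(v, thr), brute_find_peaks(v, thr))
  }
})

test_that("the minimum-interval chain rule groups peaks", {
  expect_equal(group_peaks(c(10, 13, 30), 5), list(c(10, 13), 30))
  expect_equal(group_peaks(c(10, 13, 30), 20), list(c(10, 13, 30)))
  expect_equal(group_peaks(numeric(), 5), list())
  set.seed(3)
  for (i in 1:300) {
    times <- sort(runif(sample(1:30, 1), 0, 200))
    iv <- runif(1, 1, 30)
    expect_equal(group_peaks(times, iv), brute_group_peaks(times, iv))
  }
})

test_that("APC features: rectangle arithmetic, additivity, oracle equality", {
  fs <- 20
  v <- rep(0, 100)
  v[30:70] <- 0.2  # 41 samples = 2 s wide rectangle
  f <- apc_features(50L, v, 0.1, fs)
  expect_equal(f$integral_area, 0.4)
  expect_equal(f$duration, 2)
  expect_equal(f$n_peaks, 1)

  v2 <- rep(0, 200)
  v2[30:70] <- 0.2
  v2[120:160] <- 0.2
  f2 <- apc_features(c(50L, 140L), v2, 0.1, fs)
  expect_equal(f2$integral_area, 0.8)  # sum of the two pulses
  expect_equal(f2$n_peaks, 2)

  set.seed(5)
  for (i in 1:100) {
    v3 <- pmax(0, stats::filter(rnorm(150, 0.1, 0.2), rep(1 / 5, 5)))
    v3[is.na(v3)] <- 0
    v3 <- as.numeric(v3)
    thr <- 0.15
    peaks <- find_variance_peaks(v3, thr)
    if (!length(peaks)) next
    f3 <- apc_features(peaks, v3, thr, fs)
    expect_equal(f3$integral_area,
                 brute_group_integral(v3, thr, peaks, fs), tolerance = 1e-10)
  }
})

test_that("sum integral mode adds variance samples instead of integrating", {
  v <- rep(0, 100)
  v[30:70] <- 0.2
  f <- apc_features(50L, v, 0.1, 20, integral_mode = "sum")
  expect_equal(f$integral_area, 41 * 0.2)
})

test_that("detector finds exactly the injected well-separated bursts", {
  dep <- manual_burst_deployment(c(100, 150, 250))
  det <- detect_apc(dep$accel, dep$depth20, dep$dives, detector_params())
  expect_equal(nrow(det), 3)
  expect_true(all(abs(det$t_first_peak - c(100, 150, 250)) < 4))

  quiet <- manual_burst_deployment(numeric(0))
  expect_equal(nrow(detect_apc(quiet$accel, quiet$depth20, quiet$dives,
                               detector_params())), 0)

  close2 <- manual_burst_deployment(c(150, 154.5), burst_dur = 1.5)
  det2 <- detect_apc(close2$accel, close2$depth20, close2$dives,
                     detector_params(min_interval = 5))
  expect_equal(nrow(det2), 1)
  expect_gte(det2$n_peaks, 2)
})

test_that("detected peaks lie within their dive and below surface exclusion", {
  dep <- small_clean_deployment(seed = 21, n_dives = 6)
  det <- detect_apc(dep$accel, dep$depth20, dep$dives, detector_params())
  t <- trace_times(dep$depth20)
  for (i in seq_len(nrow(det))) {
    dv <- dep$dives[dep$dives$dive_id == det$dive_id[i], ]
    expect_gte(det$t_first_peak[i], dv$start_s)
    expect_lte(det$t_first_peak[i], dv$end_s)
    expect_gt(dep$depth20$depth[which.min(abs(t - det$t_first_peak[i]))], 2)
  }
})

test_that("APC count is non-increasing in threshold and interval", {
  dep <- small_clean_deployment(seed = 8, n_dives = 6, event_gap = 25)
  for (axis in c("surge", "heave")) {
    grid <- default_grid(axis)
    counts <- matrix(NA_real_,
                     nrow = length(unique(grid$variance_threshold)),
                     ncol = length(unique(grid$min_interval)),
                     dimnames = list(sort(unique(grid$variance_threshold)),
                                     sort(unique(grid$min_interval))))
    for (g in seq_len(nrow(grid))) {
      det <- detect_apc(dep$accel, dep$depth20, dep$dives,
                        detector_params(axis = axis,
                                        variance_threshold =
                                          grid$variance_threshold[g],
                                        min_interval = grid$min_interval[g]))
      counts[as.character(grid$variance_threshold[g]),
             as.character(grid$min_interval[g])] <- nrow(det)
    }
    expect_true(all(apply(counts, 2, diff) <= 0))  # along threshold
    expect_true(all(apply(counts, 1, diff) <= 0))  # along interval
  }
})
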