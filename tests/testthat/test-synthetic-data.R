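test_that("identical configs generate identical deployments", {
  a <- generate_deployment(sim_config(seed = 5, n_dives = 3,
                                      distractor_rate = 1))
  b <- generate_deployment(sim_config(seed = 5, n_dives = 3,
                                      distractor_rate = 1))
  expect_identical(a$accel, b$accel)
  expect_identical(a$depth, b$depth)
  expect_identical(a$truth, b$truth)
  c <- generate_deployment(sim_config(seed = 6, n_dives = 3))
  expect_false(identical(a$accel$surge, c$accel$surge))
})

test_that("degenerate configs: no dives, null-amplitude bursts", {
  flat <- generate_deployment(sim_config(seed = 1, n_dives = 0))
  expect_true(all(flat$depth$depth == 0))
  expect_equal(nrow(flat$truth), 0)
  expect_equal(nrow(find_dives(flat$depth)), 0)

  null <- generate_deployment(sim_config(seed = 1, n_dives = 3,
                                         apc_amplitude = 1e-9))
  expect_gt(nrow(null$truth), 0)
  dep <- prepare_deployment(null$accel, null$depth)
  det <- detect_apc(dep$accel, dep$depth20, dep$dives, detector_params())
  expect_equal(nrow(det), 0)  # bursts indistinguishable from baseline
})

test_that("an infeasible total duration errors rather than truncating", {
  expect_error(generate_deployment(sim_config(seed = 1, n_dives = 5,
                                              duration = 100)),
               "infeasible packing")
  ok <- generate_deployment(sim_config(seed = 1, n_dives = 1,
                                       duration = 3000))
  expect_equal(max(trace_times(ok$accel)), 3000)
})

test_that("no sample exceeds the clip limit; hard clipping engages", {
  sim <- generate_deployment(sim_config(seed = 2, n_dives = 4,
                                        apc_amplitude = 4))
  for (ax in c("surge", "sway", "heave"))
    expect_lte(max(abs(sim$accel[[ax]])), 3.0)
  expect_true(any(abs(sim$accel$surge) == 3.0))  # amplitude 4 must clip
})

test_that("burst and stroke power are spectrally separated at the cutoff", {
  sim <- generate_deployment(sim_config(seed = 3, n_dives = 2,
                                        noise_sd = 0))
  fs <- sim$accel$sample_rate
  power_split <- function(x, cutoff) {
    n <- length(x)
    p <- Mod(stats::fft(x - mean(x)))[2:floor(n / 2)]^2
    freq <- (1:(floor(n / 2) - 1)) * fs / n
    c(above = sum(p[freq > cutoff]), below = sum(p[freq <= cutoff]))
  }
  # isolate one burst and one burst-free stretch
  tr <- sim$truth[1, ]
  i <- round(tr$burst_start_s * fs):round(tr$burst_end_s * fs)
  base <- sim$accel$surge
  burst_only <- generate_deployment(sim_config(seed = 3, n_dives = 2,
                                               noise_sd = 0,
                                               stroke_amplitude = 0))
  pb <- power_split(burst_only$accel$surge[i], 3)
  expect_gt(pb["above"] / sum(pb), 0.90)
  stroke_only <- generate_deployment(sim_config(seed = 3, n_dives = 2,
                                                noise_sd = 0,
                                                apc_amplitude = 0,
                                                distractor_rate = 0))
  gap <- round(100 * fs):round(130 * fs)
  ps <- power_split(stroke_only$accel$surge[gap], 3)
  expect_gt(ps["below"] / sum(ps), 0.90)
})

test_that("truth structure: counts in range, windows inside deep dives", {
  sim <- generate_deployment(sim_config(seed = 9, n_dives = 12,
                                        distractor_rate = 1))
  apc <- sim$truth[sim$truth$kind == "apc", ]
  per_dive <- table(apc$dive_id)
  expect_true(all(per_dive >= 1 & per_dive <= 7))
  expect_equal(length(per_dive), 12)
  # re-derive the total from the deterministic re-run of the same recipe
  again <- generate_deployment(sim_config(seed = 9, n_dives = 12,
                                          distractor_rate = 1))
  expect_equal(nrow(apc), sum(table(
    again$truth$dive_id[again$truth$kind == "apc"])))

  plan <- sim$dive_plan
  for (r in seq_len(nrow(sim$truth))) {
    p <- plan[plan$dive_id == sim$truth$dive_id[r], ]
    expect_gte(sim$truth$start_s[r], p$start_s)
    expect_lte(sim$truth$end_s[r], p$end_s)
    expect_gt(p$max_depth, 15)
  }
  # distractors never overlap APC annotation windows
  dis <- sim$truth[sim$truth$kind == "distractor", ]
  for (r in seq_len(nrow(dis)))
    expect_false(any(dis$start_s[r] < apc$end_s &
                       apc$start_s < dis$end_s[r]))
  # successful events may carry up to 8 sub-bursts, unsuccessful start at 1
  expect_true(all(apc$n_subbursts[!apc$success] <= 8))
  expect_true(all(apc$n_subbursts >= 1))
})

test_that("per-dive APC counts follow the truncated normal recipe", {
  sims <- lapply(1:6, function(s)
    generate_deployment(sim_config(seed = s, n_dives = 15)))
  counts <- unlist(lapply(sims, function(s)
    as.integer(table(s$truth$dive_id[s$truth$kind == "apc"]))))
  expect_gt(mean(counts), 1.8)
  expect_lt(mean(counts), 3.4)  # around the 2.6 target after truncation
  expect_true(all(counts >= 1 & counts <= 7))
})

test_that("a written deployment round-trips through the readers", {
  sim <- generate_deployment(sim_config(seed = 4, n_dives = 2,
                                        distractor_rate = 1))
  dir <- withr::local_tempdir()
  write_deployment(sim, dir)
  acc <- read_accel(file.path(dir, "accel.csv"))
  expect_equal(acc$surge, sim$accel$surge, tolerance = 1e-9)
  expect_identical(acc$surge[abs(sim$accel$surge) == 3],
                   sim$accel$surge[abs(sim$accel$surge) == 3])
  dep <- read_depth(file.path(dir, "depth.csv"))
  expect_equal(dep$depth, sim$depth$depth, tolerance = 1e-9)
  ev <- read_events(file.path(dir, "events.csv"))
  expect_equal(nrow(ev), sum(sim$truth$kind == "apc"))
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), nrow(sim$truth))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(apc_burst_freq = 2), "cutoff")
  expect_error(sim_config(baseline_stroke_freq = 4), "below the detector")
  expect_error(sim_config(success_prob = 1.2), "success_prob")
  expect_error(sim_config(apc_burst_freq = 11), "Nyquist")
})
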