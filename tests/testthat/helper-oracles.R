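# Independent brute-force reference implementations used to pin the detector
# semantics. Deliberately written as plain loops, not shared with R/.

brute_moving_variance <- function(x, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  left <- floor((w - 1) / 2)
  for (i in seq_len(n)) {
    from <- i - left
    to <- from + w - 1
    if (from >= 1 && to <= n) out[i] <- stats::var(x[from:to])
  }
  out
}

brute_find_peaks <- function(v, thr) {
  n <- length(v)
  vv <- ifelse(is.na(v), -Inf, v)
  peaks <- integer()
  for (i in seq_len(n)) {
    if (!is.finite(vv[i]) || vv[i] <= thr) next
    if (i > 1 && vv[i - 1] == vv[i]) next  # not the first sample of a plateau
    j <- i - 1
    while (j >= 1 && vv[j] == vv[i]) j <- j - 1
    k <- i
    while (k < n && vv[k + 1] == vv[i]) k <- k + 1
    k <- k + 1
    if (j < 1 || k > n) next               # plateau touches the boundary
    if (vv[j] < vv[i] && vv[k] < vv[i]) peaks <- c(peaks, i)
  }
  peaks
}

brute_group_peaks <- function(times, interval) {
  if (!length(times)) return(list())
  groups <- list(times[1])
  for (tm in times[-1]) {
    last <- groups[[length(groups)]]
    if (tm - last[length(last)] <= interval)
      groups[[length(groups)]] <- c(last, tm)
    else groups[[length(groups) + 1]] <- tm
  }
  groups
}

# trapezoidal integral of v over the supra-threshold runs containing any of
# the group's peak indices
brute_group_integral <- function(v, thr, peak_idx, fs) {
  above <- !is.na(v) & v > thr
  n <- length(v)
  total <- 0
  i <- 1
  while (i <= n) {
    if (!above[i]) { i <- i + 1; next }
    j <- i
    while (j < n && above[j + 1]) j <- j + 1
    if (any(peak_idx >= i & peak_idx <= j)) {
      seg <- v[i:j]
      if (length(seg) > 1)
        total <- total + sum((seg[-1] + seg[-length(seg)]) / 2) / fs
    }
    i <- j + 1
  }
  total
}

# independent event-matching reference: containment with nearest-start
# assignment, earliest detection per event wins
brute_match <- function(det_times, ev_start, ev_end) {
  nd <- length(det_times)
  ne <- length(ev_start)
  assign <- rep(NA_integer_, nd)
  for (i in seq_len(nd)) {
    best <- NA_integer_
    bestd <- Inf
    for (e in seq_len(ne)) {
      if (det_times[i] < ev_start[e] || det_times[i] > ev_end[e]) next
      d <- abs(ev_start[e] - det_times[i])
      if (d < bestd || (d == bestd && (is.na(best) ||
                                       ev_start[e] < ev_start[best]))) {
        best <- e
        bestd <- d
      }
    }
    assign[i] <- best
  }
  label <- rep("FP", nd)
  tp_ev <- logical(ne)
  for (e in seq_len(ne)) {
    hits <- which(assign == e)
    if (!length(hits)) next
    first <- hits[which.min(det_times[hits])]
    label[first] <- "TP"
    tp_ev[e] <- TRUE
  }
  list(TP = sum(label == "TP"), FP = sum(label == "FP"),
       FN = sum(!tp_ev), label = label)
}

# small clean deployment used by several suites
small_clean_deployment <- function(seed = 1, n_dives = 5, ...) {
  sim <- generate_deployment(sim_config(seed = seed, n_dives = n_dives, ...))
  dep <- prepare_deployment(sim$accel, sim$depth)
  dep$events <- rekey_events(sim_events(sim), dep$dives)
  dep$truth <- rekey_events(sim$truth, dep$dives)
  dep$sim <- sim
  dep
}

# hand-built single-dive deployment with bursts at given times (s); depth is
# a trapezoid to 60 m, burst carrier 8 Hz, amplitude in g
manual_burst_deployment <- function(burst_times, burst_dur = 3, amp = 1.5,
                                    total = 400, fs = 20, noise_sd = 0.02,
                                    seed = 42) {
  set.seed(seed)
  t <- seq(0, total, by = 1 / fs)
  x <- rnorm(length(t), 0, noise_sd)
  for (b0 in burst_times) {
    idx <- which(t >= b0 & t <= b0 + burst_dur)
    tt <- (seq_along(idx) - 1) / fs
    env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(idx)))
    x[idx] <- x[idx] + amp * env * sin(2 * pi * 8 * tt)
  }
  accel <- accel_trace(x, x, x, sample_rate = fs)
  td <- seq(0, total, by = 1)
  dpth <- approx(c(0, 30, 70, total - 70, total - 30, total),
                 c(0, 0, 60, 60, 0, 0), xout = td)$y
  depth <- depth_trace(dpth, sample_rate = 1)
  prepare_deployment(accel, depth)
}
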