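#' Configuration for a synthetic deployment
#'
#' Defines the statistical structure of a simulated benthic-foraging
#' deployment: tri-axial head acceleration at 20 Hz clipped at +/-3 g, depth
#' at 1 Hz, and ground-truth annotations for every injected event. Defaults
#' emulate winter foraging trips of adult female Australian fur seals on the
#' Bass Strait shelf: benthic dives with maximum depths 61-86 m, 1-7 attempted
#' prey captures (APC) per foraging dive (mean 2.6, SD 1.6), mostly successful
#' (93%) and mostly fish, with successful APC lasting 4.1 +/- 2.7 s and
#' unsuccessful 2.7 +/- 1.2 s.
#'
#' The acceleration model is: a slowly drifting gravity/orientation offset,
#' a low-frequency stroking oscillation (default 1.2 Hz, below the detector's
#' 3 Hz cutoff), APC bursts modelled as amplitude-modulated sinusoid packets
#' (Hanning envelope, default carrier 8 Hz, above the cutoff), optional
#' non-feeding head-movement distractor bursts, and Gaussian noise; the sum is
#' hard-clipped at `clip_limit`. Successful APC contain 1-8 sub-bursts
#' (emulating prey handling), unsuccessful APC a single sub-burst.
#'
#' @param seed Integer RNG seed; identical configs give identical output.
#' @param n_dives Number of dives.
#' @param duration Total deployment length in seconds, or `NULL` to fit the
#'   dives exactly. A duration too short for `n_dives` is an error, never a
#'   silent truncation.
#' @param sample_rate_accel,sample_rate_depth Sampling rates in Hz.
#' @param clip_limit Hard clip limit in g.
#' @param max_depth_range Range (m) maximum dive depths are drawn from.
#' @param prey_per_dive_mean,prey_per_dive_sd,prey_per_dive_range APC count
#'   per dive: a rounded normal draw truncated to the range.
#' @param apc_burst_freq Burst carrier frequency in Hz; must exceed the
#'   detector's high-pass cutoff.
#' @param apc_duration_mean_succ,apc_duration_sd_succ,apc_duration_mean_unsucc,apc_duration_sd_unsucc
#'   APC duration draws (s), truncated to sensible support.
#' @param apc_amplitude Burst peak amplitude in g on the surge axis.
#' @param axis_weights Relative burst amplitude per axis; heave is weaker in
#'   real data.
#' @param baseline_stroke_freq Stroking frequency in Hz; must be below the
#'   detector cutoff.
#' @param stroke_amplitude Stroke oscillation amplitude in g.
#' @param noise_sd Gaussian noise SD in g.
#' @param distractor_rate Mean non-feeding head-movement bursts per dive
#'   (Poisson).
#' @param distractor_amplitude Distractor burst amplitude in g.
#' @param success_prob Probability an APC is successful.
#' @param prey_type_probs Named probabilities over fish, cephalopod, stingray,
#'   unknown.
#' @param event_gap Minimum gap (s) between injected bursts, so that distinct
#'   truth records remain separable by the detector's generic 5 s interval.
#' @param chase_lead Seconds by which an APC's annotated window opens before
#'   its acceleration burst: video annotators see the chase begin before the
#'   head-strike reaches the accelerometer (default 1 s). Distractors have no
#'   annotation and no lead.
#' @param cutoff Detector cutoff (Hz) the frequency invariants are checked
#'   against (default 3).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_dives = 5, duration = NULL,
                       sample_rate_accel = 20, sample_rate_depth = 1,
                       clip_limit = 3.0, max_depth_range = c(61, 86),
                       prey_per_dive_mean = 2.6, prey_per_dive_sd = 1.6,
                       prey_per_dive_range = c(1, 7),
                       apc_burst_freq = 8,
                       apc_duration_mean_succ = 4.1, apc_duration_sd_succ = 2.7,
                       apc_duration_mean_unsucc = 2.7,
                       apc_duration_sd_unsucc = 1.2,
                       apc_amplitude = 1.5,
                       axis_weights = c(surge = 1, sway = 1, heave = 0.6),
                       baseline_stroke_freq = 1.2, stroke_amplitude = 0.3,
                       noise_sd = 0.05, distractor_rate = 0,
                       distractor_amplitude = 1.5,
                       success_prob = 0.93,
                       prey_type_probs = c(fish = 0.80, cephalopod = 0.03,
                                           stingray = 0.02, unknown = 0.15),
                       event_gap = 10, chase_lead = 1, cutoff = 3) {
  if (apc_burst_freq <= cutoff)
    stop("apc_burst_freq must exceed the detector cutoff", call. = FALSE)
  if (baseline_stroke_freq >= cutoff)
    stop("baseline_stroke_freq must be below the detector cutoff",
         call. = FALSE)
  if (apc_burst_freq >= sample_rate_accel / 2)
    stop("apc_burst_freq must be below the accelerometer Nyquist rate",
         call. = FALSE)
  if (success_prob < 0 || success_prob > 1)
    stop("success_prob must lie in [0, 1]", call. = FALSE)
  if (abs(sum(prey_type_probs) - 1) > 1e-6)
    stop("prey_type_probs must sum to 1", call. = FALSE)
  if (n_dives < 0) stop("n_dives must be >= 0", call. = FALSE)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# One amplitude-modulated sinusoid packet, possibly split into n_sub
# contiguous sub-bursts (each with its own Hanning envelope). Sub-burst
# intensity follows a unimodal profile across the event — handling intensity
# builds and ebbs — so within-event variance peaks rise towards the middle.
burst_packet <- function(n, fs, freq, amplitude, n_sub, phase) {
  env <- numeric(n)
  bounds <- round(seq(0, n, length.out = n_sub + 1))
  for (s in seq_len(n_sub)) {
    seg <- (bounds[s] + 1):bounds[s + 1]
    intensity <- 0.7 + 0.3 * sin(pi * (s - 0.5) / n_sub)
    if (length(seg)) env[seg] <- intensity * hann(length(seg))
  }
  tt <- (seq_len(n) - 1) / fs
  amplitude * env * sin(2 * pi * freq * tt + phase)
}

#' Generate one synthetic deployment
#'
#' Draws dives, events and distractors from `config` (see [sim_config()]) and
#' synthesises the acceleration and depth traces plus the truth table. Events
#' and distractors are laid out in each dive's bottom phase with at least
#' `event_gap` seconds between bursts; the bottom phase is sized to fit them,
#' and a user-supplied total `duration` that cannot accommodate the dives
#' raises an error.
#'
#' @param config A `sim_config`.
#' @return A list of class `sim_deployment` with elements `accel`
#'   (`accel_trace`), `depth` (`depth_trace` at 1 Hz), `truth` (data frame:
#'   `dive_id`, `start_s`, `end_s`, `category`, `prey_type`, `location`,
#'   `success`, `kind`, `n_subbursts`), and `dive_plan` (intended dive
#'   windows and maximum depths).
#' @export
generate_deployment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sample_rate_accel
  fsd <- config$sample_rate_depth
  descent_rate <- 1.5   # m/s, typical pinniped transit rate
  surface_int <- 40     # s between dives
  min_bottom <- 60      # s

  dive_plan <- list()
  truth <- list()
  t_cursor <- surface_int
  for (d in seq_len(config$n_dives)) {
    max_depth <- stats::runif(1, config$max_depth_range[1],
                              config$max_depth_range[2])
    n_prey <- round(stats::rnorm(1, config$prey_per_dive_mean,
                                 config$prey_per_dive_sd))
    n_prey <- min(max(n_prey, config$prey_per_dive_range[1]),
                  config$prey_per_dive_range[2])
    succ <- stats::runif(n_prey) < config$success_prob
    dur <- ifelse(succ,
                  rnorm_trunc(n_prey, config$apc_duration_mean_succ,
                              config$apc_duration_sd_succ, 1, 12),
                  rnorm_trunc(n_prey, config$apc_duration_mean_unsucc,
                              config$apc_duration_sd_unsucc, 1, 8))
    n_sub <- ifelse(succ, sample(1:8, n_prey, replace = TRUE), 1L)
    # keep sub-burst spacing under the generic 5 s interval so one event
    # stays one detector group, and each sub-burst >= 1 s so its variance
    # bump is resolvable by the 1.5 s window
    n_sub <- pmin(pmax(n_sub, ceiling(dur / 4)), pmax(1L, floor(dur)), 8L)
    prey <- sample(names(config$prey_type_probs), n_prey, replace = TRUE,
                   prob = config$prey_type_probs)
    n_dis <- stats::rpois(1, config$distractor_rate)
    dis_dur <- rnorm_trunc(n_dis, 2, 0.5, 1, 4)

    items <- data.frame(
      dur = c(dur, dis_dur),
      kind = c(rep("apc", n_prey), rep("distractor", n_dis)),
      success = c(succ, rep(NA, n_dis)),
      n_sub = c(n_sub, rep(1L, n_dis)),
      prey_type = c(prey, rep(NA_character_, n_dis)))
    items <- items[sample(nrow(items)), , drop = FALSE]

    gap <- config$event_gap
    lead <- ifelse(items$kind == "apc", config$chase_lead, 0)
    bottom_dur <- max(min_bottom,
                      sum(items$dur + lead) + gap * (nrow(items) + 1))
    descent_dur <- max_depth / descent_rate
    dive_start <- t_cursor
    bottom_start <- dive_start + descent_dur
    dive_end <- bottom_start + bottom_dur + descent_dur
    pos <- bottom_start + gap
    for (it in seq_len(nrow(items))) {
      st <- pos                         # annotated window opens at chase start
      b0 <- pos + lead[it]              # burst onset
      en <- b0 + items$dur[it]
      pos <- en + gap
      row <- items[it, ]
      category <- if (row$kind == "distractor") "distractor"
        else if (!row$success) "chase_missed"
        else if (row$n_sub > 1) "chase_capture_handling"
        else "chase_capture_no_handling"
      location <- if (row$kind == "distractor") NA_character_
        else if (!is.na(row$prey_type) && row$prey_type != "fish") "ascent"
        else if (stats::runif(1) < 0.72) "benthic" else "ascent"
      truth[[length(truth) + 1]] <- data.frame(
        dive_id = d, start_s = st, end_s = en,
        burst_start_s = b0, burst_end_s = en, category = category,
        prey_type = row$prey_type, location = location,
        success = row$success, kind = row$kind, n_subbursts = row$n_sub)
    }
    dive_plan[[d]] <- data.frame(
      dive_id = d, start_s = dive_start, end_s = dive_end,
      bottom_start_s = bottom_start, bottom_end_s = bottom_start + bottom_dur,
      max_depth = max_depth)
    t_cursor <- dive_end + surface_int
  }
  total_needed <- t_cursor
  total <- if (is.null(config$duration)) total_needed else config$duration
  if (total < total_needed)
    stop(sprintf(
      "infeasible packing: duration %.0f s cannot accommodate %d dives (need %.0f s)",
      total, config$n_dives, total_needed), call. = FALSE)
  if (config$n_dives == 0 && is.null(config$duration)) total <- 600

  plan <- if (length(dive_plan)) do.call(rbind, dive_plan) else NULL
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(dive_id = integer(), start_s = numeric(), end_s = numeric(),
               burst_start_s = numeric(), burst_end_s = numeric(),
               category = character(), prey_type = character(),
               location = character(), success = logical(),
               kind = character(), n_subbursts = integer())
  rownames(truth) <- NULL

  # depth profile at fsd Hz: piecewise-linear descent / flat bottom / ascent
  td <- seq(0, total, by = 1 / fsd)
  depth <- numeric(length(td))
  if (!is.null(plan)) {
    for (d in seq_len(nrow(plan))) {
      p <- plan[d, ]
      knots_t <- c(p$start_s, p$bottom_start_s, p$bottom_end_s, p$end_s)
      knots_d <- c(0, p$max_depth, p$max_depth, 0)
      in_dive <- td >= p$start_s & td <= p$end_s
      depth[in_dive] <- stats::approx(knots_t, knots_d, xout = td[in_dive])$y
    }
  }

  # acceleration at fs Hz
  ta <- seq(0, total, by = 1 / fs)
  n <- length(ta)
  drift_phase <- stats::runif(3, 0, 2 * pi)
  stroke_phase <- stats::runif(3, 0, 2 * pi)
  base_offset <- c(surge = 0.1, sway = 0.0, heave = -0.9)
  ax <- list()
  for (k in 1:3) {
    drift <- 0.25 * sin(2 * pi * ta / 180 + drift_phase[k])
    stroke <- config$stroke_amplitude *
      sin(2 * pi * config$baseline_stroke_freq * ta + stroke_phase[k])
    ax[[k]] <- base_offset[k] + drift + stroke +
      stats::rnorm(n, 0, config$noise_sd)
  }
  w <- config$axis_weights
  for (r in seq_len(nrow(truth))) {
    i0 <- round(truth$burst_start_s[r] * fs) + 1
    i1 <- min(round(truth$burst_end_s[r] * fs) + 1, n)
    len <- i1 - i0 + 1
    if (len < 2) next
    amp <- if (truth$kind[r] == "distractor") config$distractor_amplitude
      else config$apc_amplitude
    phase <- stats::runif(1, 0, 2 * pi)
    pk <- burst_packet(len, fs, config$apc_burst_freq, amp,
                       truth$n_subbursts[r], phase)
    for (k in 1:3) ax[[k]][i0:i1] <- ax[[k]][i0:i1] + w[k] * pk
  }
  cl <- config$clip_limit
  for (k in 1:3) ax[[k]] <- pmin(pmax(ax[[k]], -cl), cl)

  structure(list(
    accel = accel_trace(ax[[1]], ax[[2]], ax[[3]], sample_rate = fs,
                        start_time = 0, clip_limit = cl),
    depth = depth_trace(depth, sample_rate = fsd, start_time = 0),
    truth = truth, dive_plan = plan, config = config),
    class = "sim_deployment")
}

#' Write a synthetic deployment to a directory
#'
#' Emits `accel.csv` and `depth.csv` in the trace dialect of [write_accel()]
#' and [write_depth()], `events.csv` holding the video-visible events (true
#' APC only, in the [read_events()] schema), and `truth.csv` with the full
#' ground truth including distractors.
#'
#' @param sim A `sim_deployment` from [generate_deployment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_deployment <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_deployment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_accel(sim$accel, file.path(dir, "accel.csv"))
  write_depth(sim$depth, file.path(dir, "depth.csv"))
  ev <- sim$truth[sim$truth$kind == "apc",
                  c("dive_id", "start_s", "end_s", "category", "prey_type",
                    "location")]
  write_events(ev, file.path(dir, "events.csv"))
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Video-visible events of a synthetic deployment
#'
#' @param sim A `sim_deployment`.
#' @return Event data frame in the [read_events()] schema (distractors
#'   excluded — an animal-borne camera would not record them as APC).
#' @export
sim_events <- function(sim) {
  sim$truth[sim$truth$kind == "apc",
            c("dive_id", "start_s", "end_s", "category", "prey_type",
              "location")]
}
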