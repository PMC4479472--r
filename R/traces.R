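#' Tri-axial acceleration trace
#'
#' Container for a uniformly sampled head-mounted accelerometer record with
#' surge (anterior-posterior), sway (lateral) and heave (dorsal-ventral) axes
#' in units of g. Loggers of this class typically clip at a hard gain limit
#' (e.g. +/- 3 g); when `clip_limit` is declared, all samples must respect it.
#'
#' @param surge,sway,heave Numeric vectors of equal length, acceleration in g.
#' @param sample_rate Sampling frequency in Hz (default 20).
#' @param start_time Time of the first sample, in seconds on the deployment
#'   clock (default 0).
#' @param clip_limit Optional hard clip limit in g; `NA` for none.
#' @return An object of class `accel_trace`.
#' @examples
#' tr <- accel_trace(rnorm(100), rnorm(100), rnorm(100), sample_rate = 20)
#' trace_times(tr)[1:5]
#' @export
accel_trace <- function(surge, sway, heave, sample_rate = 20, start_time = 0,
                        clip_limit = NA_real_) {
  n <- length(surge)
  if (length(sway) != n || length(heave) != n)
    stop("surge, sway and heave must have equal length", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a single positive number", call. = FALSE)
  if (!is.finite(start_time))
    stop("start_time must be finite", call. = FALSE)
  if (!is.na(clip_limit)) {
    mx <- suppressWarnings(max(abs(c(surge, sway, heave)), na.rm = TRUE))
    if (n > 0 && mx > clip_limit + 1e-9)
      stop(sprintf("sample exceeds declared clip limit +/-%g g", clip_limit),
           call. = FALSE)
  }
  structure(
    list(start_time = as.numeric(start_time), sample_rate = sample_rate,
         surge = as.numeric(surge), sway = as.numeric(sway),
         heave = as.numeric(heave), clip_limit = clip_limit),
    class = "accel_trace")
}

#' Depth trace from a time-depth recorder
#'
#' @param depth Numeric vector of depths in metres, positive downward.
#' @param sample_rate Sampling frequency in Hz (default 1).
#' @param start_time Time of the first sample in seconds (default 0).
#' @return An object of class `depth_trace`.
#' @export
depth_trace <- function(depth, sample_rate = 1, start_time = 0) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a single positive number", call. = FALSE)
  if (!is.finite(start_time))
    stop("start_time must be finite", call. = FALSE)
  structure(
    list(start_time = as.numeric(start_time), sample_rate = sample_rate,
         depth = as.numeric(depth)),
    class = "depth_trace")
}

#' Sample times of a trace
#'
#' @param trace An `accel_trace` or `depth_trace`.
#' @return Numeric vector of per-sample times in seconds.
#' @export
trace_times <- function(trace) {
  n <- trace_length(trace)
  trace$start_time + (seq_len(n) - 1) / trace$sample_rate
}

trace_length <- function(trace) {
  if (inherits(trace, "accel_trace")) length(trace$surge) else length(trace$depth)
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz, start %g s",
              length(x$surge), x$sample_rate, x$start_time))
  if (!is.na(x$clip_limit)) cat(sprintf(", clip +/-%g g", x$clip_limit))
  cat("\n")
  invisible(x)
}

#' @export
print.depth_trace <- function(x, ...) {
  cat(sprintf("<depth_trace> %d samples @ %g Hz, start %g s, max %.1f m\n",
              length(x$depth), x$sample_rate, x$start_time,
              if (length(x$depth)) max(x$depth) else NA_real_))
  invisible(x)
}

#' Apply a constant clock offset to a trace
#'
#' Shifts the trace's timestamps by a fixed number of seconds, leaving samples
#' untouched. Logger clocks drift relative to each other; in field practice the
#' streams are aligned to within about a second before matching events, and the
#' chosen offset is applied once per stream.
#'
#' @param trace An `accel_trace` or `depth_trace`.
#' @param offset_s Seconds to add to the trace's timestamps.
#' @return The shifted trace.
#' @export
apply_offset <- function(trace, offset_s) {
  if (!is.finite(offset_s)) stop("offset must be finite", call. = FALSE)
  trace$start_time <- trace$start_time + offset_s
  trace
}

#' Linearly interpolate a depth trace to a higher rate
#'
#' Upsamples a 1 Hz time-depth record to the accelerometer's rate (typically
#' 20 Hz) by linear interpolation, so both streams share one time vector.
#' Original samples are preserved exactly.
#'
#' @param depth A `depth_trace`.
#' @param target Target rate in Hz; must be an integer multiple of the source
#'   rate.
#' @return A `depth_trace` at the target rate.
#' @export
upsample_depth <- function(depth, target) {
  stopifnot(inherits(depth, "depth_trace"))
  factor <- target / depth$sample_rate
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("target rate must be an integer multiple of the source rate",
         call. = FALSE)
  factor <- round(factor)
  n <- length(depth$depth)
  if (n < 2 || factor == 1) {
    depth$sample_rate <- target
    return(depth)
  }
  t_old <- seq_len(n) - 1
  t_new <- seq(0, n - 1, by = 1 / factor)
  out <- stats::approx(t_old, depth$depth, xout = t_new)$y
  depth_trace(out, sample_rate = target, start_time = depth$start_time)
}

#' Trim two streams to their common time window
#'
#' Subsets an acceleration trace and an upsampled depth trace so both start and
#' end together on a shared time vector. Both traces must already be at the
#' same sampling rate (use [upsample_depth()] first).
#'
#' @param accel An `accel_trace`.
#' @param depth A `depth_trace` at the same rate as `accel`.
#' @param min_overlap_s Minimum acceptable common window in seconds; shorter
#'   overlaps raise an error (default 1.5, one detector variance window).
#' @return A list with elements `accel` and `depth`, trimmed.
#' @export
align_streams <- function(accel, depth, min_overlap_s = 1.5) {
  stopifnot(inherits(accel, "accel_trace"), inherits(depth, "depth_trace"))
  if (abs(accel$sample_rate - depth$sample_rate) > 1e-9)
    stop("streams must share one sampling rate; upsample depth first",
         call. = FALSE)
  fs <- accel$sample_rate
  a_t0 <- accel$start_time
  d_t0 <- depth$start_time
  a_t1 <- a_t0 + (trace_length(accel) - 1) / fs
  d_t1 <- d_t0 + (trace_length(depth) - 1) / fs
  t0 <- max(a_t0, d_t0)
  t1 <- min(a_t1, d_t1)
  if (t1 < t0) stop("streams do not overlap in time", call. = FALSE)
  if (t1 - t0 < min_overlap_s) {
    warning("common window shorter than one detector window")
    stop(sprintf("overlap of %.2f s is shorter than min_overlap_s = %g",
                 t1 - t0, min_overlap_s), call. = FALSE)
  }
  a_from <- round((t0 - a_t0) * fs) + 1
  d_from <- round((t0 - d_t0) * fs) + 1
  n_keep <- round((t1 - t0) * fs) + 1
  idx_a <- seq(a_from, length.out = n_keep)
  idx_d <- seq(d_from, length.out = n_keep)
  accel$surge <- accel$surge[idx_a]
  accel$sway <- accel$sway[idx_a]
  accel$heave <- accel$heave[idx_a]
  accel$start_time <- t0
  depth$depth <- depth$depth[idx_d]
  depth$start_time <- t0
  list(accel = accel, depth = depth)
}

#' Estimate a clock offset by cross-correlation (optional helper)
#'
#' Cross-correlates the surge axis of two acceleration traces and returns the
#' lag (seconds) that maximises their correlation. Provided as a diagnostic
#' aid only: it is never applied implicitly, because silent re-alignment would
#' hide clock problems that should be inspected.
#'
#' @param a,b `accel_trace` objects at the same rate.
#' @param max_lag_s Maximum lag to scan, in seconds.
#' @return Estimated offset in seconds (add to `b`'s timestamps to align).
#' @export
estimate_offset <- function(a, b, max_lag_s = 10) {
  stopifnot(inherits(a, "accel_trace"), inherits(b, "accel_trace"))
  fs <- a$sample_rate
  max_lag <- round(max_lag_s * fs)
  cc <- stats::ccf(a$surge, b$surge, lag.max = max_lag, plot = FALSE)
  cc$lag[which.max(cc$acf)] / fs
}
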