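#' Dive segmentation parameters
#'
#' @param min_dive_depth Minimum maximum-depth (m) for an excursion to count
#'   as a dive; default 15 m.
#' @param surface_exclusion_depth Depth (m) above which samples are treated as
#'   surface and excluded from within-dive signal analysis; default 2 m. Dive
#'   start/end are placed at the crossings of this depth.
#' @param zoc_window Window (s) for the rolling-minimum zero-offset baseline;
#'   must exceed the longest dive so each window sees true surface readings.
#' @param phase_speed_frac Fraction of a dive's peak vertical speed below which
#'   the descent is considered finished (and symmetrically for the ascent);
#'   default 0.1.
#' @return A list of class `dive_params`.
#' @export
dive_params <- function(min_dive_depth = 15, surface_exclusion_depth = 2,
                        zoc_window = 600, phase_speed_frac = 0.1) {
  if (!(min_dive_depth > surface_exclusion_depth &&
        surface_exclusion_depth > 0))
    stop("need min_dive_depth > surface_exclusion_depth > 0", call. = FALSE)
  if (zoc_window <= 0 || phase_speed_frac <= 0 || phase_speed_frac >= 1)
    stop("zoc_window must be positive and phase_speed_frac in (0,1)",
         call. = FALSE)
  structure(list(min_dive_depth = min_dive_depth,
                 surface_exclusion_depth = surface_exclusion_depth,
                 zoc_window = zoc_window,
                 phase_speed_frac = phase_speed_frac),
            class = "dive_params")
}

rolling_min <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    min(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Zero-offset correct a depth trace
#'
#' Pressure sensors drift, so raw "depth" at the surface is rarely 0 m. The
#' correction subtracts a rolling-minimum baseline over `zoc_window` seconds
#' and floors the result at 0, mapping surface intervals back to approximately
#' 0 m while preserving the ordering of depths within any window. The window
#' must be longer than the longest dive, so that every window contains at
#' least one true surface reading.
#'
#' @param depth A `depth_trace`.
#' @param zoc_window Baseline window in seconds (default 600).
#' @return A corrected `depth_trace`.
#' @export
zero_offset_correct <- function(depth, zoc_window = 600) {
  stopifnot(inherits(depth, "depth_trace"))
  if (!length(depth$depth)) return(depth)
  half <- max(1L, round(zoc_window * depth$sample_rate / 2))
  baseline <- rolling_min(depth$depth, half)
  depth$depth <- pmax(depth$depth - baseline, 0)
  depth
}

#' Find dives in a depth trace
#'
#' A dive is a depth excursion whose maximum exceeds `min_dive_depth`. Its
#' start and end are the crossings of `surface_exclusion_depth` bracketing the
#' excursion, so the dive window includes descent and ascent through shallow
#' water but excludes surface time.
#'
#' @param depth A zero-offset-corrected `depth_trace`.
#' @param params A `dive_params` object.
#' @return A data frame with one row per dive: `dive_id`, `start_s`, `end_s`,
#'   `max_depth`, `descent_end_s`, `ascent_start_s` (phase boundaries from
#'   [split_phases()]).
#' @export
find_dives <- function(depth, params = dive_params()) {
  stopifnot(inherits(depth, "depth_trace"), inherits(params, "dive_params"))
  d <- depth$depth
  t <- trace_times(depth)
  wet <- d > params$surface_exclusion_depth
  if (!any(wet)) return(empty_dive_table())
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  rows <- list()
  id <- 0L
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    if (max(d[i0:i1]) < params$min_dive_depth) next
    id <- id + 1L
    ph <- split_phases_idx(d[i0:i1], depth$sample_rate, params$phase_speed_frac)
    rows[[id]] <- data.frame(
      dive_id = id, start_s = t[i0], end_s = t[i1],
      max_depth = max(d[i0:i1]),
      descent_end_s = t[i0 + ph$descent_end - 1],
      ascent_start_s = t[i0 + ph$ascent_start - 1])
  }
  if (!id) return(empty_dive_table())
  do.call(rbind, rows)
}

empty_dive_table <- function() {
  data.frame(dive_id = integer(), start_s = numeric(), end_s = numeric(),
             max_depth = numeric(), descent_end_s = numeric(),
             ascent_start_s = numeric())
}

# Phase boundaries from vertical speed within one dive segment. Descent ends at
# the first sample where downward speed falls below phase_speed_frac of the
# dive's peak speed; ascent starts symmetrically scanning backwards. A V-dive
# collapses both boundaries onto the apex (bottom duration 0).
split_phases_idx <- function(d, fs, frac = 0.1) {
  n <- length(d)
  if (n < 3) return(list(descent_end = 1L, ascent_start = n))
  speed <- diff(d) * fs           # m/s, positive downward
  thr <- frac * max(abs(speed))
  below <- which(speed < thr)
  descent_end <- if (length(below)) below[1] else n - 1L
  neg <- which(-speed < thr)      # upward speed below threshold
  ascent_start <- if (length(neg)) neg[length(neg)] + 1L else 2L
  if (ascent_start < descent_end) {
    apex <- which.max(d)
    descent_end <- apex
    ascent_start <- apex
  }
  list(descent_end = as.integer(descent_end),
       ascent_start = as.integer(ascent_start))
}

#' Split one dive into descent, bottom and ascent phases
#'
#' Phase boundaries are found from changes in the depth slope: the descent
#' runs until vertical speed first drops below a configurable fraction of the
#' dive's peak vertical speed, the ascent is found symmetrically from the end,
#' and the bottom phase is the remainder (possibly of zero duration for a
#' V-shaped dive).
#'
#' @param dive One row of the table returned by [find_dives()].
#' @param depth The `depth_trace` the dive was found in.
#' @param phase_speed_frac Fraction of peak vertical speed (default 0.1).
#' @return A list with `descent_end_s`, `ascent_start_s`, and the three phase
#'   durations in seconds.
#' @export
split_phases <- function(dive, depth, phase_speed_frac = 0.1) {
  stopifnot(inherits(depth, "depth_trace"))
  t <- trace_times(depth)
  i0 <- which.min(abs(t - dive$start_s))
  i1 <- which.min(abs(t - dive$end_s))
  ph <- split_phases_idx(depth$depth[i0:i1], depth$sample_rate,
                         phase_speed_frac)
  de <- t[i0 + ph$descent_end - 1]
  as_ <- t[i0 + ph$ascent_start - 1]
  list(descent_end_s = de, ascent_start_s = as_,
       descent_duration = de - dive$start_s,
       bottom_duration = as_ - de,
       ascent_duration = dive$end_s - as_)
}
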