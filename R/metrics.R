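#' Error metrics from confusion counts
#'
#' Computes the three validation metrics, all in percent:
#' \describe{
#'   \item{detection}{`100 * TP / (TP + FN)` — the fraction of true APC events
#'     the detector found (sensitivity / recall).}
#'   \item{fp_rate}{`100 * FP / (FP + TP)` — the fraction of detections that
#'     were spurious. Note this is the complement of precision, not the
#'     classical specificity-based false-positive rate.}
#'   \item{precision}{`100 - fp_rate`, i.e. `100 * TP / (TP + FP)`; computed
#'     as the complement so the identity `fp_rate + precision = 100` holds
#'     exactly.}
#' }
#' An undefined denominator (no true events, or no detections) yields `NA`
#' with the reason recorded in the `reason` column — never silently 0.
#'
#' @param counts One-row data frame (or list) with `TP`, `FP`, `FN` (and
#'   optionally `TN`, unused here).
#' @return One-row data frame: `detection`, `fp_rate`, `precision`, `reason`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  reason <- ""
  if (tp + fn == 0) {
    detection <- NA_real_
    reason <- "detection undefined: no true events (TP+FN=0)"
  } else detection <- 100 * tp / (tp + fn)
  if (tp + fp == 0) {
    fp_rate <- NA_real_
    precision <- NA_real_
    reason <- paste0(reason, if (nzchar(reason)) "; ",
                     "fp_rate/precision undefined: no detections (TP+FP=0)")
  } else {
    fp_rate <- 100 * fp / (fp + tp)
    precision <- 100 - fp_rate
  }
  data.frame(detection = detection, fp_rate = fp_rate, precision = precision,
             reason = reason)
}

#' Average metrics across animals
#'
#' Unweighted mean and standard deviation across animals: the metric is first
#' computed per animal from that animal's pooled counts, then each animal
#' contributes one data point, so animals with many dives do not dominate.
#' Animals with undefined metrics are excluded and counted.
#'
#' @param per_animal Data frame with one row per animal and columns
#'   `detection`, `fp_rate`, `precision`.
#' @return Data frame with one row per metric: `metric`, `mean`, `sd`, `n`,
#'   `n_excluded`. With a single defined animal, `sd` is 0 and `n` is 1.
#' @export
aggregate_per_animal <- function(per_animal) {
  do.call(rbind, lapply(c("detection", "fp_rate", "precision"), function(m) {
    x <- per_animal[[m]]
    ok <- is.finite(x)
    n <- sum(ok)
    if (!n) return(data.frame(metric = m, mean = NA_real_, sd = NA_real_,
                              n = 0L, n_excluded = sum(!ok)))
    data.frame(metric = m, mean = mean(x[ok]),
               sd = if (n > 1) stats::sd(x[ok]) else 0,
               n = n, n_excluded = sum(!ok))
  }))
}

#' Dive-level foraging classification and its error
#'
#' A foraging dive is a dive with at least one APC (successful or
#' unsuccessful). Both sources classify every dive: the video by its
#' non-excluded events, the accelerometer by its detections. The foraging-dive
#' identification error is the relative underestimate
#' `100 * (video_foraging - accel_foraging) / video_foraging`, signed, so an
#' accelerometer overshoot reports a negative value.
#'
#' @param detections Detection table (any subset of dives).
#' @param events Video event table for the same dives.
#' @param dives Dive table; every row is classified.
#' @return A list with `table` (per-dive `dive_id`, `video_foraging`,
#'   `accel_foraging`), the two totals, and `underestimate_pct` (or
#'   [foraging_underestimate()] of the totals).
#' @export
foraging_dive_classification <- function(detections, events, dives) {
  tab <- data.frame(dive_id = dives$dive_id)
  tab$video_foraging <- vapply(tab$dive_id, function(id) {
    e <- events[events$dive_id == id, , drop = FALSE]
    identical(dive_prey_status(e), "prey_present")
  }, logical(1))
  tab$accel_foraging <- vapply(tab$dive_id, function(id)
    any(detections$dive_id == id), logical(1))
  nv <- sum(tab$video_foraging)
  na_ <- sum(tab$accel_foraging)
  list(table = tab, video_foraging = nv, accel_foraging = na_,
       underestimate_pct = foraging_underestimate(nv, na_))
}

#' Foraging-dive underestimate
#'
#' `100 * (video - accel) / video`: the percentage of video-identified
#' foraging dives that the accelerometer missed at dive level. Negative when
#' the accelerometer classifies more foraging dives than the video.
#'
#' @param video_foraging Number of foraging dives on video.
#' @param accel_foraging Number of foraging dives from the accelerometer.
#' @return Percentage, or `NA` when `video_foraging` is 0.
#' @export
foraging_underestimate <- function(video_foraging, accel_foraging) {
  if (video_foraging == 0) return(NA_real_)
  100 * (video_foraging - accel_foraging) / video_foraging
}
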