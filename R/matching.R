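#' Match detections to video events within one dive
#'
#' Implements the per-dive confusion accounting used to validate the detector
#' against annotated video. A detection matches an event when its first-peak
#' time lies within the event's `[start_s, end_s]` window. Per event, the
#' earliest matching detection is the true positive (TP); any further
#' detections matching the same event are "multiple-match" false positives
#' (FP). Detections covered by no event window are FP; events with no matching
#' detection are false negatives (FN). A dive with neither (non-excluded)
#' events nor detections contributes exactly one dive-level true negative
#' (TN); at most one TN is possible per dive.
#'
#' A detection falling inside two overlapping event windows is assigned to the
#' event whose start time is nearest (ties to the earlier event); the choice
#' is deterministic and recorded in the match records.
#'
#' @param detections Detection rows for one dive (from [detect_apc()]).
#' @param events Video event rows for the same dive; excluded categories
#'   (`chase_no_attempt`) are dropped before matching.
#' @param dive_id Dive identifier used in the records.
#' @return A list with `records` (one row per detection and per unmatched
#'   event: `dive_id`, `kind`, `time_s`, `label`, `matched_event`) and
#'   `counts` (a one-row data frame of `TP`, `FP`, `FN`, `TN`).
#' @export
match_dive <- function(detections, events, dive_id = NA) {
  if (is.null(detections)) detections <- data.frame(t_first_peak = numeric())
  if (is.null(events)) events <- data.frame(start_s = numeric(),
                                            end_s = numeric(),
                                            category = character())
  if (nrow(events) && "category" %in% names(events))
    events <- events[classify_success(events$category) != "excluded", ,
                     drop = FALSE]
  nd <- nrow(detections)
  ne <- nrow(events)
  if (ne) events <- events[order(events$start_s), , drop = FALSE]
  det_event <- rep(NA_integer_, nd)
  if (nd && ne) {
    ord <- order(detections$t_first_peak)
    for (i in ord) {
      tm <- detections$t_first_peak[i]
      inside <- which(events$start_s <= tm & tm <= events$end_s)
      if (!length(inside)) next
      if (length(inside) > 1) {
        dmin <- abs(events$start_s[inside] - tm)
        inside <- inside[order(dmin, events$start_s[inside])]
      }
      det_event[i] <- inside[1]
    }
  }
  label <- rep("FP_outside", nd)
  matched <- rep(NA_integer_, nd)
  tp_for_event <- rep(NA_integer_, ne)
  if (nd) {
    for (ev in sort(unique(det_event[!is.na(det_event)]))) {
      hits <- which(det_event == ev)
      first <- hits[which.min(detections$t_first_peak[hits])]
      label[first] <- "TP"
      label[setdiff(hits, first)] <- "FP_multiple"
      matched[hits] <- ev
      tp_for_event[ev] <- first
    }
  }
  recs <- list()
  if (nd)
    recs[[1]] <- data.frame(dive_id = dive_id, kind = "detection",
                            time_s = detections$t_first_peak,
                            label = label, matched_event = matched)
  fn_events <- which(is.na(tp_for_event))
  if (length(fn_events))
    recs[[length(recs) + 1]] <- data.frame(
      dive_id = dive_id, kind = "event", time_s = events$start_s[fn_events],
      label = "FN", matched_event = fn_events)
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(dive_id = dive_id[0], kind = character(), time_s = numeric(),
               label = character(), matched_event = integer())
  counts <- data.frame(
    TP = sum(label == "TP"),
    FP = sum(label %in% c("FP_outside", "FP_multiple")),
    FN = length(fn_events),
    TN = as.integer(nd == 0 && ne == 0))
  list(records = records, counts = counts)
}

#' Pool confusion counts over dives
#'
#' Elementwise sums of per-dive TP/FP/FN/TN, optionally per grouping key
#' (animal, axis). Dives are disjoint so counts are additive; pooling is
#' order-invariant.
#'
#' @param counts Data frame with columns `TP`, `FP`, `FN`, `TN` and optional
#'   grouping columns.
#' @param by Character vector of grouping column names (default none: one
#'   pooled row).
#' @return Data frame of summed counts.
#' @export
pool_counts <- function(counts, by = character()) {
  cols <- c("TP", "FP", "FN", "TN")
  if (!nrow(counts)) {
    out <- as.data.frame(as.list(stats::setNames(rep(0L, 4), cols)))
    return(out)
  }
  if (!length(by)) {
    return(as.data.frame(lapply(counts[cols], function(x) sum(x))))
  }
  stats::aggregate(counts[cols], by = counts[by], FUN = sum)
}

#' Match a whole deployment, dive by dive
#'
#' Convenience wrapper running [match_dive()] for every dive in a dive table
#' and binding the per-dive records and counts.
#'
#' @param detections Detection table from [detect_apc()].
#' @param events Video event table.
#' @param dives Dive table from [find_dives()]; may be restricted to a subset
#'   (e.g. the training dives) before calling.
#' @return A list with `records` and per-dive `counts` (one row per dive).
#' @export
match_deployment <- function(detections, events, dives) {
  recs <- list()
  cnts <- list()
  for (i in seq_len(nrow(dives))) {
    id <- dives$dive_id[i]
    m <- match_dive(detections[detections$dive_id == id, , drop = FALSE],
                    events[events$dive_id == id, , drop = FALSE],
                    dive_id = id)
    recs[[i]] <- m$records
    cnts[[i]] <- cbind(dive_id = id, m$counts)
  }
  list(records = if (length(recs)) do.call(rbind, recs) else NULL,
       counts = if (length(cnts)) do.call(rbind, cnts) else
         cbind(dive_id = integer(), pool_counts(data.frame())[0, ]))
}
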