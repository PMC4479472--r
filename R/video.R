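#' @name video_events
#' @title Video-annotated behavioural events
#'
#' @description
#' Ground-truth events scored from animal-borne video. Each attempted prey
#' capture (APC) directed at one prey item is annotated with a time window
#' (chase start to end of handling for captures; chase start to chase end for
#' misses) and one behavioural category:
#' `chase_missed`, `chase_capture_handling`, `chase_capture_no_handling`,
#' `capture_no_chase`, or `chase_no_attempt` (a chase that ended with the seal
#' resuming search swimming; not an APC). The on-disk schema is CSV with
#' columns `dive_id, start_s, end_s, category, prey_type, location`.
NULL

video_categories <- c("chase_missed", "chase_capture_handling",
                      "chase_capture_no_handling", "capture_no_chase",
                      "chase_no_attempt")

prey_types <- c("fish", "cephalopod", "stingray", "unknown")

#' @rdname video_events
#' @param path CSV file path.
#' @return `read_events()`: a data frame of events sorted by `start_s`.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  required <- c("dive_id", "start_s", "end_s", "category")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!"prey_type" %in% names(df)) df$prey_type <- rep("unknown", nrow(df))
  if (!"location" %in% names(df)) df$location <- rep("benthic", nrow(df))
  if (!nrow(df)) return(df[order(df$start_s), , drop = FALSE])
  bad <- which(!df$category %in% video_categories)
  if (length(bad))
    stop(sprintf("%s: unknown category '%s' at data row %d", path,
                 df$category[bad[1]], bad[1]), call. = FALSE)
  badrow <- which(!is.finite(df$start_s) | !is.finite(df$end_s) |
                    df$start_s >= df$end_s)
  if (length(badrow))
    stop(sprintf("%s: malformed event window at data row %d", path,
                 badrow[1]), call. = FALSE)
  df <- df[order(df$dive_id, df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  # overlapping windows within a dive are legitimate but worth flagging
  for (dv in unique(df$dive_id)) {
    e <- df[df$dive_id == dv, ]
    if (nrow(e) > 1 && any(e$start_s[-1] < e$end_s[-nrow(e)]))
      warning(sprintf("overlapping event windows in dive %s", dv))
  }
  df
}

#' @rdname video_events
#' @param events Event data frame.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify an event's foraging outcome
#'
#' Maps a behavioural category to `successful`, `unsuccessful`, or `excluded`.
#' A chase with a missed capture attempt is an unsuccessful APC; all
#' chase/capture/handling combinations are successful APC; chases with no
#' capture attempt are excluded from APC matching (they are treated as
#' prey-absent context, not capture attempts).
#'
#' @param category Character vector of behavioural categories.
#' @return Character vector: `"successful"`, `"unsuccessful"` or `"excluded"`.
#' @export
classify_success <- function(category) {
  bad <- setdiff(unique(category), video_categories)
  if (length(bad))
    stop(sprintf("unknown category '%s'", bad[1]), call. = FALSE)
  out <- rep("successful", length(category))
  out[category == "chase_missed"] <- "unsuccessful"
  out[category == "chase_no_attempt"] <- "excluded"
  out
}

#' Dive-level prey status from video
#'
#' A dive is `prey_present` if the video shows at least one APC (successful or
#' unsuccessful); dives with only excluded chases, or no events at all, are
#' `prey_absent`.
#'
#' @param events Events belonging to one dive (data frame, possibly empty).
#' @return `"prey_present"` or `"prey_absent"`.
#' @export
dive_prey_status <- function(events) {
  if (is.null(events) || !nrow(events)) return("prey_absent")
  if (any(classify_success(events$category) != "excluded")) "prey_present"
  else "prey_absent"
}
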