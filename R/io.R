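#' @name trace_io
#' @title Read and write sensor trace files
#'
#' @description
#' Traces are stored as plain CSV with a small self-describing metadata block
#' of `#`-prefixed header lines (`type`, `start_time`, `sample_rate`, and for
#' acceleration `clip_limit`), then a header row and one row per sample with an
#' explicit `time_s` column. The explicit time column makes files diff-friendly
#' and lets the reader verify uniform sampling: a timestamp deviating from its
#' nominal slot by more than half a sample period is reported as a gap, with
#' its line number.
#'
#' @param path File path.
#' @param trace A trace object to write.
#' @return `read_accel()` an `accel_trace`; `read_depth()` a `depth_trace`;
#'   the writers return `path` invisibly.
NULL

write_meta <- function(path, type, trace, extra = character()) {
  meta <- c("# apcr trace v1",
            sprintf("# type: %s", type),
            sprintf("# start_time: %.10g", trace$start_time),
            sprintf("# sample_rate: %.10g", trace$sample_rate),
            extra)
  writeLines(meta, path)
}

read_meta <- function(path) {
  lines <- readLines(path, n = 16L)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub(sprintf("^# %s:", key), "", m[1]))
  }
  list(type = get("type"),
       start_time = as.numeric(get("start_time")),
       sample_rate = as.numeric(get("sample_rate")),
       clip_limit = suppressWarnings(as.numeric(get("clip_limit"))),
       n_header = length(hdr))
}

read_body <- function(path, n_header, required_cols) {
  df <- tryCatch(
    utils::read.csv(path, skip = n_header, header = TRUE),
    error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in required_cols) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: malformed value in column '%s' at data line(s) %s",
                   path, col, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
  }
  df
}

check_uniform <- function(time_s, start_time, sample_rate, path) {
  nominal <- start_time + (seq_along(time_s) - 1) / sample_rate
  tol <- 0.5 / sample_rate  # half a sample period absorbs logger rounding
  bad <- which(abs(time_s - nominal) > tol)
  if (length(bad))
    stop(sprintf(
      "%s: non-uniform sampling at data row %d (time %.4f s, expected %.4f s)",
      path, bad[1], time_s[bad[1]], nominal[bad[1]]), call. = FALSE)
}

#' @rdname trace_io
#' @export
write_accel <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  extra <- if (!is.na(trace$clip_limit))
    sprintf("# clip_limit: %.10g", trace$clip_limit) else character()
  write_meta(path, "accel", trace, extra)
  df <- data.frame(time_s = trace_times(trace), surge = trace$surge,
                   sway = trace$sway, heave = trace$heave)
  suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @rdname trace_io
#' @export
read_accel <- function(path) {
  meta <- read_meta(path)
  if (!identical(meta$type, "accel"))
    stop(sprintf("%s is not an acceleration trace file", path), call. = FALSE)
  df <- read_body(path, meta$n_header, c("time_s", "surge", "sway", "heave"))
  check_uniform(df$time_s, meta$start_time, meta$sample_rate, path)
  accel_trace(df$surge, df$sway, df$heave,
              sample_rate = meta$sample_rate, start_time = meta$start_time,
              clip_limit = if (is.na(meta$clip_limit)) NA_real_ else meta$clip_limit)
}

#' @rdname trace_io
#' @export
write_depth <- function(trace, path) {
  stopifnot(inherits(trace, "depth_trace"))
  write_meta(path, "depth", trace)
  df <- data.frame(time_s = trace_times(trace), depth = trace$depth)
  suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @rdname trace_io
#' @export
read_depth <- function(path) {
  meta <- read_meta(path)
  if (!identical(meta$type, "depth"))
    stop(sprintf("%s is not a depth trace file", path), call. = FALSE)
  df <- read_body(path, meta$n_header, c("time_s", "depth"))
  check_uniform(df$time_s, meta$start_time, meta$sample_rate, path)
  depth_trace(df$depth, sample_rate = meta$sample_rate,
              start_time = meta$start_time)
}
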