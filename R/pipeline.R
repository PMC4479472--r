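#' Prepare a deployment for detection
#'
#' Standard preprocessing: zero-offset correct the depth record, upsample it
#' to the accelerometer rate, align the two streams to their common window,
#' and segment dives. The result is the unit the detector, matcher and
#' optimiser operate on.
#'
#' @param accel An `accel_trace`.
#' @param depth A `depth_trace` (native rate, e.g. 1 Hz).
#' @param events Video event table for this deployment (may be empty).
#' @param dparams [dive_params()] controlling segmentation.
#' @param animal Animal identifier carried through outputs.
#' @return A list of class `apc_deployment`: `accel`, `depth20` (aligned,
#'   upsampled, corrected depth), `dives`, `events`, `animal`.
#' @export
prepare_deployment <- function(accel, depth, events = NULL,
                               dparams = dive_params(), animal = "A1") {
  depth <- zero_offset_correct(depth, dparams$zoc_window)
  depth20 <- upsample_depth(depth, accel$sample_rate)
  al <- align_streams(accel, depth20)
  dives <- find_dives(al$depth, dparams)
  if (is.null(events))
    events <- data.frame(dive_id = integer(), start_s = numeric(),
                         end_s = numeric(), category = character(),
                         prey_type = character(), location = character())
  structure(list(accel = al$accel, depth20 = al$depth, dives = dives,
                 events = events, animal = animal),
            class = "apc_deployment")
}

#' Attach truth events of a synthetic deployment to detector dive ids
#'
#' Truth records carry the generator's dive numbering; detection and matching
#' use the dive ids found by [find_dives()]. This helper re-keys each event to
#' the segmented dive whose window contains it.
#'
#' @param events Event table with `start_s`/`end_s`.
#' @param dives Dive table from [find_dives()].
#' @return The events, `dive_id` replaced by the containing segmented dive
#'   (events outside any dive are dropped with a warning).
#' @export
rekey_events <- function(events, dives) {
  if (!nrow(events)) return(events)
  id <- vapply(seq_len(nrow(events)), function(i) {
    hit <- which(dives$start_s <= events$start_s[i] &
                   events$end_s[i] <= dives$end_s)
    if (length(hit)) dives$dive_id[hit[1]] else NA_integer_
  }, integer(1))
  if (anyNA(id)) {
    warning(sprintf("%d event(s) fall outside all segmented dives; dropped",
                    sum(is.na(id))))
    events <- events[!is.na(id), , drop = FALSE]
    id <- id[!is.na(id)]
  }
  events$dive_id <- id
  events
}

#' Simulate a cohort of animals
#'
#' Generates one synthetic deployment per animal with per-animal seeds
#' derived from `seed`, prepares each for detection, and re-keys its truth
#' events to the segmented dives. Per-animal overrides allow heterogeneous
#' cohorts (e.g. one animal with weaker bursts).
#'
#' @param n_animals Number of animals.
#' @param seed Base seed.
#' @param overrides Optional list (length `n_animals`) of lists of
#'   [sim_config()] arguments overriding the defaults for that animal.
#' @param ... Common [sim_config()] arguments for all animals.
#' @return Named list (`A1`, `A2`, ...) of prepared deployments; each carries
#'   its `sim_deployment` in `$sim`.
#' @export
simulate_cohort <- function(n_animals, seed = 1, overrides = NULL, ...) {
  common <- list(...)
  out <- list()
  for (i in seq_len(n_animals)) {
    args <- common
    if (!is.null(overrides) && length(overrides) >= i &&
        !is.null(overrides[[i]]))
      args[names(overrides[[i]])] <- overrides[[i]]
    args$seed <- seed * 1000L + i
    cfg <- do.call(sim_config, args)
    sim <- generate_deployment(cfg)
    dep <- prepare_deployment(sim$accel, sim$depth, animal = paste0("A", i))
    dep$events <- rekey_events(sim_events(sim), dep$dives)
    dep$truth <- rekey_events(sim$truth, dep$dives)
    dep$sim <- sim
    out[[paste0("A", i)]] <- dep
  }
  out
}

#' Run the full pipeline end to end
#'
#' Simulates (or loads) a cohort, segments dives, splits them into holdout
#' subsets, grid-searches the detector parameters per animal on the training
#' dives, evaluates generic and animal-specific parameters on the testing
#' dives, and writes every artifact as CSV/JSON into `out_dir`. The summary
#' table has one row per axis and parameter set with across-animal mean and
#' SD of detection, FP rate and precision.
#'
#' @param cohort Named list of prepared deployments (e.g. from
#'   [simulate_cohort()]); alternatively pass `sim_seed`/`n_animals`/`...` to
#'   simulate here.
#' @param axes Axes to analyse (default all three).
#' @param split_seed Seed for the holdout split.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param n_animals,sim_seed,... Used only when `cohort` is `NULL`.
#' @return A list: `summary` (axis x parameter-set table), `testing` (full
#'   per-animal testing metrics), `selected` (animal-specific parameters per
#'   axis), `splits`, `foraging` (dive-level foraging classification per
#'   axis, generic parameters).
#' @export
run_pipeline <- function(cohort = NULL, axes = c("surge", "sway", "heave"),
                         split_seed = 1, out_dir = NULL,
                         n_animals = 4, sim_seed = 1, ...) {
  if (is.null(cohort))
    cohort <- simulate_cohort(n_animals, seed = sim_seed, ...)
  splits <- lapply(cohort, function(dep)
    random_split(dep$dives$dive_id, 0.5, seed = split_seed))
  summary_rows <- list()
  testing_all <- list()
  selected_all <- list()
  foraging_all <- list()
  for (axis in axes) {
    gr <- grid_search(cohort, axis, splits)
    sel <- do.call(rbind, lapply(names(cohort), function(an)
      select_animal_specific(gr[gr$animal == an, ])))
    ev <- evaluate_generic_vs_specific(cohort, axis, splits, sel)
    testing_all[[axis]] <- ev
    selected_all[[axis]] <- sel
    for (set in c("generic", "animal_specific")) {
      sub <- ev[ev$parameter_set == set, ]
      agg <- aggregate_per_animal(sub)
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        axis = axis, parameter_set = set,
        detection = agg$mean[agg$metric == "detection"],
        detection_sd = agg$sd[agg$metric == "detection"],
        fp_rate = agg$mean[agg$metric == "fp_rate"],
        fp_rate_sd = agg$sd[agg$metric == "fp_rate"],
        precision = agg$mean[agg$metric == "precision"],
        precision_sd = agg$sd[agg$metric == "precision"],
        total_apc = sum(sub$n_detections))
    }
    # dive-level foraging classification on the testing subset, generic params
    vid <- 0L; acc <- 0L; tabs <- list()
    for (an in names(cohort)) {
      dep <- cohort[[an]]
      test_ids <- splits[[an]]$dive_id[splits[[an]]$subset == "testing"]
      dv <- dep$dives[dep$dives$dive_id %in% test_ids, , drop = FALSE]
      det <- detect_apc(dep$accel, dep$depth20, dep$dives,
                        detector_params(axis = axis))
      fc <- foraging_dive_classification(
        det[det$dive_id %in% test_ids, , drop = FALSE],
        dep$events[dep$events$dive_id %in% test_ids, , drop = FALSE], dv)
      vid <- vid + fc$video_foraging
      acc <- acc + fc$accel_foraging
      tabs[[an]] <- cbind(animal = an, fc$table)
    }
    foraging_all[[axis]] <- list(
      table = do.call(rbind, tabs), video_foraging = vid,
      accel_foraging = acc,
      underestimate_pct = foraging_underestimate(vid, acc))
  }
  res <- list(summary = do.call(rbind, summary_rows),
              testing = testing_all, selected = selected_all,
              splits = splits, foraging = foraging_all)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    for (axis in axes) {
      utils::write.csv(
        testing_all[[axis]][, setdiff(names(testing_all[[axis]]), "reason")],
        file.path(out_dir, sprintf("testing_%s.csv", axis)),
        row.names = FALSE)
      utils::write.csv(selected_all[[axis]][, c("animal", "axis",
                                                "variance_threshold",
                                                "min_interval")],
                       file.path(out_dir, sprintf("selected_%s.csv", axis)),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(selected_all, function(s)
        s[, c("animal", "variance_threshold", "min_interval")]),
      file.path(out_dir, "selected_params.json"), auto_unbox = TRUE,
      digits = NA)
  }
  res
}

#' Diagnostic plot of one dive
#'
#' Four stacked panels for one dive: depth, raw acceleration on the chosen
#' axis, high-pass-filtered acceleration, and moving variance with the
#' threshold, detected peaks and per-APC first-peak markers — the standard
#' visual check that detections line up with the bursts.
#'
#' @param dep An `apc_deployment`.
#' @param dive_id Which dive to draw.
#' @param params [detector_params()].
#' @export
plot_dive_diagnostic <- function(dep, dive_id, params = detector_params()) {
  dv <- dep$dives[dep$dives$dive_id == dive_id, ]
  if (!nrow(dv)) stop("no such dive", call. = FALSE)
  fs <- dep$accel$sample_rate
  t <- trace_times(dep$accel)
  idx <- which(t >= dv$start_s & t <= dv$end_s)
  raw <- dep$accel[[params$axis]]
  filt <- highpass(raw, fs, params$cutoff)
  v <- moving_variance(filt[idx], round(params$variance_window * fs))
  det <- detect_apc(dep$accel, dep$depth20, dv, params)
  op <- graphics::par(mfrow = c(4, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(t[idx], -dep$depth20$depth[idx], type = "l", ylab = "depth (m)")
  plot(t[idx], raw[idx], type = "l", ylab = sprintf("%s (g)", params$axis))
  plot(t[idx], filt[idx], type = "l", ylab = "filtered (g)")
  plot(t[idx], v, type = "l", ylab = "variance (g^2)")
  graphics::abline(h = params$variance_threshold, lty = 2)
  if (nrow(det))
    graphics::points(det$t_first_peak, rep(params$variance_threshold,
                                           nrow(det)), pch = 17, col = 2)
  invisible(det)
}
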