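#' Random 50/50 holdout split of dives
#'
#' Assigns every dive to a training or testing subset by a seeded balanced
#' random draw: `round(n * proportion)` dives are sampled without replacement
#' into training, the remainder into testing. Each dive appears exactly once.
#' On cohorts of a few dozen dives this keeps realized training proportions
#' within a couple of percent of the target, matching the 48-53% realized
#' range typical of field holdouts after exclusions.
#'
#' @param dive_ids Vector of dive identifiers (>= 2).
#' @param proportion Target training fraction (default 0.5).
#' @param seed Integer seed; the assignment is reproducible.
#' @return A data frame `dive_id`, `subset` (`"training"`/`"testing"`), with
#'   attribute `seed`.
#' @export
random_split <- function(dive_ids, proportion = 0.5, seed = 1) {
  n <- length(dive_ids)
  if (n < 2) stop("need at least 2 dives to split", call. = FALSE)
  if (anyDuplicated(dive_ids)) stop("dive ids must be unique", call. = FALSE)
  set.seed(seed)
  n_train <- round(n * proportion)
  n_train <- min(max(n_train, 1L), n - 1L)
  train <- sample(dive_ids, n_train)
  out <- data.frame(dive_id = dive_ids,
                    subset = ifelse(dive_ids %in% train, "training",
                                    "testing"))
  attr(out, "seed") <- seed
  out
}

#' Default optimisation grids
#'
#' Variance thresholds 0.1/0.2/0.4/0.8 g^2 crossed with minimum intervals
#' 5/10/20 s for surge and sway; the heave axis carries lower-amplitude
#' signal, so its threshold grid is reduced to 0.1/0.2/0.4.
#'
#' @param axis `"surge"`, `"sway"` or `"heave"`.
#' @return Data frame `variance_threshold`, `min_interval`.
#' @export
default_grid <- function(axis = "surge") {
  axis <- match.arg(axis, c("surge", "sway", "heave"))
  thresholds <- if (axis == "heave") c(0.1, 0.2, 0.4)
    else c(0.1, 0.2, 0.4, 0.8)
  expand.grid(variance_threshold = thresholds, min_interval = c(5, 10, 20))
}

# Run detect + match + pool + metrics for one animal's deployment restricted
# to a dive subset, at one parameter point.
eval_params <- function(dep, axis, variance_threshold, min_interval,
                        dive_subset = NULL) {
  dives <- dep$dives
  if (!is.null(dive_subset))
    dives <- dives[dives$dive_id %in% dive_subset, , drop = FALSE]
  par <- detector_params(axis = axis,
                         variance_threshold = variance_threshold,
                         min_interval = min_interval)
  det <- detect_apc(dep$accel, dep$depth20, dep$dives, par)
  det <- det[det$dive_id %in% dives$dive_id, , drop = FALSE]
  ev <- dep$events[dep$events$dive_id %in% dives$dive_id, , drop = FALSE]
  m <- match_deployment(det, ev, dives)
  pooled <- pool_counts(m$counts)
  cbind(compute_metrics(pooled), pooled, n_detections = nrow(det))
}

#' Grid search of detector parameters on the training subset
#'
#' For every grid point and every animal, runs the full detect/match/metrics
#' pipeline on that animal's training dives and records the error metrics
#' with the pooled confusion counts. Counts are pooled per animal before the
#' metric is computed (counts-first pooling), so each animal yields one
#' metric per grid point.
#'
#' @param cohort Named list of prepared deployments (see
#'   [prepare_deployment()]), one per animal.
#' @param axis Acceleration axis.
#' @param split Named list of split assignments from [random_split()], one
#'   per animal (or a single assignment reused for all).
#' @param grid Data frame of grid points; defaults to [default_grid()].
#' @return Data frame: `animal`, `axis`, `variance_threshold`,
#'   `min_interval`, metrics and counts, tagged `subset = "training"`.
#' @export
grid_search <- function(cohort, axis, split, grid = NULL) {
  if (is.null(grid)) grid <- default_grid(axis)
  if (!is.null(split$dive_id)) split <- stats::setNames(
    rep(list(split), length(cohort)), names(cohort))
  out <- list()
  for (an in names(cohort)) {
    train_ids <- split[[an]]$dive_id[split[[an]]$subset == "training"]
    for (g in seq_len(nrow(grid))) {
      res <- eval_params(cohort[[an]], axis,
                         grid$variance_threshold[g], grid$min_interval[g],
                         dive_subset = train_ids)
      out[[length(out) + 1]] <- cbind(
        animal = an, axis = axis,
        variance_threshold = grid$variance_threshold[g],
        min_interval = grid$min_interval[g], res, subset = "training")
    }
  }
  do.call(rbind, out)
}

#' Select animal-specific detector parameters
#'
#' The selection rule: take the grid points whose training detection rate is
#' within `tie_window` percentage points of the maximum (default 2, i.e. 95%
#' ties with 97%), and among those pick the one with the highest precision
#' (equivalently, lowest FP rate). Any residual tie is broken by the lower
#' variance threshold, then the shorter minimum interval — the most sensitive
#' setting.
#'
#' @param results Grid-search rows for one animal and one axis.
#' @param tie_window Detection tie window in absolute percentage points
#'   (default 2).
#' @return One row of `results`: the selected parameters.
#' @export
select_animal_specific <- function(results, tie_window = 2) {
  ok <- is.finite(results$detection)
  if (!any(ok))
    stop("no grid point has a defined detection rate", call. = FALSE)
  res <- results[ok, , drop = FALSE]
  best <- max(res$detection)
  cand <- res[res$detection >= best - tie_window, , drop = FALSE]
  prec <- cand$precision
  prec[!is.finite(prec)] <- -Inf
  cand <- cand[order(-prec, cand$variance_threshold, cand$min_interval), ,
               drop = FALSE]
  cand[1, , drop = FALSE]
}

#' Evaluate generic vs animal-specific parameters on the testing subset
#'
#' Both parameterizations are run on the identical testing dives — never the
#' training dives that chose the animal-specific parameters — and the
#' per-animal metrics are reported side by side with their paired
#' differences.
#'
#' @param cohort Named list of prepared deployments.
#' @param axis Acceleration axis.
#' @param split Split assignment(s) from [random_split()].
#' @param specific Named list (per animal) of rows from
#'   [select_animal_specific()], or a data frame with `animal`,
#'   `variance_threshold`, `min_interval`.
#' @param generic Generic parameters, default `c(variance_threshold = 0.1,
#'   min_interval = 5)`.
#' @return Data frame with one row per animal x parameter-set, tagged
#'   `subset = "testing"`, plus attribute `paired` holding per-animal
#'   generic-minus-specific differences.
#' @export
evaluate_generic_vs_specific <- function(cohort, axis, split, specific,
                                         generic = c(variance_threshold = 0.1,
                                                     min_interval = 5)) {
  if (!is.null(split$dive_id)) split <- stats::setNames(
    rep(list(split), length(cohort)), names(cohort))
  if (is.data.frame(specific))
    specific <- split(specific, specific$animal)
  out <- list()
  for (an in names(cohort)) {
    test_ids <- split[[an]]$dive_id[split[[an]]$subset == "testing"]
    sp <- specific[[an]]
    for (set in c("generic", "animal_specific")) {
      vt <- if (set == "generic") generic[["variance_threshold"]]
        else sp$variance_threshold[1]
      mi <- if (set == "generic") generic[["min_interval"]]
        else sp$min_interval[1]
      res <- eval_params(cohort[[an]], axis, vt, mi, dive_subset = test_ids)
      out[[length(out) + 1]] <- cbind(
        animal = an, axis = axis, parameter_set = set,
        variance_threshold = vt, min_interval = mi, res, subset = "testing")
    }
  }
  out <- do.call(rbind, out)
  g <- out[out$parameter_set == "generic", ]
  s <- out[out$parameter_set == "animal_specific", ]
  paired <- data.frame(
    animal = g$animal,
    d_detection = g$detection - s$detection[match(g$animal, s$animal)],
    d_fp_rate = g$fp_rate - s$fp_rate[match(g$animal, s$animal)],
    identical_params =
      g$variance_threshold == s$variance_threshold[match(g$animal, s$animal)] &
      g$min_interval == s$min_interval[match(g$animal, s$animal)])
  attr(out, "paired") <- paired
  out
}
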