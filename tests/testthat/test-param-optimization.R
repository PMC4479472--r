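# one small cohort shared across the blocks in this file
cohort2 <- NULL
get_cohort2 <- function() {
  if (is.null(cohort2))
    cohort2 <<- simulate_cohort(2, seed = 31, n_dives = 6)
  cohort2
}

test_that("the holdout split is a reproducible exact partition", {
  ids <- paste0("d", 1:10)
  s1 <- random_split(ids, seed = 99)
  s2 <- random_split(ids, seed = 99)
  expect_identical(s1, s2)
  expect_false(identical(s1$subset, random_split(ids, seed = 100)$subset))
  expect_setequal(s1$dive_id, ids)
  expect_equal(sum(duplicated(s1$dive_id)), 0)
  expect_true(all(s1$subset %in% c("training", "testing")))
  expect_error(random_split("only_one"), "at least 2")
})

test_that("realized training proportions stay near 50% at field cohort sizes", {
  for (n in c(32, 36, 48, 77, 97)) {
    for (seed in 1:20) {
      s <- random_split(seq_len(n), 0.5, seed = seed)
      frac <- mean(s$subset == "training")
      expect_gte(frac, 0.48)
      expect_lte(frac, 0.53)
    }
  }
})

test_that("grid search covers the full grid per animal and axis", {
  cohort <- get_cohort2()
  split <- lapply(cohort, function(d) random_split(d$dives$dive_id, seed = 7))
  gr <- grid_search(cohort, "surge", split)
  expect_equal(nrow(gr), 12 * 2)  # 4 thresholds x 3 intervals x 2 animals
  gr_h <- grid_search(cohort, "heave", split)
  expect_equal(nrow(gr_h), 9 * 2)  # reduced heave threshold grid
  expect_true(all(gr$subset == "training"))

  # a single-point grid equals a direct pipeline run
  g1 <- grid_search(cohort["A1"], "surge", split["A1"],
                    grid = data.frame(variance_threshold = 0.1,
                                      min_interval = 5))
  direct <- gr[gr$animal == "A1" & gr$variance_threshold == 0.1 &
                 gr$min_interval == 5, ]
  expect_equal(g1$detection, direct$detection)
  expect_equal(g1$TP, direct$TP)
})

test_that("the 2% tie rule prefers precision inside the window", {
  res <- data.frame(variance_threshold = c(0.1, 0.2),
                    min_interval = c(5, 5),
                    detection = c(97, 95.5), precision = c(40, 55))
  pick <- select_animal_specific(res)
  expect_equal(pick$detection, 95.5)  # within 2%, higher precision wins

  out <- data.frame(variance_threshold = c(0.1, 0.2),
                    min_interval = c(5, 5),
                    detection = c(97, 90), precision = c(40, 80))
  expect_equal(select_animal_specific(out)$detection, 97)

  single <- res[1, ]
  expect_equal(select_animal_specific(single)$detection, 97)

  # invariant to result ordering
  expect_equal(select_animal_specific(res[2:1, ])$detection, 95.5)

  # residual tie -> lower threshold, then shorter interval
  tie <- data.frame(variance_threshold = c(0.2, 0.1, 0.1),
                    min_interval = c(5, 10, 5),
                    detection = c(96, 96, 96), precision = c(70, 70, 70))
  pick2 <- select_animal_specific(tie)
  expect_equal(pick2$variance_threshold, 0.1)
  expect_equal(pick2$min_interval, 5)

  allna <- data.frame(variance_threshold = 0.1, min_interval = 5,
                      detection = NA_real_, precision = NA_real_)
  expect_error(select_animal_specific(allna), "no grid point")
})

test_that("optimizer recovers the most sensitive parameters on clean data", {
  cohort <- get_cohort2()
  split <- lapply(cohort, function(d) random_split(d$dives$dive_id, seed = 3))
  gr <- grid_search(cohort, "surge", split)
  for (an in names(cohort)) {
    pick <- select_animal_specific(gr[gr$animal == an, ])
    expect_equal(pick$variance_threshold, 0.1)
    expect_equal(pick$min_interval, 5)
  }
})

test_that("generic vs specific evaluation uses testing dives only", {
  cohort <- get_cohort2()
  split <- lapply(cohort, function(d) random_split(d$dives$dive_id, seed = 3))
  gr <- grid_search(cohort, "surge", split)
  sel <- do.call(rbind, lapply(names(cohort), function(an)
    cbind(animal = an, select_animal_specific(gr[gr$animal == an, ]))))
  ev <- evaluate_generic_vs_specific(cohort, "surge", split, sel)
  expect_true(all(ev$subset == "testing"))
  # counts must come from the testing dives alone
  for (an in names(cohort)) {
    test_ids <- split[[an]]$dive_id[split[[an]]$subset == "testing"]
    n_ev <- sum(cohort[[an]]$events$dive_id %in% test_ids)
    row <- ev[ev$animal == an & ev$parameter_set == "generic", ]
    expect_equal(row$TP + row$FN, n_ev)
  }
  # identical parameters -> exactly zero paired difference
  paired <- attr(ev, "paired")
  expect_true(all(paired$identical_params))
  expect_true(all(paired$d_detection == 0))
  expect_true(all(paired$d_fp_rate == 0))
})

test_that("a weak-burst animal selects a threshold no higher than generic", {
  cohort <- simulate_cohort(2, seed = 41, n_dives = 5,
                            overrides = list(NULL, list(apc_amplitude = 0.7)))
  split <- lapply(cohort, function(d) random_split(d$dives$dive_id, seed = 5))
  gr <- grid_search(cohort, "surge", split)
  weak <- select_animal_specific(gr[gr$animal == "A2", ])
  expect_lte(weak$variance_threshold, 0.1)
  strong_det <- gr[gr$animal == "A2" & gr$variance_threshold == 0.1 &
                     gr$min_interval == 5, "detection"]
  high_det <- gr[gr$animal == "A2" & gr$variance_threshold == 0.8 &
                   gr$min_interval == 5, "detection"]
  expect_gte(strong_det, high_det)
})
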