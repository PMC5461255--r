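test_that("generation is deterministic under a fixed config and seed", {
  cfg <- generator_config(seed = 101)
  expect_identical(generate_battery(cfg), generate_battery(cfg))
  tr1 <- generate_trial_records(cfg)
  tr2 <- generate_trial_records(cfg)
  expect_identical(tr1, tr2)
  # trial-record generation starts from the same battery draw
  expect_identical(tr1$battery, generate_battery(cfg))
})

test_that("invalid configurations are rejected with informative messages", {
  bad <- default_latent_loadings()
  bad["TRT"] <- 1.2
  expect_error(generator_config(latent_loadings = bad), "invalid loading.*TRT")
  expect_error(generator_config(floor_mass = 1), "floor_mass")
  sds <- table1_calibration()$sds
  sds$young["WST"] <- 0
  expect_error(generator_config(group_sds = sds), "positive")
  expect_error(generator_config(n_young = 1), "at least 2")
  expect_error(generator_config(response_bounds = c(7, 0)), "ordered")
})

test_that("zero loadings give null predictor-response correlations", {
  cfg <- zero_signal_config(seed = 7, n_young = 400, n_old = 400)
  d <- generate_battery(cfg)
  # within one group (pooling the two calibrated groups would reintroduce
  # a between-group mean correlation even with zero loadings)
  young <- d$age_group == "young"
  n <- sum(young)
  r <- cor(as.matrix(d[young, battery_variables()]), d$y_median[young])
  # Bonferroni-widened null band across the 13 predictors
  expect_true(all(abs(r) < 4 / sqrt(n)))
})

test_that("sample correlation converges to the closed-form latent-model value", {
  # corr(x_j, y) = lambda_j * beta when predictor and response carry unit
  # total variance by construction; verified by Monte Carlo at n = 1e5.
  # Wide response bounds neutralize clipping so the closed form is exact.
  lam <- setNames(numeric(13), battery_variables())
  lam["TRT"] <- 0.6
  cfg <- generator_config(n_young = 100000, n_old = 2, latent_loadings = lam,
                          response_loading = 0.8, floor_mass = 0,
                          response_bounds = c(-1000, 1000), seed = 31)
  d <- generate_battery(cfg)
  young <- d$age_group == "young"
  r <- cor(d$TRT[young], d$y_median[young])
  expect_equal(r, 0.6 * 0.8, tolerance = 0.02)
})

test_that("marginal group means and SDs match the calibration", {
  reps <- 120
  stats <- vapply(seq_len(reps), function(k) {
    d <- generate_battery(generator_config(seed = 5000 + k))
    old <- d$age_group == "old"
    c(mean(d$TRT[old]), sd(d$TRT[old]), mean(d$OperationSpan[!old]))
  }, numeric(3))
  cal <- table1_calibration()
  se <- apply(stats, 1, sd) / sqrt(reps)
  expect_lt(abs(mean(stats[1, ]) - cal$means$old[["TRT"]]), 3 * se[1])
  expect_lt(abs(mean(stats[2, ]) - cal$sds$old[["TRT"]]), 3 * se[2])
  expect_lt(abs(mean(stats[3, ]) - cal$means$young[["OperationSpan"]]), 3 * se[3])
})

test_that("responses live on the half-integer lattice within bounds", {
  d <- generate_battery(generator_config(seed = 17))
  expect_true(all(d$y_median >= 0 & d$y_median <= 7))
  expect_true(all(d$y_median * 2 == round(d$y_median * 2)))
})

test_that("floor inflation produces zero-score subjects without biasing the mean", {
  reps <- 150
  res <- vapply(seq_len(reps), function(k) {
    d <- generate_battery(generator_config(seed = 9000 + k, floor_mass = 0.3))
    c(mean(d$y_median[d$age_group == "young"] == 0),
      mean(d$y_median[d$age_group == "young"]))
  }, numeric(2))
  expect_gt(mean(res[1, ]), 0.25)          # floor mass plus natural zeros
  se <- sd(res[2, ]) / sqrt(reps)
  expect_lt(abs(mean(res[2, ]) - 4.40), 3 * se)
})

test_that("trial records form six blocks of ten with medians matching the battery", {
  tr <- generate_trial_records(generator_config(seed = 23))
  per <- table(tr$trials$subject_id)
  expect_true(all(per == 60))
  expect_identical(sort(unique(tr$trials$block)), 1:6)
  expect_true(all(table(tr$trials$subject_id, tr$trials$block) == 10))
  med <- median_performance(tr$trials)
  expect_equal(unname(med[tr$battery$subject_id]), tr$battery$y_median)
})

test_that("trial scores saturate at the response bounds", {
  set.seed(1)
  hi <- vocopred:::.draw_trials(7)
  expect_equal(median(hi), 7)
  expect_true(all(hi >= 0 & hi <= 7))
  lo <- vocopred:::.draw_trials(0)
  expect_equal(median(lo), 0)
})

test_that("derived predictors round-trip through the raw records", {
  tr <- generate_trial_records(generator_config(seed = 41))
  derived <- derive_predictors(tr$raw)
  batt <- tr$battery
  # raw records are integer counts clamped to feasible test ranges; skip
  # the subjects whose Gaussian battery draw fell outside them
  t7_unclamped <- tr$raw$vlrt_t5 + round(batt$Recall)
  feasible <- batt$TRT >= 0 & batt$WST >= 0 & batt$WST <= 42 &
    batt$OperationSpan >= 0 & batt$Verbal_learning >= 0 &
    batt$Verbal_learning <= 75 & batt$Recognition >= -0.5 &
    batt$Recognition <= 15.49 & t7_unclamped >= 0 & t7_unclamped <= 15
  feasible[is.na(feasible)] <- FALSE
  expect_gt(sum(feasible), 15)
  counts <- c("TRT", "WST", "OperationSpan", "Verbal_learning", "Recall",
              "Recognition")
  for (v in counts) {
    expect_true(all(abs(derived[[v]][feasible] - batt[[v]][feasible]) <= 1.01),
                info = v)
  }
  rts <- setdiff(battery_variables(), counts)
  for (v in rts) {
    expect_equal(derived[[v]], batt[[v]], tolerance = 1e-12, info = v)
  }
})

test_that("missing Operation Span subjects shrink the analysis view", {
  cfg <- generator_config(seed = 3, n_ospan_missing_old = 2)
  d <- generate_battery(cfg)
  expect_equal(sum(is.na(d$OperationSpan)), 2)
  v <- validate_dataset(d)
  expect_equal(nrow(v), nrow(d) - 2)
  expect_equal(nrow(attr(v, "excluded")), 2)
  expect_match(attr(v, "excluded")$reason, "OperationSpan")
})

test_that("battery CSV and config YAML round-trip", {
  cfg <- generator_config(seed = 77)
  d <- generate_battery(cfg)
  f <- tempfile(fileext = ".csv")
  write_battery(d, f)
  d2 <- read_battery(f)
  expect_equal(d2$y_median, d$y_median)
  expect_equal(d2$TRT, d$TRT, tolerance = 1e-12)

  yml <- tempfile(fileext = ".yaml")
  write_generator_config(cfg, yml)
  expect_identical(read_generator_config(yml), cfg)
})

test_that("the bundled calibration file equals the package defaults", {
  path <- system.file("extdata", "table1_calibration.yaml",
                      package = "vocopred")
  expect_identical(read_generator_config(path), generator_config())
})
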