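test_that("the null-model prediction for each fold is the leave-one-out mean", {
  pr <- random_problem(12, 5, seed = 20)
  cv <- loocv_with_selection(pr$X, pr$y, j = 3, n_perm = 0)
  for (i in 1:12) {
    expect_equal(unname(cv$predictions[i, "null"]), mean(pr$y[-i]))
  }
})

test_that("nested selection CV matches an independently coded naive loop", {
  pr <- random_problem(12, 5, seed = 21)
  cv <- loocv_with_selection(pr$X, pr$y, j = 3, n_perm = 0)
  oracle <- oracle_loocv_selection(pr$X, pr$y, j = 3)
  expect_equal(unname(cv$predictions), unname(oracle$predictions),
               tolerance = 1e-12)
  expect_identical(cv$selected, oracle$selected)
  # j = p reduces to LOOCV without selection
  cvp <- loocv_with_selection(pr$X, pr$y, j = 5, n_perm = 0)
  op <- oracle_loocv_selection(pr$X, pr$y, j = 5)
  expect_equal(unname(cvp$predictions), unname(op$predictions),
               tolerance = 1e-12)
  expect_true(all(vapply(cvp$selected, setequal, TRUE, colnames(pr$X))))
})

test_that("selection CV validates its inputs", {
  pr <- random_problem(10, 4, seed = 22)
  expect_error(loocv_with_selection(pr$X, pr$y, j = 1), "2 <= j <= p")
  expect_error(loocv_with_selection(pr$X, pr$y, j = 5), "2 <= j <= p")
  expect_error(loocv_with_selection(pr$X[1:3, ], pr$y[1:3], j = 2),
               "at least 4")
  Xc <- pr$X; Xc[, 2] <- 1
  expect_error(loocv_with_selection(Xc, pr$y, j = 2), "zero-variance|degenerate")
})

test_that("VIP ranking is deterministic and consistent with vip()", {
  pr <- random_problem(15, 6, seed = 23)
  rk <- rank_by_vip(pr$X, pr$y)
  v <- vip(pls_fit(pr$X, pr$y, ncomp = 2))
  expect_identical(rk, names(sort(-v)))
  expect_setequal(rank_by_vip(pr$X[, 1:2], pr$y), colnames(pr$X)[1:2])
  # strong signal variables occupy the top ranks
  d <- generate_battery(strong_signal_config(seed = 5))
  top <- rank_by_vip(d[battery_variables()], d$y_median)[1:5]
  expect_setequal(top, signal_variables(strong_signal_config(seed = 5)))
})

test_that("the sign-flip permutation test behaves at its boundaries", {
  set.seed(24)
  e <- rnorm(20)
  same <- paired_permutation_test(e, e, n_perm = 499, seed = 1)
  expect_gte(same$p_value, 0.5)
  expect_equal(same$statistic, 0)
  # p never drops below 1/(B+1), even for an overwhelming improvement
  strong <- paired_permutation_test(rep(0.01, 20), rep(5, 20),
                                    n_perm = 499, seed = 2)
  expect_gte(strong$p_value, 1 / 500)
  expect_lte(strong$p_value, 3 / 500)
  expect_identical(paired_permutation_test(e, e + 1, 99, seed = 3),
                   paired_permutation_test(e, e + 1, 99, seed = 3))
  expect_error(paired_permutation_test(e, e[-1]), "equal length")
})

test_that("msep and rmsep match their definitions", {
  y <- c(1, 2, 3, 4)
  expect_equal(msep(y, y), 0)
  pred <- rep(mean(y), 4)
  expect_equal(msep(pred, y), mean((y - mean(y))^2))  # variance-style oracle
  expect_equal(rmsep(pred, y)^2, msep(pred, y))
})

test_that("the sweep table is consistent with standalone runs", {
  pr <- random_problem(14, 6, seed = 25)
  sw <- sweep_variable_counts(pr$X, pr$y, j_range = 2:6, n_perm = 199,
                              seed = 50)
  expect_equal(nrow(sw), 5)
  expect_equal(sw$j, 2:6)
  k <- 2                                  # row for j = 3
  alone <- loocv_with_selection(pr$X, pr$y, j = 3, n_perm = 199,
                                seed = 50 + 10L * k)
  expect_equal(sw$msep_comp1[k], alone$msep[["comp1"]])
  expect_equal(sw$p_comp1[k], alone$p_comp1)
  expect_equal(sw$p_comp2[k], alone$p_comp2)
})

test_that("subgroup tests restrict errors but reuse whole-sample predictions", {
  d <- generate_battery(strong_signal_config(seed = 26))
  X <- d[battery_variables()]
  cv <- loocv_with_selection(X, d$y_median, j = 6, n_perm = 499, seed = 9,
                             groups = d$age_group)
  gt <- cv$group_tests
  expect_setequal(gt$group, c("young", "old"))
  expect_equal(gt$n[gt$group == "young"], c(21, 21))
  # union of groups reproduces the whole-sample test
  single <- subgroup_tests(cv, factor(rep("all", 41)), n_perm = 499, seed = 11)
  whole <- paired_permutation_test(d$y_median - cv$predictions[, "comp1"],
                                   d$y_median - cv$predictions[, "null"],
                                   n_perm = 499, seed = 11)
  expect_equal(single$p_value[single$comparison == "comp1_vs_null"],
               whole$p_value)
  # oracle subsetting: recompute one group by hand
  idx <- d$age_group == "old"
  byhand <- paired_permutation_test(
    (d$y_median - cv$predictions[, "comp1"])[idx],
    (d$y_median - cv$predictions[, "null"])[idx], n_perm = 499, seed = 13)
  again <- subgroup_tests(cv, d$age_group, n_perm = 499, seed = 13)
  expect_equal(again$p_value[again$group == "old" &
                               again$comparison == "comp1_vs_null"],
               byhand$p_value)
  expect_error(subgroup_tests(cv, factor(c("a", rep("b", 40)))),
               "fewer than 2")
})

test_that("final evaluation approaches r = 1 on noiseless data and is affine-invariant", {
  set.seed(27)
  X <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- 2 + 3 * X[, 1]
  fe <- evaluate_final(X, y, c("v1", "v2"), n_perm = 99, seed = 1)
  # the 2-component model on 2 predictors is full OLS: exact recovery
  expect_gt(fe$r[["comp2"]], 0.99)
  y2 <- 10 - 0 * y + 4 * y                 # affine transform of y
  fe2 <- evaluate_final(X, y2, c("v1", "v2"), n_perm = 0)
  expect_equal(fe2$r, fe$r, tolerance = 1e-8)
  # naive per-fold oracle for the out-of-fold predictions
  for (i in c(1, 7, 20)) {
    fit <- pls_fit(X[-i, c("v1", "v2")], y[-i], ncomp = 2)
    expect_equal(unname(fe$predictions[i, "comp2"]),
                 predict(fit, X[i, c("v1", "v2"), drop = FALSE], ncomp = 2),
                 tolerance = 1e-10)
    expect_equal(unname(fe$predictions[i, "null"]), mean(y[-i]))
  }
  expect_true(all(fe$p_value >= 1 / 100 & fe$p_value <= 1))
})

test_that("univariate correlations match the closed-form Pearson oracle", {
  set.seed(28)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "y2")))
  y <- X[, 1] * 0.5 + rnorm(30)
  X[, "y2"] <- y                            # self-correlation column
  uc <- univariate_correlations(X, y, n_perm = 199, seed = 5)
  for (k in 1:3) {
    num <- sum((X[, k] - mean(X[, k])) * (y - mean(y)))
    den <- sqrt(sum((X[, k] - mean(X[, k]))^2) * sum((y - mean(y))^2))
    expect_equal(uc$r[k], num / den, tolerance = 1e-12)
  }
  expect_equal(uc$r[uc$variable == "y2"], 1)
  Xf <- X; Xf[, "a"] <- -Xf[, "a"]
  ucf <- univariate_correlations(Xf, y, n_perm = 0)
  expect_equal(ucf$r[ucf$variable == "a"], -uc$r[uc$variable == "a"])
})

test_that("exhaustive subset regression enumerates and scores subsets exactly", {
  set.seed(29)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1.5 * X[, "b"]
  tab <- exhaustive_subset_regression(X, y, max_size = 3)
  expect_equal(nrow(tab), 7)                # 2^3 - 1 subsets
  # noiseless signal: every subset containing b has (numerically) zero error
  expect_true(grepl("b", tab$subset[1], fixed = TRUE))
  expect_lt(tab$msep[1], 1e-20)
  # naive refit oracle for one subset
  s <- c("a", "c")
  loo <- vapply(1:20, function(i) {
    fit <- lm(y[-i] ~ X[-i, s])
    y[i] - (coef(fit)[1] + sum(coef(fit)[-1] * X[i, s]))
  }, 0)
  expect_equal(tab$msep[tab$subset == "a + c"], mean(loo^2),
               tolerance = 1e-10)
})

test_that("zero-score exclusion reruns report removal counts and overlap", {
  d <- generate_battery(strong_signal_config(seed = 30))
  d$y_median[d$y_median == 0] <- 0.5        # force a no-zero dataset
  res <- rerun_excluding_zero_scores(d, sweep = c(2, 6), n_perm = 99, seed = 2)
  expect_equal(res$n_removed, 0)
  expect_identical(res$selected_primary, res$selected_rerun)
  d$y_median[1:4] <- 0
  res2 <- rerun_excluding_zero_scores(d, sweep = c(2, 6), n_perm = 99, seed = 2)
  expect_equal(res2$n_removed, 4)
  expect_equal(res2$rerun$n, nrow(d) - 4)
  expect_identical(res2$overlap,
                   intersect(res2$selected_primary, res2$selected_rerun))
})
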