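#' Rank predictors by VIP from a full preliminary model
#'
#' Fits a preliminary PLS model with \code{ncomp} components on all
#' supplied variables and returns them ordered by descending VIP.  Ties
#' are broken by canonical (column) order, so the ranking is
#' deterministic.
#'
#' @param X Predictor matrix or data frame.
#' @param y Response vector.
#' @param ncomp Components of the preliminary model (default 2).
#' @param scale Standardize predictors (default TRUE).
#' @return Character vector of variable names, most important first.
#' @export
rank_by_vip <- function(X, y, ncomp = 2, scale = TRUE) {
  fit <- pls_fit(X, y, ncomp = ncomp, scale = scale)
  v <- vip(fit)
  names(v)[order(-v)]            # order() is stable: ties keep column order
}

#' Mean squared error of prediction
#'
#' @param predictions Out-of-fold predictions.
#' @param y Observed response.
#' @return \code{msep}: mean of squared prediction errors; \code{rmsep}:
#'   its square root.
#' @export
msep <- function(predictions, y) mean((predictions - y)^2)

#' @rdname msep
#' @export
rmsep <- function(predictions, y) sqrt(msep(predictions, y))

#' Paired permutation test on squared prediction errors
#'
#' Tests whether a candidate model predicts better than a reference model
#' from the same cross-validation folds.  The statistic is the mean of the
#' paired differences \eqn{d_i = e_{ref,i}^2 - e_{cand,i}^2} (positive
#' when the candidate is better); the null distribution is generated by
#' independent random sign flips of the \eqn{d_i}, and the one-sided
#' p-value is \code{(# permuted >= observed + 1) / (n_perm + 1)}.
#'
#' @param err_candidate,err_reference Paired prediction errors (observed
#'   minus predicted) of the two models; squared internally.
#' @param n_perm Number of sign-flip randomizations (default 10000).
#' @param seed Optional integer seed.
#' @return List with \code{statistic} (observed mean difference),
#'   \code{p_value} and \code{n_perm}.
#' @export
paired_permutation_test <- function(err_candidate, err_reference,
                                    n_perm = 10000, seed = NULL) {
  if (length(err_candidate) != length(err_reference)) {
    .stopf("error vectors must have equal length")
  }
  d <- err_reference^2 - err_candidate^2
  n <- length(d)
  obs <- mean(d)
  .with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    perm <- drop(signs %*% d) / n
    list(statistic = obs,
         p_value = (sum(perm >= obs) + 1) / (n_perm + 1),
         n_perm = n_perm)
  })
}

# center/scale a training block; errors on degenerate variance
.scale_train <- function(X) {
  ctr <- colMeans(X)
  sds <- .col_sds(X)
  if (any(sds < 1e-12)) {
    .stopf("degenerate training variance in variable(s): %s",
           paste(colnames(X)[sds < 1e-12], collapse = ", "))
  }
  list(ctr = ctr, sds = sds,
       Xs = sweep(sweep(X, 2, ctr), 2, sds, "/"))
}

# lean VIP ranking used inside CV folds (X pre-subset, y raw)
.vip_rank <- function(X, y, ncomp, scale) {
  st <- .scale_train(X)
  Xs <- if (scale) st$Xs else sweep(X, 2, st$ctr)
  yc <- y - mean(y)
  core <- .pls1_core(Xs, yc, ncomp)
  if (core$ncomp == 0L) return(colnames(X))   # no covariance: canonical order
  ss <- core$q^2 * colSums(core$T^2)
  v <- sqrt(ncol(X) * drop(core$W^2 %*% ss) / sum(ss))
  colnames(X)[order(-v)]
}

# out-of-fold LOOCV predictions for a fixed variable set; returns an
# n x (ncomp + 1) matrix with column 1 the training-mean null model
.loocv_preds <- function(X, y, ncomp = 2, scale = TRUE) {
  n <- nrow(X)
  preds <- matrix(NA_real_, n, ncomp + 1)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    st <- .scale_train(Xtr)
    Xs <- if (scale) st$Xs else sweep(Xtr, 2, st$ctr)
    ym <- mean(ytr)
    core <- .pls1_core(Xs, ytr - ym, ncomp)
    xnew <- (X[i, ] - st$ctr) / (if (scale) st$sds else 1)
    preds[i, 1] <- ym
    for (a in seq_len(ncomp)) {
      preds[i, a + 1] <- if (a <= core$ncomp) {
        ym + sum(xnew * core$B[, a])
      } else {
        preds[i, a]                  # rank exhausted: carry previous model
      }
    }
  }
  colnames(preds) <- c("null", paste0("comp", seq_len(ncomp)))
  preds
}

#' Leave-one-out cross-validation with in-fold VIP selection
#'
#' For each left-out subject, variables are ranked by VIP on the training
#' subjects only, the top \code{j} are kept, a PLS model with
#' \code{ncomp} components is fitted on the training set, and the
#' held-out subject is predicted with 0 (training mean), 1, ...,
#' \code{ncomp} components.  Keeping the selection inside the training
#' fold avoids the optimistic bias that full-sample selection leaks into
#' cross-validated errors; set \code{select_within_fold = FALSE} to
#' obtain that deliberately leaky variant for comparison.
#'
#' Component significance is assessed with [paired_permutation_test()]:
#' the 1-component model against the null model, and the 2-component
#' model against the 1-component model.
#'
#' @param X Predictor matrix or data frame (n x p).
#' @param y Response vector.
#' @param j Number of variables to select, \code{2 <= j <= p}.
#' @param ncomp Components of the fold models (default 2; truncated per
#'   fold if the training rank is lower).
#' @param n_perm Randomizations for the component tests; \code{0} skips
#'   them (p-values NA).
#' @param seed Optional seed for the permutation tests.
#' @param groups Optional factor of length n (e.g. age group); per-group
#'   component tests are added via [subgroup_tests()].
#' @param scale Standardize predictors within each training fold.
#' @param select_within_fold If FALSE, rank once on the full sample
#'   (leaky; for demonstrating the bias only).
#' @return An object of class \code{"selection_cv"}: \code{predictions}
#'   (n x (ncomp+1) matrix), \code{selected} (list of per-fold variable
#'   sets), \code{msep} and \code{rmsep} (named per model), \code{p_comp1},
#'   \code{p_comp2}, optional \code{group_tests}, and the call settings.
#' @export
loocv_with_selection <- function(X, y, j, ncomp = 2, n_perm = 10000,
                                 seed = NULL, groups = NULL, scale = TRUE,
                                 select_within_fold = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (anyNA(X) || anyNA(y)) .stopf("missing values are not allowed")
  if (n < 4) .stopf("at least 4 observations are required")
  if (j < 2 || j > p) .stopf("j must satisfy 2 <= j <= p (got j = %d, p = %d)", j, p)

  global_rank <- if (!select_within_fold) .vip_rank(X, y, ncomp, scale) else NULL
  preds <- matrix(NA_real_, n, ncomp + 1)
  selected <- vector("list", n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    rk <- if (select_within_fold) .vip_rank(Xtr, ytr, ncomp, scale) else global_rank
    sel <- rk[seq_len(j)]
    selected[[i]] <- sel
    Xtr_s <- Xtr[, sel, drop = FALSE]
    st <- .scale_train(Xtr_s)
    Xs <- if (scale) st$Xs else sweep(Xtr_s, 2, st$ctr)
    ym <- mean(ytr)
    core <- .pls1_core(Xs, ytr - ym, ncomp)
    xnew <- (X[i, sel] - st$ctr) / (if (scale) st$sds else 1)
    preds[i, 1] <- ym
    for (a in seq_len(ncomp)) {
      preds[i, a + 1] <- if (a <= core$ncomp) {
        ym + sum(xnew * core$B[, a])
      } else preds[i, a]
    }
  }
  colnames(preds) <- c("null", paste0("comp", seq_len(ncomp)))
  errs <- y - preds
  ms <- colMeans(errs^2)
  p1 <- p2 <- NA_real_
  if (n_perm > 0) {
    p1 <- paired_permutation_test(errs[, "comp1"], errs[, "null"],
                                  n_perm, seed)$p_value
    if (ncomp >= 2) {
      p2 <- paired_permutation_test(errs[, "comp2"], errs[, "comp1"], n_perm,
                                    if (is.null(seed)) NULL else seed + 1L)$p_value
    }
  }
  out <- structure(list(
    j = j, ncomp = ncomp, predictions = preds, y = y, selected = selected,
    msep = ms, rmsep = sqrt(ms), p_comp1 = p1, p_comp2 = p2,
    n_perm = n_perm, seed = seed, scale = scale,
    select_within_fold = select_within_fold
  ), class = "selection_cv")
  if (!is.null(groups) && n_perm > 0) {
    out$group_tests <- subgroup_tests(out, groups, n_perm = n_perm,
                                      seed = if (is.null(seed)) NULL else seed + 2L)
  }
  out
}

#' @export
print.selection_cv <- function(x, ...) {
  cat(sprintf("LOOCV with %s VIP selection: j = %d of %d-fold data\n",
              if (x$select_within_fold) "in-fold" else "full-sample (leaky)",
              x$j, nrow(x$predictions)))
  cat("  rMSEP:", paste(sprintf("%s %.3f", names(x$rmsep), x$rmsep),
                        collapse = ", "), "\n")
  cat(sprintf("  p(comp1 vs null) = %.4g, p(comp2 vs comp1) = %.4g  [B = %d]\n",
              x$p_comp1, x$p_comp2, x$n_perm))
  invisible(x)
}

#' Sweep the number of selected variables
#'
#' Repeats [loocv_with_selection()] for each candidate number of selected
#' variables \code{j}, tabulating the permutation p-value of each
#' component and the MSEP of the null, 1- and 2-component models — the
#' machine-readable analogue of plotting p-value and MSEP against the
#' number of variables with highest VIP.
#'
#' @inheritParams loocv_with_selection
#' @param j_range Candidate variable counts (default \code{2:p}).
#' @return Data frame of class \code{"vip_sweep"} with one row per j:
#'   \code{j, msep_null, msep_comp1, msep_comp2, p_comp1, p_comp2} plus
#'   per-group p-value columns when \code{groups} is supplied.  The
#'   underlying \code{"selection_cv"} objects are attached as attribute
#'   \code{"results"}.
#' @export
sweep_variable_counts <- function(X, y, j_range = 2:ncol(as.matrix(X)),
                                  ncomp = 2, n_perm = 10000, seed = NULL,
                                  groups = NULL, scale = TRUE) {
  results <- lapply(seq_along(j_range), function(k) {
    loocv_with_selection(X, y, j = j_range[k], ncomp = ncomp, n_perm = n_perm,
                         seed = if (is.null(seed)) NULL else seed + 10L * k,
                         groups = groups, scale = scale)
  })
  tab <- data.frame(
    j = j_range,
    msep_null = vapply(results, function(r) r$msep[["null"]], 0),
    msep_comp1 = vapply(results, function(r) r$msep[["comp1"]], 0),
    msep_comp2 = vapply(results, function(r) r$msep[["comp2"]], 0),
    p_comp1 = vapply(results, function(r) r$p_comp1, 0),
    p_comp2 = vapply(results, function(r) r$p_comp2, 0)
  )
  if (!is.null(groups)) {
    for (g in levels(factor(groups))) {
      tab[[paste0("p_comp1_", g)]] <- vapply(results, function(r) {
        gt <- r$group_tests
        gt$p_value[gt$group == g & gt$comparison == "comp1_vs_null"]
      }, 0)
      tab[[paste0("p_comp2_", g)]] <- vapply(results, function(r) {
        gt <- r$group_tests
        gt$p_value[gt$group == g & gt$comparison == "comp2_vs_comp1"]
      }, 0)
    }
  }
  attr(tab, "results") <- results
  class(tab) <- c("vip_sweep", "data.frame")
  tab
}

#' Plot a variable-count sweep
#'
#' Two base-graphics panels: permutation p-value and MSEP against the
#' number of selected variables, one line per component (the MSEP panel
#' also shows the intercept-only null model).
#'
#' @param x A [sweep_variable_counts()] result.
#' @param ... Unused.
#' @export
plot.vip_sweep <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(x$j, x$p_comp1, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "variables included (by VIP)", ylab = "permutation p-value")
  lines(x$j, x$p_comp2, type = "b", pch = 1, lty = 2)
  abline(h = 0.05, lty = 3)
  legend("topright", c("component 1", "component 2"), pch = c(16, 1),
         lty = c(1, 2), bty = "n")
  rng <- range(x$msep_null, x$msep_comp1, x$msep_comp2)
  plot(x$j, x$msep_comp1, type = "b", pch = 16, ylim = rng,
       xlab = "variables included (by VIP)", ylab = "MSEP")
  lines(x$j, x$msep_comp2, type = "b", pch = 1, lty = 2)
  abline(h = x$msep_null[1], lty = 3)
  invisible(x)
}

#' Per-age-group component tests on shared cross-validation errors
#'
#' The model is always trained on the whole sample; only the paired error
#' differences entering the permutation test are restricted to each
#' group, probing whether the whole-sample component reduces prediction
#' error consistently within every group.
#'
#' @param result A [loocv_with_selection()] result (or any object with an
#'   n x >=3 \code{predictions} matrix and \code{y}).
#' @param groups Factor of length n; every level needs at least 2
#'   subjects.
#' @param n_perm,seed Permutation settings.
#' @return Data frame: \code{group}, \code{comparison}, \code{n},
#'   \code{statistic}, \code{p_value}.
#' @export
subgroup_tests <- function(result, groups, n_perm = 10000, seed = NULL) {
  preds <- result$predictions
  y <- result$y
  groups <- factor(groups)
  if (length(groups) != length(y)) .stopf("`groups` must have length n")
  errs <- y - preds
  rows <- list()
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) .stopf("group '%s' has fewer than 2 subjects", g)
    t1 <- paired_permutation_test(errs[idx, "comp1"], errs[idx, "null"],
                                  n_perm, seed)
    rows[[length(rows) + 1]] <- data.frame(
      group = g, comparison = "comp1_vs_null", n = length(idx),
      statistic = t1$statistic, p_value = t1$p_value)
    if ("comp2" %in% colnames(errs)) {
      t2 <- paired_permutation_test(errs[idx, "comp2"], errs[idx, "comp1"],
                                    n_perm,
                                    if (is.null(seed)) NULL else seed + 1L)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, comparison = "comp2_vs_comp1", n = length(idx),
        statistic = t2$statistic, p_value = t2$p_value)
    }
  }
  do.call(rbind, rows)
}

#' Final model evaluation: selection-free LOOCV
#'
#' Cross-validates a fixed variable set (typically the top-VIP set chosen
#' by the sweep) with leave-one-out folds and no further selection, and
#' reports the Pearson correlation between out-of-fold predictions and
#' the observed response for the 1- and 2-component models, rMSEP of the
#' null/1-/2-component models, and permutation p-values for the
#' correlations.  Each permutation permutes the response labels and
#' recomputes the entire cross-validation, so the null distribution
#' honestly reflects the cross-validated statistic.
#'
#' @param X Predictor matrix or data frame.
#' @param y Response vector.
#' @param variables Names of the fixed selected variables.
#' @param ncomp Components (default 2).
#' @param n_perm Label permutations; \code{0} skips p-values.
#' @param seed Optional seed.
#' @param scale Standardize predictors per training fold.
#' @return List of class \code{"final_evaluation"}: \code{predictions},
#'   \code{r} (named, per component count), \code{p_value} (named),
#'   \code{rmsep} (null/comp1/comp2), \code{variables}, \code{n_perm}.
#' @export
evaluate_final <- function(X, y, variables, ncomp = 2, n_perm = 10000,
                           seed = NULL, scale = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  miss <- setdiff(variables, colnames(X))
  if (length(miss)) .stopf("unknown variable(s): %s", paste(miss, collapse = ", "))
  Xv <- X[, variables, drop = FALSE]
  y <- as.numeric(y)
  preds <- .loocv_preds(Xv, y, ncomp = ncomp, scale = scale)
  r_obs <- vapply(seq_len(ncomp),
                  function(a) cor(preds[, a + 1], y), 0)
  names(r_obs) <- paste0("comp", seq_len(ncomp))
  ms <- colMeans((y - preds)^2)
  pv <- rep(NA_real_, ncomp)
  names(pv) <- names(r_obs)
  if (n_perm > 0) {
    pv[] <- .with_seed(seed, {
      counts <- numeric(ncomp)
      for (b in seq_len(n_perm)) {
        yp <- sample(y)
        pp <- .loocv_preds(Xv, yp, ncomp = ncomp, scale = scale)
        rp <- vapply(seq_len(ncomp), function(a) {
          s <- sd(pp[, a + 1])
          if (is.na(s) || s < 1e-12) -1 else cor(pp[, a + 1], yp)
        }, 0)
        counts <- counts + (rp >= r_obs)
      }
      (counts + 1) / (n_perm + 1)
    })
  }
  structure(list(predictions = preds, y = y, r = r_obs, p_value = pv,
                 rmsep = sqrt(ms), variables = variables, ncomp = ncomp,
                 n_perm = n_perm, seed = seed),
            class = "final_evaluation")
}

#' @export
print.final_evaluation <- function(x, ...) {
  cat("Selection-free LOOCV of the final PLS model\n")
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  for (a in seq_len(x$ncomp)) {
    cat(sprintf("  %d component(s): r = %.3f, p = %.4g, rMSEP = %.3f\n",
                a, x$r[a], x$p_value[a], x$rmsep[[paste0("comp", a)]]))
  }
  cat(sprintf("  null-model rMSEP = %.3f\n", x$rmsep[["null"]]))
  invisible(x)
}

#' Univariate correlations with permutation p-values
#'
#' Pearson correlation of each listed variable with the response, with a
#' two-sided permutation p-value obtained by permuting the response
#' labels.
#'
#' @param X Predictor matrix or data frame.
#' @param y Response vector.
#' @param variables Variables to correlate (default all columns).
#' @param n_perm Label permutations (default 10000).
#' @param seed Optional seed.
#' @return Data frame: \code{variable}, \code{r}, \code{p_value}.
#' @export
univariate_correlations <- function(X, y, variables = NULL, n_perm = 10000,
                                    seed = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.null(variables)) variables <- colnames(X)
  Xv <- X[, variables, drop = FALSE]
  y <- as.numeric(y)
  n <- length(y)
  r_obs <- drop(cor(Xv, y))
  pv <- rep(NA_real_, length(variables))
  if (n_perm > 0) {
    Xs <- scale(Xv)
    ys <- scale(y)
    pv <- .with_seed(seed, {
      counts <- numeric(length(variables))
      for (b in seq_len(n_perm)) {
        rp <- drop(crossprod(Xs, ys[sample(n)])) / (n - 1)
        counts <- counts + (abs(rp) >= abs(r_obs))
      }
      (counts + 1) / (n_perm + 1)
    })
  }
  data.frame(variable = variables, r = r_obs, p_value = pv,
             row.names = NULL)
}

#' Exhaustive best-subset linear regression by LOOCV error
#'
#' Enumerates every predictor subset up to \code{max_size}, fits ordinary
#' least squares on each, and scores it by leave-one-out MSEP (computed
#' exactly via the hat-matrix identity).  Serves as an independent
#' cross-check of the PLS variable selection.
#'
#' @param X Predictor matrix or data frame.
#' @param y Response vector.
#' @param max_size Largest subset size (default \code{min(p, 6)}).
#' @return Data frame ranked by ascending MSEP: \code{subset} (variables
#'   joined by \code{" + "}), \code{size}, \code{msep}.
#' @export
exhaustive_subset_regression <- function(X, y, max_size = min(ncol(as.matrix(X)), 6)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X)
  rows <- list()
  for (size in seq_len(max_size)) {
    sets <- utils::combn(colnames(X), size, simplify = FALSE)
    for (s in sets) {
      M <- cbind(1, X[, s, drop = FALSE])
      fit <- lm.fit(M, y)
      h <- rowSums((M %*% chol2inv(chol(crossprod(M)))) * M)
      loo <- fit$residuals / (1 - h)
      rows[[length(rows) + 1]] <- data.frame(
        subset = paste(s, collapse = " + "), size = size,
        msep = mean(loo^2))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$msep), , drop = FALSE]
}
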