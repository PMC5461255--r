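#' Configuration of the synthetic battery generator
#'
#' Builds and validates the configuration object that fully determines a
#' synthetic two-age-group battery dataset.  The generative model is a
#' single shared standard-normal latent factor per subject ("cognitive
#' efficiency"): on the standardized scale each predictor is
#' \code{loading * latent + sqrt(1 - loading^2) * noise}, then shifted and
#' scaled to the configured group mean and SD, so marginal group moments
#' match the configuration exactly in expectation.  The response is driven
#' by the same latent factor with loading \code{response_loading}, mapped
#' onto the half-integer median lattice, clipped to
#' \code{response_bounds}, and floor-inflated: with probability
#' \code{floor_mass} a subject scores at the lower bound, emulating the
#' subjects unable to repeat any word.  The pre-transform center is
#' calibrated internally so the expected response after rounding, clipping
#' and floor inflation equals the configured group mean.
#'
#' @param n_young,n_old Group sizes (default 21 and 20).
#' @param group_means,group_sds Lists with named numeric vectors
#'   \code{young} and \code{old} over \code{c(battery_variables(),
#'   battery_response())}; defaults from [table1_calibration()].
#' @param latent_loadings Named vector of signed loadings in [-1, 1] over
#'   [battery_variables()]; default [default_latent_loadings()].
#' @param response_loading Loading of the response on the latent factor.
#' @param response_bounds Ordered pair, default \code{c(0, 7)} words.
#' @param floor_mass Probability in [0, 1) of a floor (zero-score)
#'   subject; default 0.15.
#' @param n_ospan_missing_old Number of older subjects whose Operation
#'   Span is marked missing (emulating task dropouts); default 0.
#' @param recall_convention Either \code{"t7_minus_t5"} (literal delayed
#'   minus immediate recall difference) or \code{"t5_minus_t7"}.
#' @param seed Integer seed; identical config + seed gives identical data.
#' @return An object of class \code{"generator_config"}.
#' @export
#' @examples
#' cfg <- generator_config(seed = 42)
#' head(generate_battery(cfg))
generator_config <- function(n_young = 21,
                             n_old = 20,
                             group_means = table1_calibration()$means,
                             group_sds = table1_calibration()$sds,
                             latent_loadings = default_latent_loadings(),
                             response_loading = 0.75,
                             response_bounds = c(0, 7),
                             floor_mass = 0.15,
                             n_ospan_missing_old = 0,
                             recall_convention = c("t7_minus_t5", "t5_minus_t7"),
                             seed = 1L) {
  vars <- battery_variables()
  all_vars <- c(vars, battery_response())
  recall_convention <- match.arg(recall_convention)
  if (n_young < 2 || n_old < 2) .stopf("group sizes must be at least 2")
  for (grp in c("young", "old")) {
    m <- group_means[[grp]]; s <- group_sds[[grp]]
    miss <- setdiff(all_vars, names(m))
    if (length(miss)) .stopf("group_means$%s missing: %s", grp, paste(miss, collapse = ", "))
    miss <- setdiff(all_vars, names(s))
    if (length(miss)) .stopf("group_sds$%s missing: %s", grp, paste(miss, collapse = ", "))
    if (any(s[all_vars] <= 0)) .stopf("group_sds$%s must be strictly positive", grp)
  }
  miss <- setdiff(vars, names(latent_loadings))
  if (length(miss)) .stopf("latent_loadings missing: %s", paste(miss, collapse = ", "))
  bad <- names(latent_loadings)[abs(latent_loadings) > 1]
  if (length(bad)) {
    .stopf("invalid loading for %s: |loading| must be <= 1 on the standardized scale",
           paste(bad, collapse = ", "))
  }
  if (abs(response_loading) > 1) .stopf("invalid response_loading: |loading| must be <= 1")
  if (length(response_bounds) != 2 || diff(response_bounds) <= 0) {
    .stopf("response_bounds must be an ordered pair")
  }
  if (floor_mass < 0 || floor_mass >= 1) .stopf("floor_mass must be in [0, 1)")
  if (n_ospan_missing_old < 0 || n_ospan_missing_old > n_old) {
    .stopf("n_ospan_missing_old must be between 0 and n_old")
  }
  structure(list(
    n_young = as.integer(n_young), n_old = as.integer(n_old),
    group_means = lapply(group_means[c("young", "old")], function(x) x[all_vars]),
    group_sds = lapply(group_sds[c("young", "old")], function(x) x[all_vars]),
    latent_loadings = latent_loadings[vars],
    response_loading = response_loading,
    response_bounds = as.numeric(response_bounds),
    floor_mass = floor_mass,
    n_ospan_missing_old = as.integer(n_ospan_missing_old),
    recall_convention = recall_convention,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic battery generator config\n")
  cat(sprintf("  groups: young n=%d, old n=%d (Operation Span missing: %d old)\n",
              x$n_young, x$n_old, x$n_ospan_missing_old))
  cat(sprintf("  response: bounds [%g, %g], floor mass %.2f, latent loading %.2f\n",
              x$response_bounds[1], x$response_bounds[2], x$floor_mass,
              x$response_loading))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# E[ clip(round-to-step(X)) ] for X ~ N(m, s) on the lattice
# seq(bounds[1], bounds[2], step); exact via normal bin probabilities.
.lattice_mean <- function(m, s, bounds, step = 0.5) {
  v <- seq(bounds[1], bounds[2], by = step)
  lo <- c(-Inf, v[-1] - step / 2)
  hi <- c(v[-length(v)] + step / 2, Inf)
  sum(v * (pnorm(hi, m, s) - pnorm(lo, m, s)))
}

# Pre-transform center such that the expected response after rounding,
# clipping and floor inflation equals `target`.
.solve_response_center <- function(target, s, floor_mass, bounds, step = 0.5) {
  b1 <- bounds[1]
  g <- function(m) (1 - floor_mass) * .lattice_mean(m, s, bounds, step) +
    floor_mass * b1 - target
  lo <- bounds[1] - 6 * s; hi <- bounds[2] + 6 * s
  if (g(lo) > 0 || g(hi) < 0) {
    .stopf("response mean %.3f is not attainable within bounds [%g, %g] at floor mass %.2f",
           target, bounds[1], bounds[2], floor_mass)
  }
  uniroot(g, c(lo, hi), tol = 1e-10)$root
}

# core generation shared by generate_battery() and generate_trial_records();
# assumes the RNG is already seeded by the caller
.generate_battery_impl <- function(config) {
  vars <- battery_variables()
  groups <- c(rep("young", config$n_young), rep("old", config$n_old))
  n <- length(groups)
  lam <- config$latent_loadings
  latent <- rnorm(n)
  X <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  y <- numeric(n)
  for (grp in c("young", "old")) {
    idx <- which(groups == grp)
    mu <- config$group_means[[grp]][vars]
    sg <- config$group_sds[[grp]][vars]
    eps <- matrix(rnorm(length(idx) * length(vars)), length(idx))
    Z <- outer(latent[idx], lam) + sweep(eps, 2, sqrt(1 - lam^2), "*")
    X[idx, ] <- sweep(sweep(Z, 2, sg, "*"), 2, mu, "+")

    muy <- config$group_means[[grp]][[battery_response()]]
    sdy <- config$group_sds[[grp]][[battery_response()]]
    beta <- config$response_loading
    center <- .solve_response_center(muy, sdy, config$floor_mass,
                                     config$response_bounds)
    z <- beta * latent[idx] + sqrt(1 - beta^2) * rnorm(length(idx))
    val <- round((center + sdy * z) * 2) / 2
    val <- pmin(pmax(val, config$response_bounds[1]), config$response_bounds[2])
    val[runif(length(idx)) < config$floor_mass] <- config$response_bounds[1]
    y[idx] <- val
  }
  out <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    age_group = factor(groups, levels = c("young", "old")),
    X,
    stringsAsFactors = FALSE
  )
  out[[battery_response()]] <- y
  if (config$n_ospan_missing_old > 0) {
    old_idx <- rev(which(groups == "old"))[seq_len(config$n_ospan_missing_old)]
    out$OperationSpan[old_idx] <- NA_real_
  }
  attr(out, "latent") <- latent
  out
}

#' Generate a synthetic battery dataset
#'
#' Draws one synthetic dataset of \code{n_young + n_old} subjects from the
#' single-latent-factor model described in [generator_config()]: thirteen
#' correlated predictors with exact marginal group means/SDs in
#' expectation, and a bounded half-integer response calibrated so its
#' expected group mean equals the configured value despite rounding,
#' clipping and floor inflation.
#'
#' @param config A [generator_config()].
#' @return A data frame with columns \code{subject_id}, \code{age_group},
#'   the thirteen [battery_variables()] and \code{y_median}; the latent
#'   factor draw is attached as attribute \code{"latent"}.
#' @seealso [generate_trial_records()] for trial-level data,
#'   [write_battery()] / [read_battery()] for CSV round-trips.
#' @export
generate_battery <- function(config) {
  if (!inherits(config, "generator_config")) {
    .stopf("`config` must be a generator_config")
  }
  .with_seed(config$seed, .generate_battery_impl(config))
}

# five nondecreasing-ish integer list-learning counts in [0,15] summing to
# clamp(round(total), 0, 75)
.split_learning <- function(total) {
  total <- max(0, min(75, round(total)))
  base <- rep(total %/% 5, 5)
  rem <- total - sum(base)
  if (rem > 0) base[(5 - rem + 1):5] <- base[(5 - rem + 1):5] + 1
  for (k in 1:2) {                    # tilt upward: learning across trials
    if (base[k] > 0 && base[6 - k] < 15) {
      base[k] <- base[k] - 1
      base[6 - k] <- base[6 - k] + 1
    }
  }
  base
}

# draw 60 integer sentence scores in [0,7] with a mild block-wise learning
# trend, then repair so the median equals `target` exactly
.draw_trials <- function(target, n_trials = 60, block_size = 10,
                         learn_slope = 0.35) {
  n_blocks <- n_trials / block_size
  p0 <- min(max(target / 7, 0.02), 0.98)
  blocks <- rep(seq_len(n_blocks), each = block_size)
  p <- plogis(qlogis(p0) + learn_slope * (blocks - (n_blocks + 1) / 2) /
                n_blocks)
  x <- rbinom(n_trials, 7, p)
  for (i in seq_len(4 * n_trials)) {
    s <- sort(x)
    m <- (s[n_trials / 2] + s[n_trials / 2 + 1]) / 2
    if (m == target) break
    if (m < target) {
      cand <- which(x == s[n_trials / 2] & x < 7)[1]
      x[cand] <- x[cand] + 1
    } else {
      cand <- which(x == s[n_trials / 2 + 1] & x > 0)[1]
      x[cand] <- x[cand] - 1
    }
  }
  x
}

#' Generate trial-level synthetic records
#'
#' Extends [generate_battery()] with (a) 60 sentence trials per subject
#' whose integer words-correct scores carry a mild block-wise learning
#' trend and whose median equals the subject's \code{y_median} exactly,
#' and (b) one row of raw cognitive test records per subject constructed
#' to invert [derive_predictors()]: deriving the thirteen predictors from
#' the raw records reproduces the battery values up to integer rounding of
#' count-valued tests (reaction-time measures round-trip exactly).
#'
#' @param config A [generator_config()].
#' @return List with elements \code{battery} (identical to
#'   \code{generate_battery(config)}), \code{trials} (data frame
#'   \code{subject_id, trial_index, block, n_correct}) and \code{raw}
#'   (one-row-per-subject raw test records, see [derive_predictors()]).
#' @export
generate_trial_records <- function(config) {
  if (!inherits(config, "generator_config")) {
    .stopf("`config` must be a generator_config")
  }
  .with_seed(config$seed, {
    battery <- .generate_battery_impl(config)
    n <- nrow(battery)

    trials <- do.call(rbind, lapply(seq_len(n), function(i) {
      sc <- .draw_trials(battery$y_median[i])
      data.frame(subject_id = battery$subject_id[i],
                 trial_index = seq_along(sc),
                 block = rep(1:6, each = 10),
                 n_correct = sc,
                 stringsAsFactors = FALSE)
    }))

    raw <- do.call(rbind, lapply(seq_len(n), function(i) {
      b <- battery[i, ]
      vl <- .split_learning(b$Verbal_learning)
      recall <- round(b$Recall)
      t7 <- if (config$recall_convention == "t7_minus_t5") {
        vl[5] + recall
      } else {
        vl[5] - recall
      }
      data.frame(
        subject_id = b$subject_id,
        vlrt_t1 = vl[1], vlrt_t2 = vl[2], vlrt_t3 = vl[3], vlrt_t4 = vl[4],
        vlrt_t5 = vl[5], vlrt_t6 = max(0, vl[5] - 3),
        vlrt_t7 = max(0, min(15, t7)),
        vlrt_t8 = max(0, min(15, round(b$Recognition))),
        ospan_letters = if (is.na(b$OperationSpan)) NA_real_ else
          max(0, round(b$OperationSpan)),
        trt_words = max(0, round(b$TRT)),
        wst_correct = max(0, min(42, round(b$WST))),
        ldt_rt_word = 600, ldt_rt_nonword = 600 + b$RT_word,
        ldt_rt_high = 620, ldt_rt_low = 620 + b$RT_freq,
        stroop_reading = 40, stroop_bar = 45,
        stroop_interference = 45 + b$Distraction_sensitivity,
        ctmt_1 = 60, ctmt_2 = 60 + b$CTMT_1_2, ctmt_3 = 60 + b$CTMT_1_3,
        ctmt_4 = 60 + b$CTMT_1_4, ctmt_5 = 60 + b$CTMT_1_5,
        stringsAsFactors = FALSE
      )
    }))
    list(battery = battery, trials = trials, raw = raw)
  })
}

#' Write / read a battery dataset as CSV
#'
#' The canonical on-disk schema is \code{subject_id, age_group,} the
#' thirteen [battery_variables()], \code{y_median}.
#'
#' @param data Battery data frame.
#' @param path File path.
#' @return \code{read_battery} returns the validated data frame (see
#'   [validate_dataset()]); \code{write_battery} returns \code{path}
#'   invisibly.
#' @export
write_battery <- function(data, path) {
  cols <- c("subject_id", "age_group", battery_variables(), battery_response())
  miss <- setdiff(cols, names(data))
  if (length(miss)) .stopf("battery data missing column(s): %s",
                           paste(miss, collapse = ", "))
  utils::write.csv(data[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_battery
#' @export
read_battery <- function(path) {
  validate_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read a generator configuration as YAML
#'
#' @param config A [generator_config()].
#' @param path File path.
#' @return \code{read_generator_config} returns a validated
#'   [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  x$group_means <- lapply(x$group_means, as.list)
  x$group_sds <- lapply(x$group_sds, as.list)
  x$latent_loadings <- as.list(x$latent_loadings)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$group_means <- lapply(x$group_means, unlist)
  x$group_sds <- lapply(x$group_sds, unlist)
  x$latent_loadings <- unlist(x$latent_loadings)
  do.call(generator_config, x)
}
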