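# Independent oracles used across the suite.  These deliberately avoid the
# package's internal fast paths: they recompute results with plain loops
# and public (or base-R) primitives only.

# Brute-force word-matching oracle: maximise credited words by trying every
# assignment of report tokens to target tokens (small cases only).
oracle_score <- function(target, report) {
  norm <- function(x) {
    if (length(x) == 1 && grepl("\\s", x)) x <- strsplit(x, "\\s+")[[1]]
    x <- gsub("[[:punct:]]", "", tolower(x))
    x[nzchar(x)]
  }
  tgt <- norm(target); rep_ <- norm(report)
  # maximum bipartite matching by exhaustive recursion: target i may be
  # credited by any unused report token with the same surface form
  recurse <- function(ti, used) {
    if (ti > length(tgt)) return(0L)
    best <- recurse(ti + 1L, used)            # leave target i uncredited
    for (h in setdiff(which(rep_ == tgt[ti]), used)) {
      best <- max(best, 1L + recurse(ti + 1L, c(used, h)))
    }
    best
  }
  recurse(1L, integer(0))
}

# Naive leave-one-out CV with in-fold VIP selection, written as a plain
# loop over the public API (pls_fit / vip / predict).
oracle_loocv_selection <- function(X, y, j, ncomp = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  preds <- matrix(NA_real_, n, ncomp + 1)
  sel_sets <- vector("list", n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    full <- pls_fit(Xtr, ytr, ncomp = ncomp)
    v <- vip(full)
    sel <- names(v)[order(-v)][seq_len(j)]
    sel_sets[[i]] <- sel
    fit <- pls_fit(Xtr[, sel, drop = FALSE], ytr, ncomp = ncomp)
    for (a in 0:ncomp) {
      preds[i, a + 1] <- predict(fit, X[i, sel, drop = FALSE], ncomp = a)
    }
  }
  list(predictions = preds, selected = sel_sets)
}

# random full-rank regression problem with named predictors
random_problem <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", seq_len(p))))
  list(X = X, y = drop(rnorm(n) + X %*% rnorm(p, sd = 0.5)))
}

# battery-shaped zero-signal dataset (exchangeable predictors and response)
zero_signal_config <- function(seed, n_young = 21, n_old = 18) {
  generator_config(
    n_young = n_young, n_old = n_old,
    latent_loadings = setNames(numeric(13), battery_variables()),
    response_loading = 0, seed = seed)
}

strong_signal_config <- function(seed) {
  generator_config(latent_loadings = strong_latent_loadings(),
                   response_loading = 0.85, floor_mass = 0, seed = seed)
}

# Welch-free pooled two-sample t statistic from first principles
oracle_pooled_t <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}
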