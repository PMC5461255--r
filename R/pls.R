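#' Single-response partial least squares regression (orthogonal scores)
#'
#' Fits a PLS1 regression by the orthogonal-scores algorithm: component
#' weights maximise covariance between the (centered, optionally scaled)
#' predictor block and the centered response; the predictor block is
#' deflated by each component's scores-times-loadings, and the response is
#' deflated symmetrically.  For a single response the weight vector of
#' each component is closed-form (\code{w = E'f / ||E'f||}), so no
#' iteration is needed.
#'
#' Predictors are standardized to unit variance by default because
#' batteries typically mix counts with reaction times in incommensurate
#' units; set \code{scale = FALSE} to reproduce covariance-scale PLS.
#' The response is centered only.
#'
#' @param X Numeric matrix or data frame of predictors (n x p), no
#'   missing values.
#' @param y Numeric response of length n.
#' @param ncomp Number of components; truncated with a warning if it
#'   exceeds \code{min(n - 1, p)} or the effective rank.
#' @param scale Standardize predictors to unit variance? Default TRUE.
#' @return An object of class \code{"pls1_fit"} with elements
#'   \code{x_center}, \code{x_scale}, \code{y_center}, \code{weights}
#'   (p x a, unit-norm columns), \code{x_loadings} (p x a),
#'   \code{y_loadings} (length a), \code{scores} (n x a, mutually
#'   orthogonal columns), \code{coef} (p x a; column a holds the
#'   regression coefficients of the a-component model on the scaled
#'   predictor space), \code{ncomp} and \code{variables}.
#' @seealso [predict.pls1_fit()], [vip()], [explained_variance()],
#'   [loadings_report()].
#' @export
#' @examples
#' d <- generate_battery(generator_config(seed = 3))
#' fit <- pls_fit(d[battery_variables()], d$y_median, ncomp = 2)
#' fit
#' vip(fit)
pls_fit <- function(X, y, ncomp = 2, scale = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) .stopf("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) .stopf("missing values are not allowed in pls_fit")
  if (n < 3) .stopf("at least 3 observations are required")
  max_comp <- min(n - 1L, p)
  if (ncomp < 1) .stopf("ncomp must be at least 1")
  if (ncomp > max_comp) {
    .warnf("ncomp = %d exceeds min(n - 1, p) = %d; truncated", ncomp, max_comp)
    ncomp <- max_comp
  }
  x_center <- colMeans(X)
  sds <- .col_sds(X)
  if (any(sds < 1e-12)) {
    .stopf("zero-variance predictor(s): %s",
           paste(colnames(X)[sds < 1e-12], collapse = ", "))
  }
  x_scale <- if (scale) sds else rep(1, p)
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y)

  core <- .pls1_core(Xs, y - y_center, ncomp)
  if (core$ncomp < ncomp) {
    .warnf("predictor block exhausted after %d component(s); ncomp truncated",
           core$ncomp)
  }
  structure(list(
    x_center = x_center, x_scale = x_scale, y_center = y_center,
    weights = core$W, x_loadings = core$P, y_loadings = core$q,
    scores = core$T, coef = core$B, ncomp = core$ncomp,
    scaled = scale, variables = colnames(X),
    ss_x_total = sum(Xs^2), ss_y_total = sum((y - y_center)^2)
  ), class = "pls1_fit")
}

# lean PLS1 on pre-centered (and pre-scaled) data; used directly inside
# cross-validation loops where pls_fit()'s validation would dominate cost
.pls1_core <- function(Xs, yc, ncomp) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  q <- numeric(ncomp); TT <- matrix(0, n, ncomp)
  E <- Xs; f <- yc; a <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10) break
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-10) break
    pk <- drop(crossprod(E, t)) / tt
    qk <- sum(f * t) / tt
    E <- E - tcrossprod(t, pk)
    f <- f - t * qk
    a <- k
    W[, k] <- w; P[, k] <- pk; q[k] <- qk; TT[, k] <- t
  }
  if (a == 0L) {
    # degenerate: X carries no covariance with y; intercept-only model
    return(list(W = W[, 0, drop = FALSE], P = P[, 0, drop = FALSE],
                q = numeric(0), T = TT[, 0, drop = FALSE],
                B = matrix(0, p, 0), ncomp = 0L))
  }
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]
  TT <- TT[, seq_len(a), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))   # columns span the prediction space
  B <- vapply(seq_len(a),
              function(j) drop(R[, seq_len(j), drop = FALSE] %*% q[seq_len(j)]),
              numeric(p))
  B <- matrix(B, nrow = p)
  list(W = W, P = P, q = q, T = TT, B = B, ncomp = a)
}

#' Predict from a fitted PLS1 model
#'
#' @param object A [pls_fit()] result.
#' @param newdata Matrix or data frame with the model's variables (matched
#'   by name when named).
#' @param ncomp Number of components to use, \code{0 <= ncomp <=
#'   object$ncomp}; \code{ncomp = 0} returns the training response mean
#'   (intercept-only null model).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) {
    miss <- setdiff(object$variables, colnames(X))
    if (length(miss)) .stopf("newdata lacks variable(s): %s",
                             paste(miss, collapse = ", "))
    X <- X[, object$variables, drop = FALSE]
  } else if (ncol(X) != length(object$variables)) {
    .stopf("newdata has %d columns; model expects %d", ncol(X),
           length(object$variables))
  }
  if (ncomp > object$ncomp || ncomp < 0) {
    .stopf("ncomp must be between 0 and %d", object$ncomp)
  }
  if (ncomp == 0) return(rep(object$y_center, nrow(X)))
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  drop(object$y_center + Xs %*% object$coef[, ncomp])
}

#' Variable importance in projection (VIP)
#'
#' VIP scores weight each variable's squared normalized weight on every
#' component by the share of response variance that component explains:
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a w_{ja}^2 / \sum_a SS_a},}
#' with \eqn{SS_a = q_a^2 t_a' t_a} the response variance captured by
#' component a.  The scores satisfy \eqn{\sum_j VIP_j^2 = p}, so variables
#' with VIP above 1 contribute more than an average variable.
#'
#' @param object A [pls_fit()] result with at least one component.
#' @return Named nonnegative numeric vector over the model variables.
#' @export
vip <- function(object) {
  if (!inherits(object, "pls1_fit")) .stopf("`object` must be a pls1_fit")
  if (object$ncomp < 1) .stopf("model has no components")
  ss <- object$y_loadings^2 * colSums(object$scores^2)
  w2 <- object$weights^2                       # columns already unit norm
  v <- sqrt(length(object$variables) * drop(w2 %*% ss) / sum(ss))
  names(v) <- object$variables
  v
}

#' Explained variance per component
#'
#' Percentage of predictor-block variance and of response variance
#' captured by each component, from \eqn{||t_a||^2 ||p_a||^2} (predictor
#' side) and \eqn{q_a^2 t_a't_a} (response side) relative to the total
#' centered (and scaled) sums of squares.
#'
#' @param object A [pls_fit()] result.
#' @return Data frame with columns \code{component}, \code{x_pct},
#'   \code{y_pct}, \code{x_cum}, \code{y_cum} (percentages).
#' @export
explained_variance <- function(object) {
  if (!inherits(object, "pls1_fit")) .stopf("`object` must be a pls1_fit")
  x_pct <- 100 * colSums(object$scores^2) * colSums(object$x_loadings^2) /
    object$ss_x_total
  y_pct <- 100 * object$y_loadings^2 * colSums(object$scores^2) /
    object$ss_y_total
  data.frame(component = seq_len(object$ncomp),
             x_pct = x_pct, y_pct = y_pct,
             x_cum = cumsum(x_pct), y_cum = cumsum(y_pct),
             row.names = NULL)
}

#' Named predictor loadings for the leading components
#'
#' @param object A [pls_fit()] result.
#' @param components Which components to tabulate (default 1:2, truncated
#'   to the fitted number).
#' @return Data frame: \code{variable} plus one signed loading column per
#'   component.  With the battery's sign conventions, reaction-time
#'   variables load negatively on a performance component.
#' @export
loadings_report <- function(object, components = 1:2) {
  if (!inherits(object, "pls1_fit")) .stopf("`object` must be a pls1_fit")
  components <- components[components <= object$ncomp]
  out <- data.frame(variable = object$variables)
  for (a in components) {
    out[[paste0("comp", a)]] <- object$x_loadings[, a]
  }
  out
}

#' Serialize / restore a PLS1 model as JSON
#'
#' @param object A [pls_fit()] result.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return \code{pls_to_json}: the JSON string (invisibly when written to
#'   a file); \code{pls_from_json}: the restored \code{"pls1_fit"}.
#' @export
pls_to_json <- function(object, path = NULL) {
  if (!inherits(object, "pls1_fit")) .stopf("`object` must be a pls1_fit")
  json <- jsonlite::toJSON(unclass(object), digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname pls_to_json
#' @param json JSON string or file path produced by \code{pls_to_json}.
#' @export
pls_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  for (m in c("weights", "x_loadings", "coef", "scores")) {
    x[[m]] <- as.matrix(x[[m]])
  }
  x$x_center <- setNames(as.numeric(x$x_center), x$variables)
  x$x_scale <- setNames(as.numeric(x$x_scale), x$variables)
  x$y_loadings <- as.numeric(x$y_loadings)
  structure(x, class = "pls1_fit")
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat(sprintf("PLS1 fit: %d component(s), %d variables, %s predictors\n",
              x$ncomp, length(x$variables),
              if (x$scaled) "standardized" else "centered"))
  ev <- explained_variance(x)
  cat(sprintf("  component %d: %.1f%% X-variance, %.1f%% y-variance\n",
              ev$component, ev$x_pct, ev$y_pct), sep = "")
  invisible(x)
}
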