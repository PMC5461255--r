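# internal helpers shared across modules

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.  seed = NULL means "use the current stream".
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

.rms <- function(x) sqrt(mean(x^2))

# column SDs with the usual n-1 denominator, without apply() overhead
.col_sds <- function(X) {
  n <- nrow(X)
  sqrt(colSums(sweep(X, 2, colMeans(X))^2) / (n - 1))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
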