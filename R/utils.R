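#' Derive a reproducible sub-stream seed from a master seed
#'
#' Every stochastic stage of the pipeline draws from its own stream, keyed by
#' a fixed sequence of small integers (e.g. subject index, run index, purpose
#' tag).  The keying is a deterministic integer hash, so adding subjects or
#' runs to a configuration never perturbs the draws of earlier ones.
#'
#' @param master master seed (integer).
#' @param ... integer keys identifying the stream (subject, run, purpose...).
#' @return an integer seed in \[1, 2^31-2\].
#' @export
substream_seed <- function(master, ...) {
  keys <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(as.numeric(master)) + 1) %% m
  for (k in keys) {
    # multiplier 48271 keeps h * mult < 2^53, so arithmetic stays exact
    h <- (h * 48271 + abs(as.numeric(k)) + 11) %% m
  }
  as.integer(max(1, h %% (m - 1)))
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' interfere with each other or with user code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Column-wise z-scoring with population variance
#'
#' Standardizes each column to mean 0 and unit population variance (divide by
#' n, not n-1).  Zero-variance columns are left at 0 after centering; a warning
#' is emitted unless `warn = FALSE`.
#'
#' @param x numeric matrix.
#' @param warn warn on zero-variance columns.
#' @return matrix of the same shape.
#' @export
zscore_cols <- function(x, warn = TRUE) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  sdv <- sqrt(colMeans(xc^2))
  zero <- sdv <= 0
  if (any(zero)) {
    if (warn) warning(sum(zero), " zero-variance column(s) left at 0 after centering")
    sdv[zero] <- 1
  }
  sweep(xc, 2, sdv, "/")
}

# Pearson correlation between columns of x and columns of y with a
# zero-variance guard: undefined correlations are set to 0 (kept finite for
# downstream matrix algebra) with a single warning.
cor_guarded <- function(x, y = NULL) {
  sx <- apply(x, 2, stats::sd)
  sy <- if (is.null(y)) sx else apply(y, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x, y))
  bad <- outer(sx == 0, sy == 0, "|")
  if (any(bad)) {
    warning("zero-variance series: ", sum(bad),
            " undefined correlation(s) set to 0")
    r[bad] <- 0
  }
  r
}

# internal: check a square matrix is orthogonal to tolerance
is_orthogonal <- function(R, tol = 1e-8) {
  max(abs(crossprod(R) - diag(ncol(R)))) < tol
}
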