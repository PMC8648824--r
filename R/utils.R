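#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not disturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with sprintf formatting, no call in message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# column standard deviations of a matrix (sample SD, N-1)
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2) abort("need at least 2 rows for a standard deviation")
  mu <- colMeans(x)
  sqrt(colSums((x - rep(mu, each = n))^2) / (n - 1))
}
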