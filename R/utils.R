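`%||%` <- function(x, y) if (is.null(x)) y else x

## scalar validators used by the constructors; fail with the offending field name
assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE,
                              lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must lie in [%g, %g]", name, lower, upper), call. = FALSE)
  }
  invisible(x)
}

## truncated Gaussian noise: per-sample noise clipped at the accuracy bound
rnorm_trunc <- function(n, sd, bound) {
  if (sd <= 0 || bound <= 0) return(numeric(n))
  pmin(pmax(stats::rnorm(n, 0, sd), -bound), bound)
}

## quantize to integer multiples of a sensor resolution
quantize <- function(x, resolution) round(x / resolution) * resolution

## first-order relaxation of y toward a (possibly time-varying) target
relax_toward <- function(target, tau, dt, init = target[1]) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * target, a, method = "recursive",
                           init = init))
}

## run the given expression with a private RNG stream, restoring global state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
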