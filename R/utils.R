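#' @importFrom stats rnbinom rpois rnorm runif rlnorm median var approx
#'   pnorm qnorm p.adjust quantile setNames complete.cases
#' @importFrom utils read.table write.table head
#' @importFrom graphics hist
NULL

# geometric mean of a strictly positive vector
gmean <- function(x) exp(mean(log(x)))

# NB draw in (mu, alpha) parameterization, Var = mu + alpha*mu^2;
# alpha = 0 falls back to Poisson.
rnb <- function(n, mu, alpha) {
  if (alpha < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (alpha == 0) rpois(n, lambda = mu) else rnbinom(n, mu = mu, size = 1 / alpha)
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
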