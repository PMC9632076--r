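#' Prior distributions for demographic parameters
#'
#' Lightweight prior objects used for bottleneck timing and severity.
#' Three kinds are supported: `"log-uniform"` (uniform on the log scale,
#' the standard choice for strictly positive timescale parameters),
#' `"uniform"`, and `"fixed"` (a point mass).
#'
#' @param lower,upper Bounds of the support. Must satisfy `lower < upper`;
#'   a log-uniform prior additionally requires `lower > 0`.
#' @param value Point value for a fixed prior.
#'
#' @return An object of class `abc_prior`: a list with elements `kind`,
#'   `lower` and `upper`.
#' @examples
#' p <- prior_log_uniform(20000, 30000)
#' draw_prior(p, 5)
#' @name priors
NULL

#' @rdname priors
#' @export
prior_log_uniform <- function(lower, upper) {
  new_prior("log-uniform", lower, upper)
}

#' @rdname priors
#' @export
prior_uniform <- function(lower, upper) {
  new_prior("uniform", lower, upper)
}

#' @rdname priors
#' @export
prior_fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  structure(list(kind = "fixed", lower = value, upper = value),
            class = "abc_prior")
}

new_prior <- function(kind, lower, upper) {
  stopifnot(is.numeric(lower), length(lower) == 1,
            is.numeric(upper), length(upper) == 1)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("prior requires finite lower < upper", call. = FALSE)
  if (kind == "log-uniform" && lower <= 0)
    stop("log-uniform prior requires lower > 0", call. = FALSE)
  structure(list(kind = kind, lower = lower, upper = upper),
            class = "abc_prior")
}

#' Draw from a prior
#'
#' Uses the current R random number stream (seed with [set.seed()] for
#' reproducibility).
#'
#' @param prior An [priors][abc_prior] object.
#' @param n Number of independent draws.
#' @return Numeric vector of length `n`.
#' @export
draw_prior <- function(prior, n = 1) {
  stopifnot(inherits(prior, "abc_prior"))
  switch(prior$kind,
    "log-uniform" = exp(stats::runif(n, log(prior$lower), log(prior$upper))),
    "uniform"     = stats::runif(n, prior$lower, prior$upper),
    "fixed"       = rep(prior$lower, n),
    stop("unknown prior kind '", prior$kind, "'", call. = FALSE)
  )
}

#' @export
print.abc_prior <- function(x, ...) {
  if (x$kind == "fixed") {
    cat("<prior> fixed at", x$lower, "\n")
  } else {
    cat("<prior>", x$kind, "on [", x$lower, ",", x$upper, "]\n")
  }
  invisible(x)
}

# analytic mean of a log-uniform on [a, b]: (b - a) / log(b / a)
loguniform_mean <- function(lower, upper) (upper - lower) / log(upper / lower)
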