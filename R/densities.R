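#' Pareto Type-I density
#'
#' Density of the Pareto Type-I distribution used for the neutral tail of the
#' site frequency spectrum: `f(x) = shape * scale^shape / x^(shape + 1)` for
#' `x >= scale`, and 0 below the scale. The power-law tail is the
#' population-genetics prediction for the frequency of neutral mutant alleles
#' spreading in a growing population.
#'
#' @param x Numeric vector of frequencies.
#' @param scale Scale parameter `x* > 0`; the support is `[scale, Inf)`.
#' @param shape Shape parameter `alpha > 0`.
#' @param log If `TRUE`, return the log-density (`-Inf` below the scale).
#'
#' @return Numeric vector of (log-)densities.
#' @export
#'
#' @examples
#' dpareto1(0.1, scale = 0.05, shape = 1) # 5
dpareto1 <- function(x, scale, shape, log = FALSE) {
  stopifnot(is.numeric(x), length(scale) == 1, length(shape) == 1,
            scale > 0, shape > 0)
  ld <- ifelse(x >= scale,
               log(shape) + shape * log(scale) - (shape + 1) * log(x),
               -Inf)
  if (log) ld else exp(ld)
}

#' Pareto Type-I random draws, truncated to (0, 1)
#'
#' Inverse-CDF sampling; draws falling at or above `upper` are resampled, so
#' the result is a truncated Pareto suitable for frequency data.
#'
#' @param n Number of draws.
#' @param scale,shape Pareto parameters.
#' @param upper Truncation bound (default 1).
#' @return Numeric vector of length `n` in `[scale, upper)`.
#' @export
rpareto1 <- function(n, scale, shape, upper = 1) {
  stopifnot(scale > 0, shape > 0, upper > scale)
  # inverse CDF of the truncated Pareto on [scale, upper)
  p_up <- 1 - (scale / upper)^shape
  u <- stats::runif(n) * p_up
  scale * (1 - u)^(-1 / shape)
}

#' Beta component parameterised by mean and variance
#'
#' Converts a (mean, variance) pair to Beta shape parameters `(a, b)` with
#' `mean = a/(a+b)` and `variance = ab/((a+b)^2 (a+b+1))`. Requires
#' `0 < variance < mean (1 - mean)`.
#'
#' @param mean Component mean in (0, 1).
#' @param var Component variance.
#' @return List with elements `a` and `b`.
#' @export
beta_from_moments <- function(mean, var) {
  stopifnot(mean > 0, mean < 1)
  if (!(var > 0 && var < mean * (1 - mean)))
    stop("variance must lie in (0, mean*(1-mean)) for a Beta component",
         call. = FALSE)
  nu <- mean * (1 - mean) / var - 1
  list(a = mean * nu, b = (1 - mean) * nu)
}

beta_mean <- function(comp) comp$a / (comp$a + comp$b)
beta_var <- function(comp) {
  s <- comp$a + comp$b
  comp$a * comp$b / (s^2 * (s + 1))
}

# log-sum-exp over rows of a matrix; -Inf rows stay -Inf
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}
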