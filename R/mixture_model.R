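#' Construct a Beta-Pareto mixture model object
#'
#' A mixture over the site frequency spectrum with one optional Pareto Type-I
#' tail at fixed component index 1 (the neutral tail) and `k` Beta components
#' (clonal/subclonal peaks). Mixing proportions must sum to one. Beta
#' components are stored in canonical order, sorted by decreasing mean, so the
#' first Beta (named `C1`) is the clonal cluster.
#'
#' @param tail `NULL`, or a list with `scale` (`x* > 0`) and `shape`
#'   (`alpha > 0`).
#' @param betas List of Beta components, each a list with shapes `a`, `b`.
#' @param pi Numeric vector of mixing proportions, tail first when present.
#' @param ... Further fields stored on the object (scores, z, seed, ...).
#' @return Object of class `sfs_model`.
#' @export
mixture_model <- function(tail = NULL, betas = list(), pi, ...) {
  k <- length(betas)
  n_comp <- k + !is.null(tail)
  if (n_comp < 1) stop("model needs at least one component", call. = FALSE)
  stopifnot(length(pi) == n_comp)
  if (abs(sum(pi) - 1) > 1e-8)
    stop("mixing proportions must sum to 1", call. = FALSE)
  if (!is.null(tail)) stopifnot(tail$scale > 0, tail$shape > 0)
  for (b in betas) stopifnot(b$a > 0, b$b > 0)

  ord <- order(vapply(betas, beta_mean, numeric(1)), decreasing = TRUE)
  betas <- betas[ord]
  if (k > 0) {
    beta_idx <- (n_comp - k + 1):n_comp
    pi[beta_idx] <- pi[beta_idx][ord]
  }
  names(pi) <- component_names(k, !is.null(tail))
  structure(
    c(list(tail = tail, betas = betas, pi = pi, k = k,
           has_tail = !is.null(tail)),
      list(...)),
    class = "sfs_model"
  )
}

component_names <- function(k, has_tail) {
  c(if (has_tail) "Tail", if (k > 0) paste0("C", seq_len(k)))
}

#' Number of free parameters of a mixture model
#'
#' Two shapes per Beta, one shape for the tail (its scale is fixed at the
#' minimum retained frequency, not estimated) and the free simplex dimensions
#' of the mixing proportions: `lambda = 2k + [tail] + (components - 1)`.
#'
#' @param m An `sfs_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(m) {
  stopifnot(inherits(m, "sfs_model"))
  n_comp <- m$k + m$has_tail
  2L * m$k + as.integer(m$has_tail) + (n_comp - 1L)
}

#' @export
print.sfs_model <- function(x, ...) {
  cat("<sfs_model> ", x$k, " Beta component(s)",
      if (x$has_tail) " + Pareto tail", "\n", sep = "")
  if (x$has_tail)
    cat(sprintf("  Tail: scale %.4f shape %.3f  pi %.3f\n",
                x$tail$scale, x$tail$shape, x$pi[["Tail"]]))
  for (i in seq_len(x$k))
    cat(sprintf("  C%d:   mean %.4f var %.5f  pi %.3f\n", i,
                beta_mean(x$betas[[i]]), beta_var(x$betas[[i]]),
                x$pi[[paste0("C", i)]]))
  if (!is.null(x$scores))
    cat(sprintf("  NLL %.2f  BIC %.2f  ICL %.2f  reICL %.2f\n",
                x$scores$nll, x$scores$bic, x$scores$icl, x$scores$reicl))
  invisible(x)
}

# n x C matrix of per-component log densities (no mixing proportions)
component_logdens <- function(x, m) {
  cols <- list()
  if (m$has_tail)
    cols$Tail <- dpareto1(x, m$tail$scale, m$tail$shape, log = TRUE)
  for (i in seq_len(m$k))
    cols[[paste0("C", i)]] <-
      stats::dbeta(x, m$betas[[i]]$a, m$betas[[i]]$b, log = TRUE)
  do.call(cbind, cols)
}

#' Mixture density over the frequency domain
#'
#' @param x Frequencies in (0, 1).
#' @param m An `sfs_model`.
#' @param by_component If `TRUE`, return the `n x C` matrix of weighted
#'   component densities `pi_c f_c(x)`; otherwise their row sums.
#' @return Density values (vector) or matrix.
#' @export
mixture_density <- function(x, m, by_component = FALSE) {
  ld <- component_logdens(x, m) + rep(log(m$pi), each = length(x))
  if (by_component) {
    out <- exp(ld)
    colnames(out) <- names(m$pi)
    out
  } else {
    exp(row_logsumexp(ld))
  }
}

#' Negative log-likelihood of a dataset under a mixture model
#'
#' `NLL = -sum_i log( pi_1 g(x_i | x*, alpha) + sum_w pi_w h(x_i | a_w, b_w) )`
#' with `g` the Pareto tail density (omitted when the model has no tail;
#' points below the tail scale contribute only Beta mass) and `h` the Beta
#' density.
#'
#' @param d An `sfs_data` object or a numeric vector of frequencies.
#' @param m An `sfs_model`.
#' @return The negative log-likelihood (scalar).
#' @export
mixture_nll <- function(d, m) {
  x <- frequencies_of(d)
  ll <- row_logsumexp(component_logdens(x, m) +
                        rep(log(m$pi), each = length(x)))
  zero <- which(!is.finite(ll))
  if (length(zero))
    stop("mixture density is 0 at point(s) ",
         paste(utils::head(zero, 5), collapse = ", "),
         " (x = ", paste(format(utils::head(x[zero], 5)), collapse = ", "),
         "); the model cannot explain these data", call. = FALSE)
  -sum(ll)
}

frequencies_of <- function(d) {
  if (inherits(d, "sfs_data")) d$data$frequency
  else if (is.numeric(d)) d
  else stop("expected an sfs_data object or a numeric vector", call. = FALSE)
}

#' Responsibilities (latent variables) of a mixture model
#'
#' Posterior component membership probabilities
#' `z_ic = pi_c f_c(x_i) / sum_c' pi_c' f_c'(x_i)`. Rows sum to one; points
#' below the tail scale have tail responsibility exactly 0.
#'
#' @inheritParams mixture_nll
#' @return `n x C` matrix with one column per component.
#' @export
responsibilities <- function(d, m) {
  x <- frequencies_of(d)
  ld <- component_logdens(x, m) + rep(log(m$pi), each = length(x))
  ll <- row_logsumexp(ld)
  zero <- which(!is.finite(ll))
  if (length(zero))
    stop("mixture density is 0 at point(s) ",
         paste(utils::head(zero, 5), collapse = ", "), call. = FALSE)
  z <- exp(ld - ll)
  colnames(z) <- names(m$pi)
  z
}

#' Hard cluster assignments from responsibilities
#'
#' Argmax responsibility per row; ties are broken toward the lowest component
#' index, i.e. toward the tail when present, so output is deterministic.
#'
#' @param z Responsibility matrix.
#' @return Character vector of component names.
#' @export
hard_assignments <- function(z) {
  colnames(z)[max.col(z, ties.method = "first")]
}

#' Moment-matching estimator for a Beta component
#'
#' Weighted method-of-moments: with weighted mean `m` and variance `v`,
#' `a = m (m(1-m)/v - 1)` and `b = (1-m)(m(1-m)/v - 1)`. Degenerate clusters
#' (`v >= m(1-m)`, or no weight) raise a condition of class
#' `sfsmix_degenerate` so the caller can drop or reinitialise the component.
#'
#' @param x Frequencies in (0, 1).
#' @param w Non-negative responsibility weights (default uniform).
#' @return A Beta component: list with `a`, `b`.
#' @export
fit_beta_moments <- function(x, w = rep(1, length(x))) {
  sw <- sum(w)
  if (sw <= 0) degenerate_stop("beta component has zero total weight")
  m <- sum(w * x) / sw
  v <- sum(w * (x - m)^2) / sw
  if (!(m > 0 && m < 1) || v <= 0 || v >= m * (1 - m))
    degenerate_stop(sprintf(
      "degenerate beta cluster (mean %.4g, variance %.4g)", m, v))
  nu <- m * (1 - m) / v - 1
  list(a = m * nu, b = (1 - m) * nu)
}

#' Weighted maximum-likelihood estimator for a Beta component
#'
#' Maximises the weighted Beta log-likelihood in the shape parameters
#' (optimised on the log scale with analytic gradients). Used by the pure
#' maximum-likelihood fitting mode; guaranteed not to return a worse
#' likelihood than the starting value, which preserves EM monotonicity.
#'
#' @inheritParams fit_beta_moments
#' @param start Optional starting component (defaults to moment matching).
#' @return A Beta component: list with `a`, `b`.
#' @export
fit_beta_mle <- function(x, w = rep(1, length(x)), start = NULL) {
  sw <- sum(w)
  if (sw <= 0) degenerate_stop("beta component has zero total weight")
  if (is.null(start))
    start <- tryCatch(fit_beta_moments(x, w), error = function(e) NULL)
  if (is.null(start)) start <- list(a = 1, b = 1)
  slx <- sum(w * log(x))
  sl1x <- sum(w * log1p(-x))
  negll <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    -((a - 1) * slx + (b - 1) * sl1x - sw * lbeta(a, b))
  }
  grad <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    dab <- digamma(a + b)
    ga <- slx - sw * (digamma(a) - dab)
    gb <- sl1x - sw * (digamma(b) - dab)
    -c(ga * a, gb * b)
  }
  p0 <- log(c(start$a, start$b))
  opt <- tryCatch(
    stats::optim(p0, negll, grad, method = "L-BFGS-B",
                 lower = log(1e-6), upper = log(1e6)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value > negll(p0))
    return(start)
  list(a = exp(opt$par[1]), b = exp(opt$par[2]))
}

#' Maximum-likelihood estimator for the Pareto tail shape
#'
#' Weighted Hill-type estimator with fixed scale:
#' `alpha = sum_i w_i / sum_i w_i log(x_i / scale)`. All points must lie at or
#' above the scale; a zero log-sum (all mass at the scale) is degenerate.
#'
#' @param x Frequencies, each `>= scale`.
#' @param w Non-negative weights (default uniform).
#' @param scale Fixed tail scale `x*`.
#' @return Shape estimate `alpha`.
#' @export
fit_pareto_shape <- function(x, w = rep(1, length(x)), scale) {
  stopifnot(scale > 0)
  if (any(x < scale & w > 0))
    stop("points below the scale cannot carry tail weight", call. = FALSE)
  sw <- sum(w)
  if (sw <= 0) degenerate_stop("tail has zero total weight")
  s <- sum(w * log(x / scale))
  if (s <= 0) degenerate_stop("degenerate tail: all weighted points at the scale")
  sw / s
}

degenerate_stop <- function(msg) {
  cond <- structure(
    class = c("sfsmix_degenerate", "error", "condition"),
    list(message = msg, call = sys.call(-1)))
  stop(cond)
}
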