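#' Fitting and model-selection configuration
#'
#' All knobs for [fit_mixture()] and [select_model()].
#'
#' @param k_range Candidate numbers of Beta components (all `>= 1`).
#' @param tail_mode `"auto"` (compare with and without tail), `"on"` or
#'   `"off"`.
#' @param score Model-selection criterion: `"reICL"` (default), `"ICL"`,
#'   `"BIC"` or `"NLL"` (the last for debugging only).
#' @param restarts Number of random initialisations per candidate (`>= 1`).
#' @param max_iter Maximum fitting iterations.
#' @param epsilon Relative negative-log-likelihood convergence tolerance.
#' @param beta_estimator `"moment_match"` (default) or `"mle"` (pure
#'   maximum-likelihood EM; its NLL trace is non-increasing).
#' @param seed Integer seed; every restart derives its own sub-seed, so
#'   results are independent of execution order.
#' @param parallel Number of workers for restarts/bootstrap (1 = serial).
#' @return A list of class `sfs_config`.
#' @export
fit_config <- function(k_range = 1:3,
                       tail_mode = c("auto", "on", "off"),
                       score = c("reICL", "ICL", "BIC", "NLL"),
                       restarts = 10, max_iter = 500, epsilon = 1e-6,
                       beta_estimator = c("moment_match", "mle"),
                       seed = 1, parallel = 1) {
  stopifnot(length(k_range) >= 1, all(k_range >= 1),
            restarts >= 1, max_iter >= 1, epsilon > 0, parallel >= 1)
  structure(list(
    k_range = sort(unique(as.integer(k_range))),
    tail_mode = match.arg(tail_mode),
    score = match.arg(score),
    restarts = as.integer(restarts),
    max_iter = as.integer(max_iter),
    epsilon = epsilon,
    beta_estimator = match.arg(beta_estimator),
    seed = as.integer(seed),
    parallel = as.integer(parallel)
  ), class = "sfs_config")
}

# deterministic sub-seed derivation, keeps results order-independent
derive_seed <- function(seed, index, stream = 0L) {
  as.integer((as.numeric(seed) * 7919 + index * 104729 + stream * 15485863) %%
               2147483587) + 1L
}

init_model <- function(x, k, tail) {
  n <- length(x)
  means <- as.numeric(stats::quantile(x, probs = seq_len(k) / (k + 1)))
  means <- means + stats::rnorm(k, 0, 0.02)
  means <- pmin(pmax(means, 0.02), 0.98)
  # peaked initial components: a flat start (variance near the maximal
  # m(1-m)) makes the Betas near-identical, and the responsibility/moment
  # iteration then sits at a symmetric fixed point it cannot leave
  betas <- lapply(means, function(m)
    beta_from_moments(m, 0.05 * m * (1 - m)))
  tl <- if (tail) list(scale = min(x), shape = stats::runif(1, 0.5, 3))
        else NULL
  n_comp <- k + tail
  list(tail = tl, betas = betas, pi = rep(1 / n_comp, n_comp))
}

em_iterate <- function(x, par, has_tail, cfg) {
  n <- length(x)
  k <- length(par$betas)
  trace <- numeric(0)
  nll_prev <- Inf
  converged <- FALSE
  for (iter in seq_len(cfg$max_iter)) {
    m_tmp <- structure(list(tail = par$tail, betas = par$betas, pi = par$pi,
                            k = k, has_tail = has_tail), class = "sfs_model")
    ld <- component_logdens(x, m_tmp) + rep(log(par$pi), each = n)
    ll <- row_logsumexp(ld)
    if (any(!is.finite(ll)))
      degenerate_stop("mixture density 0 at some data point during fit")
    nll <- -sum(ll)
    trace <- c(trace, nll)
    rel <- abs(nll_prev - nll) / max(abs(nll_prev), 1e-12)
    if (is.finite(nll_prev) && rel < cfg$epsilon) {
      converged <- TRUE
      break
    }
    nll_prev <- nll
    z <- exp(ld - ll)

    # M-step
    cs <- colSums(z)
    if (any(cs < 1e-8))
      degenerate_stop("a component lost all responsibility mass")
    pi_new <- cs / n
    off <- as.integer(has_tail)
    tail_new <- par$tail
    if (has_tail) {
      w <- z[, 1]
      tail_new$shape <- fit_pareto_shape(x[w > 0], w[w > 0],
                                         scale = par$tail$scale)
    }
    betas_new <- vector("list", k)
    for (j in seq_len(k)) {
      w <- z[, off + j]
      betas_new[[j]] <-
        if (cfg$beta_estimator == "mle")
          fit_beta_mle(x, w, start = par$betas[[j]])
        else fit_beta_moments(x, w)
    }
    par <- list(tail = tail_new, betas = betas_new, pi = pi_new)
  }
  list(par = par, trace = trace, converged = converged)
}

#' Fit a Beta-Pareto mixture with fixed structure
#'
#' Alternates a responsibility (E-like) step with component refits: mixing
#' proportions are set to mean responsibilities, Beta components are refit by
#' weighted moment matching (default) or weighted maximum likelihood, and the
#' Pareto tail shape by its weighted closed-form MLE with the scale fixed at
#' the minimum retained frequency. The fit is repeated from `restarts` random
#' initialisations (Beta means drawn from data quantiles with jitter, tail
#' shape uniform in `[0.5, 3]`, uniform mixing proportions) and the best
#' negative log-likelihood wins. In pure maximum-likelihood mode
#' (`beta_estimator = "mle"`) the procedure is an EM algorithm and the NLL
#' trace is non-increasing.
#'
#' @param d An `sfs_data` object (or numeric frequency vector strictly inside
#'   (0, 1)).
#' @param k Number of Beta components (`>= 1`).
#' @param tail Fit the Pareto tail? (`TRUE`/`FALSE`).
#' @param config An [fit_config()]; `k_range`/`tail_mode` are ignored here.
#' @return A fitted `sfs_model` carrying responsibilities (`$z`), hard
#'   `$assignments`, `$scores`, `$lambda`, `$fit_trace`, `$converged`,
#'   `$seed`.
#' @export
fit_mixture <- function(d, k, tail = TRUE, config = fit_config()) {
  x <- frequencies_of(d)
  n <- length(x)
  k <- as.integer(k)
  stopifnot(k >= 1, n >= k + as.integer(tail))
  if (any(x <= 0 | x >= 1))
    stop("frequencies must lie strictly inside (0, 1); filter first",
         call. = FALSE)

  runs <- lapply(seq_len(config$restarts), function(r) {
    set.seed(derive_seed(config$seed, r, stream = k + 10L * tail))
    tryCatch({
      par0 <- init_model(x, k, tail)
      fit <- em_iterate(x, par0, has_tail = tail, cfg = config)
      fit$nll <- utils::tail(fit$trace, 1)
      fit
    }, sfsmix_degenerate = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0)
    stop("all ", config$restarts, " restart(s) degenerate for k = ", k,
         if (tail) " with tail" else " without tail", call. = FALSE)
  best <- runs[[which.min(vapply(runs, function(f) f$nll, numeric(1)))]]

  m <- mixture_model(tail = best$par$tail, betas = best$par$betas,
                     pi = best$par$pi)
  m$n <- n
  m$fit_trace <- best$trace
  m$converged <- best$converged
  m$seed <- config$seed
  m$beta_estimator <- config$beta_estimator
  m$frequency_kind <- if (inherits(d, "sfs_data")) d$frequency_kind else "VAF"
  m$z <- responsibilities(x, m)
  m$assignments <- hard_assignments(m$z)
  m$lambda <- n_parameters(m)
  m$scores <- score_model(x, m)
  m
}

#' Draw a random generative mixture model
#'
#' Utility for synthetic benchmarking: draws valid parameters from documented
#' ranges (tail scale uniform in `[0.02, 0.08]`, tail shape in `[0.5, 3]`,
#' Beta means spread over `[0.15, 0.9]` with pairwise separation `> 0.08`,
#' Beta variances in `[0.001, 0.004]`, mixing proportions from a symmetric
#' Dirichlet with concentration 5).
#'
#' @param k Number of Beta components.
#' @param tail Include a Pareto tail?
#' @param seed Optional integer seed.
#' @return An `sfs_model`.
#' @export
random_model <- function(k, tail = TRUE, seed = NULL) {
  stopifnot(k >= 1)
  if (!is.null(seed)) set.seed(seed)
  means <- sort(stats::runif(k, 0.15, 0.9))
  for (try in 1:100) {
    if (k == 1 || min(diff(means)) > 0.08) break
    means <- sort(stats::runif(k, 0.15, 0.9))
  }
  betas <- lapply(means, function(m)
    beta_from_moments(m, stats::runif(1, 0.001, 0.004)))
  tl <- if (tail)
    list(scale = stats::runif(1, 0.02, 0.08),
         shape = stats::runif(1, 0.5, 3))
  else NULL
  g <- stats::rgamma(k + tail, shape = 5)
  mixture_model(tail = tl, betas = betas, pi = g / sum(g))
}

#' Sample frequencies from a mixture model
#'
#' Draws component labels from the mixing proportions, then frequencies from
#' the chosen component; Pareto draws falling at or above 1 are clipped to
#' just below 1 rather than rejected (rejection deletes precisely the draws
#' most informative about the tail shape and biases its recovery).
#' Ground-truth labels are returned in the dataset's `$labels` element.
#'
#' @param m An `sfs_model`.
#' @param n Number of draws (`>= 1`).
#' @param seed Optional integer seed.
#' @return An `sfs_data` with an extra `labels` element (component names).
#' @export
sample_model <- function(m, n, seed = NULL) {
  stopifnot(inherits(m, "sfs_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample(names(m$pi), n, replace = TRUE, prob = m$pi)
  x <- numeric(n)
  is_tail <- comp == "Tail"
  if (any(is_tail))
    x[is_tail] <- rpareto1(sum(is_tail), m$tail$scale, m$tail$shape,
                           upper = Inf)
  for (i in seq_len(m$k)) {
    sel <- comp == paste0("C", i)
    if (any(sel))
      x[sel] <- stats::rbeta(sum(sel), m$betas[[i]]$a, m$betas[[i]]$b)
  }
  x <- pmin(pmax(x, 1e-9), 1 - 1e-9)
  d <- freq_dataset_from_values(x)
  d$labels <- comp
  d
}
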