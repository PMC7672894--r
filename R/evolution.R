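#' Estimate the mutation rate from the neutral tail
#'
#' Under neutral growth, population genetics predicts that the number of
#' mutations with frequency above `f` grows as `M(f) = mu (1/f - 1/f_max)`
#' (the 1/f power-law site frequency spectrum). The estimator counts the
#' mutations hard-assigned to the Pareto tail with frequency inside the window
#' `[f_min, f_max]` and inverts that relation:
#' `mu = N_tail(f_min, f_max) / (1/f_min - 1/f_max)`, giving the rate in
#' mutations per effective cell doubling. The default window clips the
#' noise-dominated extremes: `f_min` is the larger of the dataset cutoff and
#' the tail's 5th percentile, `f_max` the tail's 95th percentile.
#'
#' @param m A fitted `sfs_model` with a tail.
#' @param d The `sfs_data` it was fitted on.
#' @param f_min,f_max Optional window bounds, `f_min < f_max`.
#' @return List with `mu`, `n_tail` (window count) and `f_window`.
#' @export
#'
#' @examples
#' # 160 tail mutations in (0.05, 0.25): mu = 160 / (20 - 4) = 10
estimate_mutation_rate <- function(m, d, f_min = NULL, f_max = NULL) {
  stopifnot(inherits(m, "sfs_model"))
  if (!m$has_tail)
    stop("mutation rate is undefined without a neutral tail in the model",
         call. = FALSE)
  x <- frequencies_of(d)
  if (is.null(m$assignments) || length(m$assignments) != length(x))
    stop("model carries no assignments for this dataset; refit first",
         call. = FALSE)
  tail_f <- x[m$assignments == "Tail"]
  if (length(tail_f) == 0)
    stop("no mutations are assigned to the tail; cannot form a window",
         call. = FALSE)
  if (is.null(f_min)) {
    lo <- if (inherits(d, "sfs_data")) d$min_frequency else min(x)
    f_min <- max(lo, as.numeric(stats::quantile(tail_f, 0.05)))
  }
  if (is.null(f_max)) f_max <- as.numeric(stats::quantile(tail_f, 0.95))
  if (!(f_min < f_max))
    stop("invalid window: f_min must be smaller than f_max", call. = FALSE)
  n_tail <- sum(tail_f >= f_min & tail_f <= f_max)
  if (n_tail == 0)
    stop("empty tail window [", f_min, ", ", f_max, "]", call. = FALSE)
  mu <- n_tail / (1 / f_min - 1 / f_max)
  list(mu = mu, n_tail = n_tail, f_window = c(f_min = f_min, f_max = f_max))
}

#' Estimate subclone age and selection coefficient
#'
#' For each subclonal Beta component (every Beta except the top-mean clonal
#' cluster `C1`), dates its origin and quantifies its selective advantage, in
#' units of tumour doubling times:
#' * `t = N_sub / mu` — the subclone's private (fixed) mutations accumulated
#'   along its founder lineage at rate `mu` per doubling;
#' * the subclone cell fraction is `x = 2 * mean(Beta)` for diploid
#'   heterozygous input (the same conversion restores the CCF for halved-CCF
#'   input), clamped into (0, 1);
#' * `s = 1 + log2( x / (1 - x) ) / (T - t)` with `T` the sampling time in
#'   doublings (estimated as `N_clonal / mu` from the clonal cluster when not
#'   supplied). `s > 1` indicates positive selection relative to the ancestor
#'   baseline of 1; a subclone at exactly half the cells gives `s = 1`.
#'
#' @param m A fitted `sfs_model` with at least 2 Beta components.
#' @param d The `sfs_data` it was fitted on.
#' @param mu Mutation rate per doubling; estimated via
#'   [estimate_mutation_rate()] when `NULL`.
#' @param sampling_time Sampling time `T` in doublings; estimated from the
#'   clonal cluster when `NULL`.
#' @param clamp Upper clamp for the cell fraction (default 0.995); fractions
#'   above `1 + clamp_tol` raise an error.
#' @param clamp_tol Tolerance above 1 before erroring (default 0.1).
#' @return Data frame with one row per subclone: `cluster`, `n_sub`,
#'   `t_subclone`, `cell_fraction`, `s_subclone`, plus attributes `mu` and
#'   `sampling_time`.
#' @export
estimate_subclone_parameters <- function(m, d, mu = NULL,
                                         sampling_time = NULL,
                                         clamp = 0.995, clamp_tol = 0.1) {
  stopifnot(inherits(m, "sfs_model"))
  if (m$k < 2)
    stop("subclone parameters need at least 2 Beta components ",
         "(clonal + subclonal)", call. = FALSE)
  x <- frequencies_of(d)
  if (is.null(mu)) mu <- estimate_mutation_rate(m, d)$mu
  stopifnot(mu > 0)
  counts <- table(factor(m$assignments, levels = names(m$pi)))
  if (is.null(sampling_time))
    sampling_time <- counts[["C1"]] / mu

  rows <- lapply(2:m$k, function(j) {
    nm <- paste0("C", j)
    n_sub <- counts[[nm]]
    t_sub <- n_sub / mu
    xf <- 2 * beta_mean(m$betas[[j]])
    if (xf > 1 + clamp_tol)
      stop("subclone ", nm, " implies cell fraction ", round(xf, 3),
           " > 1; check ploidy/purity assumptions", call. = FALSE)
    xf <- min(max(xf, 1e-6), clamp)
    if (sampling_time <= t_sub)
      stop("subclone ", nm, " age (", round(t_sub, 2),
           ") is not before the sampling time (", round(sampling_time, 2),
           "); selection coefficient undefined", call. = FALSE)
    s <- 1 + log2(xf / (1 - xf)) / (sampling_time - t_sub)
    data.frame(cluster = nm, n_sub = n_sub, t_subclone = t_sub,
               cell_fraction = xf, s_subclone = s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mu") <- mu
  attr(out, "sampling_time") <- sampling_time
  out
}

#' All evolutionary parameters from a fitted model
#'
#' Convenience wrapper: mutation rate from the tail, and (for polyclonal
#' models) subclone ages and selection coefficients. Selection estimates are
#' reported only when a subclonal Beta exists.
#'
#' @inheritParams estimate_subclone_parameters
#' @param f_min,f_max Tail window for the mutation rate (see
#'   [estimate_mutation_rate()]).
#' @return List of class `sfs_evolution` with `mu`, `f_window`, `n_tail`,
#'   `sampling_time` and `subclones` (data frame or `NULL` for monoclonal
#'   fits).
#' @export
evolutionary_parameters <- function(m, d, f_min = NULL, f_max = NULL,
                                    sampling_time = NULL) {
  rate <- estimate_mutation_rate(m, d, f_min = f_min, f_max = f_max)
  sub <- NULL
  note <- NULL
  if (m$k >= 2) {
    sub <- tryCatch(
      estimate_subclone_parameters(m, d, mu = rate$mu,
                                   sampling_time = sampling_time),
      error = function(e) {
        note <<- conditionMessage(e)
        warning("subclone parameters undefined: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(sub)) sampling_time <- attr(sub, "sampling_time")
  }
  if (is.null(sampling_time)) {
    counts <- table(factor(m$assignments, levels = names(m$pi)))
    sampling_time <- counts[["C1"]] / rate$mu
  }
  structure(list(
    mu = rate$mu, n_tail = rate$n_tail, f_window = rate$f_window,
    sampling_time = sampling_time, subclones = sub, note = note
  ), class = "sfs_evolution")
}

#' @export
print.sfs_evolution <- function(x, ...) {
  cat("<sfs_evolution>\n")
  cat(sprintf("  mutation rate mu: %.2f per doubling (window %.3f-%.3f, %d tail mutations)\n",
              x$mu, x$f_window[["f_min"]], x$f_window[["f_max"]], x$n_tail))
  cat(sprintf("  sampling time T: %.2f doublings\n", x$sampling_time))
  if (is.null(x$subclones)) {
    cat("  monoclonal fit: no subclone parameters\n")
  } else {
    for (i in seq_len(nrow(x$subclones)))
      cat(sprintf("  %s: age %.2f doublings, cell fraction %.3f, s = %.3f\n",
                  x$subclones$cluster[i], x$subclones$t_subclone[i],
                  x$subclones$cell_fraction[i], x$subclones$s_subclone[i]))
  }
  invisible(x)
}
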