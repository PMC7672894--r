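model_signature <- function(m) {
  paste0("k=", m$k, if (m$has_tail) "+tail")
}

#' Bootstrap confidence for a fitted mixture model
#'
#' Non-parametric bootstrap resamples `n_boot` datasets of the original size
#' with replacement from the data; parametric bootstrap samples them from the
#' fitted model. Each resample is refit with full model selection under
#' `config`; the distribution over best model structures (`model_frequency`),
#' per-parameter draws from the resamples whose structure matches the input
#' model (components matched by mean-sorted order), and empirical quantile
#' confidence intervals at level `alpha` are collected. For the non-parametric
#' kind, the pairwise co-clustering matrix is also computed: entry `(i, j)` is
#' the fraction of resamples in which `i` and `j` both appear and share a hard
#' cluster, which is bounded above by their empirical co-sampling frequency.
#' Per-resample seeds are derived from the master seed and the resample index,
#' so results do not depend on execution order.
#'
#' @param d The `sfs_data` the model was fitted on.
#' @param m The fitted `sfs_model` (from [select_model()] or
#'   [fit_mixture()]).
#' @param kind `"nonparametric"` or `"parametric"`.
#' @param n_boot Number of resamples (`>= 1`).
#' @param alpha Confidence level parameter in (0, 1); CIs are the
#'   `(alpha/2, 1 - alpha/2)` empirical quantiles. Default 0.05.
#' @param config An [fit_config()] used to refit each resample.
#' @return Object of class `sfs_bootstrap`: list with `kind`, `n_boot`,
#'   `model_frequency`, `per_resample` (structure + parameters per resample),
#'   `parameter_draws`, `ci`, `n_failed`, and (non-parametric only)
#'   `cocluster`, `cosampling` matrices.
#' @export
bootstrap_fit <- function(d, m, kind = c("nonparametric", "parametric"),
                          n_boot = 100, alpha = 0.05,
                          config = fit_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(d, "sfs_data"), inherits(m, "sfs_model"),
            n_boot >= 1, alpha > 0, alpha < 1)
  n <- d$n
  x <- d$data$frequency

  run_one <- function(b) {
    seed_b <- derive_seed(config$seed, b, stream = 7L)
    cfg <- config
    cfg$seed <- seed_b
    set.seed(seed_b)
    idx <- NULL
    if (kind == "nonparametric") {
      idx <- sample.int(n, n, replace = TRUE)
      db <- freq_dataset_from_values(x[idx])
    } else {
      db <- sample_model(m, n)
    }
    sel <- tryCatch(select_model(db, cfg), error = function(e) NULL)
    if (is.null(sel)) return(list(ok = FALSE))
    bm <- sel$best
    list(ok = TRUE, idx = idx, signature = model_signature(bm),
         k = bm$k, has_tail = bm$has_tail,
         tail_shape = if (bm$has_tail) bm$tail$shape else NA_real_,
         beta_means = vapply(bm$betas, beta_mean, numeric(1)),
         beta_vars = vapply(bm$betas, beta_var, numeric(1)),
         pi = bm$pi,
         labels = if (!is.null(idx)) bm$assignments else NULL)
  }
  res <- if (config$parallel > 1)
    parallel::mclapply(seq_len(n_boot), run_one, mc.cores = config$parallel)
  else lapply(seq_len(n_boot), run_one)

  ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot)
    stop(n_failed, " of ", n_boot,
         " bootstrap refits failed (> 20%); aborting", call. = FALSE)
  if (n_failed > 0)
    message(n_failed, " bootstrap refit(s) failed and were excluded")
  res <- res[ok]

  sigs <- vapply(res, function(r) r$signature, character(1))
  model_frequency <- table(sigs) / length(sigs)
  target_sig <- model_signature(m)
  match_sig <- sigs == target_sig

  draws <- list()
  if (any(match_sig)) {
    sub <- res[match_sig]
    if (m$has_tail)
      draws$tail_shape <- vapply(sub, function(r) r$tail_shape, numeric(1))
    for (j in seq_len(m$k)) {
      draws[[paste0("C", j, "_mean")]] <-
        vapply(sub, function(r) r$beta_means[j], numeric(1))
      draws[[paste0("C", j, "_var")]] <-
        vapply(sub, function(r) r$beta_vars[j], numeric(1))
    }
    for (nm in names(m$pi))
      draws[[paste0("pi_", nm)]] <-
        vapply(sub, function(r) unname(r$pi[nm]), numeric(1))
  }
  ci <- if (length(draws))
    t(vapply(draws, stats::quantile,
             probs = c(alpha / 2, 1 - alpha / 2), numeric(2)))
  else NULL

  cocluster <- cosampling <- NULL
  if (kind == "nonparametric") {
    cocluster <- matrix(0, n, n)
    cosampling <- matrix(0, n, n)
    for (r in res) {
      present <- unique(r$idx)
      cosampling[present, present] <- cosampling[present, present] + 1
      lab_of <- r$labels
      for (lv in unique(lab_of)) {
        pts <- unique(r$idx[lab_of == lv])
        cocluster[pts, pts] <- cocluster[pts, pts] + 1
      }
    }
    cocluster <- cocluster / length(res)
    cosampling <- cosampling / length(res)
    rownames(cocluster) <- colnames(cocluster) <- d$data$id
    rownames(cosampling) <- colnames(cosampling) <- d$data$id
  }

  structure(list(
    kind = kind, n_boot = n_boot, alpha = alpha,
    model_frequency = model_frequency,
    target_signature = target_sig,
    per_resample = res, parameter_draws = draws, ci = ci,
    n_failed = n_failed, cocluster = cocluster, cosampling = cosampling,
    seed = config$seed
  ), class = "sfs_bootstrap")
}

#' @export
print.sfs_bootstrap <- function(x, ...) {
  cat("<sfs_bootstrap> ", x$kind, ", ", x$n_boot, " resamples (",
      x$n_failed, " failed)\n", sep = "")
  cat("Model frequency:\n")
  print(round(x$model_frequency, 3))
  if (!is.null(x$ci)) {
    cat("Parameter CIs (level ", x$alpha, "):\n", sep = "")
    print(round(x$ci, 4))
  }
  invisible(x)
}

#' Pairwise co-clustering matrix from a non-parametric bootstrap
#'
#' Default normalisation divides the pairwise co-assignment counts by the
#' total number of resamples, so entries are bounded above by the empirical
#' co-sampling frequency of each pair; the `"conditional"` variant divides by
#' the number of resamples in which both points appear (0 where they never
#' co-occur).
#'
#' @param boot An `sfs_bootstrap` of kind `"nonparametric"`.
#' @param normalisation `"total"` (default) or `"conditional"`.
#' @return Symmetric `n x n` matrix with entries in `[0, 1]`; the diagonal is
#'   each point's self-sampling frequency.
#' @export
cocluster_matrix <- function(boot, normalisation = c("total", "conditional")) {
  normalisation <- match.arg(normalisation)
  stopifnot(inherits(boot, "sfs_bootstrap"))
  if (boot$kind != "nonparametric")
    stop("co-clustering is defined for the non-parametric bootstrap only ",
         "(pairs are not resampled entities under the parametric kind)",
         call. = FALSE)
  if (normalisation == "total") return(boot$cocluster)
  out <- boot$cocluster / boot$cosampling
  out[boot$cosampling == 0] <- 0
  out
}
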