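#' Deconvolve a site frequency spectrum by model selection
#'
#' The main fitting interface. Fits every candidate structure on the grid
#' (each `k` in `k_range`, with and/or without the Pareto tail according to
#' `tail_mode`), each with `restarts` random initialisations, keeps the best
#' restart per candidate, and ranks candidates by the chosen score (default
#' reICL, minimised). A selected model with `k = 1` represents a monoclonal
#' tumour (no evidence of ongoing subclonal selection); `k > 1` is polyclonal.
#'
#' @param d An `sfs_data` object with frequencies strictly inside (0, 1).
#' @param config An [fit_config()].
#' @return Object of class `sfs_selection`: list with `best` (the selected
#'   `sfs_model`), `models` (all candidates), `candidates` (score table,
#'   ranked), `score_used`, and `clonal_status`.
#' @export
select_model <- function(d, config = fit_config()) {
  stopifnot(inherits(d, "sfs_data"))
  tails <- switch(config$tail_mode,
                  auto = c(TRUE, FALSE), on = TRUE, off = FALSE)
  grid <- expand.grid(k = config$k_range, tail = tails)
  grid <- grid[order(grid$k, !grid$tail), , drop = FALSE]

  fit_one <- function(i) {
    tryCatch(
      fit_mixture(d, k = grid$k[i], tail = grid$tail[i], config = config),
      error = function(e) e)
  }
  models <- if (config$parallel > 1)
    parallel::mclapply(seq_len(nrow(grid)), fit_one,
                       mc.cores = config$parallel)
  else lapply(seq_len(nrow(grid)), fit_one)

  ok <- vapply(models, inherits, logical(1), what = "sfs_model")
  if (!any(ok)) {
    msgs <- vapply(models, conditionMessage, character(1))
    stop("all candidate fits failed:\n  ",
         paste(unique(msgs), collapse = "\n  "), call. = FALSE)
  }
  tab <- data.frame(
    k = grid$k, tail = grid$tail,
    nll = NA_real_, bic = NA_real_, icl = NA_real_, reicl = NA_real_,
    entropy = NA_real_, reduced_entropy = NA_real_,
    lambda = NA_integer_, converged = NA, degenerate = !ok)
  for (i in which(ok)) {
    s <- models[[i]]$scores
    tab$nll[i] <- s$nll; tab$bic[i] <- s$bic
    tab$icl[i] <- s$icl; tab$reicl[i] <- s$reicl
    tab$entropy[i] <- s$entropy
    tab$reduced_entropy[i] <- s$reduced_entropy
    tab$lambda[i] <- s$lambda
    tab$converged[i] <- models[[i]]$converged
  }
  crit <- c(reICL = "reicl", ICL = "icl", BIC = "bic", NLL = "nll")[
    config$score]
  ord <- order(ifelse(ok, tab[[crit]], Inf))
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  models <- models[ord]
  best <- models[[1]]

  structure(list(
    best = best, models = models[vapply(models, inherits, logical(1),
                                        what = "sfs_model")],
    candidates = tab, score_used = config$score, config = config,
    clonal_status = if (best$k == 1) "monoclonal" else "polyclonal"
  ), class = "sfs_selection")
}

#' @export
print.sfs_selection <- function(x, ...) {
  cat("<sfs_selection> best model by ", x$score_used, " (",
      x$clonal_status, " tumour)\n", sep = "")
  print(x$best)
  cat("Candidates:\n")
  print(x$candidates[, c("rank", "k", "tail", "nll", "bic", "icl", "reicl",
                         "degenerate")],
        row.names = FALSE, digits = 6)
  invisible(x)
}

#' Post-hoc removal of small Beta clusters
#'
#' Removes Beta components whose mixing proportion is below `min_pi` or whose
#' hard-assigned mutation count is below `min_count`; the tail is never
#' removed by this heuristic. Mixing proportions are renormalised and
#' responsibilities, assignments and scores recomputed under the surviving
#' components (set `refit = TRUE` to re-run the full fit at the reduced `k`
#' instead).
#'
#' @param m A fitted `sfs_model` (with `$z`).
#' @param d The `sfs_data` it was fitted on.
#' @param min_pi Minimum mixing proportion (default 0.02).
#' @param min_count Minimum hard-assigned mutation count (default 10).
#' @param refit Refit remaining components from scratch?
#' @param config Configuration used when `refit = TRUE`.
#' @return A pruned (or refitted) `sfs_model`.
#' @export
filter_clusters <- function(m, d, min_pi = 0.02, min_count = 10,
                            refit = FALSE, config = fit_config()) {
  stopifnot(inherits(m, "sfs_model"), min_pi >= 0, min_count >= 0)
  x <- frequencies_of(d)
  counts <- table(factor(m$assignments, levels = names(m$pi)))
  beta_names <- paste0("C", seq_len(m$k))
  keep <- vapply(beta_names, function(nm)
    m$pi[[nm]] >= min_pi && counts[[nm]] >= min_count, logical(1))
  if (!any(keep))
    stop("cluster filter would remove every Beta component; ",
         "lower the thresholds", call. = FALSE)
  if (all(keep)) return(m)

  if (refit) {
    cfg <- config
    cfg$k_range <- sum(keep)
    return(fit_mixture(d, k = sum(keep), tail = m$has_tail, config = cfg))
  }
  pi_new <- m$pi[c(if (m$has_tail) "Tail", beta_names[keep])]
  pi_new <- pi_new / sum(pi_new)
  out <- mixture_model(tail = m$tail, betas = m$betas[keep], pi = pi_new)
  out$n <- length(x)
  out$seed <- m$seed
  out$beta_estimator <- m$beta_estimator
  out$frequency_kind <- m$frequency_kind
  out$converged <- m$converged
  out$fit_trace <- m$fit_trace
  out$z <- responsibilities(x, out)
  out$assignments <- hard_assignments(out$z)
  out$lambda <- n_parameters(out)
  out$scores <- score_model(x, out)
  out$filtered <- list(min_pi = min_pi, min_count = min_count,
                       removed = beta_names[!keep])
  out
}

#' Assign previously unseen mutations to a fitted model
#'
#' Computes responsibilities and hard labels for new frequencies, conditioning
#' on the inferred parameters; the model is not modified.
#'
#' @param m A fitted `sfs_model`.
#' @param x Numeric vector of frequencies in (0, 1).
#' @return List with `z` (responsibility matrix) and `labels` (hard
#'   assignments).
#' @export
assign_mutations <- function(m, x) {
  stopifnot(is.numeric(x), all(x > 0), all(x < 1))
  z <- responsibilities(x, m)
  list(z = z, labels = hard_assignments(z))
}
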