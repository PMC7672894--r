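#' Entropy of a responsibility matrix
#'
#' `H(z) = -sum_ic z_ic log z_ic` with the convention `0 log 0 = 0`; natural
#' logarithm.
#'
#' @param z Matrix with simplex-normalised rows.
#' @return Scalar entropy (nats).
#' @export
latent_entropy <- function(z) {
  z <- as.matrix(z)
  t <- z * log(z)
  t[z == 0] <- 0
  -sum(t)
}

#' Reduced entropy of a responsibility matrix
#'
#' Entropy of the latent variables after removal of tail mutations: rows whose
#' hard assignment is the tail are dropped, the tail column is removed, the
#' remaining rows are renormalised over the Beta columns, and the entropy of
#' the result is returned. For a model without a tail this equals
#' [latent_entropy()]. The reduced entropy is what the reICL score penalises:
#' overlap between Beta components, ignoring the tail.
#'
#' @param z Responsibility matrix, tail in column `tail_index`.
#' @param tail_index Column index of the tail, or `NULL`/`NA` for no tail.
#' @return Scalar entropy; 0 (with a warning) if every row is tail-assigned.
#' @export
reduced_latent_entropy <- function(z, tail_index = 1) {
  z <- as.matrix(z)
  if (is.null(tail_index) || is.na(tail_index)) return(latent_entropy(z))
  hard <- max.col(z, ties.method = "first")
  keep <- hard != tail_index
  if (!any(keep)) {
    warning("all points hard-assigned to the tail; reduced entropy is 0",
            call. = FALSE)
    return(0)
  }
  zz <- z[keep, -tail_index, drop = FALSE]
  zz <- zz / rowSums(zz)
  latent_entropy(zz)
}

#' Score a fitted mixture model
#'
#' Computes the full score set:
#' `BIC = 2 NLL + lambda log n`, `ICL = BIC + H(z)`,
#' `reICL = BIC + H(z-hat)` where `H(z)` is the entropy of the latent
#' variables and `z-hat` is their tail-reduced renormalisation. reICL (the
#' default selection criterion) penalises overlap between Beta components,
#' promoting models with well-separated subclonal peaks.
#'
#' @param d An `sfs_data` or frequency vector the model was fitted on.
#' @param m An `sfs_model`.
#' @return List of class `sfs_scores` with `nll`, `bic`, `icl`, `reicl`,
#'   `entropy`, `reduced_entropy`, `lambda`, `n`.
#' @export
score_model <- function(d, m) {
  x <- frequencies_of(d)
  n <- length(x)
  z <- if (!is.null(m$z) && nrow(m$z) == n) m$z else responsibilities(x, m)
  nll <- mixture_nll(x, m)
  lambda <- n_parameters(m)
  H <- latent_entropy(z)
  Hred <- reduced_latent_entropy(z, tail_index = if (m$has_tail) 1 else NA)
  bic <- 2 * nll + lambda * log(n)
  structure(list(
    nll = nll, bic = bic, icl = bic + H, reicl = bic + Hred,
    entropy = H, reduced_entropy = Hred, lambda = lambda, n = n
  ), class = "sfs_scores")
}
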