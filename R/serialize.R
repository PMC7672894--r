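#' Serialise a fitted model to JSON
#'
#' Writes components, mixing proportions, scores, parameter count, seed and
#' fitting metadata (not the responsibility matrix; use
#' [write_assignments()] for the per-mutation table).
#'
#' @param m A fitted `sfs_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(m, path) {
  stopifnot(inherits(m, "sfs_model"))
  obj <- list(
    k = m$k, has_tail = m$has_tail,
    tail = m$tail,
    betas = lapply(m$betas, function(b)
      list(a = b$a, b = b$b, mean = beta_mean(b), var = beta_var(b))),
    pi = as.list(m$pi),
    scores = if (!is.null(m$scores)) unclass(m$scores),
    lambda = m$lambda, n = m$n,
    converged = m$converged, seed = m$seed,
    beta_estimator = m$beta_estimator,
    frequency_kind = m$frequency_kind)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a model back from JSON
#'
#' @param path A file written by [write_model_json()].
#' @return An `sfs_model` (without responsibilities; use
#'   [assign_mutations()] to score data against it).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  m <- mixture_model(
    tail = if (!is.null(obj$tail))
      list(scale = obj$tail$scale, shape = obj$tail$shape),
    betas = lapply(obj$betas, function(b) list(a = b$a, b = b$b)),
    pi = unlist(obj$pi))
  m$scores <- obj$scores
  m$lambda <- obj$lambda
  m$n <- obj$n
  m$converged <- obj$converged
  m$seed <- obj$seed
  m$beta_estimator <- obj$beta_estimator
  m$frequency_kind <- obj$frequency_kind
  m
}

#' Write the per-mutation assignment table
#'
#' TSV with mutation id, frequency, hard cluster label and per-component
#' responsibilities, in input order. Designed so downstream tools (dN/dS,
#' clone trees) can consume the clusters.
#'
#' @param d The `sfs_data`.
#' @param m The fitted `sfs_model` for it.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(d, m, path) {
  stopifnot(inherits(d, "sfs_data"), inherits(m, "sfs_model"),
            !is.null(m$z), nrow(m$z) == d$n)
  out <- data.frame(id = d$data$id, frequency = d$data$frequency,
                    cluster = m$assignments, stringsAsFactors = FALSE)
  z <- as.data.frame(m$z)
  names(z) <- paste0("z_", names(z))
  out <- cbind(out, z)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialise a model-selection report to JSON
#'
#' @param sel An `sfs_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(sel, path) {
  stopifnot(inherits(sel, "sfs_selection"))
  obj <- list(
    score_used = sel$score_used,
    clonal_status = sel$clonal_status,
    candidates = sel$candidates,
    best = list(k = sel$best$k, has_tail = sel$best$has_tail,
                tail = sel$best$tail,
                betas = lapply(sel$best$betas, function(b)
                  list(a = b$a, b = b$b, mean = beta_mean(b))),
                pi = as.list(sel$best$pi),
                scores = unclass(sel$best$scores)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", dataframe = "rows")
  invisible(path)
}

#' Serialise bootstrap results
#'
#' Writes the result JSON (model frequency, CIs, failure count) and, for
#' non-parametric runs, the co-clustering matrix as TSV.
#'
#' @param boot An `sfs_bootstrap`.
#' @param dir Output directory (created if missing).
#' @return Named vector of written paths, invisibly.
#' @export
write_bootstrap <- function(boot, dir) {
  stopifnot(inherits(boot, "sfs_bootstrap"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(json = file.path(dir, "bootstrap.json"))
  obj <- list(
    kind = boot$kind, n_boot = boot$n_boot, alpha = boot$alpha,
    n_failed = boot$n_failed,
    target_signature = boot$target_signature,
    model_frequency = as.list(boot$model_frequency),
    ci = if (!is.null(boot$ci))
      stats::setNames(lapply(seq_len(nrow(boot$ci)), function(i)
        as.list(stats::setNames(boot$ci[i, ], colnames(boot$ci)))),
        rownames(boot$ci)))
  jsonlite::write_json(obj, paths[["json"]], auto_unbox = TRUE, digits = I(17),
                       null = "null")
  if (!is.null(boot$ci)) {
    paths[["ci"]] <- file.path(dir, "ci.tsv")
    ci <- data.frame(parameter = rownames(boot$ci), boot$ci,
                     check.names = FALSE)
    utils::write.table(ci, paths[["ci"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(boot$cocluster)) {
    paths[["cocluster"]] <- file.path(dir, "cocluster.tsv")
    utils::write.table(boot$cocluster, paths[["cocluster"]], sep = "\t",
                       quote = FALSE, row.names = TRUE, col.names = NA)
  }
  invisible(paths)
}

#' Serialise evolutionary estimates
#'
#' JSON with the mutation rate and window, plus a one-row-per-subclone TSV.
#'
#' @param ev An `sfs_evolution`.
#' @param dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_evolution <- function(ev, dir) {
  stopifnot(inherits(ev, "sfs_evolution"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(json = file.path(dir, "evolution.json"))
  obj <- list(mu = ev$mu, n_tail = ev$n_tail,
              f_window = as.list(ev$f_window),
              sampling_time = ev$sampling_time,
              subclones = ev$subclones)
  jsonlite::write_json(obj, paths[["json"]], auto_unbox = TRUE, digits = I(17),
                       null = "null", dataframe = "rows")
  if (!is.null(ev$subclones)) {
    paths[["subclones"]] <- file.path(dir, "subclones.tsv")
    utils::write.table(ev$subclones, paths[["subclones"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
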