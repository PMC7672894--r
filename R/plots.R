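# Every plotting function returns an `sfs_plot`: the ggplot object plus the
# exact numeric series plotted, so tests target data rather than pixels.
new_sfs_plot <- function(plot, series, kind) {
  structure(list(plot = plot, series = series, kind = kind),
            class = "sfs_plot")
}

#' @export
print.sfs_plot <- function(x, ...) {
  print(x$plot)
  invisible(x)
}

#' Render a plot object to a figure file
#'
#' @param p An `sfs_plot`.
#' @param path Output file (`.png`, `.pdf` or `.svg` by extension).
#' @param width,height,dpi Device settings.
#' @return `path`, invisibly.
#' @export
render_plot <- function(p, path, width = 7, height = 5, dpi = 150) {
  stopifnot(inherits(p, "sfs_plot"))
  ggplot2::ggsave(path, plot = p$plot, width = width, height = height,
                  dpi = dpi)
  invisible(path)
}

density_grid <- function(m, from, to, grid_n = 512) {
  grid <- seq(from, to, length.out = grid_n)
  grid <- grid[grid > 0 & grid < 1]
  dens <- mixture_density(grid, m, by_component = TRUE)
  data.frame(x = grid, dens, total = rowSums(dens), check.names = FALSE)
}

#' Fit histogram with overlaid mixture density
#'
#' Histogram of the observed frequencies coloured by hard clustering
#' assignment, with the fitted density of each component (`pi_c f_c`) and
#' their sum overlaid.
#'
#' @param d The `sfs_data`.
#' @param m The fitted `sfs_model` for it.
#' @param bins Number of histogram bins on `[0, 1]` (default 100).
#' @return An `sfs_plot`; its series holds the density grid and the per-bin
#'   assignment counts.
#' @export
plot_fit <- function(d, m, bins = 100) {
  stopifnot(inherits(d, "sfs_data"), inherits(m, "sfs_model"))
  x <- d$data$frequency
  if (m$n != length(x))
    stop("model and dataset sizes differ", call. = FALSE)
  breaks <- seq(0, 1, length.out = bins + 1)
  lab <- m$assignments
  bin_id <- cut(x, breaks, include.lowest = TRUE)
  counts <- as.data.frame(table(bin = bin_id, cluster = lab),
                          stringsAsFactors = FALSE)
  dens <- density_grid(m, min(x), max(x))

  hdf <- data.frame(x = x, cluster = lab)
  long <- do.call(rbind, lapply(names(m$pi), function(nm)
    data.frame(x = dens$x, density = dens[[nm]], component = nm)))
  bw <- breaks[2] - breaks[1]
  gg <- ggplot2::ggplot(hdf, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density),
                   fill = .data$cluster),
      breaks = breaks, alpha = 0.7) +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_line(data = data.frame(x = dens$x, y = dens$total),
                       ggplot2::aes(y = .data$y), linewidth = 0.9) +
    ggplot2::labs(x = "Observed frequency", y = "Density",
                  title = sprintf("%d Beta component(s)%s, n = %d", m$k,
                                  if (m$has_tail) " + Pareto tail" else "",
                                  m$n)) +
    ggplot2::theme_minimal()
  new_sfs_plot(gg, list(density = dens, bin_counts = counts,
                        breaks = breaks, binwidth = bw),
               kind = "fit_histogram")
}

#' Model-selection score panel
#'
#' One point per candidate structure and score, with the selected model
#' highlighted.
#'
#' @param sel An `sfs_selection`.
#' @return An `sfs_plot`; its series is the ranked candidate table.
#' @export
plot_scores <- function(sel) {
  stopifnot(inherits(sel, "sfs_selection"))
  tab <- sel$candidates
  tab$model <- paste0("k=", tab$k, ifelse(tab$tail, "+tail", ""))
  long <- do.call(rbind, lapply(c("nll", "bic", "icl", "reicl"), function(s)
    data.frame(model = tab$model, score = toupper(s), value = tab[[s]],
               best = tab$rank == 1)))
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value,
                                           colour = .data$best)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~score, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red",
                                            `FALSE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "Score",
                  title = paste("Model selection by", sel$score_used)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  new_sfs_plot(gg, tab, kind = "score_panel")
}

#' Entropy profile over the frequency domain
#'
#' Computes, on a grid over the observed support, the entropy of the
#' assignment probabilities implied by the relative component densities at
#' each frequency: high values mark regions where cluster assignments are
#' uncertain. Both the standard profile and the reduced variant (0 where the
#' tail dominates; Beta-renormalised elsewhere) are returned; the reduced
#' profile is bounded above by the standard one.
#'
#' @param m A fitted `sfs_model`.
#' @param from,to Grid range (defaults to the tail scale, or 0.01, up to
#'   0.99).
#' @param grid_n Grid size.
#' @return An `sfs_plot`; its series has columns `x`, `entropy`,
#'   `reduced_entropy`.
#' @export
plot_entropy_profile <- function(m, from = NULL, to = 0.99, grid_n = 200) {
  stopifnot(inherits(m, "sfs_model"))
  if (is.null(from)) from <- if (m$has_tail) m$tail$scale else 0.01
  grid <- seq(from, to, length.out = grid_n)
  z <- responsibilities(grid, m)
  row_entropy <- function(zz) {
    t <- zz * log(zz); t[zz == 0] <- 0; -rowSums(t)
  }
  H <- row_entropy(z)
  if (m$has_tail) {
    hard <- max.col(z, ties.method = "first")
    zz <- z[, -1, drop = FALSE]
    rs <- rowSums(zz)
    zz <- zz / ifelse(rs > 0, rs, 1)
    Hred <- ifelse(hard == 1 | rs == 0, 0, row_entropy(zz))
  } else Hred <- H
  series <- data.frame(x = grid, entropy = H, reduced_entropy = Hred)
  long <- rbind(
    data.frame(x = grid, value = H, variant = "standard"),
    data.frame(x = grid, value = Hred, variant = "reduced"))
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$value,
                                           linetype = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency", y = "Entropy (nats)",
                  title = "Assignment entropy profile") +
    ggplot2::theme_minimal()
  new_sfs_plot(gg, series, kind = "entropy_profile")
}

#' Latent-variable heatmap
#'
#' Per-mutation assignment probabilities, rows ordered by hard assignment and
#' then frequency, so cluster blocks are contiguous.
#'
#' @param m A fitted `sfs_model` (with `$z`).
#' @param d The `sfs_data` it was fitted on.
#' @return An `sfs_plot`; its series is the row-ordered `z` matrix.
#' @export
plot_latent_heatmap <- function(m, d) {
  stopifnot(inherits(m, "sfs_model"), !is.null(m$z))
  x <- frequencies_of(d)
  ord <- order(factor(m$assignments, levels = names(m$pi)), x)
  z <- m$z[ord, , drop = FALSE]
  long <- data.frame(
    row = rep(seq_len(nrow(z)), ncol(z)),
    component = rep(colnames(z), each = nrow(z)),
    value = as.vector(z))
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$component, .data$row,
                                           fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Mutation (ordered by cluster)",
                  fill = "z") +
    ggplot2::theme_minimal()
  new_sfs_plot(gg, list(z = z, order = ord), kind = "latent_heatmap")
}

#' Mixing-proportion barplot
#'
#' @param m A fitted `sfs_model`.
#' @return An `sfs_plot`; its series is the named proportion vector.
#' @export
plot_mixing <- function(m) {
  stopifnot(inherits(m, "sfs_model"))
  df <- data.frame(component = names(m$pi), pi = as.numeric(m$pi))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$pi,
                                         fill = .data$component)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Mixing proportion") +
    ggplot2::theme_minimal()
  new_sfs_plot(gg, m$pi, kind = "mixing_barplot")
}

#' Coverage histogram
#'
#' Histogram of the sequencing depth of the input mutations.
#'
#' @param d An `sfs_data` with a `depth` column.
#' @param bins Number of bins.
#' @return An `sfs_plot`; its series is the depth vector.
#' @export
plot_coverage <- function(d, bins = 50) {
  stopifnot(inherits(d, "sfs_data"))
  if (is.null(d$data$depth) || all(is.na(d$data$depth)))
    stop("dataset has no depth information", call. = FALSE)
  df <- data.frame(depth = d$data$depth)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$depth)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue") +
    ggplot2::labs(x = "Sequencing depth", y = "Mutations",
                  title = sprintf("Median coverage %dx",
                                  as.integer(stats::median(df$depth)))) +
    ggplot2::theme_minimal()
  new_sfs_plot(gg, df$depth, kind = "coverage_histogram")
}

#' Bootstrap distributions
#'
#' Model-frequency barplot and histograms of the per-parameter bootstrap
#' draws with their confidence intervals.
#'
#' @param boot An `sfs_bootstrap`.
#' @return An `sfs_plot`; its series holds the model-frequency table and the
#'   parameter draws.
#' @export
plot_bootstrap_distributions <- function(boot) {
  stopifnot(inherits(boot, "sfs_bootstrap"))
  freq <- data.frame(signature = names(boot$model_frequency),
                     frequency = as.numeric(boot$model_frequency))
  draws <- boot$parameter_draws
  if (length(draws)) {
    long <- do.call(rbind, lapply(names(draws), function(nm)
      data.frame(parameter = nm, value = draws[[nm]])))
    gg <- ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
      ggplot2::geom_histogram(bins = 30, fill = "grey40") +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = "Bootstrap draw", y = "Count",
                    title = sprintf("%s bootstrap (%d resamples)",
                                    boot$kind, boot$n_boot)) +
      ggplot2::theme_minimal()
  } else {
    gg <- ggplot2::ggplot(freq,
                          ggplot2::aes(.data$signature, .data$frequency)) +
      ggplot2::geom_col() + ggplot2::theme_minimal()
  }
  new_sfs_plot(gg, list(model_frequency = freq, draws = draws, ci = boot$ci),
               kind = "bootstrap_distributions")
}

#' Co-clustering heatmap
#'
#' The pairwise co-clustering probability matrix of a non-parametric
#' bootstrap, rows and columns permuted so cluster blocks from the reference
#' model are contiguous (ordered by hard assignment, then frequency).
#'
#' @param boot An `sfs_bootstrap` of kind `"nonparametric"`.
#' @param m The reference fitted `sfs_model`.
#' @param d The `sfs_data`.
#' @param normalisation Passed to [cocluster_matrix()].
#' @return An `sfs_plot`; its series holds the permuted matrix and the row
#'   order.
#' @export
plot_cocluster <- function(boot, m, d,
                           normalisation = c("total", "conditional")) {
  cc <- cocluster_matrix(boot, normalisation)
  x <- frequencies_of(d)
  if (nrow(cc) != length(x) || length(m$assignments) != length(x))
    stop("bootstrap, model and dataset sizes differ", call. = FALSE)
  ord <- order(factor(m$assignments, levels = names(m$pi)), x)
  ccp <- cc[ord, ord]
  long <- data.frame(i = rep(seq_len(nrow(ccp)), ncol(ccp)),
                     j = rep(seq_len(ncol(ccp)), each = nrow(ccp)),
                     value = as.vector(ccp))
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$i, .data$j,
                                           fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-clustering",
                  title = "Pairwise co-clustering probability") +
    ggplot2::theme_minimal()
  new_sfs_plot(gg, list(matrix = ccp, order = ord),
               kind = "cocluster_heatmap")
}
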