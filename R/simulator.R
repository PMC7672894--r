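#' Configuration for the branching-process tumour simulator
#'
#' The simulator grows a tumour through discrete, non-overlapping generations
#' of a linear birth-death process: each baseline cell divides with
#' probability `birth_prob` (both daughters inherit the parent's mutations and
#' each gains a Poisson(`mu_sim`) load of new, unique mutations -
#' infinite-sites), dies with probability `death_prob`, or persists. The
#' stochasticity of divisions and deaths is what diffuses lineage sizes and
#' produces the smooth 1/f neutral tail the Pareto component encodes; a
#' deterministic doubling regime (`birth_prob = 1`, `death_prob = 0`) instead
#' concentrates the site frequency spectrum on dyadic atoms.
#'
#' `driver_time` and `sampling_time` are expressed in effective tumour
#' doublings: one time unit is one expected division along the ancestry of a
#' randomly drawn surviving cell, which is the clock under which a lineage
#' accrues `mu_sim` mutations per unit - exactly the convention the
#' downstream mutation-rate and subclone-age estimators assume. The ancestry
#' of a random cell is size-biased (paths through a division carry double
#' weight), so it divides with probability `2b / (2b + persist)` per
#' generation, and times are converted to generations through that rate. The
#' default birth/death/persist probabilities (0.417 / 0.058 / 0.525, growth
#' e/2 per generation) additionally make the windowed site frequency
#' spectrum of neutral mutations carry exactly `mu_sim` mutations per unit
#' of 1/VAF: the generation-shell structure of the discrete process (growth
#' `gamma` places mutation cohorts on frequency shells `gamma^-g`) gives a
#' windowed spectrum of `mu * b / (gamma log gamma)` per 1/VAF unit, and
#' `b = gamma log gamma` pins it at `mu`.
#'
#' At the end of the generation closest to `driver_time` doublings, one
#' uniformly chosen live cell gains a driver mutation and founds the
#' subclone. The driver's selective advantage is a clock-speed multiplier:
#' driver cells run `fitness_multiplier` standard birth-death-persist rounds
#' per generation (integer part guaranteed, fractional part Bernoulli per
#' cell), so the driver clone grows by `gamma^fitness_multiplier` per
#' generation while its internal neutral dynamics remain statistically
#' identical to the host clone's. A division-probability advantage alone is
#' bounded at one division per generation and can never lift a late
#' single-cell founder to a detectable fraction within a few doublings.
#'
#' Driver runs condition on a detectable, unswept subclone: runs in which the
#' driver lineage dies out, or whose final subclone cell fraction falls
#' outside `subclone_range`, are re-drawn with a derived seed (the biopsy is
#' taken mid-sweep, when the subclone is detectable relative to the tumour
#' mass but has not yet fixed). Whole-population extinctions are re-drawn the
#' same way.
#'
#' The founder cell carries a Poisson(`clonal_mutations`) truncal load; its
#' default, `mu_sim * sampling_time`, makes the truncal branch length equal
#' the tumour age in doublings, the convention the age estimator assumes.
#'
#' @param birth_prob Per-generation division probability of baseline cells.
#' @param death_prob Per-generation death probability
#'   (`birth_prob + death_prob <= 1`; the remainder persists).
#' @param mu_sim Mean new mutations per daughter cell per division (Poisson).
#' @param driver_time Tumour doubling at which the driver appears, or `NA`
#'   for a neutral (monoclonal) tumour.
#' @param fitness_multiplier Relative growth advantage of driver progeny
#'   (`> 1`): the factor by which the driver clone's birth-death dynamics run
#'   faster than the baseline clock.
#' @param sampling_time Tumour doubling of the biopsy.
#' @param subclone_range Admissible final subclone cell-fraction interval for
#'   driver runs (conditioning; see above).
#' @param coverage_rate Mean sequencing depth (Poisson rate).
#' @param purity Fraction of tumour cells in the sample.
#' @param vaf_cutoff Detection threshold: observed VAF must exceed it.
#' @param clonal_mutations Expected truncal mutation load of the founding
#'   cell; default `mu_sim * sampling_time`.
#' @param population_cap Stop growing early beyond this many cells.
#' @param min_true_vaf Mutations whose true VAF is below this floor are not
#'   expanded into the sequencing table (they cannot plausibly pass the
#'   detection threshold, and the full infinite-sites catalog is huge).
#' @param seed Integer seed.
#' @param max_retries Re-draws allowed when the population goes extinct.
#' @return List of class `sfs_sim_config`.
#' @export
simulation_config <- function(birth_prob = 0.417, death_prob = 0.058,
                              mu_sim = 16,
                              driver_time = 13, fitness_multiplier = 4.1,
                              sampling_time = 17, coverage_rate = 120,
                              purity = 1, vaf_cutoff = 0.05,
                              clonal_mutations = NULL,
                              subclone_range = c(0.45, 0.62),
                              population_cap = 1e6, min_true_vaf = 0.01,
                              seed = 1, max_retries = 100) {
  stopifnot(birth_prob >= 0, birth_prob <= 1,
            death_prob >= 0, death_prob <= 1,
            birth_prob + death_prob <= 1,
            birth_prob > death_prob,
            mu_sim >= 0, sampling_time >= 1,
            coverage_rate > 0, purity > 0, purity <= 1,
            vaf_cutoff >= 0, vaf_cutoff <= 1, population_cap >= 1)
  has_driver <- !is.null(driver_time) && !is.na(driver_time)
  if (has_driver) {
    stopifnot(driver_time >= 1, sampling_time >= driver_time,
              fitness_multiplier > 1,
              length(subclone_range) == 2, subclone_range[1] >= 0,
              subclone_range[2] <= 1,
              subclone_range[1] < subclone_range[2])
  }
  if (is.null(clonal_mutations)) clonal_mutations <- mu_sim * sampling_time
  # effective doublings -> generations: the size-biased ancestry of a random
  # surviving cell divides with probability 2b/(2b + persist) per generation
  persist <- 1 - birth_prob - death_prob
  gens_per_doubling <- (2 * birth_prob + persist) / (2 * birth_prob)
  structure(list(
    birth_prob = birth_prob, death_prob = death_prob, mu_sim = mu_sim,
    driver_time = if (has_driver) driver_time else NA_real_,
    fitness_multiplier = fitness_multiplier,
    sampling_time = sampling_time,
    driver_generation = if (has_driver)
      max(1L, as.integer(round(driver_time * gens_per_doubling)))
    else NA_integer_,
    sampling_generation = max(1L, as.integer(round(sampling_time *
                                                     gens_per_doubling))),
    gens_per_doubling = gens_per_doubling,
    subclone_range = subclone_range,
    coverage_rate = coverage_rate, purity = purity,
    vaf_cutoff = vaf_cutoff, clonal_mutations = clonal_mutations,
    population_cap = population_cap, min_true_vaf = min_true_vaf,
    seed = as.integer(seed), max_retries = as.integer(max_retries)
  ), class = "sfs_sim_config")
}

# one synchronous division round: every cell in `nodes` divides; returns the
# appended node table and the new cell node-ids
divide_all <- function(state, nodes, mu) {
  nd <- length(nodes)
  if (nd == 0) return(integer(0))
  first <- length(state$parent) + 1L
  ids <- first:(first + 2L * nd - 1L)
  state$parent <- c(state$parent, rep(nodes, each = 2L))
  state$nmut <- c(state$nmut, stats::rpois(2L * nd, mu))
  ids
}

#' Grow a tumour with the stochastic branching process
#'
#' Runs the discrete-generation birth-death process of
#' [simulation_config()], recording the full genotype tree (one node per
#' daughter cell, annotated with its Poisson count of new mutations) and the
#' per-generation population sizes per clone. Extinct runs are re-drawn with a
#' derived seed up to `max_retries` times.
#'
#' @param cfg An [simulation_config()].
#' @return Object of class `sfs_growth`: genotype tree (`parent`, `nmut`,
#'   `node_driver`), final `cells` (node ids) and `cell_driver` flags, the
#'   driver `founder_lineage`, `pop_history` (per-generation sizes, births and
#'   deaths per clone) and bookkeeping fields.
#' @export
simulate_growth <- function(cfg) {
  stopifnot(inherits(cfg, "sfs_sim_config"))
  for (attempt in seq_len(cfg$max_retries)) {
    set.seed(derive_seed(cfg$seed, attempt, stream = 3L))
    g <- simulate_growth_once(cfg)
    if (!is.null(g)) {
      g$attempt <- attempt
      return(g)
    }
  }
  stop("no admissible run in ", cfg$max_retries,
       " attempt(s): the population went extinct or the driver subclone ",
       "missed the conditioning range; adjust birth/death probabilities, ",
       "the fitness multiplier or subclone_range", call. = FALSE)
}

simulate_growth_once <- function(cfg) {
  state <- new.env(parent = emptyenv())
  state$parent <- 0L
  state$nmut <- stats::rpois(1, cfg$clonal_mutations)
  cells <- 1L
  cell_driver <- FALSE
  driver_node <- NA_integer_
  b <- cfg$birth_prob; d <- cfg$death_prob
  r_driver <- cfg$fitness_multiplier
  hist <- list()
  gens_run <- 0L

  for (g in seq_len(cfg$sampling_generation)) {
    births <- c(ancestor = 0L, driver = 0L)
    deaths <- c(ancestor = 0L, driver = 0L)

    base <- cells[!cell_driver]
    drv <- cells[cell_driver]

    # baseline clone: divide / die / persist
    if (length(base)) {
      u <- stats::runif(length(base))
      dividing <- base[u < b]
      dying <- u >= b & u < b + d
      persisting <- base[u >= b + d]
      deaths["ancestor"] <- sum(dying)
      births["ancestor"] <- length(dividing)
      kids <- divide_all(state, dividing, cfg$mu_sim)
      base <- c(kids, persisting)
    }

    # driver clone: fitness_multiplier standard birth-death-persist rounds
    if (length(drv)) {
      n_full <- floor(r_driver)
      frac <- r_driver - n_full
      extra <- if (frac > 0)
        stats::rbinom(length(drv), 1L, frac)
      else integer(length(drv))
      rl <- n_full + extra
      done <- drv[rl == 0]
      active <- drv[rl > 0]
      rl <- rl[rl > 0]
      while (length(active)) {
        u <- stats::runif(length(active))
        dividing <- u < b
        dying <- u >= b & u < b + d
        persisting <- u >= b + d
        births["driver"] <- births["driver"] + sum(dividing)
        deaths["driver"] <- deaths["driver"] + sum(dying)
        kids <- divide_all(state, active[dividing], cfg$mu_sim)
        nxt <- c(kids, active[persisting])
        rl_nxt <- c(rep(rl[dividing], each = 2L), rl[persisting]) - 1L
        done <- c(done, nxt[rl_nxt == 0])
        active <- nxt[rl_nxt > 0]
        rl <- rl_nxt[rl_nxt > 0]
      }
      drv <- done
    }

    cells <- c(base, drv)
    cell_driver <- c(rep(FALSE, length(base)), rep(TRUE, length(drv)))
    if (length(cells) == 0) return(NULL)  # extinct; caller retries

    # driver conversion at the end of the generation reaching driver_time
    # doublings
    if (!is.na(cfg$driver_generation) && g == cfg$driver_generation &&
        is.na(driver_node)) {
      pick <- sample.int(length(cells), 1L)
      driver_node <- length(state$parent) + 1L
      state$parent <- c(state$parent, cells[pick])
      state$nmut <- c(state$nmut, 1L)  # the driver mutation itself
      cells[pick] <- driver_node
      cell_driver[pick] <- TRUE
    }

    gens_run <- g
    hist[[g]] <- data.frame(
      generation = g,
      ancestor = sum(!cell_driver), driver = sum(cell_driver),
      births_ancestor = births[["ancestor"]],
      births_driver = births[["driver"]],
      deaths_ancestor = deaths[["ancestor"]],
      deaths_driver = deaths[["driver"]])
    if (length(cells) >= cfg$population_cap) break
  }

  # condition on a detectable, unswept subclone: a driver run whose driver
  # lineage died out (or was never placed), or whose final subclone fraction
  # falls outside the admissible range, is re-drawn
  if (!is.na(cfg$driver_generation)) {
    frac_drv <- mean(cell_driver)
    if (is.na(driver_node) || frac_drv < cfg$subclone_range[1] ||
        frac_drv > cfg$subclone_range[2])
      return(NULL)
  }

  founder_lineage <- integer(0)
  node_driver <- rep(FALSE, length(state$parent))
  if (!is.na(driver_node)) {
    p <- state$parent[driver_node]
    while (p != 0L) {
      founder_lineage <- c(founder_lineage, p)
      p <- state$parent[p]
    }
    # driver-clone nodes: conversion node and everything created after it
    # whose ancestry passes through it (parents precede children, so one
    # sequential forward pass propagates the flag)
    node_driver[driver_node] <- TRUE
    if (driver_node < length(state$parent)) {
      for (i in (driver_node + 1L):length(state$parent))
        node_driver[i] <- node_driver[state$parent[i]]
    }
  }

  structure(list(
    parent = state$parent, nmut = state$nmut, node_driver = node_driver,
    cells = cells, cell_driver = cell_driver,
    driver_node = driver_node,
    founder_lineage = rev(founder_lineage),
    generations = gens_run,
    pop_history = do.call(rbind, hist),
    config = cfg
  ), class = "sfs_growth")
}

# carrier count per genotype-tree node: number of final cells carrying the
# mutations on that node's edge (subtree accumulation; parents precede
# children by construction)
carrier_counts <- function(growth) {
  n_nodes <- length(growth$parent)
  cnt <- tabulate(growth$cells, nbins = n_nodes)
  parent <- growth$parent
  for (i in n_nodes:2) {
    p <- parent[i]
    cnt[p] <- cnt[p] + cnt[i]
  }
  cnt
}

#' Sequence a simulated tumour
#'
#' Converts the grown tumour into an observed frequency dataset: each
#' mutation's true VAF is `purity * carriers / (2 * n_cells)` (diploid
#' heterozygous), depth is Poisson(`coverage_rate`), variant reads are
#' Binomial(depth, true VAF), and mutations with zero depth or observed VAF at
#' or below `vaf_cutoff` are removed. Ground truth (clone label, true VAF,
#' carrier count per mutation) is returned alongside.
#'
#' @param growth An `sfs_growth` from [simulate_growth()].
#' @param cfg Optional [simulation_config()] overriding the one stored in
#'   `growth` (to re-sequence the same tumour under different noise).
#' @return Object of class `sfs_simulation`: list with `dataset` (an
#'   `sfs_data`), `truth` (data frame), `n_cells`, `subclone_fraction`,
#'   `generations`, `pop_history` and `config`.
#' @export
sequence_tumour <- function(growth, cfg = NULL) {
  stopifnot(inherits(growth, "sfs_growth"))
  if (is.null(cfg)) cfg <- growth$config
  set.seed(derive_seed(cfg$seed, 9999L, stream = 5L))
  n_cells <- length(growth$cells)
  labels_all <- ifelse(seq_along(growth$parent) == 1L, "clonal",
                ifelse(seq_along(growth$parent) %in%
                         c(growth$founder_lineage, growth$driver_node),
                       "subclone_lineage", "tail"))

  cnt <- carrier_counts(growth)
  true_vaf <- cfg$purity * cnt / (2 * n_cells)
  sel <- which(growth$nmut > 0 & cnt > 0 & true_vaf >= cfg$min_true_vaf)
  if (length(sel) == 0) {
    warning("empty mutation catalog (nothing to sequence)", call. = FALSE)
    empty <- freq_dataset_from_values(numeric(0))
    return(structure(list(
      dataset = empty,
      truth = data.frame(id = character(0), label = character(0),
                         true_vaf = numeric(0), carriers = integer(0)),
      n_cells = n_cells,
      subclone_fraction = mean(growth$cell_driver),
      generations = growth$generations,
      pop_history = growth$pop_history, config = cfg
    ), class = "sfs_simulation"))
  }

  node <- rep(sel, growth$nmut[sel])
  tv <- true_vaf[node]
  n_mut <- length(node)
  depth <- stats::rpois(n_mut, cfg$coverage_rate)
  alt <- stats::rbinom(n_mut, depth, tv)
  vaf <- ifelse(depth > 0, alt / depth, NA_real_)
  keep <- which(depth > 0 & !is.na(vaf) & vaf > cfg$vaf_cutoff & vaf < 1)

  if (length(keep) == 0) {
    warning("no mutations pass the detection threshold", call. = FALSE)
  }
  ids <- paste0("m", seq_along(node))
  df <- data.frame(
    id = ids, chrom = "sim1", pos = seq_along(node),
    ref = "A", alt = "T", depth = depth, alt_reads = alt,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  dataset <- freq_dataset(df, frequency_kind = "VAF",
                          min_frequency = cfg$vaf_cutoff)
  truth <- data.frame(
    id = ids, label = labels_all[node], true_vaf = tv,
    carriers = cnt[node], detected = seq_along(node) %in% keep,
    stringsAsFactors = FALSE)
  structure(list(
    dataset = dataset, truth = truth, n_cells = n_cells,
    subclone_fraction = mean(growth$cell_driver),
    generations = growth$generations,
    pop_history = growth$pop_history, config = cfg
  ), class = "sfs_simulation")
}

#' Simulate a sequenced tumour in one call
#'
#' [simulate_growth()] followed by [sequence_tumour()].
#'
#' @param cfg An [simulation_config()].
#' @return An `sfs_simulation`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  sequence_tumour(simulate_growth(cfg))
}

#' @export
print.sfs_simulation <- function(x, ...) {
  cat("<sfs_simulation> ", x$n_cells, " cells after ", x$generations,
      " generation(s); subclone fraction ",
      sprintf("%.3f", x$subclone_fraction), "\n", sep = "")
  cat("  detected mutations: ", x$dataset$n, " (VAF > ",
      x$config$vaf_cutoff, ")\n", sep = "")
  invisible(x)
}

#' Write a simulated tumour to disk
#'
#' Emits the observed dataset in the delimited input format, a truth sidecar
#' TSV (mutation id, clone label, true VAF, carrier count) and a JSON snapshot
#' of the configuration.
#'
#' @param sim An `sfs_simulation`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sfs_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dataset = file.path(dir, "mutations.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "sim_config.json"))
  write_freq_table(sim$dataset, paths[["dataset"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  jsonlite::write_json(unclass(cfg), paths[["config"]],
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(paths)
}
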