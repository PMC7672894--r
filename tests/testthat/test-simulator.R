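test_that("degenerate configurations behave as documented", {
  # no mutation process: empty catalog
  cfg0 <- simulation_config(mu_sim = 0, clonal_mutations = 0,
                            driver_time = NA, sampling_time = 8, seed = 1)
  expect_warning(sim0 <- sequence_tumour(simulate_growth(cfg0)),
                 "empty mutation catalog")
  expect_equal(sim0$dataset$n, 0)

  # detection threshold 1: nothing passes
  cfg1 <- simulation_config(mu_sim = 5, driver_time = NA, sampling_time = 10,
                            vaf_cutoff = 1, min_true_vaf = 0, seed = 2)
  expect_warning(sim1 <- simulate_dataset(cfg1), "detection threshold")
  expect_equal(sim1$dataset$n, 0)
})

test_that("pure deterministic doubling gives exactly 2^t cells", {
  cfg <- simulation_config(birth_prob = 1, death_prob = 0, mu_sim = 1,
                           driver_time = NA, sampling_time = 6,
                           vaf_cutoff = 0, seed = 3)
  g <- simulate_growth(cfg)
  expect_equal(length(g$cells), 2^6)
  expect_equal(g$pop_history$ancestor, 2^(1:6))
})

test_that("per-generation cell counts are conserved", {
  cfg <- simulation_config(mu_sim = 1, sampling_time = 10, driver_time = 8,
                           subclone_range = c(0.001, 0.999), seed = 4)
  g <- simulate_growth(cfg)
  h <- g$pop_history
  prev_a <- 1; prev_d <- 0
  for (i in seq_len(nrow(h))) {
    # conversion moves one cell between clones at the driver generation
    conv <- if (i == cfg$driver_generation) 1 else 0
    expect_equal(h$ancestor[i],
                 prev_a + h$births_ancestor[i] - h$deaths_ancestor[i] - conv)
    expect_equal(h$driver[i],
                 prev_d + h$births_driver[i] - h$deaths_driver[i] + conv)
    prev_a <- h$ancestor[i]; prev_d <- h$driver[i]
  }
})

test_that("sequencing noise follows the stated read model", {
  # single clonal mutation at effectively infinite coverage: VAF 1/2
  cfg <- simulation_config(mu_sim = 0, clonal_mutations = 50,
                           driver_time = NA, sampling_time = 8,
                           coverage_rate = 1e6, vaf_cutoff = 0.05,
                           min_true_vaf = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  expect_true(all(abs(sim$dataset$data$frequency - 0.5) < 0.01))
  expect_true(all(sim$truth$label == "clonal"))
  expect_equal(unique(sim$truth$true_vaf), 0.5)

  # Poisson coverage: mean observed depth near the rate
  cfg2 <- simulation_config(mu_sim = 45, driver_time = NA,
                            sampling_time = 14, coverage_rate = 120,
                            seed = 6)
  sim2 <- simulate_dataset(cfg2)
  expect_gt(sim2$dataset$n, 1000)
  expect_lt(abs(mean(sim2$dataset$data$depth) - 120), 2)

  # purity scales the expected clonal VAF
  cfg3 <- simulation_config(mu_sim = 0, clonal_mutations = 200,
                            driver_time = NA, sampling_time = 8,
                            coverage_rate = 5000, purity = 0.6,
                            vaf_cutoff = 0.05, min_true_vaf = 0, seed = 7)
  sim3 <- simulate_dataset(cfg3)
  expect_lt(abs(mean(sim3$dataset$data$frequency) - 0.3), 0.01)
})

test_that("runs are reproducible and driver lineage is consistent", {
  cfg <- simulation_config(mu_sim = 10, sampling_time = 12, driver_time = 9,
                           seed = 8)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$dataset$data$frequency, s2$dataset$data$frequency)

  g <- simulate_growth(cfg)
  # subclone-specific mutations are carried by at most the subclone size
  cnt <- sfsmix:::carrier_counts(g)
  n_driver_cells <- sum(g$cell_driver)
  expect_gt(n_driver_cells, 0)
  expect_true(all(cnt[g$node_driver] <= n_driver_cells))
  # the driver clone fraction respects the conditioning range
  frac <- n_driver_cells / length(g$cells)
  expect_gte(frac, cfg$subclone_range[1])
  expect_lte(frac, cfg$subclone_range[2])
})

test_that("the neutral site frequency spectrum is a 1/f power law", {
  cfg <- simulation_config(driver_time = NA, seed = 9)
  sim <- simulate_dataset(cfg)
  x <- sim$dataset$data$frequency
  # cumulative count M(f) against 1/f over the tail window
  grid <- seq(0.06, 0.25, length.out = 15)
  M <- vapply(grid, function(f) sum(x >= f & x <= 0.4), numeric(1))
  fit <- lm(M ~ I(1 / grid))
  expect_gt(summary(fit)$r.squared, 0.95)
  expect_gt(coef(fit)[2], 0)
})

test_that("a driver lineage vastly exceeds the neutral expectation", {
  # a neutral lineage founded at doubling 9 of 12 has expected final
  # fraction ~ 1/pop(9); the selected clone must be far above it
  cfg <- simulation_config(mu_sim = 0, clonal_mutations = 0,
                           sampling_time = 12, driver_time = 9, seed = 10)
  fr <- vapply(1:5, function(s) {
    cfg$seed <- 10 + s
    g <- simulate_growth(cfg)
    mean(g$cell_driver)
  }, numeric(1))
  growth_factor <- 1 + cfg$birth_prob - cfg$death_prob
  neutral_expect <- 1 / growth_factor^(9 * cfg$gens_per_doubling)
  expect_gt(mean(fr), 20 * neutral_expect)
})

test_that("simulation output files round-trip", {
  cfg <- simulation_config(mu_sim = 5, driver_time = NA, sampling_time = 10,
                           seed = 11)
  sim <- simulate_dataset(cfg)
  dir <- tempfile()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_freq_table(paths[["dataset"]])
  expect_equal(back$n, sim$dataset$n)
  truth <- read.delim(paths[["truth"]])
  expect_equal(nrow(truth), nrow(sim$truth))
  cfg_back <- jsonlite::read_json(paths[["config"]])
  expect_equal(cfg_back$mu_sim, 5)
})
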