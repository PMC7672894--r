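test_that("latent entropy matches its definition", {
  z_hard <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(latent_entropy(z_hard), 0)

  n <- 7
  z_unif <- matrix(0.5, n, 2)
  expect_equal(latent_entropy(z_unif), n * log(2))

  set.seed(61)
  z <- matrix(rgamma(20 * 3, 1), 20, 3)
  z <- z / rowSums(z)
  expect_equal(latent_entropy(z), oracle_entropy(z), tolerance = 1e-12)
})

test_that("reduced entropy strips tail-assigned rows and renormalises", {
  # every row one-hot on a Beta column: 0, and equal to the full entropy
  z <- cbind(Tail = 0, C1 = c(1, 0, 1), C2 = c(0, 1, 0))
  expect_equal(reduced_latent_entropy(z, 1), 0)
  expect_equal(reduced_latent_entropy(z, 1), latent_entropy(z))

  # a single row hard-assigned to the tail is removed entirely (and, being
  # the only row, triggers the all-tail warning)
  z1 <- matrix(c(0.6, 0.2, 0.2), 1, 3)
  expect_warning(h1 <- reduced_latent_entropy(z1, 1), "tail")
  expect_equal(h1, 0)

  set.seed(62)
  z <- matrix(rgamma(30 * 3, 1), 30, 3)
  z <- z / rowSums(z)
  expect_equal(reduced_latent_entropy(z, 1), oracle_reduced_entropy(z, 1),
               tolerance = 1e-12)

  # no tail: identical to the standard entropy
  expect_equal(reduced_latent_entropy(z, NULL), latent_entropy(z))

  # all rows tail-assigned: 0 with a warning
  zt <- matrix(c(0.9, 0.05, 0.05), 4, 3, byrow = TRUE)
  expect_warning(h <- reduced_latent_entropy(zt, 1), "tail")
  expect_equal(h, 0)
})

test_that("score identities hold exactly on fitted models", {
  # closed form: NLL = 100, lambda = 5, n = 1000
  expect_equal(2 * 100 + 5 * log(1000), 234.5388, tolerance = 1e-4)

  d <- fixture_dataset(700, seed = 63)
  m <- fit_mixture(d, k = 2, tail = TRUE, config = quick_config(seed = 63))
  s <- m$scores
  expect_equal(s$bic, 2 * s$nll + s$lambda * log(m$n), tolerance = 1e-10)
  expect_equal(s$icl, s$bic + s$entropy, tolerance = 1e-10)
  expect_equal(s$reicl, s$bic + s$reduced_entropy, tolerance = 1e-10)
  expect_lte(s$reduced_entropy, s$entropy)
  expect_gte(s$icl, s$reicl)
  expect_gte(s$reicl, s$bic)

  # near-hard assignments: ICL collapses towards BIC
  far <- mixture_model(betas = list(beta_from_moments(0.9, 1e-4),
                                    beta_from_moments(0.1, 1e-4)),
                       pi = c(0.5, 0.5))
  x <- sample_model(far, 200, seed = 64)$data$frequency
  sc <- score_model(x, far)
  expect_lt(sc$entropy, 1e-6)
  expect_equal(sc$icl, sc$bic, tolerance = 1e-6)
})

test_that("model selection finds the generative structure on easy data", {
  cfg <- quick_config(seed = 65, restarts = 2)

  # clonal + subclonal + tail
  d2 <- fixture_dataset(1500, seed = 65)
  sel2 <- select_model(d2, cfg)
  expect_equal(sel2$best$k, 2)
  expect_true(sel2$best$has_tail)
  expect_equal(sel2$clonal_status, "polyclonal")
  expect_equal(sel2$candidates$rank[1], 1)
  best_score <- sel2$candidates$reicl[1]
  expect_true(all(na.omit(sel2$candidates$reicl) >= best_score - 1e-9))

  # monoclonal: one Beta + tail
  gen1 <- mixture_model(tail = list(scale = 0.05, shape = 1.6),
                        betas = list(beta_from_moments(0.48, 0.0018)),
                        pi = c(0.4, 0.6))
  d1 <- sample_model(gen1, 1500, seed = 66)
  sel1 <- select_model(d1, cfg)
  expect_equal(sel1$best$k, 1)
  expect_true(sel1$best$has_tail)
  expect_equal(sel1$clonal_status, "monoclonal")

  # two Betas, no tail (minimum frequency far from zero)
  gen0 <- mixture_model(betas = list(beta_from_moments(0.55, 0.002),
                                     beta_from_moments(0.28, 0.002)),
                        pi = c(0.5, 0.5))
  d0 <- sample_model(gen0, 1500, seed = 67)
  sel0 <- select_model(d0, cfg)
  expect_equal(sel0$best$k, 2)
  expect_false(sel0$best$has_tail)
})

test_that("post-hoc cluster filtering prunes and renormalises", {
  d <- fixture_dataset(900, seed = 68)
  m <- fit_mixture(d, k = 3, tail = TRUE, config = quick_config(seed = 68))

  # thresholds 0: identity
  expect_identical(filter_clusters(m, d, min_pi = 0, min_count = 0), m)

  # force removal of the smallest cluster by count
  counts <- table(factor(m$assignments, levels = names(m$pi)))
  beta_counts <- counts[paste0("C", 1:3)]
  cut <- sort(as.integer(beta_counts))[1] + 1L
  f <- filter_clusters(m, d, min_pi = 0, min_count = cut)
  expect_lt(f$k, 3)
  expect_equal(sum(f$pi), 1, tolerance = 1e-8)
  expect_true(f$has_tail)  # the tail is never removed

  # surviving assignments match a fresh responsibility computation
  z_oracle <- oracle_responsibilities(d$data$frequency, f)
  expect_equal(unname(f$z), z_oracle, tolerance = 1e-10)
  expect_identical(f$assignments, hard_assignments(f$z))

  expect_error(filter_clusters(m, d, min_pi = 0.99), "every Beta")
})

test_that("unseen mutations are assigned under fixed parameters", {
  d <- fixture_dataset(500, seed = 69)
  m <- fit_mixture(d, k = 2, tail = TRUE, config = quick_config(seed = 69))

  # a training point gets exactly its training responsibility row
  x0 <- d$data$frequency[17]
  res <- assign_mutations(m, x0)
  expect_equal(unname(res$z), unname(m$z[17, , drop = FALSE]),
               tolerance = 1e-12)

  # below the tail scale: zero tail responsibility
  res0 <- assign_mutations(m, m$tail$scale * 0.5)
  expect_identical(unname(res0$z[1, "Tail"]), 0)

  # batch of new points vs the oracle
  xn <- fixture_dataset(50, seed = 70)$data$frequency
  resn <- assign_mutations(m, xn)
  expect_equal(unname(resn$z), oracle_responsibilities(xn, m),
               tolerance = 1e-10)
  expect_identical(resn$labels, hard_assignments(resn$z))
})
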