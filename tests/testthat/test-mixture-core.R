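test_that("Pareto Type-I density matches its closed form and normalises", {
  expect_equal(dpareto1(0.05, scale = 0.05, shape = 2), 2 / 0.05)
  expect_equal(dpareto1(0.1, scale = 0.05, shape = 1), 5.0)
  expect_equal(dpareto1(0.04, scale = 0.05, shape = 1), 0)
  expect_identical(dpareto1(0.04, scale = 0.05, shape = 1, log = TRUE), -Inf)

  for (a in c(0.8, 1.5, 3)) {
    q <- integrate(dpareto1, 0.05, Inf, scale = 0.05, shape = a,
                   rel.tol = 1e-9)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }

  # truncated sampler stays inside (scale, 1) and matches analytic moments
  set.seed(1)
  x <- rpareto1(1e4, scale = 0.05, shape = 4, upper = 1)
  expect_true(all(x >= 0.05 & x < 1))
  m_analytic <- integrate(function(v) v * dpareto1(v, 0.05, 4), 0.05, 1)$value /
    integrate(dpareto1, 0.05, 1, scale = 0.05, shape = 4)$value
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - m_analytic), 2 * se + 1e-4)
})

test_that("moment parameterisation of Beta components is invertible", {
  b <- beta_from_moments(0.5, 0.05)
  expect_equal(b$a, 2)
  expect_equal(b$b, 2)
  expect_equal(beta_mean(b), 0.5)
  expect_equal(beta_var(b), 0.05)
  expect_error(beta_from_moments(0.5, 0.3), "variance")
})

test_that("mixture NLL matches closed forms and a brute-force oracle", {
  # single point under a uniform Beta: log 1 = 0
  m1 <- mixture_model(betas = list(list(a = 1, b = 1)), pi = 1)
  expect_equal(mixture_nll(0.5, m1), 0)

  # tail-only model, two points, closed form from the Pareto density
  mt <- mixture_model(tail = list(scale = 0.05, shape = 1), pi = 1)
  expect_equal(mixture_nll(c(0.05, 0.1), mt), -log(20) - log(5))

  # random instances vs direct per-point summation
  set.seed(11)
  for (rep in 1:5) {
    m <- random_model(k = 2, tail = TRUE)
    x <- fixture_dataset(50, seed = rep)$data$frequency
    expect_equal(mixture_nll(x, m), oracle_nll(x, m), tolerance = 1e-8)
  }

  # a point no component can explain is an error identifying the point
  mlow <- mixture_model(tail = list(scale = 0.2, shape = 1), pi = 1)
  expect_error(mixture_nll(c(0.3, 0.1), mlow), "cannot explain")
})

test_that("responsibilities follow Bayes' rule with tail support handled", {
  # two identical components, equal weights: all responsibilities 1/2
  m <- mixture_model(betas = list(list(a = 2, b = 2), list(a = 2, b = 2)),
                     pi = c(0.5, 0.5))
  z <- responsibilities(c(0.3, 0.6, 0.9), m)
  expect_equal(unname(z), matrix(0.5, 3, 2))

  # below the tail scale, the tail column is exactly zero
  mt <- fixture_model()
  z2 <- responsibilities(c(0.03, 0.2), mt)
  expect_identical(unname(z2[1, "Tail"]), 0)
  expect_gt(z2[2, "Tail"], 0)
  expect_equal(rowSums(z2), c(1, 1), tolerance = 1e-12)

  # 20-point instance vs the brute-force oracle
  x <- fixture_dataset(20, seed = 3)$data$frequency
  expect_equal(unname(responsibilities(x, mt)),
               oracle_responsibilities(x, mt), tolerance = 1e-10)
})

test_that("weighted Beta moment matching has the stated closed form", {
  # uniform weights on symmetric data: a = b
  x <- c(0.3, 0.4, 0.6, 0.7)
  b <- fit_beta_moments(x)
  expect_equal(b$a, b$b, tolerance = 1e-9)

  # Monte-Carlo recovery: fitted mean near the generative mean
  set.seed(5)
  draws <- rbeta(1e4, 10, 30)
  f <- fit_beta_moments(draws)
  expect_lt(abs(beta_mean(f) - 0.25), 0.01)

  # degenerate cluster: all mass on one point
  expect_error(fit_beta_moments(rep(0.4, 5)), class = "sfsmix_degenerate")
  expect_error(fit_beta_moments(x, w = rep(0, 4)),
               class = "sfsmix_degenerate")
})

test_that("weighted Hill estimator for the tail shape is exact", {
  xs <- 0.05
  expect_equal(fit_pareto_shape(xs * exp(1), w = 1, scale = xs), 1)
  expect_equal(fit_pareto_shape(c(xs, xs * exp(1)), w = c(1, 1), scale = xs),
               2)
  set.seed(8)
  draws <- xs * (1 - runif(1e4))^(-1 / 1.5)  # untruncated Pareto(1.5)
  expect_lt(abs(fit_pareto_shape(draws, scale = xs) - 1.5), 0.05)

  expect_error(fit_pareto_shape(rep(xs, 3), scale = xs),
               class = "sfsmix_degenerate")
  expect_error(fit_pareto_shape(c(0.01, 0.2), w = c(1, 1), scale = 0.05),
               "below the scale")
})

test_that("weighted Beta MLE never worsens the weighted likelihood", {
  set.seed(13)
  x <- rbeta(500, 8, 4)
  w <- runif(500)
  start <- fit_beta_moments(x, w)
  mle <- fit_beta_mle(x, w, start = start)
  ll <- function(p) sum(w * dbeta(x, p$a, p$b, log = TRUE))
  expect_gte(ll(mle), ll(start) - 1e-8)
  expect_lt(abs(beta_mean(mle) - 8 / 12), 0.05)
})
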