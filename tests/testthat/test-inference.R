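test_that("non-hierarchical posterior matches the conjugate Beta oracle", {
  # uniform implied prior on p (probit N(0,1)), fixed sigma = 0, one
  # participant with 14 hits / 20 -> posterior of Phi(mu) is Beta(15, 7)
  m <- toy_binomial_model()
  prior <- toy_binomial_prior()
  data <- freq_table(
    matrix(c(14L, 6L), 1, dimnames = list(NULL, c("old:hit", "old:miss"))),
    design = tibble::tibble(tree = "old", items = 20L)
  )
  fit <- suppressWarnings(fit_posterior(
    m, prior, data,
    settings = mcmc_settings(draws = 8000, warmup = 2000, chains = 2,
                             seed = 31, thin = 1)
  ))
  p <- pnorm(fit$draws$group_mu[, 1])
  expect_equal(mean(p), 15 / 22, tolerance = 0.01)
  expect_equal(sd(p), sqrt(15 * 7 / (22^2 * 23)), tolerance = 0.01)
})

test_that("with zero-information data the posterior recovers the prior", {
  # zero items per tree: likelihood is constant, so posterior == prior
  m <- toy_binomial_model()
  prior <- toy_binomial_prior()
  data <- freq_table(
    matrix(c(0L, 0L), 2, 2, dimnames = list(NULL, c("old:hit", "old:miss"))),
    design = tibble::tibble(tree = "old", items = 0L)
  )
  fit <- suppressWarnings(fit_posterior(
    m, prior, data,
    settings = mcmc_settings(draws = 8000, warmup = 2000, chains = 2,
                             seed = 32, thin = 1)
  ))
  mu <- fit$draws$group_mu[, 1]
  expect_equal(mean(mu), 0, tolerance = 0.05)
  expect_equal(sd(mu), 1, tolerance = 0.05)
})

test_that("the smoke fit converges and recovers its truth", {
  fit <- smoke_fit()
  gen <- smoke_gen()
  g <- glance(fit)
  expect_lt(g$max_rhat, 1.1)
  rec <- recovery_report(fit, gen$truth)
  expect_true(all(abs(rec$error) < 0.1))
})

test_that("diagnostics report R-hat and ESS per quantity", {
  fit <- smoke_fit()
  d <- diagnostics(fit, level = "group")
  expect_true(all(c("mu[D]", "sigma[D]", "corr[d,D]") %in% d$quantity))
  expect_true(all(d$ess > 0))
  expect_true(all(is.finite(d$rhat)))
  d_all <- diagnostics(fit, level = "all")
  expect_gt(nrow(d_all), nrow(d))
})

test_that("split R-hat separates stationary from drifting chains", {
  set.seed(41)
  good <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(ordtree:::split_rhat(good), 1.02)
  bad <- cbind(rnorm(1000), rnorm(1000) + 1.5)
  expect_gt(ordtree:::split_rhat(bad), 1.2)
})

test_that("single-chain fits report NA R-hat with a notice", {
  m <- toy_binomial_model()
  data <- freq_table(
    matrix(c(14L, 6L), 1, dimnames = list(NULL, c("old:hit", "old:miss"))),
    design = tibble::tibble(tree = "old", items = 20L)
  )
  fit <- suppressWarnings(fit_posterior(
    m, toy_binomial_prior(), data,
    settings = mcmc_settings(draws = 500, warmup = 300, chains = 1,
                             seed = 33, thin = 1)
  ))
  expect_message(d <- diagnostics(fit, "group"), "single chain")
  expect_true(all(is.na(d$rhat)))
})

test_that("tidy and glance follow broom conventions", {
  fit <- smoke_fit()
  td <- tidy(fit)
  expect_setequal(names(td), c("parameter", "estimate", "conf.low",
                               "conf.high", "mean", "sd"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  tp <- tidy(fit, scale = "probit")
  expect_false(any(td$estimate == tp$estimate))
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_participants, 60)
})

test_that("fit draws expose tidy accessors", {
  fit <- smoke_fit()
  td <- tidy_draws(fit$draws, parameters = "D")
  expect_setequal(names(td), c("draw", "participant", "parameter", "value"))
  expect_true(all(td$value >= 0 & td$value <= 1))
  tg <- tidy_group_draws(fit$draws, scale = "probability")
  expect_true(all(tg$mu > 0 & tg$mu < 1))
})
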