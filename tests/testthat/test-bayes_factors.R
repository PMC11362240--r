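test_that("prior_density_at_null gives the exact triangular values", {
  m <- build_2htsm_bell()
  pr <- matzke_klauer_preset(m)
  q <- derived_quantity("dd", "d_A_pleasant - d_B_pleasant")
  expect_identical(prior_density_at_null(q, pr, m, "analytic", at = 0), 1)
  expect_equal(prior_density_at_null(q, pr, m, "analytic", at = 0.5), 0.5)
  expect_identical(prior_density_at_null(q, pr, m, "analytic", at = 1), 0)
  expect_identical(prior_density_at_null(q, pr, m, "analytic", at = -1), 0)
  # non-uniform implied prior -> error directing to simulation
  inf <- informative_preset(m)
  qg <- derived_quantity("gg", "g_pleasant - g_disgusting")
  err <- tryCatch(prior_density_at_null(qg, inf, m, "analytic"),
                  error = identity)
  expect_s3_class(err, "ordtree_value_error")
  expect_match(conditionMessage(err), "logspline")
  # log-spline route approximates the triangular density
  got <- prior_density_at_null(q, pr, m, "logspline", n_draws = 5e4, seed = 3)
  expect_equal(got, 1, tolerance = 0.05)
})

test_that("savage_dickey_bf is the density ratio and multiplies quantities", {
  m <- toy_binomial_model()
  pr <- toy_binomial_prior()
  d <- toy_conjugate_draws(14, 20, n = 2e4, seed = 61)
  q <- derived_quantity("p", "p")
  bf <- savage_dickey_bf(d, list(q), prior = pr, model = m, at = 0.5,
                         support = c(0, 1))
  exact <- dbeta(0.5, 15, 7)
  expect_equal(bf$bf, exact, tolerance = 0.1 * exact)
  expect_equal(bf$quantities$prior_density, 1)
  # posterior centered far from the null -> evidence against the null
  d2 <- toy_conjugate_draws(19, 20, n = 2e4, seed = 62)
  bf2 <- savage_dickey_bf(d2, list(q), prior = pr, model = m, at = 0.5,
                          support = c(0, 1))
  expect_lt(bf2$bf, 1)
})

test_that("log-spline and truncated-normal agree on exactly normal draws", {
  m <- build_2htsm_bell()
  pr <- matzke_klauer_preset(m)
  set.seed(63)
  mu <- matrix(0, 3e4, 12)
  k1 <- match("d_A_pleasant", m$parameters)
  mu[, k1] <- rnorm(3e4, 0.4, 0.5)
  d <- inject_group_draws(m, mu)
  q <- derived_quantity("dd", "d_A_pleasant - d_B_pleasant",
                        scale = "probit")
  b1 <- savage_dickey_bf(d, list(q), prior = pr, model = m,
                         method = "logspline", support = c(-3, 3),
                         prior_method = "logspline", n_prior_draws = 5e4)
  b2 <- savage_dickey_bf(d, list(q), prior = pr, model = m,
                         method = "truncated_normal", support = c(-3, 3),
                         prior_method = "logspline", n_prior_draws = 5e4)
  expect_lt(abs(b1$bf - b2$bf) / b2$bf, 0.1)
})

test_that("the joint bivariate option approximates the product rule", {
  m <- build_2htsm_bell()
  pr <- matzke_klauer_preset(m)
  set.seed(64)
  mu <- matrix(0, 3e4, 12)
  mu[, match("d_A_pleasant", m$parameters)] <- rnorm(3e4, 0.3, 0.6)
  mu[, match("d_A_disgusting", m$parameters)] <- rnorm(3e4, 0.2, 0.7)
  d <- inject_group_draws(m, mu)
  qs <- list(derived_quantity("q1", "d_A_pleasant - d_B_pleasant"),
             derived_quantity("q2", "d_A_disgusting - d_B_disgusting"))
  b_prod <- savage_dickey_bf(d, qs, prior = pr, model = m)
  b_joint <- savage_dickey_bf(d, qs, prior = pr, model = m, joint = TRUE)
  # the two differences are a-posteriori independent here by construction
  expect_lt(abs(b_joint$bf - b_prod$bf) / b_prod$bf, 0.2)
  expect_error(savage_dickey_bf(d, qs[1], prior = pr, model = m,
                                joint = TRUE),
               class = "ordtree_value_error")
})

test_that("encompassing_bf is the proportion ratio with reliability flags", {
  m <- build_2htsm_bell()
  cs <- constraint_spec("d_A_pleasant - d_B_pleasant > 0", scale = "probit")
  # 3 of 4 draws conform, injected prior proportion 0.125 -> BF = 6
  mu <- matrix(0, 4, 12)
  mu[, match("d_A_pleasant", m$parameters)] <- c(1, 2, 0.5, -1)
  d <- inject_group_draws(m, mu)
  bf <- encompassing_bf(d, cs, prior_proportion = 0.125)
  expect_equal(bf$bf, 0.75 / 0.125)
  expect_false(bf$reliable)          # < 10 conforming draws
  # all draws conform -> maximal BF given the prior proportion
  mu2 <- matrix(0, 20, 12)
  mu2[, match("d_A_pleasant", m$parameters)] <- 1
  bf2 <- encompassing_bf(inject_group_draws(m, mu2), cs,
                         prior_proportion = 0.125)
  expect_equal(bf2$bf, 8)
  # zero conforming draws -> flagged upper bound 1/(n * prior_proportion)
  mu3 <- matrix(0, 20, 12)
  mu3[, match("d_A_pleasant", m$parameters)] <- -1
  bf3 <- encompassing_bf(inject_group_draws(m, mu3), cs,
                         prior_proportion = 0.125)
  expect_true(bf3$is_bound)
  expect_equal(bf3$bf, 1 / (20 * 0.125))
})

test_that("transitivity composition is exact and guards the reference", {
  m <- build_2htsm_bell()
  cs <- constraint_spec("d_A_pleasant - d_B_pleasant > 0", scale = "probit")
  set.seed(65)
  mu <- matrix(0, 2000, 12)
  mu[, match("d_A_pleasant", m$parameters)] <- rnorm(2000, 0.5, 1)
  d <- inject_group_draws(m, mu)
  pr <- matzke_klauer_preset(m)
  bf_re <- encompassing_bf(d, cs, prior_proportion = 0.5)
  q <- derived_quantity("dd", "d_A_pleasant - d_B_pleasant")
  bf_0e <- savage_dickey_bf(d, list(q), prior = pr, model = m)
  bf_r0 <- compose_by_transitivity(bf_re, bf_0e)
  expect_equal(bf_r0$bf * bf_0e$bf, bf_re$bf, tolerance = 1e-12)
  # different encompassing posterior -> refuse
  mu2 <- mu; mu2[1, 1] <- mu2[1, 1] + 1
  d2 <- inject_group_draws(m, mu2)
  bf_0e2 <- savage_dickey_bf(d2, list(q), prior = pr, model = m)
  expect_error(compose_by_transitivity(bf_re, bf_0e2),
               class = "ordtree_value_error")
})

test_that("bf_repeat reports a median and a covering range", {
  fit <- smoke_fit()
  cs <- constraint_spec("D - g > 0")
  rep_ <- bf_repeat(fit, function(d, s) {
    encompassing_bf(d, cs, prior_proportion = 0.5)
  }, n_repetitions = 4, mode = "fast")
  expect_length(rep_$repetitions, 4)
  expect_true(rep_$bf_min <= rep_$bf && rep_$bf <= rep_$bf_max)
  expect_equal(rep_$failures, 0)
  expect_error(bf_repeat(fit, function(d, s) 1, n_repetitions = 1))
  # identical BFs per repetition -> zero-width range
  flat <- bf_repeat(fit, function(d, s) 2.5, n_repetitions = 3, mode = "fast")
  expect_equal(c(flat$bf_min, flat$bf, flat$bf_max), c(2.5, 2.5, 2.5))
  # failures are counted, not fatal, while >= 2 repetitions succeed
  k <- 0
  partial <- bf_repeat(fit, function(d, s) {
    k <<- k + 1
    if (k == 1) stop("boom") else 1
  }, n_repetitions = 4, mode = "fast")
  expect_equal(partial$failures, 1)
})

test_that("full-mode bf_repeat delegates to the refit function", {
  calls <- integer(0)
  fit <- smoke_fit()
  out <- bf_repeat(fit, function(d, s) s, n_repetitions = 2,
                   seeds = c(101L, 202L), mode = "full",
                   refit = function(seed) {
                     calls <<- c(calls, seed)
                     fit
                   })
  expect_equal(calls, c(101L, 202L))
  expect_equal(sort(out$repetitions), c(101, 202))
})

test_that("individual_level_bf counts the all-participants event", {
  m <- build_2htsm_bell()
  pr <- informative_preset(m)
  cs <- constraint_spec("d_A_pleasant - d_B_pleasant > 0",
                        level = "every_individual")
  # injected posterior over N = 3 participants: prior all-conform
  # probability ~ 0.5^3, comfortably estimable
  set.seed(67)
  n <- 4000
  eta <- array(rnorm(n * 3 * 12, 0, 0.3), c(n, 3, 12))
  k1 <- match("d_A_pleasant", m$parameters)
  eta[, , k1] <- eta[, , k1] + 0.8
  d <- ordtree:::new_mpt_draws(m$parameters, matrix(0, n, 12),
                               matrix(0, n, 12), NULL, eta,
                               "posterior", 67)
  bf <- individual_level_bf(d, cs, prior = pr, model = m,
                            n_prior_draws = 1e5, seed = 7)
  expect_gt(bf$bf, 0)
  expect_equal(bf$posterior_proportion, mean(evaluate_constraint(cs, d)))
  # participants share the group-level configuration, so the all-conform
  # probability is E[p(config)^3] >= (E p)^3 = 0.125 by Jensen's inequality
  expect_gt(bf$prior_proportion, 0.125 - 3 * bf$prior_se)
  expect_lt(bf$prior_proportion, 0.6)
  # level mismatches are rejected in both directions
  fit <- smoke_fit()
  expect_error(
    individual_level_bf(fit, constraint_spec("D - g > 0")),
    class = "ordtree_value_error")
  expect_error(encompassing_bf(fit, constraint_spec("D - g > 0",
                                 level = "every_individual")),
               class = "ordtree_value_error")
})

test_that("sensitivity_grid runs per-prior analyses and records failures", {
  m <- build_2htsm_bell()
  cs <- constraint_spec("d_A_pleasant - d_B_pleasant > 0", scale = "probit")
  set.seed(66)
  mu <- matrix(0, 2000, 12)
  mu[, match("d_A_pleasant", m$parameters)] <- rnorm(2000, 0.5, 1)
  d <- inject_group_draws(m, mu)
  grid <- sensitivity_grid(
    list(a = matzke_klauer_preset(m), b = matzke_klauer_preset(m),
         broken = "not a prior"),
    function(pr) {
      if (!inherits(pr, "prior_spec")) stop("bad prior")
      encompassing_bf(d, cs, prior = pr, model = m)
    })
  expect_equal(nrow(grid), 3)
  expect_equal(grid$bf[1], grid$bf[2])    # identical specs, same draws
  expect_true(is.na(grid$bf[3]) && !is.na(grid$error[3]))
  expect_error(sensitivity_grid(list(), identity))
})

test_that("descriptive_individual_effects bounds and attributes hold", {
  fit <- smoke_fit()
  cs <- constraint_spec("D - g > 0")
  de <- descriptive_individual_effects(fit, cs)
  expect_equal(nrow(de), 60)
  counts <- attr(de, "counts")
  expect_true(all(counts >= 0 & counts <= 60))
  expect_equal(unname(counts["point"]), sum(de$point_conforms))
  expect_equal(unname(counts["interval"]), sum(de$interval_conforms))
  # all-conforming posterior -> both counts = n
  m <- build_2htsm_bell()
  mu <- matrix(0, 50, 12)
  mu[, match("d_A_pleasant", m$parameters)] <- 3
  d <- inject_group_draws(m, mu)
  cs2 <- constraint_spec("d_A_pleasant - d_B_pleasant > 0")
  de2 <- descriptive_individual_effects(d, cs2)
  expect_equal(unname(attr(de2, "counts")), c(1, 1))  # single participant
})

test_that("tidy methods on bf_result follow broom conventions", {
  m <- build_2htsm_bell()
  cs <- constraint_spec("d_A_pleasant - d_B_pleasant > 0", scale = "probit")
  mu <- matrix(0, 100, 12)
  mu[, match("d_A_pleasant", m$parameters)] <- 1
  bf <- encompassing_bf(inject_group_draws(m, mu), cs, prior_proportion = 0.5)
  td <- tidy(bf)
  expect_equal(nrow(td), 1)
  expect_equal(td$bf, 2)
  expect_equal(td$log10_bf, log10(2))
})
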