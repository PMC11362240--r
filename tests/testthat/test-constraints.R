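test_that("constraint evaluation matches a brute-force loop", {
  m <- build_2htsm_bell()
  set.seed(51)
  n <- 10000
  mu <- matrix(rnorm(n * 12), n, 12)
  d <- inject_group_draws(m, mu)
  cs <- constraint_spec(c("d_A_pleasant - d_B_pleasant > 0",
                          "d_A_disgusting - d_B_disgusting > 0",
                          "d_A_pleasant - d_B_pleasant > d_A_disgusting - d_B_disgusting"))
  got <- evaluate_constraint(cs, d)
  th <- pnorm(mu)
  colnames(th) <- m$parameters
  want <- logical(n)
  for (t in seq_len(n)) {
    d1 <- th[t, "d_A_pleasant"] - th[t, "d_B_pleasant"]
    d2 <- th[t, "d_A_disgusting"] - th[t, "d_B_disgusting"]
    want[t] <- d1 > 0 && d2 > 0 && d1 > d2
  }
  expect_identical(got, want)
})

test_that("exact ties count as non-conforming (strict inequalities)", {
  m <- build_2htsm_bell()
  mu <- matrix(0, 2, 12)          # all parameters equal -> all diffs zero
  mu[2, match("d_A_pleasant", m$parameters)] <- 0.5
  d <- inject_group_draws(m, mu)
  cs <- constraint_spec("d_A_pleasant - d_B_pleasant > 0")
  expect_identical(evaluate_constraint(cs, d), c(FALSE, TRUE))
})

test_that("direction and scale of constraints are configurable", {
  m <- build_2htsm_bell()
  mu <- matrix(0, 1, 12)
  mu[1, match("d_A_pleasant", m$parameters)] <- 1
  d <- inject_group_draws(m, mu)
  up <- constraint_spec("d_A_pleasant - d_B_pleasant > 0")
  down <- constraint_spec("d_A_pleasant - d_B_pleasant < 0")
  expect_true(evaluate_constraint(up, d))
  expect_false(evaluate_constraint(down, d))
  pro <- constraint_spec("d_A_pleasant - d_B_pleasant > 0", scale = "probit")
  expect_true(evaluate_constraint(pro, d))
})

test_that("malformed and cyclic constraints are rejected", {
  expect_error(constraint_spec("a >= b"), class = "ordtree_format_error")
  expect_error(constraint_spec("a > b > c"), class = "ordtree_format_error")
  expect_error(constraint_spec("a >"), class = "ordtree_format_error")
  expect_error(constraint_spec(c("a - b > 0", "0 > a - b")),
               class = "ordtree_value_error")  # cycle
  expect_error(constraint_spec(character(0)))
})

test_that("analytic prior proportions give the symmetry-exact values", {
  m <- build_2htsm_bell()
  pr <- matzke_klauer_preset(m)
  one <- constraint_spec("d_A_pleasant - d_B_pleasant > 0")
  two <- constraint_spec(c("d_A_pleasant - d_B_pleasant > 0",
                           "d_A_disgusting - d_B_disgusting > 0"))
  three <- constraint_spec(c("d_A_pleasant - d_B_pleasant > 0",
                             "d_A_disgusting - d_B_disgusting > 0",
                             "d_A_pleasant - d_B_pleasant > d_A_disgusting - d_B_disgusting"))
  expect_identical(
    prior_constraint_proportion(one, pr, m, "analytic")$proportion, 0.5)
  expect_identical(
    prior_constraint_proportion(two, pr, m, "analytic")$proportion, 0.25)
  expect_identical(
    prior_constraint_proportion(three, pr, m, "analytic")$proportion, 0.125)
})

test_that("analytic validation rejects non-exchangeable structures", {
  m <- build_2htsm_bell()
  inf <- informative_preset(m)
  # memory (scale 1) vs guessing (scale 0.28): difference not symmetric
  bad <- constraint_spec("d_A_pleasant - g_pleasant > 0")
  expect_error(prior_constraint_proportion(bad, inf, m, "analytic"),
               class = "ordtree_value_error")
  # ordering without sign constraints on the quantities
  ord_only <- constraint_spec(
    "d_A_pleasant - d_B_pleasant > d_A_disgusting - d_B_disgusting")
  expect_error(prior_constraint_proportion(ord_only, inf, m, "analytic"),
               class = "ordtree_value_error")
  # shared parameter across quantities breaks independence
  shared <- constraint_spec(c("d_A_pleasant - d_B_pleasant > 0",
                              "d_A_pleasant - d_B_disgusting > 0"))
  expect_error(prior_constraint_proportion(shared, inf, m, "analytic"),
               class = "ordtree_value_error")
})

test_that("Monte Carlo group proportions agree with analytic within 3 SE", {
  m <- build_2htsm_bell()
  pr <- matzke_klauer_preset(m)
  three <- constraint_spec(c("d_A_pleasant - d_B_pleasant > 0",
                             "d_A_disgusting - d_B_disgusting > 0",
                             "d_A_pleasant - d_B_pleasant > d_A_disgusting - d_B_disgusting"))
  mc <- prior_constraint_proportion(three, pr, m, "monte_carlo",
                                    n_draws = 2e5, seed = 13)
  expect_lt(abs(mc$proportion - 0.125), 3 * mc$mc_se)
  expect_gt(mc$mc_se, 0)
})

test_that("single-participant individual proportion reduces to the flat case", {
  m <- build_2htsm_bell()
  pr <- informative_preset(m)
  cs <- constraint_spec("d_A_pleasant - d_B_pleasant > 0",
                        level = "every_individual")
  out <- prior_constraint_proportion(cs, pr, m, "monte_carlo",
                                     n_draws = 4e4, n_participants = 1,
                                     seed = 14)
  expect_lt(abs(out$proportion - 0.5), 3 * out$mc_se + 0.01)
})

test_that("sequential elimination matches brute-force hierarchical draws", {
  m <- build_2htsm_bell()
  pr <- informative_preset(m)
  cs <- constraint_spec("d_A_pleasant - d_B_pleasant > 0",
                        level = "every_individual")
  N <- 4
  fast <- prior_constraint_proportion(cs, pr, m, "monte_carlo",
                                      n_draws = 3e4, n_participants = N,
                                      seed = 15)
  # brute force via full-dimensional draw_prior and evaluate_constraint
  full <- draw_prior(pr, m, n_participants = N, n_draws = 3e4, seed = 99)
  conform <- evaluate_constraint(cs, full)
  brute <- mean(conform)
  pooled_se <- sqrt(fast$mc_se^2 + brute * (1 - brute) / 3e4)
  expect_lt(abs(fast$proportion - brute), 4 * pooled_se)
  # and the per-participant attribute reduces by AND
  expect_identical(as.vector(conform),
                   unname(rowSums(!attr(conform, "by_participant")) == 0))
})

test_that("individual-level constraints demand n_participants", {
  m <- build_2htsm_bell()
  cs <- constraint_spec("d_A_pleasant - d_B_pleasant > 0",
                        level = "every_individual")
  expect_error(
    prior_constraint_proportion(cs, informative_preset(m), m, "monte_carlo",
                                n_draws = 100),
    class = "ordtree_value_error")
  expect_error(
    prior_constraint_proportion(cs, informative_preset(m), m, "analytic"),
    class = "ordtree_value_error")
})

test_that("constraints referencing unknown parameters error", {
  m <- build_2htsm()
  cs <- constraint_spec("nope - d > 0")
  expect_error(
    prior_constraint_proportion(cs, informative_preset(m), m, "analytic"),
    class = "ordtree_value_error")
  d <- inject_group_draws(m, matrix(0, 1, 4))
  expect_error(evaluate_constraint(cs, d), class = "ordtree_value_error")
})
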