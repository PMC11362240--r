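test_that("probit and its inverse are mutually inverse and guard domains", {
  p <- c(0.01, 0.3, 0.5, 0.99)
  expect_equal(probit_inverse(probit(p)), p, tolerance = 1e-12)
  expect_error(probit(0), class = "ordtree_domain_error")
  expect_error(probit(1), class = "ordtree_domain_error")
  expect_error(probit_inverse(Inf), class = "ordtree_domain_error")
})

test_that("presets encode the documented prior structure", {
  m <- build_2htsm()
  inf <- informative_preset(m)
  expect_equal(inf$group_mean$scale[inf$group_mean$parameter == "D"], 1)
  expect_equal(inf$group_mean$scale[inf$group_mean$parameter == "g"], 0.28)
  expect_equal(inf$deviation$dist, "gamma")
  expect_equal(c(inf$deviation$shape, inf$deviation$rate), c(2, 3))
  expect_equal(inf$correlation$dist, "lkj")
  mk <- matzke_klauer_preset(m)
  expect_true(all(mk$group_mean$scale == 1))
  expect_equal(mk$deviation$dist, "treebugs_default")
  expect_equal(mk$deviation$xi_upper, 10)
})

test_that("unknown parameter roles demand an explicit tagging", {
  m <- parse_eqn(c("T x q1", "T y (1-q1)"), validate = TRUE)
  expect_error(informative_preset(m), class = "ordtree_value_error")
  pr <- informative_preset(m, roles = c(q1 = "guessing"))
  expect_equal(pr$group_mean$scale, 0.28)
})

test_that("LKJ(1) marginal correlations in dimension 4 follow Beta(2,2)", {
  # marginal of r_ij under LKJ(eta, d): Beta(eta - 1 + d/2, .) on (-1, 1);
  # for eta = 1, d = 4 that is Beta(2, 2), variance (2*2)/((4)^2*5) on the
  # transformed scale -> var(r) = 4 * 4/(16*5) = 0.2
  set.seed(1)
  L <- ordtree:::rlkj_chol(20000, 4, eta = 1)
  R <- ordtree:::chol_to_corr(L)
  r <- R[, 2, 1]
  expect_equal(mean(r), 0, tolerance = 0.02)
  expect_equal(var(r), 0.2, tolerance = 0.01)
  # diagonals exactly 1, symmetric, positive definite
  expect_equal(R[, 3, 3], rep(1, 20000), tolerance = 1e-12)
  expect_equal(R[, 4, 2], R[, 2, 4], tolerance = 1e-12)
})

test_that("LKJ principal-submatrix marginal matches the adjusted eta", {
  # 2x2 principal submatrix of LKJ(1) in dimension 6 ~ LKJ(1 + (6-2)/2 = 3),
  # whose off-diagonal is 2*Beta(3.5, 3.5) - 1 in dimension 2... compare the
  # submatrix draw path used for constraint subsetting against full draws.
  set.seed(2)
  n <- 40000
  full <- ordtree:::chol_to_corr(ordtree:::rlkj_chol(n, 6, eta = 1))[, 2, 1]
  sub <- ordtree:::chol_to_corr(
    ordtree:::rlkj_chol(n, 2, eta = 1 + (6 - 2) / 2))[, 2, 1]
  # compare first two moments and a tail probability
  expect_equal(mean(sub), mean(full), tolerance = 0.01)
  expect_equal(var(sub), var(full), tolerance = 0.005)
  expect_equal(mean(sub > 0.5), mean(full > 0.5), tolerance = 0.01)
})

test_that("inverse-Wishart submatrix keeps the TreeBUGS-default form", {
  # covariance ~ IW(I_P, P+1); the k x k principal submatrix is
  # IW(I_k, k+1).  Compare sigma and correlation marginals.
  set.seed(3)
  n <- 30000
  full <- ordtree:::rtreebugs_cov(n, 4, xi_upper = 10)
  sub <- ordtree:::rtreebugs_cov(n, 2, xi_upper = 10, df = 3)
  r_full <- ordtree:::chol_to_corr(full$chol)[, 2, 1]
  r_sub <- ordtree:::chol_to_corr(sub$chol)[, 2, 1]
  expect_equal(mean(r_sub), mean(r_full), tolerance = 0.015)
  expect_equal(var(r_sub), var(r_full), tolerance = 0.02)
  expect_equal(median(sub$sigma[, 1]), median(full$sigma[, 1]),
               tolerance = 0.05 * median(full$sigma[, 1]) + 0.05)
})

test_that("prior draws are seed-deterministic and leave the RNG untouched", {
  m <- build_2htsm()
  pr <- informative_preset(m)
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  d1 <- draw_prior(pr, m, n_participants = 3, n_draws = 50, seed = 7)
  after <- runif(1)
  expect_equal(before, after)  # global stream untouched by draw_prior
  d2 <- draw_prior(pr, m, n_participants = 3, n_draws = 50, seed = 7)
  expect_equal(d1$group_mu, d2$group_mu)
  expect_equal(d1$indiv_prob, d2$indiv_prob)
  expect_equal(dim(d1$indiv_prob), c(50, 3, 4))
})

test_that("scale_deviations matches per-draw matrix algebra", {
  set.seed(4)
  n <- 20; N <- 3; P <- 4
  Z <- array(rnorm(n * N * P), c(n, N, P))
  sigma <- matrix(rgamma(n * P, 2, 3), n, P)
  L <- ordtree:::rlkj_chol(n, P, eta = 1)
  got <- ordtree:::scale_deviations(Z, sigma, L)
  for (t in c(1, 7, 20)) for (i in seq_len(N)) {
    want <- diag(sigma[t, ]) %*% L[t, , ] %*% Z[t, i, ]
    expect_equal(got[t, i, ], as.vector(want), tolerance = 1e-12)
  }
})

test_that("group_prob_summary computes the median and latent-mean correctly", {
  m <- toy_binomial_model()
  mu <- matrix(0.5, 100, 1, dimnames = list(NULL, "p"))
  d <- ordtree:::new_mpt_draws("p", mu, sigma = matrix(1, 100, 1),
                               corr_chol = NULL,
                               indiv_probit = array(0.5, c(100, 1, 1)),
                               provenance = "prior", seed = 1)
  s <- group_prob_summary(d, "p")
  expect_equal(s$median, pnorm(0.5))
  expect_equal(s$mean, pnorm(0.5 / sqrt(2)))
})

test_that("extremeness_index measures boundary mass with an MC SE", {
  m <- toy_binomial_model()
  eta <- array(qnorm(c(0.01, 0.5, 0.95, 0.5)), c(4, 1, 1))
  d <- ordtree:::new_mpt_draws("p", matrix(0, 4, 1), matrix(0, 4, 1),
                               NULL, eta, "prior", 1)
  out <- extremeness_index(d, "p", band = 0.1)
  expect_equal(out$index, 0.5)
  expect_equal(out$n, 4)
  expect_error(extremeness_index(d, "nope"))
})
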