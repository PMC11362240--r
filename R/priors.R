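# ---------------------------------------------------------------------------
# Latent-trait hierarchy: priors and prior sampling
#
# Individual parameters live on the probit scale: eta_i = mu + delta_i with
# delta_i ~ MVN(0, Sigma), Sigma = diag(sigma) %*% Omega %*% diag(sigma),
# and theta_i = pnorm(eta_i) on the probability scale.
# ---------------------------------------------------------------------------

# Evaluate `code` under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Probit link and its inverse
#'
#' The probit transformation maps probabilities to the latent scale via the
#' standard-normal quantile function; its inverse is the standard-normal CDF.
#'
#' @param p Probabilities strictly inside (0, 1).
#' @param z Finite latent-scale values.
#' @return `probit()` returns latent values; `probit_inverse()` probabilities.
#' @export
probit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("probit() requires probabilities strictly inside (0, 1)",
          class = "ordtree_domain_error")
  }
  qnorm(p)
}

#' @rdname probit
#' @export
probit_inverse <- function(z) {
  if (any(!is.finite(z))) {
    abort("probit_inverse() requires finite values",
          class = "ordtree_domain_error")
  }
  pnorm(z)
}

# --- prior specification ----------------------------------------------------

#' Specify priors for the latent-trait hierarchy
#'
#' @param group_mean A data frame with columns `parameter`, `loc`, `scale`
#'   giving an independent normal prior on each probit-scale group mean.
#' @param deviation Prior on the individual deviation SDs: one of
#'   `list(dist = "gamma", shape, rate)`, `list(dist = "fixed", value)`, or
#'   `list(dist = "treebugs_default", df = NULL, xi_upper = 10)` (a
#'   parameter-expanded Wishart construction that also determines the
#'   correlations; see Details).
#' @param correlation Prior on the correlation matrix:
#'   `list(dist = "lkj", eta)` or `list(dist = "identity")`.  Ignored when
#'   `deviation` uses the `treebugs_default` construction.
#' @param scale_is Whether the `scale` column of `group_mean` is a standard
#'   deviation (`"sd"`, default) or a variance (`"var"`).
#' @param preset Optional preset name carried for bookkeeping.
#'
#' @details The `treebugs_default` construction draws a precision matrix from
#'   a Wishart distribution with identity scale and `df = P + 1` degrees of
#'   freedom, inverts it, and scales the implied standard deviations by
#'   independent Uniform(0, `xi_upper`) expansion factors; correlations are
#'   taken from the inverted Wishart draw.
#'
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(group_mean, deviation, correlation = list(dist = "lkj", eta = 1),
                       scale_is = c("sd", "var"), preset = NA_character_) {
  scale_is <- match.arg(scale_is)
  group_mean <- as_tibble(group_mean)
  stopifnot(all(c("parameter", "loc", "scale") %in% names(group_mean)))
  if (any(group_mean$scale <= 0)) abort("group-mean prior scales must be > 0")
  if (anyDuplicated(group_mean$parameter)) {
    abort("each parameter must map to exactly one group-mean prior")
  }
  if (scale_is == "var") {
    group_mean$scale <- sqrt(group_mean$scale)
    scale_is <- "sd"
  }
  deviation$dist <- match.arg(deviation$dist,
                              c("gamma", "fixed", "treebugs_default"))
  if (deviation$dist == "gamma" &&
      (deviation$shape <= 0 || deviation$rate <= 0)) {
    abort("gamma deviation prior requires shape > 0 and rate > 0")
  }
  if (deviation$dist == "treebugs_default" && is.null(deviation$xi_upper)) {
    deviation$xi_upper <- 10
  }
  correlation$dist <- match.arg(correlation$dist, c("lkj", "identity"))
  if (correlation$dist == "lkj") {
    if (is.null(correlation$eta)) correlation$eta <- 1
    if (correlation$eta <= 0) abort("LKJ eta must be > 0")
  }
  structure(
    list(group_mean = group_mean, deviation = deviation,
         correlation = correlation, preset = preset),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec", if (!is.na(x$preset)) paste0(" preset=", x$preset), ">\n",
      sep = "")
  print(x$group_mean)
  cat("deviation:", x$deviation$dist,
      if (x$deviation$dist == "gamma")
        paste0("(shape ", x$deviation$shape, ", rate ", x$deviation$rate, ")"),
      "\n")
  cat("correlation:", x$correlation$dist,
      if (x$correlation$dist == "lkj") paste0("(eta ", x$correlation$eta, ")"),
      "\n")
  invisible(x)
}

prior_parameters <- function(prior) prior$group_mean$parameter

#' Theory-informed prior preset
#'
#' Group-mean priors of Normal(0, 1) for memory-type parameters and
#' Normal(0, 0.28) (SD scale) for guessing-type parameters on the probit
#' scale -- the latter mildly favors values around the nominal guessing level
#' -- together with Gamma(shape 2, rate 3) deviation SDs and an LKJ(1)
#' correlation prior.
#'
#' @param model An `mpt_model`.
#' @param roles Optional named character vector mapping each free parameter
#'   to `"memory"` or `"guessing"`; by default inferred from the leading
#'   letter of the parameter name (`D`/`d` memory, `b`/`g`/`a` guessing).
#' @param guessing_scale Prior SD for guessing-type group means.
#' @return A `prior_spec`.
#' @export
informative_preset <- function(model, roles = NULL, guessing_scale = 0.28) {
  roles <- resolve_roles(model, roles)
  gm <- tibble(
    parameter = model$parameters,
    loc = 0,
    scale = unname(ifelse(roles[model$parameters] == "memory", 1,
                          guessing_scale))
  )
  prior_spec(gm, deviation = list(dist = "gamma", shape = 2, rate = 3),
             correlation = list(dist = "lkj", eta = 1),
             preset = "informative")
}

#' Matzke--Klauer prior preset
#'
#' Standard-normal group-mean priors for all parameters (implying a uniform
#' prior on the probability scale) with the TreeBUGS-default covariance
#' construction: precision ~ Wishart(identity, P + 1) and parameter-expanded
#' scaling factors ~ Uniform(0, 10).
#'
#' @inheritParams informative_preset
#' @return A `prior_spec`.
#' @export
matzke_klauer_preset <- function(model, roles = NULL) {
  roles <- resolve_roles(model, roles)  # validates tagging
  gm <- tibble(parameter = model$parameters, loc = 0, scale = 1)
  prior_spec(gm, deviation = list(dist = "treebugs_default", xi_upper = 10),
             correlation = list(dist = "identity"),
             preset = "matzke_klauer")
}

resolve_roles <- function(model, roles) {
  inferred <- default_parameter_roles(model)
  if (!is.null(roles)) inferred[names(roles)] <- roles
  untagged <- model$parameters[is.na(inferred[model$parameters])]
  if (length(untagged)) {
    abort(paste0("parameter(s) not tagged as memory or guessing: ",
                 paste(untagged, collapse = ", "),
                 "; supply `roles`"), class = "ordtree_value_error")
  }
  inferred
}

# --- LKJ sampling (C-vine construction) -------------------------------------

# Draw n lower-triangular Cholesky factors of LKJ(eta) correlation matrices,
# dimension p.  Canonical partial correlations in vine column j follow
# 2 * Beta(b_j, b_j) - 1 with b_j = eta + (p - 1 - j)/2 (Lewandowski,
# Kurowicka & Joe, 2009).  Returns an n x p x p array; vectorized over draws.
rlkj_chol <- function(n, p, eta = 1) {
  L <- array(0, c(n, p, p))
  L[, 1, 1] <- 1
  if (p == 1L) return(L)
  for (i in 2:p) {
    rem <- rep(1, n)
    for (j in 1:(i - 1)) {
      b <- eta + (p - 1 - j) / 2
      z <- 2 * rbeta(n, b, b) - 1
      L[, i, j] <- z * sqrt(rem)
      rem <- rem - L[, i, j]^2
    }
    L[, i, i] <- sqrt(pmax(rem, 0))
  }
  L
}

# Correlation matrices from Cholesky factors: R = L %*% t(L), vectorized.
chol_to_corr <- function(L) {
  n <- dim(L)[1]; p <- dim(L)[2]
  R <- array(0, c(n, p, p))
  for (i in 1:p) for (j in 1:i) {
    s <- rep(0, n)
    for (k in 1:j) s <- s + L[, i, k] * L[, j, k]
    R[, i, j] <- s
    R[, j, i] <- s
  }
  R
}

# TreeBUGS-default covariance draws: precision ~ Wishart(I, p + 1), inverted;
# SDs scaled by xi ~ U(0, xi_upper).  Returns list(sigma = n x p,
# chol = n x p x p Cholesky factors of the correlation matrix).
rtreebugs_cov <- function(n, p, xi_upper = 10, df = NULL) {
  if (is.null(df)) df <- p + 1
  W <- rWishart(n, df = df, Sigma = diag(p))
  sigma <- matrix(NA_real_, n, p)
  Lc <- array(0, c(n, p, p))
  for (t in seq_len(n)) {
    Q <- chol2inv(chol(W[, , t]))
    s <- sqrt(diag(Q))
    R <- Q / tcrossprod(s)
    Lc[t, , ] <- t(chol(R))
    sigma[t, ] <- s
  }
  xi <- matrix(runif(n * p, 0, xi_upper), n, p)
  list(sigma = xi * sigma, chol = Lc)
}

# --- prior draws ------------------------------------------------------------

new_mpt_draws <- function(parameters, group_mu, sigma, corr_chol,
                          indiv_probit, provenance, seed,
                          participants = NULL) {
  indiv_prob <- pnorm(indiv_probit)
  structure(
    list(parameters = parameters, group_mu = group_mu, sigma = sigma,
         corr_chol = corr_chol, indiv_probit = indiv_probit,
         indiv_prob = indiv_prob, provenance = provenance, seed = seed,
         participants = participants %||%
           paste0("p", seq_len(dim(indiv_probit)[2]))),
    class = "mpt_draws"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mpt_draws <- function(x, ...) {
  d <- dim(x$indiv_probit)
  cat("<mpt_draws ", x$provenance, ": ", d[1], " draws x ", d[2],
      " participants x ", d[3], " parameters>\n", sep = "")
  invisible(x)
}

#' Number of draws in an `mpt_draws` object
#' @param draws An `mpt_draws` object.
#' @return Integer count of retained draws.
#' @export
n_draws <- function(draws) dim(draws$indiv_probit)[1]

#' Draw from the prior of the latent-trait hierarchy
#'
#' Samples group means, deviation SDs, correlation matrices, and individual
#' probit-scale parameters (group mean plus multivariate-normal deviation)
#' from a prior specification.
#'
#' @param prior A `prior_spec`.
#' @param model An `mpt_model` (defines the parameter set and order).
#' @param n_participants Number of participants per draw.
#' @param n_draws Number of prior draws.
#' @param seed Integer seed; the global RNG stream is left untouched.
#' @return An `mpt_draws` object with provenance `"prior"`.
#' @export
draw_prior <- function(prior, model, n_participants = 1, n_draws = 1000,
                       seed = 1) {
  stopifnot(inherits(prior, "prior_spec"), n_participants >= 1, n_draws >= 1)
  pars <- model$parameters
  miss <- setdiff(pars, prior$group_mean$parameter)
  if (length(miss)) {
    abort(paste0("prior is missing group-mean spec for: ",
                 paste(miss, collapse = ", ")))
  }
  P <- length(pars)
  gm <- prior$group_mean[match(pars, prior$group_mean$parameter), ]
  with_seed(seed, {
    mu <- matrix(rnorm(n_draws * P, mean = rep(gm$loc, each = n_draws),
                       sd = rep(gm$scale, each = n_draws)), n_draws, P)
    cov <- draw_cov_prior(prior, n_draws, P)
    Z <- array(rnorm(n_draws * n_participants * P),
               c(n_draws, n_participants, P))
    delta <- scale_deviations(Z, cov$sigma, cov$chol)
    eta <- delta
    for (p in seq_len(P)) eta[, , p] <- delta[, , p] + mu[, p]
    colnames(mu) <- pars
    colnames(cov$sigma) <- pars
    new_mpt_draws(pars, mu, cov$sigma, cov$chol, eta,
                  provenance = "prior", seed = seed)
  })
}

draw_cov_prior <- function(prior, n_draws, P) {
  dev <- prior$deviation
  if (dev$dist == "treebugs_default") {
    return(rtreebugs_cov(n_draws, P, xi_upper = dev$xi_upper, df = dev$df))
  }
  sigma <- switch(dev$dist,
    gamma = matrix(rgamma(n_draws * P, shape = dev$shape, rate = dev$rate),
                   n_draws, P),
    fixed = matrix(dev$value, n_draws, P)
  )
  chol <- if (prior$correlation$dist == "lkj") {
    rlkj_chol(n_draws, P, eta = prior$correlation$eta)
  } else {
    L <- array(0, c(n_draws, P, P))
    for (p in seq_len(P)) L[, p, p] <- 1
    L
  }
  list(sigma = sigma, chol = chol)
}

# delta[t, i, ] = diag(sigma[t, ]) %*% L[t, , ] %*% Z[t, i, ]; vectorized over
# draws and participants by looping over the P x P Cholesky entries.
scale_deviations <- function(Z, sigma, L) {
  d <- dim(Z)
  delta <- array(0, d)
  P <- d[3]
  for (p in seq_len(P)) {
    acc <- array(0, d[1:2])
    for (q in seq_len(p)) {
      lc <- L[, p, q]
      if (all(lc == 0)) next
      acc <- acc + Z[, , q, drop = FALSE][, , 1] * lc
    }
    delta[, , p] <- acc * sigma[, p]
  }
  delta
}

# --- summaries --------------------------------------------------------------

#' Proportion of individual-level prior mass near the parameter boundaries
#'
#' Measures how much individual-level probability-scale mass a set of draws
#' places within `band` of 0 or 1 -- the diagnostic for priors that favor
#' implausibly extreme individual parameter values.
#'
#' @param draws An `mpt_draws` object.
#' @param parameter Parameter name.
#' @param band Width of the boundary bands (default 0.1).
#' @return A tibble with columns `parameter`, `band`, `index`, `mc_se`, `n`.
#' @export
extremeness_index <- function(draws, parameter, band = 0.1) {
  stopifnot(inherits(draws, "mpt_draws"))
  p <- match(parameter, draws$parameters)
  if (is.na(p)) abort(paste0("unknown parameter '", parameter, "'"))
  x <- draws$indiv_prob[, , p]
  if (!length(x)) abort("empty draws", class = "ordtree_value_error")
  hit <- x <= band | x >= 1 - band
  n <- length(hit)
  idx <- mean(hit)
  tibble(parameter = parameter, band = band, index = idx,
         mc_se = sqrt(idx * (1 - idx) / n), n = n)
}

#' Probability-scale summary of a group-level parameter
#'
#' On the probability scale the probit-transformed group mean is the
#' group-level *median*, not the mean; the group-level mean additionally
#' depends on the deviation SD and equals
#' `pnorm(mu / sqrt(1 + sigma^2))` for a normal latent population, averaged
#' over the draws.
#'
#' @param draws An `mpt_draws` object.
#' @param parameter Parameter name.
#' @return A tibble with columns `parameter`, `median`, `mean`.
#' @export
group_prob_summary <- function(draws, parameter) {
  stopifnot(inherits(draws, "mpt_draws"))
  p <- match(parameter, draws$parameters)
  if (is.na(p)) abort(paste0("unknown parameter '", parameter, "'"))
  mu <- draws$group_mu[, p]
  sg <- draws$sigma[, p]
  tibble(parameter = parameter,
         median = pnorm(median(mu)),
         mean = mean(pnorm(mu / sqrt(1 + sg^2))))
}

#' Tidy individual-level draws
#'
#' @param draws An `mpt_draws` object.
#' @param parameters Optional subset of parameter names.
#' @param scale `"probability"` or `"probit"`.
#' @return A tibble with columns `draw`, `participant`, `parameter`, `value`.
#' @export
tidy_draws <- function(draws, parameters = NULL, scale = c("probability", "probit")) {
  scale <- match.arg(scale)
  arr <- if (scale == "probability") draws$indiv_prob else draws$indiv_probit
  pars <- parameters %||% draws$parameters
  idx <- match(pars, draws$parameters)
  d <- dim(arr)
  purrr::map_dfr(seq_along(pars), function(k) {
    tibble(
      draw = rep(seq_len(d[1]), times = d[2]),
      participant = rep(draws$participants, each = d[1]),
      parameter = pars[k],
      value = as.vector(arr[, , idx[k]])
    )
  })
}

#' Tidy group-level draws
#'
#' @param draws An `mpt_draws` object.
#' @param scale `"probit"` (raw group means) or `"probability"`
#'   (probit-inverse transformed, i.e. group-level medians).
#' @return A tibble with columns `draw`, `parameter`, `mu`, `sigma`.
#' @export
tidy_group_draws <- function(draws, scale = c("probit", "probability")) {
  scale <- match.arg(scale)
  mu <- draws$group_mu
  if (scale == "probability") mu <- pnorm(mu)
  tibble(
    draw = rep(seq_len(nrow(mu)), times = ncol(mu)),
    parameter = rep(draws$parameters, each = nrow(mu)),
    mu = as.vector(mu),
    sigma = as.vector(draws$sigma)
  )
}
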