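# ---------------------------------------------------------------------------
# Bayes factors: Savage--Dickey ratios for point nulls and encompassing-prior
# counting for order constraints, composed by transitivity
# ---------------------------------------------------------------------------

new_bf_result <- function(bf, comparison, method, details = list()) {
  structure(c(list(bf = bf, comparison = comparison, method = method),
              details),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat("<bf_result ", x$comparison, ": BF = ", signif(x$bf, 4), sep = "")
  if (!is.null(x$bf_min)) {
    cat("  [", signif(x$bf_min, 4), ", ", signif(x$bf_max, 4), "] over ",
        length(x$repetitions), " repetitions", sep = "")
  }
  cat(" (", x$method, ")", sep = "")
  if (isTRUE(x$is_bound)) cat("  ! lower/upper bound, no conforming draws")
  if (isFALSE(x$reliable)) cat("  ! unreliable (few conforming draws)")
  cat(">\n")
  invisible(x)
}

#' Tidy a Bayes-factor result
#'
#' @param x A `bf_result`.
#' @param ... Unused.
#' @return A one-row tibble with the Bayes factor, comparison label, method,
#'   and reliability flags.
#' @export
tidy.bf_result <- function(x, ...) {
  tibble(
    comparison = x$comparison,
    bf = x$bf,
    log10_bf = log10(x$bf),
    method = x$method,
    bf_min = x$bf_min %||% NA_real_,
    bf_max = x$bf_max %||% NA_real_,
    reliable = x$reliable %||% TRUE,
    is_bound = x$is_bound %||% FALSE
  )
}

# Per-draw values of a derived quantity at the group level.
quantity_draws <- function(draws, quantity) {
  env <- draws_env(draws, quantity$parameters, quantity$scale, "group")
  as.vector(eval(quantity$expr, env))
}

as_draws <- function(x) {
  if (inherits(x, "mpt_fit")) return(x$draws)
  if (inherits(x, "mpt_draws")) return(x)
  abort("expected an mpt_fit or mpt_draws object",
        class = "ordtree_value_error")
}

# A cheap fingerprint of a draw set, used to verify that transitivity-composed
# Bayes factors share the same encompassing posterior.
draws_fingerprint <- function(draws) {
  sprintf("%d/%d/%.10g", nrow(draws$group_mu), ncol(draws$group_mu),
          sum(draws$group_mu))
}

#' Prior density of a derived quantity at its null value
#'
#' For the difference of two parameters whose group-level priors are standard
#' normal on the probit scale -- hence uniform on the probability scale -- the
#' probability-scale prior of the difference is triangular on (-1, 1) and the
#' density is `1 - |at|` exactly.  When that structure does not hold, the
#' density is estimated by the package's log-spline estimator on prior draws.
#'
#' @param quantity A `derived_quantity` (or expression string).
#' @param prior A `prior_spec`.
#' @param model An `mpt_model`.
#' @param method `"analytic"` (validated structurally; errors with guidance if
#'   inapplicable) or `"logspline"`.
#' @param at Evaluation point (default 0).
#' @param n_draws Prior draws for the log-spline route.
#' @param seed Integer seed for the log-spline route.
#' @param support Support passed to the log-spline estimator.
#' @return The prior density value at `at`.
#' @export
prior_density_at_null <- function(quantity, prior, model,
                                  method = c("analytic", "logspline"),
                                  at = 0, n_draws = 1e5, seed = 1,
                                  support = c(-1, 1)) {
  method <- match.arg(method)
  quantity <- as_quantity(quantity)
  if (method == "analytic") {
    fail <- function(why) {
      abort(paste0("analytic prior density unavailable: ", why,
                   "; use method = 'logspline'"),
            class = "ordtree_value_error")
    }
    if (quantity$scale != "probability") {
      fail("only probability-scale quantities have a closed form here")
    }
    check_uniform <- function(p) {
      row <- prior$group_mean[prior$group_mean$parameter == p, ]
      if (!nrow(row)) fail(paste0("no prior for parameter '", p, "'"))
      if (abs(row$loc) > 1e-12 || abs(row$scale - 1) > 1e-12) {
        fail(paste0("prior of '", p, "' is not standard normal on the probit",
                    " scale (uniform on the probability scale)"))
      }
    }
    if (is.name(quantity$expr)) {
      # a single parameter with an implied uniform(0, 1) prior
      check_uniform(as.character(quantity$expr))
      return(if (at <= 0 || at >= 1) 0 else 1)
    }
    pair <- simple_difference(quantity$expr)
    if (is.null(pair)) {
      fail(paste0("'", quantity$text,
                  "' is neither a single parameter nor a difference of two"))
    }
    for (p in pair) check_uniform(p)
    if (pair[1] == pair[2]) fail("the two parameters must be distinct")
    if (abs(at) >= 1) return(0)
    return(1 - abs(at))
  }
  pars <- quantity$parameters
  gm <- prior$group_mean[match(pars, prior$group_mean$parameter), ]
  if (anyNA(gm$parameter)) {
    abort(paste0("prior is missing group-mean spec for: ",
                 paste(pars[is.na(gm$parameter)], collapse = ", ")))
  }
  vals <- with_seed(seed, {
    env <- list()
    for (k in seq_along(pars)) {
      mu <- rnorm(n_draws, gm$loc[k], gm$scale[k])
      env[[pars[k]]] <- if (quantity$scale == "probability") pnorm(mu) else mu
    }
    as.vector(eval(quantity$expr, env))
  })
  f <- logspline_density(vals, support = support)
  f(at)
}

#' Savage--Dickey Bayes factor for point-null constraints
#'
#' The Bayes factor of the point-null model (each quantity pinned to its null
#' value, 0 by default) against the encompassing model is the product over
#' quantities of posterior over prior density at the null value.  The
#' posterior density is approximated either by the package's log-spline
#' estimator or by a truncated-normal fit; the prior density is analytic when
#' the triangular-prior structure holds and log-spline otherwise.
#'
#' @param fit An `mpt_fit` (or `mpt_draws` posterior).
#' @param quantities A list of `derived_quantity` objects or expression
#'   strings (probability scale assumed for strings).
#' @param prior The `prior_spec` the posterior was fitted under (defaults to
#'   the fit's own prior).
#' @param model The `mpt_model` (defaults to the fit's model).
#' @param method Posterior density estimator: `"logspline"` or
#'   `"truncated_normal"`.
#' @param prior_method Prior density route, see [prior_density_at_null()];
#'   `"auto"` tries analytic and falls back to log-spline.
#' @param at Null value(s), recycled over quantities.
#' @param n_prior_draws,seed Settings for log-spline prior densities.
#' @param support Support of each quantity (passed to the estimators).
#' @param joint With exactly two quantities: estimate the posterior density
#'   at the joint null by a bivariate log-spline instead of the default
#'   product of univariate ratios (the default is justified by the a-priori
#'   independence of the group means).
#' @return A `bf_result` for "null vs encompassing" (`BF_0e`) with a
#'   per-quantity breakdown in `$quantities`.
#' @export
savage_dickey_bf <- function(fit, quantities, prior = NULL, model = NULL,
                             method = c("logspline", "truncated_normal"),
                             prior_method = c("auto", "analytic", "logspline"),
                             at = 0, n_prior_draws = 1e5, seed = 1,
                             support = c(-1, 1), joint = FALSE) {
  method <- match.arg(method)
  prior_method <- match.arg(prior_method)
  draws <- as_draws(fit)
  prior <- prior %||% fit$prior
  model <- model %||% fit$model
  if (is.null(prior)) abort("supply `prior` when passing raw draws")
  if (inherits(quantities, "derived_quantity") || is.character(quantities)) {
    quantities <- if (is.character(quantities)) as.list(quantities)
                  else list(quantities)
  }
  quantities <- lapply(quantities, as_quantity)
  at <- rep(at, length.out = length(quantities))
  if (joint) {
    if (length(quantities) != 2) {
      abort("`joint = TRUE` requires exactly two quantities",
            class = "ordtree_value_error")
    }
    if (method != "logspline") {
      abort("`joint = TRUE` is only available with method = 'logspline'",
            class = "ordtree_value_error")
    }
    post <- cbind(quantity_draws(draws, quantities[[1]]),
                  quantity_draws(draws, quantities[[2]]))
    f2 <- logspline_density2d(post, support = list(support, support))
    post_dens <- f2(at[1], at[2])
    prior_dens <- prod(vapply(seq_along(quantities), function(k) {
      prior_density_at_null(quantities[[k]], prior, model,
                            method = "analytic", at = at[k])
    }, numeric(1)))
    return(new_bf_result(
      bf = post_dens / prior_dens,
      comparison = "null vs encompassing",
      method = "savage_dickey/logspline-joint",
      details = list(
        quantities = tibble(
          quantity = vapply(quantities, `[[`, character(1), "name"),
          at = at, posterior_density = c(post_dens, NA),
          prior_density = c(prior_dens, NA),
          bf_0e = c(post_dens / prior_dens, NA)),
        encompassing_id = draws_fingerprint(draws))
    ))
  }
  rows <- vector("list", length(quantities))
  for (k in seq_along(quantities)) {
    q <- quantities[[k]]
    post <- quantity_draws(draws, q)
    post_dens <- if (method == "logspline") {
      logspline_density(post, support = support)(at[k])
    } else {
      truncnorm_density(post, at[k], bounds = support)
    }
    prior_dens <- if (prior_method == "auto") {
      tryCatch(
        prior_density_at_null(q, prior, model, method = "analytic",
                              at = at[k]),
        ordtree_value_error = function(e) {
          prior_density_at_null(q, prior, model, method = "logspline",
                                at = at[k], n_draws = n_prior_draws,
                                seed = seed + k, support = support)
        })
    } else {
      prior_density_at_null(q, prior, model, method = prior_method,
                            at = at[k], n_draws = n_prior_draws,
                            seed = seed + k, support = support)
    }
    rows[[k]] <- tibble(quantity = q$name, at = at[k],
                        posterior_density = post_dens,
                        prior_density = prior_dens,
                        bf_0e = post_dens / prior_dens)
  }
  qt <- dplyr::bind_rows(rows)
  new_bf_result(
    bf = prod(qt$bf_0e),
    comparison = "null vs encompassing",
    method = paste0("savage_dickey/", method),
    details = list(quantities = qt,
                   encompassing_id = draws_fingerprint(draws))
  )
}

#' Encompassing-prior Bayes factor for order constraints
#'
#' `BF_re` = (posterior proportion of draws conforming to the constraint) /
#' (prior proportion).  With zero conforming posterior draws the Bayes factor
#' cannot be estimated; an upper bound of `1 / (n_draws * prior proportion)`
#' is reported and flagged.  Results based on fewer than `min_conform`
#' conforming posterior draws are flagged unreliable.
#'
#' @param fit An `mpt_fit` or posterior `mpt_draws`.
#' @param constraint A `constraint_spec` (group level).
#' @param prior The `prior_spec` (defaults to the fit's).
#' @param model The `mpt_model` (defaults to the fit's).
#' @param prior_method Passed to [prior_constraint_proportion()].
#' @param prior_proportion Optional precomputed prior proportion (overrides
#'   computation; useful when reusing one proportion across repetitions).
#' @param n_prior_draws,seed Monte Carlo settings for the prior proportion.
#' @param min_conform Reliability threshold on conforming posterior draws.
#' @return A `bf_result` for "restricted vs encompassing" (`BF_re`).
#' @export
encompassing_bf <- function(fit, constraint, prior = NULL, model = NULL,
                            prior_method = c("analytic", "monte_carlo"),
                            prior_proportion = NULL, n_prior_draws = 1e5,
                            seed = 1, min_conform = 10) {
  prior_method <- match.arg(prior_method)
  draws <- as_draws(fit)
  prior <- prior %||% fit$prior
  model <- model %||% fit$model
  if (constraint$level != "group") {
    abort("use individual_level_bf() for every_individual constraints",
          class = "ordtree_value_error")
  }
  if (is.null(prior_proportion)) {
    if (is.null(prior) || is.null(model)) {
      abort("supply `prior` and `model` (or a precomputed prior_proportion)")
    }
    pp <- prior_constraint_proportion(constraint, prior, model,
                                      method = prior_method,
                                      n_draws = n_prior_draws, seed = seed)
    prior_proportion <- pp$proportion
    prior_se <- pp$mc_se
  } else {
    prior_se <- NA_real_
  }
  if (prior_proportion <= 0) {
    abort("prior proportion is zero; increase n_prior_draws",
          class = "ordtree_value_error")
  }
  conform <- evaluate_constraint(constraint, draws)
  n <- length(conform)
  n_conform <- sum(conform)
  post_prop <- n_conform / n
  is_bound <- n_conform == 0
  bf <- if (is_bound) 1 / (n * prior_proportion) else post_prop / prior_proportion
  new_bf_result(
    bf = bf,
    comparison = "restricted vs encompassing",
    method = paste0("encompassing/", prior_method),
    details = list(
      posterior_proportion = post_prop,
      posterior_se = sqrt(post_prop * (1 - post_prop) / n),
      prior_proportion = prior_proportion,
      prior_se = prior_se,
      n_posterior = n, n_conform = n_conform,
      reliable = n_conform >= min_conform,
      is_bound = is_bound,
      encompassing_id = draws_fingerprint(draws)
    )
  )
}

#' Compose Bayes factors by transitivity
#'
#' `BF_r0 = BF_re / BF_0e`: the restricted (order-constrained) model against
#' the point-null model, both having been compared with the same encompassing
#' posterior.  The function refuses to compose results whose encompassing
#' draws differ.
#'
#' @param bf_re A `bf_result` from [encompassing_bf()].
#' @param bf_0e A `bf_result` from [savage_dickey_bf()].
#' @return A `bf_result` for "restricted vs null".
#' @export
compose_by_transitivity <- function(bf_re, bf_0e) {
  stopifnot(inherits(bf_re, "bf_result"), inherits(bf_0e, "bf_result"))
  id1 <- bf_re$encompassing_id
  id2 <- bf_0e$encompassing_id
  if (!is.null(id1) && !is.null(id2) && !identical(id1, id2)) {
    abort("the two Bayes factors were computed against different encompassing posteriors; transitivity does not apply",
          class = "ordtree_value_error")
  }
  new_bf_result(
    bf = bf_re$bf / bf_0e$bf,
    comparison = "restricted vs null",
    method = paste(bf_re$method, "/", bf_0e$method),
    details = list(
      bf_re = bf_re$bf, bf_0e = bf_0e$bf,
      reliable = isTRUE(bf_re$reliable %||% TRUE) &&
                 isTRUE(bf_0e$reliable %||% TRUE),
      is_bound = isTRUE(bf_re$is_bound %||% FALSE),
      encompassing_id = id1 %||% id2
    )
  )
}

# Subset of the retained draws (used by bf_repeat's fast mode).
subset_draws <- function(draws, idx) {
  new_mpt_draws(
    draws$parameters,
    draws$group_mu[idx, , drop = FALSE],
    draws$sigma[idx, , drop = FALSE],
    corr_chol = if (!is.null(draws$corr_chol)) {
      draws$corr_chol[idx, , , drop = FALSE]
    },
    indiv_probit = draws$indiv_probit[idx, , , drop = FALSE],
    provenance = draws$provenance, seed = draws$seed,
    participants = draws$participants
  )
}

#' Monte-Carlo variability of a Bayes factor
#'
#' Recomputes a Bayes factor over repetitions and reports the median with the
#' min--max range.  `mode = "fast"` partitions the existing posterior draws
#' into disjoint, chain-respecting contiguous segments and recomputes the
#' Bayes factor on each; `mode = "full"` re-runs posterior sampling with a
#' fresh seed per repetition via `refit`.
#'
#' @param fit An `mpt_fit`.
#' @param bf_fun A function `(draws, seed) -> bf_result` (or a bare number).
#' @param n_repetitions Number of repetitions.
#' @param seeds Optional integer seeds (default `seed_base + 1:n`).
#' @param mode `"fast"` or `"full"`.
#' @param refit Required for `"full"`: a function `(seed) -> mpt_fit`.
#' @param seed_base Base for default seeds.
#' @return A `bf_result` with `bf` = median, `bf_min`/`bf_max`, and the
#'   per-repetition values in `$repetitions`; failed repetitions are dropped
#'   and counted in `$failures`.
#' @export
bf_repeat <- function(fit, bf_fun, n_repetitions = 10, seeds = NULL,
                      mode = c("fast", "full"), refit = NULL, seed_base = 100) {
  mode <- match.arg(mode)
  stopifnot(n_repetitions >= 2)
  seeds <- seeds %||% (seed_base + seq_len(n_repetitions))
  stopifnot(length(seeds) == n_repetitions)
  one <- function(r) {
    if (mode == "fast") {
      ch <- fit$chain_id
      idx <- unlist(lapply(unique(ch), function(c0) {
        rows <- which(ch == c0)
        cuts <- floor(seq(0, length(rows), length.out = n_repetitions + 1))
        rows[(cuts[r] + 1):cuts[r + 1]]
      }))
      d <- subset_draws(fit$draws, idx)
      bf_fun(d, seeds[r])
    } else {
      if (is.null(refit)) abort("mode = 'full' requires `refit`")
      d <- refit(seeds[r])$draws
      bf_fun(d, seeds[r])
    }
  }
  vals <- numeric(0)
  failures <- 0L
  for (r in seq_len(n_repetitions)) {
    res <- tryCatch(one(r), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      next
    }
    vals <- c(vals, if (inherits(res, "bf_result")) res$bf else as.numeric(res))
  }
  if (length(vals) < 2) {
    abort("too few successful repetitions to summarize",
          class = "ordtree_value_error")
  }
  new_bf_result(
    bf = median(vals),
    comparison = "repeated",
    method = paste0("bf_repeat/", mode),
    details = list(bf_min = min(vals), bf_max = max(vals),
                   repetitions = vals, failures = failures)
  )
}

#' Individual-level encompassing Bayes factor
#'
#' Bayes factor for the hypothesis that an order constraint holds for *every
#' participant's* individual parameters, via encompassing-prior counting: the
#' posterior proportion of draws in which all participants conform, divided by
#' the Monte Carlo prior proportion of the same event under the hierarchical
#' prior (computed by sequential elimination; see
#' [prior_constraint_proportion()]).
#'
#' @param fit An `mpt_fit`.
#' @param constraint A `constraint_spec` with `level = "every_individual"`.
#' @param prior,model Default to the fit's own.
#' @param n_prior_draws Prior Monte Carlo draws (large, e.g. 1e6: the prior
#'   proportion of a joint event over a hundred-odd participants is tiny).
#' @param seed Integer seed for the prior simulation.
#' @param min_conform Reliability threshold, applied to both prior and
#'   posterior conforming counts.
#' @return A `bf_result` for "restricted (every individual) vs encompassing".
#' @export
individual_level_bf <- function(fit, constraint, prior = NULL, model = NULL,
                                n_prior_draws = 1e6, seed = 1,
                                min_conform = 10) {
  draws <- as_draws(fit)
  prior <- prior %||% fit$prior
  model <- model %||% fit$model
  if (constraint$level != "every_individual") {
    abort("constraint must have level = 'every_individual'",
          class = "ordtree_value_error")
  }
  N <- dim(draws$indiv_probit)[2]
  pp <- prior_constraint_proportion(constraint, prior, model,
                                    method = "monte_carlo",
                                    n_draws = n_prior_draws,
                                    n_participants = N, seed = seed)
  if (pp$proportion <= 0) {
    abort(paste0("no prior draws conform (n = ", n_prior_draws,
                 "); increase n_prior_draws"),
          class = "ordtree_value_error")
  }
  conform <- evaluate_constraint(constraint, draws)
  n <- length(conform)
  n_conform <- sum(conform)
  post_prop <- n_conform / n
  is_bound <- n_conform == 0
  bf <- if (is_bound) 1 / (n * pp$proportion) else post_prop / pp$proportion
  new_bf_result(
    bf = bf,
    comparison = "restricted (every individual) vs encompassing",
    method = "encompassing/monte_carlo",
    details = list(
      posterior_proportion = post_prop,
      prior_proportion = pp$proportion,
      prior_se = pp$mc_se,
      n_posterior = n, n_conform = n_conform,
      n_prior = pp$n_draws, n_prior_conform = pp$n_conform,
      reliable = n_conform >= min_conform && pp$n_conform >= min_conform,
      is_bound = is_bound,
      encompassing_id = draws_fingerprint(draws)
    )
  )
}

#' Prior-sensitivity grid for a Bayes-factor analysis
#'
#' Runs one full analysis per prior specification and tabulates the resulting
#' Bayes factors; failures are recorded per cell rather than aborting the
#' grid.
#'
#' @param priors A named list of `prior_spec` objects.
#' @param bf_fun A function `(prior) -> bf_result` (or a bare number) running
#'   the complete analysis under that prior.
#' @return A tibble with columns `prior`, `bf`, `log10_bf`, `error`.
#' @export
sensitivity_grid <- function(priors, bf_fun) {
  stopifnot(is.list(priors), length(priors) >= 1)
  nms <- names(priors) %||% paste0("prior", seq_along(priors))
  purrr::map_dfr(seq_along(priors), function(k) {
    res <- tryCatch(bf_fun(priors[[k]]), error = function(e) e)
    if (inherits(res, "error")) {
      tibble(prior = nms[k], bf = NA_real_, log10_bf = NA_real_,
             error = conditionMessage(res))
    } else {
      bf <- if (inherits(res, "bf_result")) res$bf else as.numeric(res)
      tibble(prior = nms[k], bf = bf, log10_bf = log10(bf),
             error = NA_character_)
    }
  })
}

#' Descriptive individual-level conformity with an order constraint
#'
#' For each participant, computes the per-draw differences implied by each
#' order constraint and reports whether the participant's posterior medians
#' conform to all constraints and whether the equal-tailed credible intervals
#' of all differences lie wholly on the conforming side.
#'
#' @param fit An `mpt_fit`.
#' @param constraint A `constraint_spec` (its `level` is ignored here; the
#'   evaluation is per participant by construction).
#' @param interval_mass Credible-interval mass (default 0.8).
#' @return A tibble with one row per participant: `participant`,
#'   `point_conforms`, `interval_conforms`, and for single-constraint specs
#'   the median difference `median_diff`.  The total counts are attached as
#'   attribute `"counts"` (`point`, `interval`).
#' @export
descriptive_individual_effects <- function(fit, constraint,
                                           interval_mass = 0.8) {
  draws <- as_draws(fit)
  env <- draws_env(draws, constraint$parameters, constraint$scale,
                   "every_individual")
  N <- dim(draws$indiv_probit)[2]
  a <- (1 - interval_mass) / 2
  point_ok <- rep(TRUE, N)
  int_ok <- rep(TRUE, N)
  med1 <- NULL
  for (cn in constraint$order) {
    diff <- eval(cn$lhs, env) - eval(cn$rhs, env)     # draws x participants
    med <- apply(diff, 2, median)
    lo <- apply(diff, 2, quantile, probs = a, names = FALSE)
    point_ok <- point_ok & (med > 0)
    int_ok <- int_ok & (lo > 0)
    if (length(constraint$order) == 1) med1 <- med
  }
  out <- tibble(participant = draws$participants,
                point_conforms = point_ok,
                interval_conforms = int_ok)
  if (!is.null(med1)) out$median_diff <- med1
  attr(out, "counts") <- c(point = sum(point_ok), interval = sum(int_ok))
  out
}
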