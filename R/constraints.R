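# ---------------------------------------------------------------------------
# Derived quantities and order/equality constraints over group-level or
# individual-level parameters
# ---------------------------------------------------------------------------

parse_expression <- function(s) {
  e <- tryCatch(str2lang(s), error = function(err) {
    abort(paste0("cannot parse expression '", s, "': ",
                 conditionMessage(err)), class = "ordtree_format_error")
  })
  bad <- setdiff(all.names(e), c(all.vars(e), "+", "-", "*", "/", "(", "min",
                                 "max", "abs"))
  if (length(bad)) {
    abort(paste0("unsupported symbol(s) in '", s, "': ",
                 paste(bad, collapse = ", ")), class = "ordtree_format_error")
  }
  e
}

# Split "lhs > rhs" (or "lhs < rhs", normalized) into parsed sides.
parse_inequality <- function(s) {
  if (grepl(">=|<=|==", s)) {
    abort(paste0("only strict inequalities are supported: '", s, "'"),
          class = "ordtree_format_error")
  }
  gt <- gregexpr(">", s, fixed = TRUE)[[1]]
  lt <- gregexpr("<", s, fixed = TRUE)[[1]]
  n_gt <- sum(gt > 0); n_lt <- sum(lt > 0)
  if (n_gt + n_lt != 1) {
    abort(paste0("expected exactly one '>' or '<' in '", s, "'"),
          class = "ordtree_format_error")
  }
  sides <- strsplit(s, "[<>]")[[1]]
  if (length(sides) != 2 || !nzchar(trimws(sides[1])) ||
      !nzchar(trimws(sides[2]))) {
    abort(paste0("malformed inequality '", s, "'"),
          class = "ordtree_format_error")
  }
  if (n_lt == 1) sides <- rev(sides)
  list(text = s,
       lhs = parse_expression(trimws(sides[1])),
       rhs = parse_expression(trimws(sides[2])))
}

#' Define a derived quantity over model parameters
#'
#' A named arithmetic expression over free parameters, evaluated per draw on
#' the probability scale (default) or the probit scale.  The central example
#' is a difference of two parameters, e.g. `d_B - d_A`.
#'
#' @param name A label.
#' @param expr A string expression over parameter names.
#' @param scale `"probability"` or `"probit"`.
#' @return A `derived_quantity` object.
#' @export
derived_quantity <- function(name, expr, scale = c("probability", "probit")) {
  scale <- match.arg(scale)
  e <- parse_expression(expr)
  structure(list(name = name, expr = e, text = expr, scale = scale,
                 parameters = all.vars(e)),
            class = "derived_quantity")
}

#' @export
print.derived_quantity <- function(x, ...) {
  cat("<derived_quantity ", x$name, ": ", x$text, " [", x$scale, "]>\n",
      sep = "")
  invisible(x)
}

as_quantity <- function(q, scale = "probability") {
  if (inherits(q, "derived_quantity")) return(q)
  if (is.character(q) && length(q) == 1) {
    return(derived_quantity(q, q, scale = scale))
  }
  abort("quantities must be derived_quantity objects or expression strings",
        class = "ordtree_value_error")
}

#' Specify order (and point-null) constraints on model parameters
#'
#' Order constraints are strict inequalities between expressions of free
#' parameters (e.g. `"d_B_pleasant - d_A_pleasant > 0"`, or an ordering of two
#' such differences).  The direction of every inequality is part of the
#' specification, so reversed or alternative hypotheses are expressed by
#' editing the strings, not by code changes.
#'
#' @param order Character vector of strict inequalities (`>` or `<`).
#' @param scale Scale on which expressions are evaluated: `"probability"`
#'   (default) or `"probit"`.
#' @param level `"group"`: constraints apply to group-level parameters;
#'   `"every_individual"`: they must hold for each participant's parameters
#'   jointly.
#' @return A `constraint_spec` object.
#' @export
constraint_spec <- function(order, scale = c("probability", "probit"),
                            level = c("group", "every_individual")) {
  scale <- match.arg(scale)
  level <- match.arg(level)
  if (!length(order)) abort("need at least one constraint")
  parsed <- lapply(order, parse_inequality)
  pars <- unique(unlist(lapply(parsed, function(cn) {
    c(all.vars(cn$lhs), all.vars(cn$rhs))
  })))
  # the inequality graph over expression texts must be acyclic
  edges <- lapply(parsed, function(cn) {
    c(canonical_quantity(cn$lhs), canonical_quantity(cn$rhs))
  })
  nodes <- unique(unlist(edges))
  adj <- lapply(nodes, function(n) {
    unlist(lapply(edges, function(e) if (e[1] == n) e[2]))
  })
  names(adj) <- nodes
  state <- setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  visit <- function(n) {
    if (state[[n]] == 1L) {
      abort("order constraints are cyclic (contradictory)",
            class = "ordtree_value_error")
    }
    if (state[[n]] == 2L) return(invisible())
    state[[n]] <<- 1L
    for (m in adj[[n]]) visit(m)
    state[[n]] <<- 2L
  }
  for (n in nodes) visit(n)
  structure(list(order = parsed, scale = scale, level = level,
                 parameters = pars),
            class = "constraint_spec")
}

#' @export
print.constraint_spec <- function(x, ...) {
  cat("<constraint_spec [", x$scale, ", ", x$level, "]>\n", sep = "")
  for (cn in x$order) cat("  ", cn$text, "\n", sep = "")
  invisible(x)
}

# Build an evaluation environment (a named list) from draws.  Group level:
# one numeric vector per parameter.  Individual level: one draws x
# participants matrix per parameter.
draws_env <- function(draws, parameters, scale, level) {
  miss <- setdiff(parameters, draws$parameters)
  if (length(miss)) {
    abort(paste0("constraint references unknown parameter(s): ",
                 paste(miss, collapse = ", ")), class = "ordtree_value_error")
  }
  env <- list()
  for (p in parameters) {
    k <- match(p, draws$parameters)
    env[[p]] <- if (level == "group") {
      if (scale == "probability") pnorm(draws$group_mu[, k])
      else draws$group_mu[, k]
    } else {
      m <- if (scale == "probability") draws$indiv_prob[, , k, drop = FALSE]
           else draws$indiv_probit[, , k, drop = FALSE]
      dim(m) <- dim(m)[1:2]      # keep draws x participants even when N = 1
      m
    }
  }
  env
}

#' Evaluate a constraint on a set of draws
#'
#' @param constraint A `constraint_spec`.
#' @param draws An `mpt_draws` object (prior or posterior).
#' @return A logical vector, one entry per draw: whether all constraints hold
#'   (for `level = "every_individual"`, whether they hold for every
#'   participant).  For individual-level constraints, the per-participant
#'   conformity matrix is attached as attribute `"by_participant"`.
#' @export
evaluate_constraint <- function(constraint, draws) {
  stopifnot(inherits(constraint, "constraint_spec"),
            inherits(draws, "mpt_draws"))
  env <- draws_env(draws, constraint$parameters, constraint$scale,
                   constraint$level)
  conform <- NULL
  for (cn in constraint$order) {
    ok <- eval(cn$lhs, env) > eval(cn$rhs, env)
    conform <- if (is.null(conform)) ok else conform & ok
  }
  if (constraint$level == "every_individual") {
    by_part <- conform
    all_ok <- rowSums(!by_part) == 0
    attr(all_ok, "by_participant") <- by_part
    return(all_ok)
  }
  as.vector(conform)
}

# --- analytic prior proportion ------------------------------------------------

# Classify an order constraint's difference lhs - rhs for the analytic rule.
# Returns either list(type = "sign", quantity = <canonical text>) when one
# side is zero-like, or list(type = "ordering", hi = <text>, lo = <text>).
canonical_quantity <- function(e) paste(deparse(e), collapse = " ")

is_zero_expr <- function(e) is.numeric(e) && length(e) == 1 && e == 0

# A "simple difference": a call `a - b` with a, b plain parameter names.
simple_difference <- function(e) {
  if (is.call(e) && identical(e[[1]], as.name("-")) && length(e) == 3 &&
      is.name(e[[2]]) && is.name(e[[3]])) {
    c(as.character(e[[2]]), as.character(e[[3]]))
  } else NULL
}

#' Prior probability that a constraint holds
#'
#' For order constraints that consist of sign constraints on differences of
#' parameters with exchangeable (identical, independent) group-mean priors,
#' optionally plus a complete ordering among those sign-constrained
#' differences, the prior proportion is exact by symmetry:
#' `(1/2)^(number of sign constraints) / (number of ordered quantities)!`.
#' Otherwise, or on request, the proportion is estimated by Monte Carlo with
#' a standard error; individual-level (`every_individual`) constraints are
#' always Monte Carlo, using sequential elimination of non-conforming draws
#' across participants so that later participants are only simulated for
#' still-conforming prior draws.
#'
#' @param constraint A `constraint_spec`.
#' @param prior A `prior_spec`.
#' @param model The `mpt_model` (defines the full parameter set; only the
#'   parameters the constraint references are simulated, using the exact
#'   marginal prior families of the sub-vector).
#' @param method `"analytic"` or `"monte_carlo"`.
#' @param n_draws Monte Carlo draws.
#' @param n_participants Required for `every_individual` constraints.
#' @param seed Integer seed.
#' @param chunk Monte Carlo chunk size (memory control).
#' @return A one-row tibble with columns `method`, `proportion`, `mc_se`
#'   (0 for analytic), `n_draws`, `n_conform`, `level`.
#' @export
prior_constraint_proportion <- function(constraint, prior, model,
                                        method = c("analytic", "monte_carlo"),
                                        n_draws = 1e5, n_participants = NULL,
                                        seed = 1, chunk = 1e5) {
  method <- match.arg(method)
  stopifnot(inherits(constraint, "constraint_spec"),
            inherits(prior, "prior_spec"), inherits(model, "mpt_model"))
  miss <- setdiff(constraint$parameters, model$parameters)
  if (length(miss)) {
    abort(paste0("constraint references parameter(s) not in the model: ",
                 paste(miss, collapse = ", ")), class = "ordtree_value_error")
  }
  if (method == "analytic") {
    if (constraint$level != "group") {
      abort("analytic prior proportions are only available for group-level constraints; use method = 'monte_carlo'",
            class = "ordtree_value_error")
    }
    prop <- analytic_prior_proportion(constraint, prior)
    return(tibble(method = "analytic", proportion = prop, mc_se = 0,
                  n_draws = NA_integer_, n_conform = NA_integer_,
                  level = constraint$level))
  }
  if (constraint$level == "group") {
    res <- mc_group_proportion(constraint, prior, n_draws, seed, chunk)
  } else {
    if (is.null(n_participants)) {
      abort("every_individual constraints need `n_participants`",
            class = "ordtree_value_error")
    }
    res <- mc_individual_proportion(constraint, prior, model, n_draws,
                                    n_participants, seed, chunk)
  }
  prop <- res$n_conform / res$n_draws
  tibble(method = "monte_carlo", proportion = prop,
         mc_se = sqrt(prop * (1 - prop) / res$n_draws),
         n_draws = res$n_draws, n_conform = res$n_conform,
         level = constraint$level)
}

# Exact-by-symmetry proportion; errors (with guidance) whenever the required
# structure cannot be verified.
analytic_prior_proportion <- function(constraint, prior) {
  fail <- function(why) {
    abort(paste0("analytic prior proportion unavailable: ", why,
                 "; use method = 'monte_carlo'"),
          class = "ordtree_value_error")
  }
  gm <- prior$group_mean
  sign_q <- list()     # canonical text -> parameter pair
  orderings <- list()  # list of c(hi, lo) canonical texts
  for (cn in constraint$order) {
    lhs0 <- is_zero_expr(cn$rhs)
    if (lhs0) {
      pair <- simple_difference(cn$lhs)
      if (is.null(pair)) fail(paste0("'", cn$text,
        "' is not a sign constraint on a difference of two parameters"))
      sign_q[[canonical_quantity(cn$lhs)]] <- pair
    } else {
      lq <- simple_difference(cn$lhs)
      rq <- simple_difference(cn$rhs)
      if (is.null(lq) || is.null(rq)) fail(paste0("'", cn$text,
        "' is not an ordering of two parameter differences"))
      orderings[[length(orderings) + 1]] <-
        c(canonical_quantity(cn$lhs), canonical_quantity(cn$rhs))
    }
  }
  prior_of <- function(p) {
    row <- gm[gm$parameter == p, ]
    if (!nrow(row)) fail(paste0("no prior for parameter '", p, "'"))
    unname(c(row$loc, row$scale))
  }
  # every sign-constrained difference must be of two parameters with an
  # identical independent prior (so the difference is symmetric about 0)
  for (q in names(sign_q)) {
    pr <- lapply(sign_q[[q]], prior_of)
    if (!isTRUE(all.equal(pr[[1]], pr[[2]]))) {
      fail(paste0("parameters in '", q, "' have different priors, so the ",
                  "difference is not symmetric about 0"))
    }
  }
  # all referenced parameters must be distinct (independence across
  # quantities) -- group means are independent a priori by construction
  all_pars <- unlist(sign_q)
  if (anyDuplicated(all_pars)) {
    fail("a parameter appears in more than one constrained quantity")
  }
  if (length(orderings)) {
    ord_q <- unique(unlist(orderings))
    if (!all(ord_q %in% names(sign_q))) {
      fail("ordered quantities must each also carry a sign constraint")
    }
    # exchangeability: all ordered quantities share the same prior signature
    sigs <- vapply(ord_q, function(q) {
      paste(vapply(sign_q[[q]], function(p) {
        paste(prior_of(p), collapse = ",")
      }, character(1)), collapse = ";")
    }, character(1))
    if (length(unique(sigs)) != 1) {
      fail("ordered quantities do not have exchangeable priors")
    }
    # the orderings must form one complete strict chain over ord_q
    k <- length(ord_q)
    if (length(orderings) != k - 1) {
      fail("orderings must form a single complete chain")
    }
    hi <- vapply(orderings, `[`, character(1), 1)
    lo <- vapply(orderings, `[`, character(1), 2)
    chain_top <- setdiff(ord_q, lo)
    chain_bot <- setdiff(ord_q, hi)
    if (length(chain_top) != 1 || length(chain_bot) != 1 ||
        anyDuplicated(hi) || anyDuplicated(lo)) {
      fail("orderings must form a single complete chain")
    }
    ord_factor <- factorial(k)
  } else {
    ord_factor <- 1
  }
  (1 / 2)^length(sign_q) / ord_factor
}

# --- Monte Carlo prior proportions -------------------------------------------

# Group level: group means are independent normals, so only the referenced
# parameters are drawn.
mc_group_proportion <- function(constraint, prior, n_draws, seed, chunk) {
  pars <- constraint$parameters
  gm <- prior$group_mean[match(pars, prior$group_mean$parameter), ]
  if (anyNA(gm$parameter)) {
    abort(paste0("prior is missing group-mean spec for: ",
                 paste(pars[is.na(gm$parameter)], collapse = ", ")))
  }
  n_conform <- 0L
  with_seed(seed, {
    done <- 0
    while (done < n_draws) {
      m <- min(chunk, n_draws - done)
      env <- list()
      for (k in seq_along(pars)) {
        mu <- rnorm(m, gm$loc[k], gm$scale[k])
        env[[pars[k]]] <- if (constraint$scale == "probability") pnorm(mu)
                          else mu
      }
      ok <- NULL
      for (cn in constraint$order) {
        this <- eval(cn$lhs, env) > eval(cn$rhs, env)
        ok <- if (is.null(ok)) this else ok & this
      }
      n_conform <- n_conform + sum(ok)
      done <- done + m
    }
  })
  list(n_conform = n_conform, n_draws = n_draws)
}

# Marginal prior of the covariance block for a subset of k out of P
# parameters.  LKJ(eta): the principal submatrix is LKJ(eta + (P - k) / 2).
# TreeBUGS default (precision ~ Wishart(I_P, P + 1)): the covariance is
# inverse-Wishart(I_P, P + 1) and its principal submatrix is
# inverse-Wishart(I_k, k + 1) -- the same default in dimension k; the
# expansion factors are independent Uniform(0, xi_upper) per parameter.
draw_cov_prior_subset <- function(prior, n, k, P) {
  dev <- prior$deviation
  if (dev$dist == "treebugs_default") {
    return(rtreebugs_cov(n, k, xi_upper = dev$xi_upper,
                         df = (dev$df %||% (P + 1)) - (P - k)))
  }
  sigma <- switch(dev$dist,
    gamma = matrix(rgamma(n * k, shape = dev$shape, rate = dev$rate), n, k),
    fixed = matrix(dev$value, n, k)
  )
  chol <- if (prior$correlation$dist == "lkj") {
    rlkj_chol(n, k, eta = prior$correlation$eta + (P - k) / 2)
  } else {
    L <- array(0, c(n, k, k))
    for (p in seq_len(k)) L[, p, p] <- 1
    L
  }
  list(sigma = sigma, chol = chol)
}

# Individual level ("holds for every participant"): sequential elimination.
# For each chunk of prior draws of the group-level configuration, participants
# are simulated one at a time and draws whose current participant violates the
# constraint are dropped, so the per-participant work shrinks geometrically.
# The surviving fraction is an unbiased estimate of the all-participants
# conforming probability.
mc_individual_proportion <- function(constraint, prior, model, n_draws,
                                     n_participants, seed, chunk) {
  pars <- constraint$parameters
  k <- length(pars)
  P <- length(model$parameters)
  gm <- prior$group_mean[match(pars, prior$group_mean$parameter), ]
  if (anyNA(gm$parameter)) {
    abort(paste0("prior is missing group-mean spec for: ",
                 paste(pars[is.na(gm$parameter)], collapse = ", ")))
  }
  n_conform <- 0L
  with_seed(seed, {
    done <- 0
    while (done < n_draws) {
      m <- min(chunk, n_draws - done)
      mu <- matrix(rnorm(m * k, rep(gm$loc, each = m),
                         rep(gm$scale, each = m)), m, k)
      cov <- draw_cov_prior_subset(prior, m, k, P)
      alive <- seq_len(m)
      for (i in seq_len(n_participants)) {
        na <- length(alive)
        if (!na) break
        Z <- matrix(rnorm(na * k), na, k)
        eta <- mu[alive, , drop = FALSE]
        for (p in seq_len(k)) {
          acc <- numeric(na)
          for (q in seq_len(p)) {
            lc <- cov$chol[alive, p, q]
            if (all(lc == 0)) next
            acc <- acc + Z[, q] * lc
          }
          eta[, p] <- eta[, p] + acc * cov$sigma[alive, p]
        }
        env <- list()
        for (p in seq_len(k)) {
          env[[pars[p]]] <- if (constraint$scale == "probability") {
            pnorm(eta[, p])
          } else eta[, p]
        }
        ok <- NULL
        for (cn in constraint$order) {
          this <- eval(cn$lhs, env) > eval(cn$rhs, env)
          ok <- if (is.null(ok)) this else ok & this
        }
        alive <- alive[ok]
      }
      n_conform <- n_conform + length(alive)
      done <- done + m
    }
  })
  list(n_conform = n_conform, n_draws = n_draws)
}
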