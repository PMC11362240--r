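# ---------------------------------------------------------------------------
# Posterior fitting and convergence diagnostics
# ---------------------------------------------------------------------------

#' Sample the posterior of the hierarchical latent-trait MPT model
#'
#' Runs the package's adaptive Metropolis-within-Gibbs sampler (see
#' `?mcmc_settings`) on a frequency table, targeting the joint posterior of
#' group means, deviation SDs, correlations, and individual probit-scale
#' parameters.
#'
#' @param model An `mpt_model`.
#' @param prior A `prior_spec`.
#' @param data A `freq_table`.
#' @param settings An `mcmc_settings` object.
#' @param rhat_warn Warn (and flag the fit) when the maximum split R-hat over
#'   group-level quantities exceeds this threshold.
#' @return An `mpt_fit` with posterior draws, acceptance rates, and
#'   convergence metadata.
#' @export
fit_posterior <- function(model, prior, data, settings = mcmc_smoke_profile(),
                          rhat_warn = 1.05) {
  stopifnot(inherits(model, "mpt_model"), inherits(prior, "prior_spec"),
            inherits(data, "freq_table"), inherits(settings, "mcmc_settings"))
  counts <- split_counts(data, model)
  N <- nrow(data)
  if (N < 1) abort("need at least one participant")
  chains <- lapply(seq_len(settings$chains), function(ch) {
    run_chain(model, prior, counts, settings,
              chain_seed = (settings$seed + 1000003L * ch) %% .Machine$integer.max,
              n_participants = N)
  })
  n_keep <- nrow(chains[[1]]$mu)
  P <- length(model$parameters)
  mu <- do.call(rbind, lapply(chains, `[[`, "mu"))
  sigma <- do.call(rbind, lapply(chains, `[[`, "sigma"))
  corr <- do.call(rbind, lapply(chains, `[[`, "corr"))
  eta <- array(NA_real_, c(n_keep * settings$chains, N, P))
  for (ch in seq_along(chains)) {
    eta[(ch - 1) * n_keep + seq_len(n_keep), , ] <- chains[[ch]]$eta
  }
  draws <- new_mpt_draws(model$parameters, mu, sigma, corr_chol = NULL,
                         indiv_probit = eta, provenance = "posterior",
                         seed = settings$seed,
                         participants = data$participant)
  fit <- structure(
    list(draws = draws,
         chain_id = rep(seq_len(settings$chains), each = n_keep),
         corr_lower = corr,
         model = model, prior = prior, data = data, settings = settings,
         acceptance = do.call(rbind, lapply(chains, `[[`, "acceptance")),
         convergence_warning = FALSE),
    class = "mpt_fit"
  )
  diag <- diagnostics(fit, level = "group")
  max_rhat <- suppressWarnings(max(diag$rhat, na.rm = TRUE))
  if (is.finite(max_rhat) && max_rhat > rhat_warn) {
    fit$convergence_warning <- TRUE
    warn(paste0("max split R-hat over group-level quantities is ",
                round(max_rhat, 3), " (> ", rhat_warn, ")"))
  }
  fit$max_rhat_group <- max_rhat
  fit
}

#' @export
print.mpt_fit <- function(x, ...) {
  cat("<mpt_fit: ", n_draws(x$draws), " draws (",
      x$settings$chains, " chains) x ", length(x$draws$participants),
      " participants x ", length(x$draws$parameters), " parameters>\n",
      sep = "")
  if (isTRUE(x$convergence_warning)) cat("  ! convergence warning attached\n")
  invisible(x)
}

# Split R-hat (Gelman et al.): each chain halved, rank-free version on raw
# draws.  x: iterations x chains matrix.
split_rhat <- function(x) {
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- n %/% 2
  segs <- cbind(x[seq_len(half), , drop = FALSE],
                x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(segs)
  means <- colMeans(segs)
  vars <- apply(segs, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Convergence diagnostics for a fitted model
#'
#' Split R-hat and effective sample size for sampled quantities.  With a
#' single chain R-hat is reported as `NA` with a message.
#'
#' @param fit An `mpt_fit`.
#' @param level `"group"` (group means and deviation SDs, plus correlations)
#'   or `"all"` (additionally every individual probit parameter).
#' @return A tibble with columns `quantity`, `rhat`, `ess`.
#' @export
diagnostics <- function(fit, level = c("group", "all")) {
  level <- match.arg(level)
  stopifnot(inherits(fit, "mpt_fit"))
  ch <- fit$chain_id
  chains <- sort(unique(ch))
  single <- length(chains) < 2
  if (single) {
    rlang::inform("single chain: R-hat omitted")
  }
  pars <- fit$draws$parameters
  P <- length(pars)
  series <- list()
  for (p in seq_len(P)) {
    series[[paste0("mu[", pars[p], "]")]] <- fit$draws$group_mu[, p]
  }
  has_sigma <- any(fit$draws$sigma != 0)
  if (has_sigma) {
    for (p in seq_len(P)) {
      series[[paste0("sigma[", pars[p], "]")]] <- fit$draws$sigma[, p]
    }
  }
  if (P > 1 && has_sigma && !all(is.na(fit$corr_lower))) {
    ij <- which(lower.tri(diag(P)), arr.ind = TRUE)
    for (k in seq_len(nrow(ij))) {
      series[[paste0("corr[", pars[ij[k, 1]], ",", pars[ij[k, 2]], "]")]] <-
        fit$corr_lower[, k]
    }
  }
  if (level == "all") {
    ids <- fit$draws$participants
    for (i in seq_along(ids)) for (p in seq_len(P)) {
      series[[paste0("eta[", ids[i], ",", pars[p], "]")]] <-
        fit$draws$indiv_probit[, i, p]
    }
  }
  res <- purrr::map_dfr(names(series), function(nm) {
    x <- series[[nm]]
    bychain <- vapply(chains, function(c0) list(x[ch == c0]), vector("list", 1))
    mat <- do.call(cbind, bychain)
    ess <- sum(vapply(bychain, function(v) {
      unname(coda::effectiveSize(coda::mcmc(v)))
    }, numeric(1)))
    tibble(quantity = nm,
           rhat = if (single) NA_real_ else split_rhat(mat),
           ess = min(ess, length(x)))
  })
  res
}

# --- broom-style methods -----------------------------------------------------

#' Tidy posterior summaries of group-level parameters
#'
#' @param x An `mpt_fit`.
#' @param scale `"probability"` (probit-inverse group medians per draw) or
#'   `"probit"`.
#' @param conf_level Credible-interval mass (equal-tailed).
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `estimate` (posterior median),
#'   `conf.low`, `conf.high`, `mean`, `sd`.
#' @export
tidy.mpt_fit <- function(x, scale = c("probability", "probit"),
                         conf_level = 0.95, ...) {
  scale <- match.arg(scale)
  mu <- x$draws$group_mu
  if (scale == "probability") mu <- pnorm(mu)
  a <- (1 - conf_level) / 2
  purrr::map_dfr(seq_along(x$draws$parameters), function(p) {
    v <- mu[, p]
    tibble(parameter = x$draws$parameters[p],
           estimate = median(v),
           conf.low = quantile(v, a, names = FALSE),
           conf.high = quantile(v, 1 - a, names = FALSE),
           mean = mean(v), sd = sd(v))
  })
}

#' One-row summary of a fitted model
#'
#' @param x An `mpt_fit`.
#' @param ... Unused.
#' @return A tibble with draw counts, chains, max group-level R-hat, minimum
#'   ESS, and the convergence flag.
#' @export
glance.mpt_fit <- function(x, ...) {
  d <- diagnostics(x, level = "group")
  tibble(
    n_draws = n_draws(x$draws),
    chains = x$settings$chains,
    n_participants = length(x$draws$participants),
    max_rhat = suppressWarnings(max(d$rhat, na.rm = TRUE)),
    min_ess = min(d$ess),
    convergence_warning = x$convergence_warning
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
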