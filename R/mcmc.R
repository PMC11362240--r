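# ---------------------------------------------------------------------------
# Posterior sampler for the hierarchical latent-trait MPT model
#
# Adaptive Metropolis-within-Gibbs over the unconstrained parameterization:
#   * individual probits eta_i: componentwise random-walk MH, vectorized
#     across participants (conditionally independent given group structure)
#   * group means mu: exact Gibbs draw (normal prior x MVN population model)
#   * deviation SDs: random-walk MH on the log scale (gamma prior)
#   * correlations: random-walk MH on atanh-transformed canonical partial
#     correlations of a C-vine, whose independent-beta prior is exactly the
#     LKJ distribution
#   * TreeBUGS-default covariance: conjugate Wishart Gibbs for the precision
#     matrix plus MH for the parameter-expansion factors xi ~ U(0, xi_upper)
# Step sizes adapt during warmup toward ~0.44 acceptance.
# ---------------------------------------------------------------------------

#' MCMC settings
#'
#' @param draws Post-warmup draws per chain.
#' @param warmup Warmup (adaptation) iterations per chain, discarded.
#' @param chains Number of chains.
#' @param seed Integer seed.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param target_accept Target acceptance rate for the adaptive random walks.
#' @return An `mcmc_settings` object.
#' @export
mcmc_settings <- function(draws = 50000, warmup = 10000, chains = 3,
                          seed = 1, thin = 1, target_accept = 0.44) {
  stopifnot(draws >= 1, warmup >= 0, chains >= 1, thin >= 1)
  structure(list(draws = as.integer(draws), warmup = as.integer(warmup),
                 chains = as.integer(chains), seed = as.integer(seed),
                 thin = as.integer(thin), target_accept = target_accept),
            class = "mcmc_settings")
}

#' Desk-scale MCMC profile for tests and examples
#' @param seed Integer seed.
#' @param chains Number of chains.
#' @param draws,warmup Iteration counts.
#' @return An `mcmc_settings` object.
#' @export
mcmc_smoke_profile <- function(seed = 1, chains = 2, draws = 2000,
                               warmup = 1000) {
  mcmc_settings(draws = draws, warmup = warmup, chains = chains, seed = seed)
}

# Trees affected by each free parameter (directly or through a derived
# parameter).  Returns a list: parameter name -> integer vector of trees.
param_tree_incidence <- function(model) {
  derived_vars <- lapply(model$derived, all.vars)
  tree_pars <- lapply(model$trees, function(tr) {
    nm <- unique(unlist(lapply(tr$branches, function(br) {
      vapply(Filter(function(f) f$kind == "param", br$factors),
             `[[`, character(1), "name")
    })))
    expanded <- nm
    for (dn in intersect(nm, names(derived_vars))) {
      expanded <- union(expanded, derived_vars[[dn]])
    }
    expanded
  })
  setNames(lapply(model$parameters, function(p) {
    which(vapply(tree_pars, function(tp) p %in% tp, logical(1)))
  }), model$parameters)
}

# MVN log-density of residual rows given lower-triangular chol A of Sigma.
mvn_logdens_rows <- function(resid, A) {
  v <- forwardsolve(A, t(resid))
  -0.5 * colSums(v * v) - sum(log(diag(A))) - ncol(resid) / 2 * log(2 * pi)
}

# Lower Cholesky of a correlation matrix from C-vine canonical partial
# correlations z (lower-tri P x P matrix, columns j < rows i).
vine_to_chol <- function(Zm) {
  P <- nrow(Zm)
  L <- matrix(0, P, P)
  L[1, 1] <- 1
  if (P == 1L) return(L)
  for (i in 2:P) {
    rem <- 1
    for (j in 1:(i - 1)) {
      L[i, j] <- Zm[i, j] * sqrt(rem)
      rem <- rem - L[i, j]^2
    }
    L[i, i] <- sqrt(max(rem, 1e-12))
  }
  L
}

# Robbins-Monro style step-size adaptation.
adapt_step <- function(log_step, accepted, iter, target) {
  log_step + (accepted - target) * min(0.25, 2 / sqrt(iter))
}

run_chain <- function(model, prior, counts_list, settings, chain_seed,
                      n_participants, jitter_sd = 0.1) {
  pars <- model$parameters
  P <- length(pars)
  N <- n_participants
  dev <- prior$deviation
  hierarchical <- !(dev$dist == "fixed" && all(dev$value == 0))
  treebugs <- dev$dist == "treebugs_default"
  fixed_sigma <- dev$dist == "fixed"
  use_lkj <- !treebugs && prior$correlation$dist == "lkj"
  target <- settings$target_accept
  incidence <- param_tree_incidence(model)
  gm <- prior$group_mean[match(pars, prior$group_mean$parameter), ]
  m0 <- gm$loc; s0 <- gm$scale
  n_trees <- length(model$trees)
  counts_total <- lapply(counts_list, colSums)   # non-hierarchical shortcut

  n_keep <- settings$draws %/% settings$thin
  rec_mu <- matrix(NA_real_, n_keep, P, dimnames = list(NULL, pars))
  rec_sigma <- matrix(NA_real_, n_keep, P, dimnames = list(NULL, pars))
  n_corr <- P * (P - 1) / 2
  rec_corr <- matrix(NA_real_, n_keep, max(n_corr, 1))
  rec_eta <- array(NA_real_, c(n_keep, N, P))

  with_seed(chain_seed, {
    # --- initialization (retry on non-finite density) ---
    init_ok <- FALSE
    for (attempt in 1:20) {
      mu <- m0 + rnorm(P, 0, jitter_sd)
      sigma <- switch(dev$dist,
        gamma = rep(stats::qgamma(0.5, dev$shape, dev$rate), P),
        fixed = rep(dev$value, length.out = P),
        treebugs_default = rep(1, P))
      xi <- rep(1, P)
      s_raw <- rep(1, P)
      Zm <- matrix(0, P, P)
      L <- diag(P)
      A <- diag(sigma, P) %*% L
      eta <- matrix(rep(mu, each = N), N, P) +
        if (hierarchical) matrix(rnorm(N * P, 0, jitter_sd), N, P) else 0
      theta <- pnorm(eta)
      colnames(theta) <- pars
      tree_ll <- loglik_by_tree(model, theta, counts_list)
      if (all(is.finite(tree_ll))) { init_ok <- TRUE; break }
    }
    if (!init_ok) {
      abort("could not find a finite initial density after 20 attempts",
            class = "ordtree_sampler_error")
    }
    prior_ld <- if (hierarchical) {
      mvn_logdens_rows(eta - rep(mu, each = N), A)
    } else rep(0, N)

    # adaptive step sizes (log scale)
    ls_eta <- matrix(log(0.25), N, P)
    ls_sigma <- rep(log(0.3), P)
    ls_z <- rep(log(0.3), n_corr)
    ls_xi <- rep(log(0.5), P)
    ls_mu <- rep(log(0.15), P)
    ls_resc <- rep(log(0.3), P)
    acc_count <- c(eta = 0, mu = 0, sigma = 0, corr = 0, xi = 0, rescale = 0)
    prop_count <- c(eta = 0, mu = 0, sigma = 0, corr = 0, xi = 0, rescale = 0)

    vine_cols <- which(lower.tri(Zm), arr.ind = TRUE)  # (row i, col j) pairs
    lkj_eta <- if (use_lkj) prior$correlation$eta else 1

    total_iter <- settings$warmup + settings$draws
    keep_i <- 0L
    for (iter in seq_len(total_iter)) {
      adapting <- iter <= settings$warmup

      if (hierarchical) {
        # --- individual probits, componentwise over parameters ---
        for (p in seq_len(P)) {
          step <- exp(ls_eta[, p])
          prop_col <- eta[, p] + step * rnorm(N)
          theta_prop <- theta
          theta_prop[, p] <- pnorm(prop_col)
          idx <- incidence[[p]]
          ll_new <- loglik_by_tree(model, theta_prop, counts_list, idx)
          eta_prop <- eta
          eta_prop[, p] <- prop_col
          pld_new <- mvn_logdens_rows(eta_prop - rep(mu, each = N), A)
          logr <- rowSums(ll_new) - rowSums(tree_ll[, idx, drop = FALSE]) +
            pld_new - prior_ld
          acc <- log(runif(N)) < logr
          if (any(acc)) {
            eta[acc, p] <- prop_col[acc]
            theta[acc, p] <- theta_prop[acc, p]
            tree_ll[acc, idx] <- ll_new[acc, , drop = FALSE]
            prior_ld[acc] <- pld_new[acc]
          }
          if (adapting) ls_eta[, p] <- adapt_step(ls_eta[, p], acc, iter, target)
          acc_count["eta"] <- acc_count["eta"] + sum(acc)
          prop_count["eta"] <- prop_count["eta"] + N
        }

        # --- group means: exact Gibbs ---
        Sig_inv <- chol2inv(chol(tcrossprod(A)))
        prec <- diag(1 / s0^2, P) + N * Sig_inv
        b <- m0 / s0^2 + Sig_inv %*% colSums(eta)
        cp <- chol(prec)
        mu <- drop(backsolve(cp, backsolve(cp, b, transpose = TRUE)) +
                     backsolve(cp, rnorm(P)))
        prior_ld <- mvn_logdens_rows(eta - rep(mu, each = N), A)
        acc_count["mu"] <- acc_count["mu"] + 1
        prop_count["mu"] <- prop_count["mu"] + 1

        # --- covariance structure ---
        if (treebugs) {
          df0 <- dev$df %||% (P + 1)
          resid <- eta - rep(mu, each = N)
          draw <- sweep(resid, 2, xi, "/")
          S <- crossprod(draw)
          Tprec <- rWishart(1, df = df0 + N, Sigma = chol2inv(chol(diag(P) + S)))[, , 1]
          Q <- chol2inv(chol(Tprec))
          s_raw <- sqrt(diag(Q))
          R <- Q / tcrossprod(s_raw)
          L <- t(chol(R))
          sigma <- xi * s_raw
          A <- diag(sigma, P) %*% L
          prior_ld <- mvn_logdens_rows(resid, A)
          # parameter-expansion factors
          for (p in seq_len(P)) {
            xp <- xi[p] + exp(ls_xi[p]) * rnorm(1)
            okp <- xp > 0 && xp < dev$xi_upper
            if (okp) {
              xi_new <- xi; xi_new[p] <- xp
              sigma_new <- xi_new * s_raw
              A_new <- diag(sigma_new, P) %*% L
              pld_new <- mvn_logdens_rows(resid, A_new)
              acc1 <- log(runif(1)) < sum(pld_new) - sum(prior_ld)
            } else acc1 <- FALSE
            if (acc1) {
              xi <- xi_new; sigma <- sigma_new; A <- A_new; prior_ld <- pld_new
            }
            if (adapting) ls_xi[p] <- adapt_step(ls_xi[p], acc1, iter, target)
            acc_count["xi"] <- acc_count["xi"] + acc1
            prop_count["xi"] <- prop_count["xi"] + 1
          }
        } else {
          resid <- eta - rep(mu, each = N)
          if (!fixed_sigma) {
            for (p in seq_len(P)) {
              lsp <- log(sigma[p]) + exp(ls_sigma[p]) * rnorm(1)
              sp <- exp(lsp)
              sigma_new <- sigma; sigma_new[p] <- sp
              A_new <- diag(sigma_new, P) %*% L
              pld_new <- mvn_logdens_rows(resid, A_new)
              logr <- sum(pld_new) - sum(prior_ld) +
                dgamma(sp, dev$shape, dev$rate, log = TRUE) -
                dgamma(sigma[p], dev$shape, dev$rate, log = TRUE) +
                lsp - log(sigma[p])   # Jacobian of the log transform
              acc1 <- is.finite(logr) && log(runif(1)) < logr
              if (acc1) { sigma <- sigma_new; A <- A_new; prior_ld <- pld_new }
              if (adapting) ls_sigma[p] <- adapt_step(ls_sigma[p], acc1, iter,
                                                      target)
              acc_count["sigma"] <- acc_count["sigma"] + acc1
              prop_count["sigma"] <- prop_count["sigma"] + 1
            }
          }
          if (use_lkj && n_corr > 0) {
            for (k in seq_len(n_corr)) {
              i <- vine_cols[k, 1]; j <- vine_cols[k, 2]
              bpar <- lkj_eta + (P - 1 - j) / 2
              w <- atanh(Zm[i, j]) + exp(ls_z[k]) * rnorm(1)
              znew <- tanh(w)
              Zm_new <- Zm; Zm_new[i, j] <- znew
              L_new <- vine_to_chol(Zm_new)
              A_new <- diag(sigma, P) %*% L_new
              pld_new <- mvn_logdens_rows(resid, A_new)
              logr <- sum(pld_new) - sum(prior_ld) +
                dbeta((znew + 1) / 2, bpar, bpar, log = TRUE) -
                dbeta((Zm[i, j] + 1) / 2, bpar, bpar, log = TRUE) +
                log1p(-znew^2) - log1p(-Zm[i, j]^2)   # atanh Jacobian
              acc1 <- is.finite(logr) && log(runif(1)) < logr
              if (acc1) { Zm <- Zm_new; L <- L_new; A <- A_new; prior_ld <- pld_new }
              if (adapting) ls_z[k] <- adapt_step(ls_z[k], acc1, iter, target)
              acc_count["corr"] <- acc_count["corr"] + acc1
              prop_count["corr"] <- prop_count["corr"] + 1
            }
          }
        }
        # --- non-centered rescale: jointly scale sigma_p (or xi_p) and the
        #     participant deviations in coordinate p; fixes the slow mixing
        #     of hierarchy scales under the centered parameterization.
        if (!fixed_sigma) {
          for (p in seq_len(P)) {
            cmul <- exp(exp(ls_resc[p]) * rnorm(1))
            ok <- if (treebugs) {
              xi[p] * cmul > 0 && xi[p] * cmul < dev$xi_upper
            } else TRUE
            acc1 <- FALSE
            if (ok) {
              eta_col <- mu[p] + cmul * (eta[, p] - mu[p])
              theta_prop <- theta
              theta_prop[, p] <- pnorm(eta_col)
              idx <- incidence[[p]]
              ll_new <- loglik_by_tree(model, theta_prop, counts_list, idx)
              logr <- sum(ll_new) - sum(tree_ll[, idx, drop = FALSE]) +
                log(cmul) +
                if (treebugs) 0 else {
                  dgamma(cmul * sigma[p], dev$shape, dev$rate, log = TRUE) -
                    dgamma(sigma[p], dev$shape, dev$rate, log = TRUE)
                }
              acc1 <- is.finite(logr) && log(runif(1)) < logr
              if (acc1) {
                eta[, p] <- eta_col
                theta[, p] <- theta_prop[, p]
                tree_ll[, idx] <- ll_new
                if (treebugs) xi[p] <- xi[p] * cmul
                sigma[p] <- sigma[p] * cmul
                A <- diag(sigma, P) %*% L
                # quadratic form is invariant; only the log-determinant moves
                prior_ld <- prior_ld - log(cmul)
              }
            }
            if (adapting) ls_resc[p] <- adapt_step(ls_resc[p], acc1, iter,
                                                   target)
            acc_count["rescale"] <- acc_count["rescale"] + acc1
            prop_count["rescale"] <- prop_count["rescale"] + 1
          }
        }
      } else {
        # --- no hierarchy: theta identical across participants ---
        for (p in seq_len(P)) {
          mp <- mu
          mp[p] <- mu[p] + exp(ls_mu[p]) * rnorm(1)
          th_new <- matrix(pnorm(mp), 1, P, dimnames = list(NULL, pars))
          probs <- compute_tree_probs(model, th_new)
          ll_new <- sum(vapply(seq_len(n_trees), function(t) {
            pv <- probs[[t]][1, ]
            nv <- counts_total[[t]]
            if (any(nv > 0 & pv <= 0)) return(-Inf)
            sum(ifelse(nv > 0, nv * log(pv), 0))
          }, numeric(1)))
          ll_old <- sum(tree_ll)
          logr <- ll_new - ll_old +
            dnorm(mp[p], m0[p], s0[p], log = TRUE) -
            dnorm(mu[p], m0[p], s0[p], log = TRUE)
          acc1 <- is.finite(logr) && log(runif(1)) < logr
          if (acc1) {
            mu <- mp
            theta <- matrix(rep(pnorm(mu), each = N), N, P,
                            dimnames = list(NULL, pars))
            tree_ll <- loglik_by_tree(model, theta, counts_list)
            eta <- matrix(rep(mu, each = N), N, P)
          }
          if (adapting) ls_mu[p] <- adapt_step(ls_mu[p], acc1, iter, target)
          acc_count["mu"] <- acc_count["mu"] + acc1
          prop_count["mu"] <- prop_count["mu"] + 1
        }
      }

      # --- record ---
      if (!adapting) {
        k <- iter - settings$warmup
        if (k %% settings$thin == 0L) {
          keep_i <- keep_i + 1L
          rec_mu[keep_i, ] <- mu
          rec_sigma[keep_i, ] <- sigma
          if (n_corr > 0) {
            R <- tcrossprod(L)
            rec_corr[keep_i, ] <- R[lower.tri(R)]
          }
          rec_eta[keep_i, , ] <- eta
        }
      }
    }
    list(mu = rec_mu, sigma = rec_sigma, corr = rec_corr, eta = rec_eta,
         acceptance = ifelse(prop_count > 0, acc_count / prop_count, NA_real_))
  })
}
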