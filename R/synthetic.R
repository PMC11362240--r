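# ---------------------------------------------------------------------------
# Synthetic source-monitoring datasets from the hierarchical model
# ---------------------------------------------------------------------------

#' Define a study design
#'
#' @param items A data frame with columns `tree` and `items` (items presented
#'   per tree per participant), or a named numeric vector.
#' @param n_participants Number of participants.
#' @param conditions Optional condition labels (bookkeeping).
#' @return A `study_design` object.
#' @export
study_design <- function(items, n_participants, conditions = NULL) {
  if (!is.data.frame(items)) {
    items <- tibble(tree = names(items), items = as.integer(items))
  }
  items <- as_tibble(items)
  stopifnot(all(c("tree", "items") %in% names(items)),
            all(items$items >= 0), n_participants >= 1)
  structure(list(design = items, n_participants = as.integer(n_participants),
                 conditions = conditions),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design: ", x$n_participants, " participants, ",
      sum(x$design$items), " trials each>\n", sep = "")
  print(x$design)
  invisible(x)
}

#' The Bell-style source-monitoring design
#'
#' Two within-subject face conditions; per condition each participant studies
#' 10 source-A and 10 source-B face--behavior pairs and is tested on 20 new
#' faces (the 40 new items of the test phase split evenly across conditions,
#' configurable), for 80 trials per participant in total.
#'
#' @param n_participants Number of participants (138 in the first experiment,
#'   114 in the second).
#' @param condition_labels Two condition labels matching
#'   [build_2htsm_bell()].
#' @param new_split Integer vector: new items assigned to each condition.
#' @return A `study_design` whose trees match `build_2htsm_bell()`.
#' @export
bell_design <- function(n_participants = 138,
                        condition_labels = c("pleasant", "disgusting"),
                        new_split = c(20L, 20L)) {
  stopifnot(length(condition_labels) == 2, length(new_split) == 2)
  items <- tibble(
    tree = c(paste0("sourceA_", condition_labels),
             paste0("sourceB_", condition_labels),
             paste0("new_", condition_labels)),
    items = c(10L, 10L, 10L, 10L, as.integer(new_split))
  )
  study_design(items, n_participants, conditions = condition_labels)
}

#' Generate a synthetic dataset from the hierarchical model
#'
#' Draws per-participant parameters around fixed group-level values (or around
#' a draw from a prior) and samples multinomial response counts per tree.
#'
#' @param model An `mpt_model`.
#' @param design A `study_design` whose trees match the model.
#' @param truth Either a list with elements `group_prob` (named
#'   probability-scale group-level medians for every free parameter), `sigma`
#'   (probit-scale deviation SD, scalar or named vector; 0 gives identical
#'   participants), and optionally `corr` (correlation matrix, default
#'   identity) -- or a `prior_spec` from which one group-level configuration
#'   is drawn.
#' @param seed Integer seed.
#' @return A list with elements `data` (a `freq_table`), `truth` (a tibble
#'   with per-parameter probit mean, probability-scale median, and deviation
#'   SD), and `theta` (the realized participant-level probability-scale
#'   parameters).
#' @export
generate_dataset <- function(model, design, truth, seed = 1) {
  stopifnot(inherits(model, "mpt_model"), inherits(design, "study_design"))
  pars <- model$parameters
  P <- length(pars)
  tree_names <- vapply(model$trees, `[[`, character(1), "name")
  if (!setequal(design$design$tree, tree_names)) {
    abort("design trees do not match the model's trees",
          class = "ordtree_value_error")
  }
  N <- design$n_participants
  with_seed(seed, {
    if (inherits(truth, "prior_spec")) {
      one <- draw_prior(truth, model, n_participants = 1, n_draws = 1,
                        seed = sample.int(.Machine$integer.max, 1))
      mu <- one$group_mu[1, ]
      sigma <- one$sigma[1, ]
      L <- one$corr_chol[1, , ]
    } else {
      miss <- setdiff(pars, names(truth$group_prob))
      if (length(miss)) {
        abort(paste0("truth$group_prob missing: ", paste(miss, collapse = ", ")))
      }
      gp <- truth$group_prob[pars]
      mu <- ifelse(gp <= 0, -Inf, ifelse(gp >= 1, Inf, qnorm(gp)))
      sigma <- rep(truth$sigma %||% 0, length.out = P)
      if (!is.null(names(truth$sigma))) sigma <- truth$sigma[pars]
      corr <- truth$corr %||% diag(P)
      L <- t(chol(corr))
    }
    finite_mu <- ifelse(is.finite(mu), mu, 0)
    Z <- matrix(rnorm(N * P), N, P)
    delta <- (Z %*% t(L)) * rep(sigma, each = N)
    eta <- delta + rep(finite_mu, each = N)
    theta <- pnorm(eta)
    # degenerate group values (0/1 on the probability scale) stay degenerate
    for (p in seq_len(P)) {
      if (!is.finite(mu[p])) theta[, p] <- if (mu[p] > 0) 1 else 0
    }
    colnames(theta) <- pars
    probs <- compute_tree_probs(model, theta)
    items <- design$design$items[match(tree_names, design$design$tree)]
    counts <- vector("list", length(tree_names))
    for (t in seq_along(tree_names)) {
      pm <- probs[[t]]
      m <- matrix(0L, N, ncol(pm))
      if (items[t] > 0) {
        for (i in seq_len(N)) {
          m[i, ] <- rmultinom(1, items[t], pm[i, ])
        }
      }
      colnames(m) <- paste0(tree_names[t], ":", colnames(pm))
      counts[[t]] <- m
    }
    data <- freq_table(do.call(cbind, counts),
                       design = tibble(tree = tree_names, items = items))
    truth_tbl <- tibble(parameter = pars, mu = unname(mu),
                        prob = pnorm(unname(mu)), sigma = unname(sigma))
    list(data = data, truth = truth_tbl, theta = theta)
  })
}

#' Truth defaults for demonstrations
#'
#' Illustrative group-level values of roughly the magnitudes seen in empirical
#' source-monitoring work (moderate item memory, low-to-moderate source
#' memory, guessing biased per condition); not ground truth for any study.
#'
#' @param model An `mpt_model` built by [build_2htsm()] or
#'   [build_2htsm_bell()].
#' @return A truth list suitable for [generate_dataset()].
#' @export
demo_truth <- function(model) {
  pars <- model$parameters
  base <- c(D = 0.5, d = 0.3, b = 0.5, g = 0.5,
            D_A = 0.5, D_B = 0.55, d_A = 0.45, d_B = 0.1)
  lead <- sub("_(pleasant|disgusting)$", "", pars)
  gp <- base[lead]
  gp[lead == "g" & grepl("pleasant$", pars)] <- 0.35
  gp[lead == "g" & grepl("disgusting$", pars)] <- 0.65
  names(gp) <- pars
  list(group_prob = gp, sigma = 0.4, corr = diag(length(pars)))
}

#' Per-parameter recovery of group-level truth
#'
#' @param fit An `mpt_fit` obtained on a generated dataset.
#' @param truth The `truth` tibble returned by [generate_dataset()].
#' @param conf_level Credible-interval mass.
#' @return A tibble with per-parameter columns `truth`, `estimate`
#'   (probability-scale posterior median), `error`, `conf.low`, `conf.high`,
#'   `covered`.
#' @export
recovery_report <- function(fit, truth, conf_level = 0.95) {
  est <- tidy(fit, scale = "probability", conf_level = conf_level)
  tr <- truth[match(est$parameter, truth$parameter), ]
  tibble(
    parameter = est$parameter,
    truth = tr$prob,
    estimate = est$estimate,
    error = est$estimate - tr$prob,
    conf.low = est$conf.low,
    conf.high = est$conf.high,
    covered = tr$prob >= est$conf.low & tr$prob <= est$conf.high
  )
}

#' Aggregate recovery reports across simulated datasets
#'
#' @param reports A list of tibbles from [recovery_report()].
#' @return A tibble with per-parameter `bias`, `rmse`, and `coverage`
#'   (`rmse >= |bias|` holds by construction).
#' @export
recovery_summary <- function(reports) {
  all <- dplyr::bind_rows(reports)
  dplyr::summarise(
    dplyr::group_by(all, .data$parameter),
    bias = mean(.data$error),
    rmse = sqrt(mean(.data$error^2)),
    coverage = mean(.data$covered),
    .groups = "drop"
  )
}
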