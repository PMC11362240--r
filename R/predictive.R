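# ---------------------------------------------------------------------------
# Prior / posterior predictive simulation and fit statistics
# ---------------------------------------------------------------------------

#' Simulate predictive response frequencies
#'
#' For each retained parameter draw, simulates per-participant multinomial
#' counts from the individual-level parameters, yielding replicated frequency
#' tables (the machinery behind prior-predictive response-rate checks and
#' posterior-predictive re-description of observed data).
#'
#' @param draws An `mpt_draws` object (prior or posterior).
#' @param model The `mpt_model` the draws belong to.
#' @param design A `study_design`; its participant count must equal the
#'   participant dimension of `draws`.
#' @param seed Integer seed.
#' @param n_rep Number of replicates; draws are thinned by stride to this
#'   count (default: all draws).
#' @return A `predictive_sample`: counts array (`rep` x participant x
#'   tree:category cell), matching per-draw category probabilities, the
#'   generating draw indices, and the design.
#' @export
predictive_simulate <- function(draws, model, design, seed = 1, n_rep = NULL) {
  stopifnot(inherits(draws, "mpt_draws"), inherits(design, "study_design"))
  tree_names <- vapply(model$trees, `[[`, character(1), "name")
  if (!setequal(design$design$tree, tree_names)) {
    abort("design trees do not match the model's trees",
          class = "ordtree_value_error")
  }
  N <- dim(draws$indiv_prob)[2]
  if (N != design$n_participants) {
    abort(paste0("draws hold ", N, " participants but the design expects ",
                 design$n_participants), class = "ordtree_value_error")
  }
  D <- n_draws(draws)
  idx <- if (is.null(n_rep) || n_rep >= D) seq_len(D) else {
    round(seq(1, D, length.out = n_rep))
  }
  items <- design$design$items[match(tree_names, design$design$tree)]
  cats <- unlist(lapply(model$trees, function(tr) {
    paste0(tr$name, ":", tr$categories)
  }))
  K <- length(cats)
  counts <- array(0L, c(length(idx), N, K), dimnames = list(NULL, NULL, cats))
  probs <- array(NA_real_, c(length(idx), N, K),
                 dimnames = list(NULL, NULL, cats))
  with_seed(seed, {
    for (r in seq_along(idx)) {
      th <- draws$indiv_prob[idx[r], , , drop = FALSE]
      th <- matrix(th, N, length(draws$parameters),
                   dimnames = list(NULL, draws$parameters))
      pl <- compute_tree_probs(model, th)
      col0 <- 0L
      for (t in seq_along(tree_names)) {
        pm <- pl[[t]]
        nc <- ncol(pm)
        probs[r, , col0 + seq_len(nc)] <- pm
        if (items[t] > 0) {
          for (i in seq_len(N)) {
            counts[r, i, col0 + seq_len(nc)] <- rmultinom(1, items[t], pm[i, ])
          }
        }
        col0 <- col0 + nc
      }
    }
  })
  structure(
    list(counts = counts, probs = probs, draw_idx = idx, design = design,
         model_trees = tree_names, categories = cats,
         participants = draws$participants, provenance = draws$provenance),
    class = "predictive_sample"
  )
}

#' @export
print.predictive_sample <- function(x, ...) {
  d <- dim(x$counts)
  cat("<predictive_sample (", x$provenance, "): ", d[1], " replicates x ",
      d[2], " participants x ", d[3], " cells>\n", sep = "")
  invisible(x)
}

#' Per-draw predicted response probabilities for one category
#'
#' @param pred A `predictive_sample`.
#' @param tree,category Tree and category labels.
#' @return A tibble with columns `rep`, `participant`, `prob`, `count`.
#' @export
response_rate_draws <- function(pred, tree, category) {
  cell <- paste0(tree, ":", category)
  if (!cell %in% pred$categories) {
    abort(paste0("unknown tree/category '", cell, "'"),
          class = "ordtree_value_error")
  }
  d <- dim(pred$counts)
  tibble(
    rep = rep(seq_len(d[1]), times = d[2]),
    participant = rep(pred$participants, each = d[1]),
    prob = as.vector(pred$probs[, , cell]),
    count = as.vector(pred$counts[, , cell])
  )
}

#' Summary of predicted response probabilities for one category
#'
#' @inheritParams response_rate_draws
#' @param probs Quantile probabilities.
#' @return A one-row tibble with mean, SD, and the requested quantiles of the
#'   per-draw individual response probability.
#' @export
response_rate_summary <- function(pred, tree, category,
                                  probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  rr <- response_rate_draws(pred, tree, category)
  if (!nrow(rr)) abort("empty predictive sample", class = "ordtree_value_error")
  q <- quantile(rr$prob, probs, names = FALSE)
  out <- tibble(tree = tree, category = category,
                mean = mean(rr$prob), sd = sd(rr$prob))
  for (k in seq_along(probs)) out[[paste0("q", probs[k])]] <- q[k]
  out
}

# --- T1 / T2 posterior-predictive checks -------------------------------------

# Pearson-type discrepancy between a count matrix (participants x cells) and
# the per-participant expected counts implied by one parameter draw.
t1_discrepancy <- function(counts, expected) {
  mo <- colMeans(counts)
  me <- colMeans(expected)
  ok <- me > 1e-12
  sum((mo[ok] - me[ok])^2 / me[ok])
}

# Analogous discrepancy on the across-participant covariance of counts.
# Expected covariance = covariance of expected counts across participants
# plus the mean within-participant multinomial covariance.
t2_discrepancy <- function(counts, expected, mult_cov) {
  S <- cov(counts)
  C <- cov(expected) + mult_cov
  dd <- sqrt(pmax(diag(C), 0))
  scale <- tcrossprod(dd)
  ok <- scale > 1e-12
  lt <- lower.tri(C, diag = TRUE) & ok
  sum(((S - C)[lt])^2 / scale[lt])
}

#' Posterior-predictive p values for mean and covariance structure (T1, T2)
#'
#' Compares the observed mean category frequencies (T1) and the observed
#' across-participant covariances of category frequencies (T2) with data
#' replicated from the joint posterior: for each retained draw a replicate
#' dataset is simulated from that draw's individual parameters, the
#' discrepancy of observed and replicated data from the draw's expectation is
#' computed, and the p value is the fraction of replicates whose discrepancy
#' is at least the observed one (ties count as exceeding).
#'
#' @param fit An `mpt_fit`.
#' @param data The observed `freq_table` (defaults to the fitted data).
#' @param n_rep Number of replicates (posterior draws thinned by stride).
#' @param seed Integer seed.
#' @return A tibble with columns `statistic` (`"T1"`, `"T2"`), `p_value`,
#'   `n_rep`.  With a single participant T2 is undefined and flagged `NA`.
#' @export
t1_t2 <- function(fit, data = fit$data, n_rep = 1000, seed = 1) {
  stopifnot(inherits(fit, "mpt_fit"), n_rep >= 100)
  model <- fit$model
  design <- study_design(freq_design(data), n_participants = nrow(data))
  pred <- predictive_simulate(fit$draws, model, design, seed = seed,
                              n_rep = n_rep)
  obs <- as.matrix(data[, pred$categories, drop = FALSE])
  N <- nrow(obs)
  items <- design$design$items[match(pred$model_trees, design$design$tree)]
  R <- length(pred$draw_idx)
  t1o <- t1r <- numeric(R)
  t2o <- t2r <- numeric(R)
  single <- N < 2
  K <- length(pred$categories)
  tree_of <- rep(seq_along(model$trees),
                 times = vapply(model$trees, function(tr) length(tr$categories),
                                integer(1)))
  for (r in seq_len(R)) {
    p <- pred$probs[r, , , drop = FALSE]
    p <- matrix(p, N, K)
    expected <- sweep(p, 2, items[tree_of], "*")
    repl <- matrix(pred$counts[r, , , drop = FALSE], N, K)
    t1o[r] <- t1_discrepancy(obs, expected)
    t1r[r] <- t1_discrepancy(repl, expected)
    if (!single) {
      mc <- matrix(0, K, K)
      for (t in seq_along(model$trees)) {
        cols <- which(tree_of == t)
        if (items[t] == 0) next
        pm <- p[, cols, drop = FALSE]
        # mean over participants of items * (diag(p) - p p')
        cross <- crossprod(pm) / N
        block <- items[t] * (diag(colMeans(pm), length(cols)) - cross)
        mc[cols, cols] <- block
      }
      t2o[r] <- t2_discrepancy(obs, expected, mc)
      t2r[r] <- t2_discrepancy(repl, expected, mc)
    }
  }
  p1 <- mean(t1r >= t1o)
  p2 <- if (single) NA_real_ else mean(t2r >= t2o)
  if (single) warn("single participant: T2 undefined")
  tibble(statistic = c("T1", "T2"), p_value = c(p1, p2), n_rep = R)
}
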