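# ---------------------------------------------------------------------------
# Multinomial likelihood of a frequency table under an MPT model
# ---------------------------------------------------------------------------

# Multinomial log-coefficients per participant per tree: log(N! / prod n_k!)
log_multinom_const <- function(counts_list) {
  Reduce(`+`, lapply(counts_list, function(m) {
    lgamma(rowSums(m) + 1) - rowSums(lgamma(m + 1))
  }))
}

# Per-tree multinomial log-mass (without coefficient) for an N x P theta
# matrix; returns N x n_trees matrix.  A positive count on a zero-probability
# category yields -Inf.
loglik_by_tree <- function(model, theta, counts_list, tree_idx = NULL) {
  idx <- tree_idx %||% seq_along(model$trees)
  probs <- compute_tree_probs(model, theta, idx)
  out <- matrix(0, nrow(theta), length(idx))
  for (k in seq_along(idx)) {
    p <- probs[[k]]
    n <- counts_list[[idx[k]]]
    ll <- rowSums(ifelse(n > 0, n * log(p), 0))
    ll[apply(n > 0 & p <= 0, 1, any)] <- -Inf
    out[, k] <- ll
  }
  out
}

#' Per-participant multinomial log-likelihood
#'
#' Sums, over trees, the multinomial log-mass of each participant's observed
#' category counts at that participant's parameter values (aggregated over
#' items, i.e. assuming item homogeneity).
#'
#' @param model An `mpt_model`.
#' @param theta_individual A named numeric vector (shared by all
#'   participants), or a matrix / data frame with one row per participant and
#'   one column per free parameter.
#' @param data A `freq_table` whose columns match the model's trees.
#' @return A tibble with columns `participant` and `loglik`.  Counts in
#'   zero-probability categories yield `-Inf`.
#' @export
log_likelihood <- function(model, theta_individual, data) {
  counts <- split_counts(data, model)
  n <- nrow(data)
  th <- theta_individual
  if (is.data.frame(th)) th <- as.matrix(th)
  if (is.null(dim(th))) {
    th <- matrix(rep(th, each = n), nrow = n,
                 dimnames = list(NULL, names(theta_individual)))
  }
  if (nrow(th) != n) {
    abort("theta_individual must have one row per participant",
          class = "ordtree_value_error")
  }
  ll <- rowSums(loglik_by_tree(model, th, counts)) + log_multinom_const(counts)
  tibble(participant = data$participant, loglik = ll)
}
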