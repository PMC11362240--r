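# Shared fixtures.  Heavier objects are built lazily and cached for the
# duration of the test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

toy_binomial_model <- function() {
  fixture("toy_binomial", function() parse_eqn("old hit p\nold miss (1-p)"))
}

toy_binomial_prior <- function() {
  prior_spec(tibble::tibble(parameter = "p", loc = 0, scale = 1),
             deviation = list(dist = "fixed", value = 0),
             correlation = list(dist = "identity"))
}

# Exact conjugate posterior draws for the toy: uniform prior on p, `hits`
# successes in `trials` -> Beta(hits + 1, trials - hits + 1), injected as an
# mpt_draws object.
toy_conjugate_draws <- function(hits, trials, n = 1e5, seed = 1) {
  p <- ordtree:::with_seed(seed, rbeta(n, hits + 1, trials - hits + 1))
  mu <- matrix(qnorm(p), n, 1, dimnames = list(NULL, "p"))
  ordtree:::new_mpt_draws("p", mu, sigma = matrix(0, n, 1),
                          corr_chol = NULL,
                          indiv_probit = array(mu, c(n, 1, 1)),
                          provenance = "posterior", seed = seed)
}

# Inject arbitrary group-level draws for a model (sigma 0, one participant).
inject_group_draws <- function(model, mu) {
  n <- nrow(mu)
  P <- length(model$parameters)
  stopifnot(ncol(mu) == P)
  colnames(mu) <- model$parameters
  eta <- array(mu, c(n, 1, P))
  ordtree:::new_mpt_draws(model$parameters, mu, sigma = matrix(0, n, P),
                          corr_chol = NULL, indiv_probit = eta,
                          provenance = "posterior", seed = 0)
}

smoke_design <- function(n_participants = 100) {
  study_design(c(sourceA = 20L, sourceB = 20L, new = 40L), n_participants)
}

smoke_truth <- function() {
  list(group_prob = c(D = 0.6, d = 0.4, b = 0.5, g = 0.45), sigma = 0.4)
}

# One cached hierarchical fit on the packaged smoke configuration, reused by
# the inference / predictive / BF unit tests.
smoke_fit <- function() {
  fixture("smoke_fit", function() {
    model <- build_2htsm()
    gen <- generate_dataset(model, smoke_design(60), smoke_truth(), seed = 5)
    suppressWarnings(fit_posterior(
      model, informative_preset(model), gen$data,
      settings = mcmc_settings(draws = 5000, warmup = 2000, chains = 2,
                               seed = 5, thin = 1)
    ))
  })
}

smoke_gen <- function() {
  fixture("smoke_gen", function() {
    generate_dataset(build_2htsm(), smoke_design(60), smoke_truth(), seed = 5)
  })
}
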