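# Independent brute-force likelihood oracle: R's own distribution functions
# plus a direct mixture for the zero-inflated negative binomial. Kept apart
# from the package's lgamma-based implementation on purpose.
oracle_nll <- function(x, family, mu, theta = NULL, pi_ = NULL, var_ = NULL) {
  ll <- switch(family,
    gaussian = dnorm(x, mean = mu, sd = sqrt(var_), log = TRUE),
    poisson = dpois(x, lambda = mu, log = TRUE),
    zinb = {
      nb <- dnbinom(x, size = theta, mu = mu)
      log(pi_ * (x == 0) + (1 - pi_) * nb)
    })
  -sum(ll)
}

# one randomized small likelihood case per draw; returns the absolute error
# between the package NLL and the oracle
likelihood_case_error <- function() {
  family <- sample(c("gaussian", "poisson", "zinb"), 1)
  m <- sample(1:6, 1)
  mu <- runif(m, 0.05, 20)
  theta <- runif(m, 0.3, 10)
  var_ <- runif(m, 0.2, 4)
  s <- runif(m, -3, 3)
  x <- switch(family,
              gaussian = rnorm(m, mu, 1),
              poisson = rpois(m, mu),
              zinb = {
                z <- rnbinom(m, size = theta, mu = mu)
                z[runif(m) < plogis(s)] <- 0
                z
              })
  dist <- expression_distribution(
    family, mean = matrix(mu, 1),
    dispersion = if (family == "zinb") theta else if (family == "gaussian") var_ else NULL,
    zero_inflation_logit = if (family == "zinb") matrix(s, 1) else NULL)
  abs(nll(x, dist) -
        oracle_nll(x, family, mu, theta = theta, pi_ = plogis(s), var_ = var_))
}

# ---------------------------------------------------------------------------
# full-scale study fixtures for the acceptance checks: the default synthetic
# conditions (2000 cells x 200 features, zinb) with one held-out
# (cell type, dose) combination, shared across acceptance blocks

accept_sim <- function() memo("accept_sim", function() {
  simulate_cells(synthetic_config(seed = 11L))
})

accept_split <- function() memo("accept_split", function() {
  split_dataset(accept_sim()$dataset,
                held_out = list(cell_type = "typeB", dose = 1), match = "all")
})

accept_spec <- function(lambda = 0.1) {
  latent_spec(n_latent_attr = 16L, n_latent_u = 16L,
              encoder_depth = 2L, encoder_width = 32L,
              decoder_depth = 2L, decoder_width = 64L,
              sigma = 1, lambda = lambda, tau = 1, family = "zinb")
}

accept_model <- function() memo("accept_model", function() {
  disentangle(accept_split()$train, accept_spec(), epochs = 150L,
              batch_size = 256L, seed = 3L)
})
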