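# Shared fixtures, built lazily once per test run and memoised so several
# test files can reuse the same trained model without repeating the fit.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small synthetic study: 300 cells x 40 features, two categorical
# attributes and one binary dose, clear planted effects
small_plan <- function() {
  list(
    synthetic_attribute("cell_type", "categorical",
                        categories = c("typeA", "typeB"), targets = 1:8,
                        effect_range = c(0.8, 1.2)),
    synthetic_attribute("status", "categorical",
                        categories = c("control", "perturbed"), targets = 9:16,
                        effect_range = c(0.8, 1.2)),
    synthetic_attribute("dose", "ordered", values = c(0, 1), targets = 17:24,
                        effect_range = c(0.8, 1.2))
  )
}

small_config <- function(seed = 101L, n = 300L, family = "zinb") {
  synthetic_config(n = n, m_features = 40L, attributes = small_plan(),
                   nuisance_dim = 2L, nuisance_scale = 0.15,
                   library_meanlog = log(1500), family = family, seed = seed)
}

small_sim <- function() memo("small_sim", function() simulate_cells(small_config()))

small_spec <- function(lambda = 0.1, sigma = 1) {
  latent_spec(n_latent_attr = 8L, n_latent_u = 8L,
              encoder_depth = 1L, encoder_width = 16L,
              decoder_depth = 2L, decoder_width = 32L,
              sigma = sigma, lambda = lambda, tau = 1, family = "zinb")
}

small_model <- function() {
  memo("small_model", function() {
    disentangle(small_sim()$dataset, small_spec(), epochs = 80L,
                batch_size = 128L, seed = 7L)
  })
}

# semi-supervised variant: half the status labels masked
small_masked <- function() {
  memo("small_masked", function() {
    mask_labels(small_sim()$dataset, "status", 0.5, seed = 5L)
  })
}

small_semisup_model <- function() {
  memo("small_semisup_model", function() {
    disentangle_semisupervised(small_masked()$dataset, small_spec(),
                               epochs = 80L, batch_size = 128L, seed = 7L,
                               classifier_width = 32L)
  })
}

# tiny fully-specified dataset for data-model unit tests
tiny_schema <- function() {
  attribute_schema(cat_attr("type", c("typeA", "typeB")), ord_attr("dose", 1L))
}

tiny_dataset <- function(n = 10L, m = 4L, seed = 1L) {
  set.seed(seed)
  x <- matrix(rpois(n * m, 5), n, m,
              dimnames = list(paste0("c", seq_len(n)), paste0("g", seq_len(m))))
  attrs <- data.frame(cell_id = rownames(x),
                      type = rep(c("typeA", "typeB"), length.out = n),
                      dose = rep(c(0, 0.5), length.out = n))
  cell_dataset(x, attrs, tiny_schema(), "raw_counts")
}
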