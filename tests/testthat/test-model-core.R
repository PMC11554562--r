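test_that("categorical codes are shared within a label and distinct across trained labels", {
  model <- small_model()
  two <- embed_categorical(model, "cell_type", c("typeA", "typeA"))
  expect_identical(two[1, ], two[2, ], ignore_attr = TRUE)
  ab <- embed_categorical(model, "cell_type", c("typeA", "typeB"))
  expect_gt(sum((ab[1, ] - ab[2, ])^2), 0)
  expect_error(embed_categorical(model, "cell_type", "unknown-line"),
               "unknown label.*cell_type|cell_type.*unknown-line")
})

test_that("ordered codes are deterministic and reject non-finite features", {
  model <- small_model()
  a <- embed_ordered(model, "dose", 0.3)
  b <- embed_ordered(model, "dose", 0.3)
  expect_identical(a, b)
  expect_error(embed_ordered(model, "dose", NaN), "non-finite")
})

test_that("a zero-depth ordered encoder is an affine map", {
  sim <- small_sim()
  spec <- latent_spec(n_latent_attr = 4L, n_latent_u = 4L,
                      encoder_depth = 0L, encoder_width = 8L,
                      decoder_depth = 1L, decoder_width = 16L,
                      sigma = 0, family = "zinb")
  m <- disentangle(sim$dataset, spec, epochs = 2L, seed = 1L)
  f <- function(v) embed_ordered(m, "dose", v)
  # affine: f(a) + f(b) - f(0) == f(a + b)
  expect_equal(f(0.2) + f(0.5) - f(0), f(0.7), tolerance = 1e-10)
})

test_that("the unknown code is returned exactly at evaluation and noised in training mode", {
  model <- small_model()
  id <- model$cell_ids[5]
  stored <- model$par$Zu[5, ]
  expect_identical(drop(embed_unknown(model, id)), stored, ignore_attr = TRUE)

  # Monte-Carlo check of the noise law eta ~ N(0, sigma^2 I)
  set.seed(31)
  draws <- t(replicate(10000, drop(embed_unknown(model, id, training_mode = TRUE))))
  expect_true(all(abs(colMeans(draws) - stored) < 3 / sqrt(10000) * 1.3))
  expect_true(all(abs(apply(draws, 2, sd) - model$spec$sigma) < 0.05 * model$spec$sigma))
})

test_that("sigma = 0 disables training noise entirely", {
  sim <- small_sim()
  m <- disentangle(sim$dataset, small_spec(sigma = 0), epochs = 2L, seed = 1L)
  expect_identical(drop(embed_unknown(m, m$cell_ids[1], training_mode = TRUE)),
                   m$par$Zu[1, ], ignore_attr = TRUE)
})

test_that("the generator is deterministic, positive for counts, and depends on z_u", {
  model <- small_model()
  lat <- latentsplit:::training_latent(model, 1:2)
  d1 <- generate_expression(model, lat, model$library_size[1:2])
  d2 <- generate_expression(model, lat, model$library_size[1:2])
  expect_identical(d1$mean, d2$mean)
  expect_true(all(d1$mean > 0))

  # swapping z_u changes the output iff the codes differ
  lat_swap <- lat
  lat_swap$z_u <- lat$z_u[2:1, , drop = FALSE]
  d3 <- generate_expression(model, lat_swap, model$library_size[1:2])
  expect_gt(max(abs(d3$mean - d1$mean)), 0)
  lat_same <- latentsplit:::training_latent(model, c(1L, 1L))
  d4 <- generate_expression(model, lat_same, model$library_size[c(1, 1)])
  expect_identical(d4$mean[1, ], d4$mean[2, ])
})

test_that("generation demands a complete set of attribute codes", {
  model <- small_model()
  lat <- latentsplit:::training_latent(model, 1:2)
  lat$z_y$dose <- NULL
  expect_error(generate_expression(model, lat, model$library_size[1:2]), "dose")
})

test_that("completeness loss reduces to the NLL at tau = 0 and adds the stated MSE", {
  g <- expression_distribution("gaussian", mean = matrix(c(1, 1), 1),
                               dispersion = c(1, 1))
  x <- c(1, 3)
  expect_equal(completeness_loss(x, g, tau = 0), nll(x, g))
  # gaussian MSE is on raw values, averaged over features: (0 + 4) / 2 = 2
  expect_equal(completeness_loss(x, g, tau = 2), nll(x, g) + 4)
  expect_equal(completeness_loss(c(1, 1), g, tau = 5), nll(c(1, 1), g))
})

test_that("the minimality penalty is lambda times the squared norm", {
  expect_equal(minimality_loss(c(0, 0), lambda = 3), 0)
  expect_equal(minimality_loss(c(1, 1), lambda = 0.5), 1)
  expect_equal(minimality_loss(rnorm(8), lambda = 0), 0)
})

test_that("training reduces the loss and is bit-reproducible given the seed", {
  model <- small_model()
  log <- model$training_log
  expect_lt(log$total[nrow(log)], log$total[1])
  m2 <- disentangle(small_sim()$dataset, small_spec(), epochs = 80L,
                    batch_size = 128L, seed = 7L)
  expect_identical(m2$par, model$par)
  expect_identical(m2$training_log, model$training_log)
})

test_that("plain training refuses partially labeled data", {
  mk <- small_masked()
  expect_error(disentangle(mk$dataset, small_spec(), epochs = 2L), "missing")
})

test_that("a stronger minimality penalty shrinks the unknown codes", {
  sim <- small_sim()
  norms <- vapply(c(0, 10), function(lam) {
    m <- disentangle(sim$dataset, small_spec(lambda = lam), epochs = 40L,
                     batch_size = 128L, seed = 7L)
    median(sqrt(rowSums(m$par$Zu^2)))
  }, numeric(1))
  expect_lt(norms[2], norms[1])
})

test_that("refitting recovers a cell's unknown code to at least the stored optimum", {
  model <- small_model()
  idx <- 3L
  x <- model$x[idx, ]
  tab <- latentsplit:::attribute_table_model(model)
  vals <- list(cell_type = tab$cell_type[idx], status = tab$status[idx],
               dose = tab$dose[idx])

  loss_at <- function(z) {
    lat <- latentsplit:::training_latent(model, idx)
    lat$z_u <- matrix(z, 1)
    d <- generate_expression(model, lat, model$library_size[idx])
    completeness_loss(x, d, tau = model$spec$tau) +
      minimality_loss(z, model$spec$lambda)
  }

  # a training cell's own data: the refit must do at least as well as the
  # stored embedding
  z_hat <- fit_new_cell_embedding(model, x, vals)
  expect_lte(attr(z_hat, "loss"), loss_at(model$par$Zu[idx, ]) + 1e-3)

  # self-consistency: data generated by the model itself from a known code
  set.seed(17)
  lat <- latentsplit:::training_latent(model, idx)
  d <- generate_expression(model, lat, model$library_size[idx])
  x_gen <- drop(sample_expression(d))
  z_hat2 <- fit_new_cell_embedding(model, x_gen, vals)
  lat2 <- lat; lat2$z_u <- matrix(z_hat2, 1)
  d2 <- generate_expression(model, lat2, model$library_size[idx])
  loss_star <- completeness_loss(x_gen, d, tau = model$spec$tau) +
    minimality_loss(lat$z_u, model$spec$lambda)
  loss_hat <- completeness_loss(x_gen, d2, tau = model$spec$tau) +
    minimality_loss(z_hat2, model$spec$lambda)
  expect_lte(loss_hat, loss_star + 1e-3)

  # penalty-dominated limit: an enormous lambda pins the code at zero
  model_big <- model
  model_big$spec$lambda <- 1e6
  z0 <- fit_new_cell_embedding(model_big, x, vals)
  expect_lt(sqrt(sum(z0^2)), 1e-2)

  # unseen cells must be directed to the refit entry point
  expect_error(embed_unknown(model, "no-such-cell"), "fit_new_cell_embedding")
})
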