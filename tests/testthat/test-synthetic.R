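test_that("generation is bit-identical given the seed and respects family support", {
  cfg <- small_config(seed = 9L, n = 100L)
  a <- simulate_cells(cfg)
  b <- simulate_cells(cfg)
  expect_identical(a$dataset$x, b$dataset$x)
  expect_identical(a$ground_truth$effects, b$ground_truth$effects)
  expect_true(all(a$dataset$x >= 0))
  expect_true(all(a$dataset$x == round(a$dataset$x)))

  g <- simulate_cells(small_config(seed = 9L, n = 50L, family = "gaussian"))
  expect_identical(g$dataset$layer_kind, "log_normalized")
})

test_that("empirical means match the planted expected expression at large n", {
  cfg <- synthetic_config(n = 4000L, m_features = 120L, attributes = list(
    synthetic_attribute("grp", "categorical", categories = c("A", "B"),
                        targets = 1:10, effects = rbind(A = rep(0, 10),
                                                        B = rep(log(2), 10)))),
    nuisance_dim = 0L, library_sdlog = 0, family = "poisson", seed = 21L)
  sim <- simulate_cells(cfg)
  x <- sim$dataset$x
  expected <- sim$ground_truth$expected
  grp <- attribute_table(sim$dataset)$grp
  for (g in c("A", "B")) {
    emp <- colMeans(x[grp == g, ])
    want <- colMeans(expected[grp == g, ])
    keep <- want > 1            # well-expressed features only
    expect_true(all(abs(emp[keep] / want[keep] - 1) < 0.05))
  }
  # the planted 2x effect shows up as roughly doubled class-B means on the
  # target features, shrunk slightly by the compositional renormalization
  ratio <- colMeans(x[grp == "B", 1:10]) / colMeans(x[grp == "A", 1:10])
  ratio_true <- colMeans(expected[grp == "B", 1:10]) /
    colMeans(expected[grp == "A", 1:10])
  expect_true(all(abs(ratio / ratio_true - 1) < 0.05))
  expect_true(all(ratio_true > 1.7 & ratio_true < 2.0))
})

test_that("a zero-effect attribute carries no predictive signal", {
  skip_if_not_installed("class")
  accs <- sapply(1:5, function(r) {
    cfg <- synthetic_config(n = 400L, m_features = 30L, attributes = list(
      synthetic_attribute("null_grp", "categorical", categories = c("A", "B"),
                          targets = 1:5, effects = matrix(0, 2, 5))),
      nuisance_dim = 0L, family = "poisson", seed = 100L + r)
    sim <- simulate_cells(cfg)
    lab <- attribute_table(sim$dataset)$null_grp
    xin <- log1p(sim$dataset$x)
    tr <- 1:200; te <- 201:400
    pred <- class::knn(xin[tr, ], xin[te, ], cl = lab[tr], k = 15)
    mean(pred == lab[te])
  })
  # accuracy should match the majority frequency up to Monte-Carlo error
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * max(se, 0.02))
})

test_that("label masking hits the exact count and preserves observed labels", {
  ds <- small_sim()$dataset
  n <- nrow(ds$x)
  mk <- mask_labels(ds, "status", 0.5, seed = 4L)
  expect_length(mk$masked, floor(0.5 * n))
  expect_true(all(is.na(mk$dataset$attribute_values$status[mk$masked])))
  keep <- setdiff(seq_len(n), mk$masked)
  expect_identical(mk$dataset$attribute_values$status[keep],
                   ds$attribute_values$status[keep])

  mk0 <- mask_labels(ds, "status", 0, seed = 4L)
  expect_identical(mk0$dataset$attribute_values, ds$attribute_values)
  expect_length(mk0$masked, 0L)
})

test_that("stratified masking preserves class proportions within one cell", {
  ds <- small_sim()$dataset
  mk <- mask_labels(ds, "cell_type", 0.4, seed = 6L, stratified = TRUE)
  truth <- attribute_table(ds)$cell_type
  for (cl in unique(truth)) {
    expected <- sum(truth == cl) * 0.4
    got <- sum(truth[mk$masked] == cl)
    expect_lte(abs(got - expected), 1)
  }
})

test_that("degenerate generator configurations are rejected", {
  expect_error(synthetic_attribute("bad", "categorical", categories = character(0),
                                   targets = 1:2), ">= 1 category")
  expect_error(synthetic_config(m_features = 10L, attributes = list(
    synthetic_attribute("a", "categorical", categories = c("x", "y"),
                        targets = 5:15))), "outside")
})

test_that("ground truth round-trips through its JSON sidecar", {
  sim <- simulate_cells(small_config(seed = 2L, n = 40L))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$ground_truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$baseline, sim$ground_truth$baseline, tolerance = 1e-12)
  expect_equal(back$labels$cell_id, sim$ground_truth$labels$cell_id)
  expect_equal(unname(unlist(back$effects$dose)),
               unname(sim$ground_truth$effects$dose), tolerance = 1e-12)
})
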