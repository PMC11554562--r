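test_that("an empty manipulation reproduces the reconstruction bit-exactly", {
  model <- small_model()
  cf <- counterfactual_predict(model, 1:20, manipulations = list())
  rec <- reconstruct(model, 1:20)
  expect_identical(cf$mean, expected_value(rec))
  expect_false(cf$noise_applied)
})

test_that("counterfactuals are cell-specific and reject unseen categories", {
  model <- small_model()
  tab <- latentsplit:::attribute_table_model(model)
  same <- which(tab$cell_type == "typeA" & tab$status == "control" &
                  tab$dose == 0)[1:2]
  cf <- counterfactual_predict(model, same, list(status = "perturbed"))
  expect_gt(max(abs(cf$mean[1, ] - cf$mean[2, ])), 0)
  expect_error(counterfactual_predict(model, same, list(status = "exposed")),
               "exposed")
  # only manipulated attributes differ between original and target records
  expect_identical(cf$original$cell_type, cf$target$cell_type)
  expect_identical(cf$original$dose, cf$target$dose)
  expect_true(all(cf$target$status == "perturbed"))
})

test_that("flipping a planted attribute moves its target features preferentially", {
  model <- small_model()
  sim <- small_sim()
  tab <- latentsplit:::attribute_table_model(model)
  ref <- which(tab$status == "control")
  cf <- counterfactual_predict(model, ref, list(status = "perturbed"))
  base <- expected_value(reconstruct(model, ref))
  delta <- colMeans(abs(cf$mean - base))
  targets <- planted_targets(sim$ground_truth, "status")
  expect_gt(mean(delta[targets]) / mean(delta[-targets]), 3)

  # the predicted shift carries the sign of the planted effect
  eff <- sim$ground_truth$effects$status["perturbed", targets]
  shift <- colMeans(cf$mean - base)[targets]
  expect_gt(cor(sign(eff), sign(shift)), 0.8)
})

test_that("the additive composite rule sums single-manipulation shifts", {
  model <- small_model()
  base <- expected_value(reconstruct(model, 1:5))
  one <- counterfactual_predict(model, 1:5, list(dose = 0.4))
  two <- counterfactual_predict(model, 1:5, list(dose = 0.7))
  both <- counterfactual_predict(model, 1:5, list(dose = list(0.4, 0.7)),
                                 additive = TRUE)
  expect_equal(both$mean, base + (one$mean - base) + (two$mean - base),
               tolerance = 1e-12)
})

test_that("the r2 / nmse harness matches hand-worked sums of squares", {
  truth <- matrix(c(2, 4, 6, 1, 3), 1)          # one truth cell, 5 features
  pred_mat <- matrix(c(2.5, 3.5, 5, 1.5, 3.5), 1)
  ctrl <- matrix(c(1, 1, 1, 1, 1), 1)
  fake <- structure(list(cell_ids = "r1", mean = pred_mat, x_original = ctrl,
                         feature_names = paste0("g", 1:5),
                         manipulated = "status", family = "zinb",
                         noise_applied = FALSE),
                    class = "counterfactual_result")
  ev <- evaluate_counterfactuals(fake, truth)
  tm <- mean(truth)
  expect_equal(ev$r2_mean_profile,
               1 - sum((truth - pred_mat)^2) / sum((truth - tm)^2),
               tolerance = 1e-12)
  expect_equal(ev$nmse, sum((pred_mat - truth)^2) / sum((ctrl - truth)^2),
               tolerance = 1e-12)

  # anchors: predicting the truth scores perfectly; predicting the control
  # (no perturbation effect) scores nmse = 1 by construction
  fake$mean <- truth
  ev2 <- evaluate_counterfactuals(fake, truth)
  expect_equal(ev2$r2_mean_profile, 1)
  expect_equal(ev2$nmse, 0)
  fake$mean <- ctrl
  ev3 <- evaluate_counterfactuals(fake, truth)
  expect_equal(ev3$nmse, 1)
})

make_cf <- function(cf_mean, x_orig, features = paste0("g", seq_len(ncol(cf_mean)))) {
  structure(list(cell_ids = as.character(seq_len(nrow(cf_mean))),
                 mean = cf_mean, x_original = x_orig, feature_names = features,
                 manipulated = "status", family = "gaussian",
                 noise_applied = FALSE),
            class = "counterfactual_result")
}

test_that("the paired test matches the closed form and t.test", {
  # differences (1, 2, 3): t = 2 / (1 / sqrt(3)), p from t with df = 2
  x <- matrix(0, 3, 1)
  cf <- make_cf(matrix(c(1, 2, 3), 3, 1), x)
  tab <- associate_features(counterfactual = cf)
  expect_equal(tab$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(tab$p_value, 2 * pt(-sqrt(12), df = 2), tolerance = 1e-10)
  expect_equal(tab$p_value, 0.07418, tolerance = 1e-4)
  expect_equal(tab$direction, "up")

  # randomized cross-check against stats::t.test, paired
  set.seed(123)
  n <- 15; m <- 8
  orig <- matrix(rnorm(n * m), n, m)
  cfm <- orig + matrix(rnorm(n * m, sd = 0.7), n, m)
  tab2 <- associate_features(counterfactual = make_cf(cfm, orig))
  tab2 <- tab2[order(tab2$feature), ]
  for (j in seq_len(m)) {
    tt <- t.test(cfm[, j], orig[, j], paired = TRUE)
    expect_equal(tab2$statistic[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tab2$p_value[j], tt$p.value, tolerance = 1e-10)
  }
  expect_equal(tab2$p_adjusted, p.adjust(tab2$p_value, "BH"), tolerance = 1e-12)
})

test_that("constant paired differences are flagged with p = 1", {
  orig <- matrix(rnorm(10), 5, 2)
  cfm <- orig
  cfm[, 2] <- cfm[, 2] + rnorm(5)
  tab <- associate_features(counterfactual = make_cf(cfm, orig))
  g1 <- tab[tab$feature == "g1", ]
  expect_true(g1$constant)
  expect_equal(g1$p_value, 1)
  expect_equal(g1$p_adjusted, 1)
  expect_true(is.na(g1$statistic))
  expect_error(associate_features(counterfactual = make_cf(cfm[1, , drop = FALSE],
                                                           orig[1, , drop = FALSE])),
               "2 pairs")
})

test_that("BH keeps the empirical false discovery proportion near the nominal level", {
  set.seed(2024)
  reps <- 20; n <- 40; m <- 500
  fdp <- replicate(reps, {
    orig <- matrix(rnorm(n * m), n, m)
    cfm <- orig + matrix(rnorm(n * m), n, m)      # pure null differences
    tab <- associate_features(counterfactual = make_cf(cfm, orig), alpha = 0.05)
    mean(tab$significant)
  })
  mc_se <- sd(fdp) / sqrt(reps)
  expect_lte(mean(fdp), 0.05 + 3 * max(mc_se, 1e-4))

  # planted effects must outrank null features by adjusted p
  orig <- matrix(rnorm(n * m), n, m)
  shift <- matrix(rnorm(n * m), n, m)
  shift[, 1:25] <- shift[, 1:25] + 1.5
  tab <- associate_features(counterfactual = make_cf(orig + shift, orig))
  top <- tab$feature[seq_len(25)]
  expect_gte(sum(top %in% paste0("g", 1:25)), 23)
})

test_that("the k-NN uncertainty follows the factored entropy formula", {
  # homogeneous neighborhood: entropy 0, uncertainty 0
  emb <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), ncol = 1)
  u <- knn_uncertainty(emb, c("a", "a", "a", "b", "b", "b"), k = 2,
                       standardize = FALSE)
  expect_true(all(u$uncertainty == 0))

  # hand-computed case: k = 2, both neighbors at distance e^2, labels split
  D <- matrix(exp(2), 3, 3); diag(D) <- 0
  u2 <- knn_uncertainty(D, c("a", "b", "a"), k = 2, distance = "precomputed")
  expect_equal(u2$uncertainty[1], log(2), tolerance = 1e-12)

  expect_error(knn_uncertainty(emb, rep("a", 6), k = 0), "k must")
  expect_error(knn_uncertainty(emb, rep("a", 6), k = 6), "k must")
  expect_warning(knn_uncertainty(rbind(emb, emb[1, , drop = FALSE]),
                                 rep(c("a", "b"), length.out = 7), k = 2,
                                 standardize = FALSE),
                 "distance 0")
})

test_that("the uncertainty matches an exhaustive brute-force implementation", {
  brute <- function(D, cov, k, clamp = 1 + 1e-6) {
    n <- nrow(D)
    sapply(seq_len(n), function(i) {
      others <- setdiff(seq_len(n), i)
      nb <- others[order(D[i, others])][seq_len(k)]
      counts <- table(cov[nb])
      p <- counts / sum(counts)
      H <- -sum(p * log(p))
      s <- 0
      for (j in nb) s <- s + 1 / log(max(D[i, j], clamp))
      s * H
    })
  }
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    emb <- matrix(rnorm(n * 3), n, 3)
    cov <- sample(letters[1:3], n, replace = TRUE)
    k <- sample(2:(n - 1), 1)
    D <- as.matrix(dist(emb))
    got <- knn_uncertainty(D, cov, k, distance = "precomputed")
    expect_equal(got$uncertainty, brute(D, cov, k), tolerance = 1e-12)
  }
})

test_that("latent export has the declared shape and recovers planted structure", {
  model <- small_model()
  ex <- export_latent(model, "cell_type")
  expect_equal(dim(ex), c(2L, 1L + model$spec$n_latent_attr))
  expect_identical(ex, export_latent(model, "cell_type"))
  exu <- export_latent(model, "unknown")
  expect_equal(nrow(exu), length(model$cell_ids))
  exd <- export_latent(model, "dose", features = c(0, 0.5, 1))
  expect_equal(nrow(exd), 3L)
  expect_error(export_latent(model, "nope"), "unknown attribute")

  # a dataset planted with two alike classes and one distinct class is
  # exported with the alike pair closest in latent space
  eff <- rbind(tA = rep(0, 8), tB = rep(0.1, 8), tC = rep(1.5, 8))
  cfg <- synthetic_config(n = 300L, m_features = 40L, attributes = list(
    synthetic_attribute("ct", "categorical", categories = c("tA", "tB", "tC"),
                        targets = 1:8, effects = eff)), nuisance_dim = 2L,
    library_meanlog = log(1500), seed = 77L)
  sim2 <- simulate_cells(cfg)
  m <- disentangle(sim2$dataset,
                   latent_spec(n_latent_attr = 8L, n_latent_u = 8L,
                               encoder_width = 16L, decoder_width = 32L,
                               family = "zinb"),
                   epochs = 60L, batch_size = 128L, seed = 7L)
  ex3 <- export_latent(m, "ct")
  Z <- as.matrix(ex3[, -1])
  d_ab <- sqrt(sum((Z[1, ] - Z[2, ])^2))
  d_ac <- sqrt(sum((Z[1, ] - Z[3, ])^2))
  d_bc <- sqrt(sum((Z[2, ] - Z[3, ])^2))
  expect_lt(d_ab, d_ac)
  expect_lt(d_ab, d_bc)
})
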