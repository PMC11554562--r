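#' Counterfactual prediction
#'
#' Predicts the expression of reference cells under manipulated known
#' attributes: each cell keeps its trained unknown code and unmanipulated
#' attribute codes exactly, while manipulated attributes use the target
#' value's embedding. The generator runs with noise disabled, so every
#' change in the prediction is attributable to the manipulation. An empty
#' manipulation reproduces the model's reconstruction bit-exactly.
#'
#' Categorical targets must be schema categories seen in training;
#' generalization to unseen values is only possible for ordered attributes,
#' whose encoder extrapolates by construction.
#'
#' With `additive = TRUE` and a list of component values for one ordered
#' attribute, the predicted shift is the sum of the shifts of each
#' single-component manipulation (the additive composite-perturbation rule);
#' only predicted means are available in that mode.
#'
#' @param model A fitted `latentsplit_model`.
#' @param reference Training-cell ids or indices (default: all).
#' @param manipulations Named list, attribute -> target value (a category
#'   label, or a numeric vector of the attribute's dimension). For the
#'   additive mode, a list of such numeric vectors for a single ordered
#'   attribute.
#' @param additive Use the additive composite rule (see above).
#' @return An object of class `counterfactual_result` with elements
#'   `cell_ids`, `original` / `target` attribute records, the predicted
#'   expression distribution (`dist`), predicted means (`mean`, the
#'   distribution's expected value), the observed expression of the
#'   reference cells (`x_original`) and `noise_applied = FALSE`.
#' @export
counterfactual_predict <- function(model, reference = NULL,
                                   manipulations = list(), additive = FALSE) {
  idx <- resolve_cells(model, reference)
  if (length(manipulations) > 0L && is.null(names(manipulations))) {
    stop("manipulations must be a named list keyed by attribute name")
  }
  for (nm in names(manipulations)) schema_attr(model$schema, nm)  # existence
  lib <- if (!is.null(model$library_size)) model$library_size[idx] else NULL

  build <- function(manip) {
    latent <- training_latent(model, idx)
    for (nm in names(manip)) {
      a <- schema_attr(model$schema, nm)
      v <- manip[[nm]]
      code <- if (a$kind == "categorical") {
        embed_categorical(model, nm, as.character(v))
      } else {
        embed_ordered(model, nm, as.numeric(v))
      }
      latent$z_y[[nm]] <- code[rep(1L, length(idx)), , drop = FALSE]
    }
    latent
  }

  if (additive) {
    comp_attr <- names(manipulations)
    if (length(comp_attr) != 1L ||
        schema_attr(model$schema, comp_attr)$kind != "ordered" ||
        !is.list(manipulations[[1L]])) {
      stop("additive mode expects a single ordered attribute mapped to a list of component values")
    }
    base_mean <- expected_value(reconstruct(model, idx))
    total <- base_mean
    for (v in manipulations[[1L]]) {
      one <- generate_expression(model, build(stats::setNames(list(v), comp_attr)), lib)
      total <- total + (expected_value(one) - base_mean)
    }
    dist <- NULL
    mean_pred <- total
  } else {
    dist <- generate_expression(model, build(manipulations), lib)
    mean_pred <- expected_value(dist)
  }

  orig <- attribute_table_model(model)[idx, , drop = FALSE]
  target <- orig
  for (nm in names(manipulations)) {
    a <- schema_attr(model$schema, nm)
    v <- manipulations[[nm]]
    if (a$kind == "categorical") {
      target[[nm]] <- as.character(v)
    } else if (!additive) {
      v <- as.numeric(v)
      if (a$dim == 1L) target[[nm]] <- v
      else for (j in seq_len(a$dim)) target[[paste0(nm, "_", j)]] <- v[j]
    }
  }
  structure(
    list(cell_ids = model$cell_ids[idx], original = orig, target = target,
         manipulated = names(manipulations),
         dist = dist, mean = mean_pred,
         x_original = model$x[idx, , drop = FALSE],
         feature_names = model$feature_names,
         family = model$spec$family, noise_applied = FALSE,
         additive = additive),
    class = "counterfactual_result"
  )
}

attribute_table_model <- function(model) {
  fake <- structure(
    list(x = model$x, cell_ids = model$cell_ids,
         feature_names = model$feature_names,
         attribute_values = model$labels, schema = model$schema,
         layer_kind = model$layer_kind),
    class = "cell_dataset")
  attribute_table(fake)
}

#' @export
print.counterfactual_result <- function(x, ...) {
  cat("<counterfactual_result> ", length(x$cell_ids), " reference cells, ",
      ncol(x$mean), " features\n", sep = "")
  cat("  manipulated: ",
      if (length(x$manipulated) > 0) paste(x$manipulated, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

r2_score <- function(truth, pred) {
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((truth - pred)^2) / ss_tot
}

#' Score counterfactual predictions against held-out measurements
#'
#' `r2_mean_profile` is the coefficient of determination between the mean
#' predicted expression profile and the mean observed profile of real cells
#' in the target condition, over all features — the convention used in
#' perturbation-response benchmarking. `nmse` is the mean squared error of
#' the prediction normalized by the error of predicting no perturbation
#' effect (the control profile), so predicting "no change" scores exactly 1.
#' The naive control baseline (control profile scored against the truth) is
#' always reported alongside.
#'
#' @param pred A [counterfactual_predict()] result.
#' @param truth A [cell_dataset()] of real cells measured in the target
#'   condition (>= 1 cell).
#' @param control Control profile source: a [cell_dataset()], a matrix, or
#'   `NULL` to use the reference cells' observed expression.
#' @param per_cell Also compute the mean per-cell r2 of predictions against
#'   the truth profile.
#' @return A one-row tibble with `r2_mean_profile`, `r2_naive`, `nmse`,
#'   `n_reference` and `n_truth` (plus `r2_per_cell` when requested).
#' @export
evaluate_counterfactuals <- function(pred, truth, control = NULL,
                                     per_cell = FALSE) {
  stopifnot(inherits(pred, "counterfactual_result"))
  truth_x <- if (inherits(truth, "cell_dataset")) truth$x else as.matrix(truth)
  if (nrow(truth_x) < 1L) stop("need at least one truth cell")
  control_x <- if (is.null(control)) {
    pred$x_original
  } else if (inherits(control, "cell_dataset")) control$x else as.matrix(control)

  pred_profile <- colMeans(pred$mean)
  truth_profile <- colMeans(truth_x)
  control_profile <- colMeans(control_x)

  r2 <- r2_score(truth_profile, pred_profile)
  r2_naive <- r2_score(truth_profile, control_profile)
  if (is.na(r2)) {
    warning("truth profile has zero variance; r2 is undefined")
  }
  mse_pred <- mean((pred_profile - truth_profile)^2)
  mse_ctrl <- mean((control_profile - truth_profile)^2)
  nmse <- if (mse_ctrl > 0) mse_pred / mse_ctrl else NA_real_

  out <- tibble::tibble(
    r2_mean_profile = r2, r2_naive = r2_naive, nmse = nmse,
    n_reference = length(pred$cell_ids), n_truth = nrow(truth_x))
  if (per_cell) {
    out$r2_per_cell <- mean(apply(pred$mean, 1L, function(p) r2_score(truth_profile, p)))
  }
  out
}

#' Associate features with a state via paired t tests
#'
#' Pairs each reference cell's observed expression with its own
#' counterfactual prediction and runs a dependent (paired) two-sided t test
#' per feature on the differences `counterfactual - original`, followed by
#' Benjamini-Hochberg adjustment across all features. Features whose paired
#' differences have zero variance are flagged and assigned p = 1. The
#' returned table is ranked (ascending adjusted p, then descending absolute
#' statistic) and directly exportable as a ranked list for external
#' enrichment tools.
#'
#' @param original Observed expression of the reference cells: a
#'   [cell_dataset()], a matrix aligned row-by-row with the counterfactual,
#'   or `NULL` to use the observations stored in the result.
#' @param counterfactual A [counterfactual_predict()] result.
#' @param alpha FDR level used for the `significant` flag.
#' @return A tibble with `feature`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`, `mean_diff`, `direction`, `constant` and `significant`.
#' @export
associate_features <- function(original = NULL, counterfactual, alpha = 0.05) {
  stopifnot(inherits(counterfactual, "counterfactual_result"))
  x <- if (is.null(original)) {
    counterfactual$x_original
  } else if (inherits(original, "cell_dataset")) original$x else as.matrix(original)
  cf <- counterfactual$mean
  if (!identical(dim(x), dim(cf))) {
    stop("original (", nrow(x), " x ", ncol(x), ") does not align with the ",
         "counterfactual (", nrow(cf), " x ", ncol(cf), ")")
  }
  n <- nrow(x)
  if (n < 2L) stop("paired t test needs at least 2 pairs")
  d <- cf - x
  m <- colMeans(d)
  s <- sqrt(colSums(sweep(d, 2L, m, `-`)^2) / (n - 1L))
  constant <- s < .Machine$double.eps^0.5
  stat <- ifelse(constant, NA_real_, m / (s / sqrt(n)))
  p <- ifelse(constant, 1, 2 * stats::pt(-abs(stat), df = n - 1L))
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(
    feature = counterfactual$feature_names,
    statistic = stat, df = n - 1L, p_value = p, p_adjusted = p_adj,
    mean_diff = m,
    direction = dplyr::case_when(constant ~ "none", m > 0 ~ "up", m < 0 ~ "down",
                                 TRUE ~ "none"),
    constant = constant,
    significant = p_adj <= alpha & !constant)
  dplyr::arrange(out, .data$p_adjusted, dplyr::desc(abs(.data$statistic)))
}

#' k-NN uncertainty of an embedding with respect to a covariate
#'
#' Quantifies, per item, how poorly a covariate (for example a drug's
#' pathway) can be read off the local neighborhood of the item's embedding:
#' `u_i = H(C_N(i)) * sum_{j in N(i)} 1 / log d(i, j)`, where `N(i)` are the
#' k nearest neighbors of item i (self excluded), `H` is the Shannon entropy
#' (natural log) of the covariate values among those neighbors, and `d` the
#' pairwise distance. A homogeneous neighborhood gives `u_i = 0`. Since the
#' entropy does not depend on the neighbor index it factors out of the sum.
#' Distances are clamped below at `clamp` so `1 / log d` stays positive and
#' bounded; by default embeddings are standardized per dimension before
#' distances are computed.
#'
#' @param embedding Items x dimensions matrix, or a full pairwise distance
#'   matrix with `distance = "precomputed"`.
#' @param covariate Per-item covariate labels (length = number of items).
#' @param k Number of neighbors, `0 < k < n`.
#' @param distance `"euclidean"`, `"manhattan"`, `"cosine"` or
#'   `"precomputed"`.
#' @param standardize Z-score each embedding dimension first (ignored for
#'   precomputed distances).
#' @param clamp Lower clamp for distances (default `1 + 1e-6`).
#' @return A tibble with `item`, `covariate` and `uncertainty`, carrying
#'   `k` and the metric name as attributes.
#' @export
knn_uncertainty <- function(embedding, covariate, k,
                            distance = c("euclidean", "manhattan", "cosine",
                                         "precomputed"),
                            standardize = TRUE, clamp = 1 + 1e-6) {
  distance <- match.arg(distance)
  emb <- as.matrix(embedding)
  n <- if (distance == "precomputed") nrow(emb) else nrow(emb)
  if (length(covariate) != n) stop("covariate must have one value per item")
  if (k <= 0L || k >= n) stop("k must satisfy 0 < k < n (n = ", n, ")")
  if (distance == "precomputed") {
    if (nrow(emb) != ncol(emb)) stop("precomputed distances must be a square matrix")
    D <- emb
  } else {
    if (standardize) {
      sds <- apply(emb, 2L, stats::sd)
      sds[sds < 1e-12] <- 1
      emb <- sweep(sweep(emb, 2L, colMeans(emb), `-`), 2L, sds, `/`)
    }
    D <- switch(distance,
                euclidean = as.matrix(stats::dist(emb, method = "euclidean")),
                manhattan = as.matrix(stats::dist(emb, method = "manhattan")),
                cosine = {
                  nrm <- sqrt(rowSums(emb^2)); nrm[nrm < 1e-12] <- 1
                  u <- emb / nrm
                  pmin(pmax(1 - tcrossprod(u), 0), 2)
                })
  }
  if (any(D[upper.tri(D)] <= 0)) {
    warning("duplicate items at distance 0; distances clamped at ", clamp)
  }
  covariate <- as.character(covariate)
  u <- numeric(n)
  item <- if (!is.null(rownames(D))) rownames(D) else as.character(seq_len(n))
  for (i in seq_len(n)) {
    d_i <- D[i, -i]
    ord <- order(d_i)[seq_len(k)]
    nb_d <- pmax(d_i[ord], clamp)
    nb_c <- covariate[-i][ord]
    tab <- table(nb_c) / k
    H <- -sum(tab * log(tab))
    u[i] <- H * sum(1 / log(nb_d))
  }
  out <- tibble::tibble(item = item, covariate = covariate, uncertainty = u)
  attr(out, "k") <- as.integer(k)
  attr(out, "distance") <- distance
  out
}

#' Export a latent-space representation
#'
#' Categorical attributes export one row per category; ordered attributes
#' apply the trained encoder to caller-supplied feature values; `"unknown"`
#' exports the per-cell unknown-attribute codes keyed by cell id. The
#' resulting matrix is the substrate for correlation, clustering or
#' low-dimensional inspection of an attribute's internal structure.
#'
#' @param model A fitted `latentsplit_model`.
#' @param attribute Attribute name, or `"unknown"`.
#' @param features For ordered attributes: a matrix (or vector) of feature
#'   values to embed; rownames become labels.
#' @return A tibble with a `label` column and `latent_1 ... latent_d`.
#' @export
export_latent <- function(model, attribute, features = NULL) {
  if (identical(attribute, "unknown")) {
    Z <- model$par$Zu
    labels <- model$cell_ids
  } else {
    a <- schema_attr(model$schema, attribute)
    if (a$kind == "categorical") {
      Z <- embed_categorical(model, attribute, a$categories)
      labels <- a$categories
    } else {
      if (is.null(features)) {
        stop("ordered attribute '", attribute, "' needs `features` to embed")
      }
      Fm <- if (is.matrix(features)) features else matrix(features, ncol = a$dim)
      Z <- embed_ordered(model, attribute, Fm)
      labels <- if (!is.null(rownames(Fm))) rownames(Fm) else as.character(seq_len(nrow(Fm)))
    }
  }
  out <- tibble::as_tibble(as.data.frame(Z, optional = TRUE),
                           .name_repair = ~ paste0("latent_", seq_along(.x)))
  dplyr::bind_cols(tibble::tibble(label = labels), out)
}
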