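#' Fit the disentangling model with partial labels
#'
#' Semi-supervised variant: attributes with missing values get an auxiliary
#' classifier (categorical) or regressor (ordered) that maps measured
#' expression to the attribute, trained jointly with the rest of the model
#' through an added classification loss (cross-entropy / MSE on the labeled
#' cells only). For unlabeled cells the attribute's latent code is completed
#' from the classifier output — by default the probability-weighted mixture
#' of category embeddings, which keeps the whole objective differentiable;
#' `soft_completion = FALSE` switches to hard argmax completion.
#'
#' @inheritParams disentangle
#' @param attributes Attribute names to treat as semi-supervised; defaults
#'   to every attribute with at least one missing value.
#' @param classifier_depth,classifier_width Hidden-layer count and width of
#'   the classifier/regressor MLPs.
#' @param cls_weight Weight of the classification loss (the model objective
#'   adds the terms unweighted; this optional factor defaults to 1).
#' @param soft_completion Use the soft embedding mixture for unlabeled cells
#'   during training (recommended).
#' @return A fitted `latentsplit_model` whose classifier bank is available
#'   via [classifier_bank()].
#' @export
disentangle_semisupervised <- function(ds, spec = latent_spec(), epochs = 300L,
                                       batch_size = 256L, lr_net = 1e-3,
                                       lr_emb = 5e-3, seed = 1L,
                                       attributes = NULL,
                                       classifier_depth = 1L,
                                       classifier_width = 64L,
                                       cls_weight = 1,
                                       soft_completion = TRUE,
                                       verbose = FALSE) {
  stopifnot(inherits(ds, "cell_dataset"), inherits(spec, "latent_spec"))
  if (is.null(attributes)) {
    attributes <- schema_names(ds$schema)[vapply(schema_names(ds$schema),
                                                 function(nm) n_missing(ds, nm) > 0L,
                                                 logical(1))]
  }
  for (nm in attributes) {
    a <- schema_attr(ds$schema, nm)
    miss <- missing_mask(ds, nm)
    if (all(miss)) {
      stop("attribute '", nm, "' has zero labeled cells; ",
           "at least one label per supervised attribute is required")
    }
    if (a$kind == "categorical") {
      seen <- unique(ds$attribute_values[[nm]][!miss])
      absent <- setdiff(a$categories, seen)
      if (length(absent) > 0L) {
        warning("attribute '", nm, "': no labeled support for class(es) ",
                paste(absent, collapse = ", "))
      }
    }
  }
  # fully labeled attributes outside `attributes` must stay fully labeled
  for (nm in setdiff(schema_names(ds$schema), attributes)) {
    if (n_missing(ds, nm) > 0L) {
      stop("attribute '", nm, "' has missing values but is not listed in `attributes`")
    }
  }
  config <- default_train_config(epochs = epochs, batch_size = batch_size,
                                 lr_net = lr_net, lr_emb = lr_emb, seed = seed,
                                 classifier_depth = classifier_depth,
                                 classifier_width = classifier_width,
                                 cls_weight = cls_weight,
                                 soft_completion = soft_completion,
                                 verbose = verbose)
  train_impl(ds, spec, config, attributes)
}

#' Extract the classifier bank from a semi-supervised fit
#'
#' @param model A model fitted with [disentangle_semisupervised()].
#' @return An object of class `classifier_bank` holding, per semi-supervised
#'   attribute, the trained classifier (categorical) or regressor (ordered)
#'   together with the input standardization.
#' @export
classifier_bank <- function(model) {
  if (length(model$semisup) == 0L) {
    stop("model was fitted without semi-supervised attributes")
  }
  structure(
    list(attributes = model$semisup, schema = model$schema,
         nets = model$par$cls,
         center = model$cls_center, scale = model$cls_scale,
         layer_kind = model$layer_kind),
    class = "classifier_bank"
  )
}

#' @export
print.classifier_bank <- function(x, ...) {
  cat("<classifier_bank> attributes: ", paste(x$attributes, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

standardize_input <- function(bank, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  xin <- if (bank$layer_kind == "raw_counts") log1p(x) else x
  sweep(sweep(xin, 2L, bank$center, `-`), 2L, bank$scale, `/`)
}

#' Classifier probabilities / regressor outputs for cells
#'
#' @param bank A [classifier_bank()].
#' @param attribute A semi-supervised attribute name.
#' @param x Expression matrix (cells x features) on the model's layer kind.
#' @return Category probabilities (rows sum to 1) or regressed feature
#'   vectors, one row per cell.
#' @export
predict_attribute <- function(bank, attribute, x) {
  if (!attribute %in% bank$attributes) {
    stop("attribute '", attribute, "' has no trained classifier/regressor")
  }
  a <- schema_attr(bank$schema, attribute)
  out <- mlp_forward(bank$nets[[attribute]], standardize_input(bank, x))
  if (a$kind == "categorical") {
    out <- row_softmax(out)
    colnames(out) <- a$categories
  }
  out
}

# internal helpers used during latent assembly for training cells
impute_categorical_labels <- function(model, attribute, idx) {
  bank <- classifier_bank(model)
  probs <- predict_attribute(bank, attribute, model$x[idx, , drop = FALSE])
  schema_attr(model$schema, attribute)$categories[max.col(probs, ties.method = "first")]
}

regress_ordered_features <- function(model, attribute, idx) {
  bank <- classifier_bank(model)
  predict_attribute(bank, attribute, model$x[idx, , drop = FALSE])
}

#' Classification loss of a fitted model on a dataset
#'
#' Sum over semi-supervised attributes of the categorical cross-entropy
#' (mean over labeled cells, natural log) and the regression MSE, evaluated
#' only on cells with observed labels. This is the term added to the base
#' objective during semi-supervised training.
#'
#' @param model A model fitted with [disentangle_semisupervised()].
#' @param ds A [cell_dataset()]; defaults to the training data.
#' @param weight Loss weight, defaulting to the one used in training.
#' @return A scalar loss.
#' @export
classification_loss <- function(model, ds = NULL, weight = NULL) {
  bank <- classifier_bank(model)
  if (is.null(weight)) weight <- model$config$cls_weight
  x <- if (is.null(ds)) model$x else ds$x
  values <- if (is.null(ds)) model$labels else ds$attribute_values
  total <- 0
  for (nm in bank$attributes) {
    a <- schema_attr(bank$schema, nm)
    v <- values[[nm]]
    if (a$kind == "categorical") {
      lab <- which(!is.na(v))
      if (length(lab) == 0L) next
      probs <- predict_attribute(bank, nm, x[lab, , drop = FALSE])
      tgt <- match(v[lab], a$categories)
      total <- total + weight * mean(-log(pmax(probs[cbind(seq_along(tgt), tgt)], 1e-12)))
    } else {
      lab <- which(!apply(v, 1L, function(r) anyNA(r) || any(is.nan(r))))
      if (length(lab) == 0L) next
      pred <- predict_attribute(bank, nm, x[lab, , drop = FALSE])
      total <- total + weight * mean((pred - v[lab, , drop = FALSE])^2)
    }
  }
  total
}

#' Impute missing attribute labels
#'
#' Completes every missing label of the semi-supervised attributes:
#' categorical labels become the argmax category (ties broken toward the
#' first category in schema order and flagged), ordered values become the
#' regressor output. Observed labels are never overwritten and carry
#' confidence 1 with status `"observed"`.
#'
#' @param model A model fitted with [disentangle_semisupervised()].
#' @param ds Dataset to complete; defaults to the training data.
#' @return A list with `dataset` (the completed [cell_dataset()]) and
#'   `labels`, a tibble with columns `cell_id`, `attribute`, `value`,
#'   `confidence`, `status` (`"observed"` / `"imputed"`) and `tie`. Ordered
#'   attribute values are serialized as comma-joined numbers in `value`.
#' @export
impute_labels <- function(model, ds = NULL) {
  bank <- classifier_bank(model)
  own <- is.null(ds)
  if (own) {
    ds <- structure(
      list(x = model$x, cell_ids = model$cell_ids,
           feature_names = model$feature_names,
           attribute_values = model$labels, schema = model$schema,
           layer_kind = model$layer_kind),
      class = "cell_dataset")
  }
  rows <- list()
  for (nm in bank$attributes) {
    a <- schema_attr(ds$schema, nm)
    v <- ds$attribute_values[[nm]]
    if (a$kind == "categorical") {
      miss <- is.na(v)
      conf <- rep(1, length(v)); tie <- rep(FALSE, length(v))
      if (any(miss)) {
        probs <- predict_attribute(bank, nm, ds$x[miss, , drop = FALSE])
        pick <- max.col(probs, ties.method = "first")
        top <- probs[cbind(seq_len(nrow(probs)), pick)]
        second <- apply(probs, 1L, function(p) sort(p, decreasing = TRUE)[2])
        v[miss] <- a$categories[pick]
        conf[miss] <- top
        tie[miss] <- (top - second) < 1e-9
      }
      ds$attribute_values[[nm]] <- v
      rows[[nm]] <- tibble::tibble(
        cell_id = ds$cell_ids, attribute = nm, value = v,
        confidence = conf,
        status = ifelse(miss, "imputed", "observed"), tie = tie)
    } else {
      miss <- apply(v, 1L, function(r) anyNA(r) || any(is.nan(r)))
      if (any(miss)) {
        v[miss, ] <- predict_attribute(bank, nm, ds$x[miss, , drop = FALSE])
      }
      ds$attribute_values[[nm]] <- v
      rows[[nm]] <- tibble::tibble(
        cell_id = ds$cell_ids, attribute = nm,
        value = apply(v, 1L, function(r) paste(signif(r, 8), collapse = ",")),
        confidence = ifelse(miss, NA_real_, 1),
        status = ifelse(miss, "imputed", "observed"), tie = FALSE)
    }
  }
  list(dataset = ds, labels = dplyr::bind_rows(rows))
}
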