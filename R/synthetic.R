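#' Plan a synthetic attribute
#'
#' Describes one planted attribute of a synthetic dataset: its kind, value
#' space, the features it targets and the effect size on the log-mean scale.
#' Categorical attributes use their first category as the zero-effect
#' reference; other categories receive per-target-feature effects with
#' magnitudes drawn uniformly from `effect_range` and random signs. Ordered
#' attributes act through a monotone dose-response, linear in log-mean:
#' `value * slope_f` with per-feature slopes drawn the same way, so the
#' full listed effect size is reached at value 1.
#'
#' @param name Attribute name.
#' @param kind `"categorical"` or `"ordered"`.
#' @param categories Category labels (categorical).
#' @param values Value grid sampled per cell (ordered, dimension 1).
#' @param targets Integer feature indices the attribute acts on.
#' @param effect_range Length-2 range of absolute effect sizes (log units).
#' @param effects Optional explicit effects overriding the random draw: a
#'   `length(categories)` x `length(targets)` matrix (categorical) or a
#'   vector of per-target slopes (ordered).
#' @return A plan entry for [synthetic_config()].
#' @export
synthetic_attribute <- function(name, kind = c("categorical", "ordered"),
                                categories = NULL, values = NULL,
                                targets, effect_range = c(0.5, 1.0),
                                effects = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical" && (is.null(categories) || length(categories) < 1L)) {
    stop("categorical attribute '", name, "' needs >= 1 category")
  }
  if (kind == "ordered" && (is.null(values) || length(values) < 1L)) {
    stop("ordered attribute '", name, "' needs a value grid")
  }
  if (!is.null(effects)) {
    if (kind == "categorical") {
      effects <- as.matrix(effects)
      stopifnot(nrow(effects) == length(categories),
                ncol(effects) == length(targets))
    } else {
      stopifnot(length(effects) == length(targets))
    }
  }
  list(name = name, kind = kind, categories = categories, values = values,
       targets = as.integer(targets), effect_range = effect_range,
       effects = effects)
}

#' Default synthetic attribute plan
#'
#' Three attributes on disjoint target blocks, each spanning a fifth of the
#' features: a 3-class cell type, a binary perturbation status and a
#' one-dimensional dose on a 4-point grid. At the default 200 features the
#' blocks are 1-40, 41-80 and 81-120.
#'
#' @param m_features Number of features the plan must fit into.
#' @return A list of [synthetic_attribute()] entries.
#' @export
default_attribute_plan <- function(m_features = 200L) {
  k <- max(1L, m_features %/% 5L)
  list(
    synthetic_attribute("cell_type", "categorical",
                        categories = c("typeA", "typeB", "typeC"),
                        targets = seq_len(k)),
    synthetic_attribute("status", "categorical",
                        categories = c("control", "perturbed"),
                        targets = k + seq_len(k)),
    synthetic_attribute("dose", "ordered", values = c(0, 0.25, 0.5, 1),
                        targets = 2L * k + seq_len(min(k, m_features - 2L * k)))
  )
}

#' Configure the synthetic single-cell generator
#'
#' The generator emulates the structure the model assumes: per-cell
#' log-means composed of a feature baseline, additive known-attribute
#' effects on declared target features, and low-rank cell-specific nuisance
#' structure unexplained by any known attribute; counts are drawn with
#' log-normal library-size variation under a zero-inflated negative
#' binomial, Poisson or Gaussian family. Defaults: 2000 cells, 200
#' features, two categorical attributes (3 and 2 classes) plus one
#' one-dimensional ordered dose, effects of 0.5-1.0 log units, zinb family.
#'
#' @param n Number of cells.
#' @param m_features Number of features.
#' @param attributes List of [synthetic_attribute()] plans.
#' @param nuisance_dim Rank of the Gaussian nuisance structure.
#' @param nuisance_scale Standard deviation of the nuisance loadings.
#' @param baseline_mean,baseline_sd Feature baseline log-mean distribution.
#' @param library_meanlog,library_sdlog Log-normal library-size parameters
#'   (`library_sdlog = 0` fixes the library size).
#' @param family Count/value family of the observations.
#' @param dispersion ZINB inverse-dispersion theta, or Gaussian noise
#'   variance.
#' @param zero_inflation Structural-zero probability (zinb).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 2000L, m_features = 200L,
                             attributes = NULL,
                             nuisance_dim = 4L, nuisance_scale = 0.2,
                             baseline_mean = 1, baseline_sd = 1,
                             library_meanlog = log(4000), library_sdlog = 0.3,
                             family = c("zinb", "poisson", "gaussian"),
                             dispersion = 5, zero_inflation = 0.05,
                             seed = 1L) {
  family <- match.arg(family)
  stopifnot(n >= 1, m_features >= 1, nuisance_dim >= 0,
            zero_inflation >= 0, zero_inflation < 1, dispersion > 0)
  if (is.null(attributes)) attributes <- default_attribute_plan(m_features)
  for (a in attributes) {
    if (any(a$targets < 1L | a$targets > m_features)) {
      stop("attribute '", a$name, "' targets features outside 1..", m_features)
    }
  }
  structure(
    list(n = as.integer(n), m_features = as.integer(m_features),
         attributes = attributes, nuisance_dim = as.integer(nuisance_dim),
         nuisance_scale = nuisance_scale,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         library_meanlog = library_meanlog, library_sdlog = library_sdlog,
         family = family, dispersion = dispersion,
         zero_inflation = zero_inflation, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

plan_schema <- function(config) {
  attrs <- lapply(config$attributes, function(a) {
    if (a$kind == "categorical") cat_attr(a$name, a$categories) else ord_attr(a$name, 1L)
  })
  attribute_schema(attrs)
}

#' Generate a synthetic dataset with known ground truth
#'
#' Draws per-cell attribute values, builds log-means as baseline + planted
#' effects + low-rank nuisance, converts them to feature proportions via a
#' softmax, scales by a sampled library size and draws observations from
#' the configured family. The returned ground truth records every planted
#' effect, the true (pre-masking) labels, the nuisance factors and the
#' expected expression of every cell, sufficient for oracle evaluation of
#' recovery without re-deriving anything.
#'
#' @param config A [synthetic_config()].
#' @return A list with `dataset` (a [cell_dataset()]) and `ground_truth`
#'   (class `synthetic_truth`).
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n; m <- config$m_features
  baseline <- rnorm(m, config$baseline_mean, config$baseline_sd)
  log_mean <- matrix(baseline, n, m, byrow = TRUE)

  labels <- tibble::tibble(cell_id = sprintf("cell_%04d", seq_len(n)))
  effects <- list()
  for (a in config$attributes) {
    if (a$kind == "categorical") {
      C <- length(a$categories)
      eff <- matrix(0, C, m, dimnames = list(a$categories, NULL))
      if (!is.null(a$effects)) {
        eff[, a$targets] <- a$effects
      } else {
        for (ci in seq_len(C)[-1L]) {
          eff[ci, a$targets] <- sample(c(-1, 1), length(a$targets), replace = TRUE) *
            stats::runif(length(a$targets), a$effect_range[1L], a$effect_range[2L])
        }
      }
      lab <- sample(a$categories, n, replace = TRUE)
      labels[[a$name]] <- lab
      log_mean <- log_mean + eff[match(lab, a$categories), , drop = FALSE]
      effects[[a$name]] <- eff
    } else {
      slope <- numeric(m)
      slope[a$targets] <- if (!is.null(a$effects)) {
        a$effects
      } else {
        sample(c(-1, 1), length(a$targets), replace = TRUE) *
          stats::runif(length(a$targets), a$effect_range[1L], a$effect_range[2L])
      }
      val <- a$values[sample.int(length(a$values), n, replace = TRUE)]
      labels[[a$name]] <- val
      log_mean <- log_mean + outer(val, slope)
      effects[[a$name]] <- slope
    }
  }
  nuisance <- NULL
  if (config$nuisance_dim > 0L) {
    U <- matrix(rnorm(n * config$nuisance_dim), n, config$nuisance_dim)
    V <- matrix(rnorm(config$nuisance_dim * m, sd = config$nuisance_scale),
                config$nuisance_dim, m)
    log_mean <- log_mean + U %*% V
    nuisance <- list(scores = U, loadings = V)
  }

  if (config$family == "gaussian") {
    x <- log_mean + matrix(rnorm(n * m, sd = sqrt(config$dispersion)), n, m)
    mu <- log_mean
    library_size <- NULL
    layer_kind <- "log_normalized"
  } else {
    props <- row_softmax(log_mean)
    library_size <- exp(rnorm(n, config$library_meanlog, config$library_sdlog))
    mu <- props * library_size
    dist <- expression_distribution(
      family = config$family, mean = mu,
      dispersion = if (config$family == "zinb") rep(config$dispersion, m) else NULL,
      zero_inflation_logit = if (config$family == "zinb") {
        matrix(stats::qlogis(max(config$zero_inflation, 1e-12)), n, m)
      } else NULL)
    x <- sample_expression(dist)
    layer_kind <- "raw_counts"
  }
  rownames(x) <- labels$cell_id
  colnames(x) <- sprintf("feature_%03d", seq_len(m))

  ds <- cell_dataset(x, labels, plan_schema(config), layer_kind = layer_kind)
  truth <- structure(
    list(config = config, baseline = baseline, effects = effects,
         labels = labels, nuisance = nuisance, log_mean = log_mean,
         expected = mu, library_size = library_size),
    class = "synthetic_truth")
  list(dataset = ds, ground_truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", x$config$n, " cells x ", x$config$m_features,
      " features, family = ", x$config$family, "\n", sep = "")
  invisible(x)
}

#' Target features of a planted attribute
#'
#' @param truth A `synthetic_truth`.
#' @param attribute Attribute name.
#' @return Integer feature indices the attribute was planted on.
#' @export
planted_targets <- function(truth, attribute) {
  plans <- truth$config$attributes
  nm <- vapply(plans, `[[`, character(1), "name")
  if (!attribute %in% nm) stop("no planted attribute '", attribute, "'")
  plans[[match(attribute, nm)]]$targets
}

#' Write ground truth to a structured sidecar file
#'
#' @param truth A `synthetic_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(
    config = unclass(truth$config),
    baseline = truth$baseline,
    effects = lapply(truth$effects, function(e) if (is.matrix(e)) apply(e, 1L, identity, simplify = FALSE) else e),
    labels = truth$labels,
    library_size = truth$library_size
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Mask a fraction of an attribute's labels
#'
#' Replaces exactly `floor(fraction * n)` labels with the missing marker,
#' recording which cells were masked so imputation accuracy can be scored
#' against the held-back truth. Stratified mode preserves class proportions
#' within one cell per class.
#'
#' @param ds A [cell_dataset()].
#' @param attribute Attribute to mask.
#' @param fraction Fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @param stratified Sample the masked set within classes (categorical
#'   attributes only).
#' @return A list with `dataset` (labels masked) and `masked` (integer cell
#'   indices).
#' @export
mask_labels <- function(ds, attribute, fraction, seed = 1L, stratified = FALSE) {
  a <- schema_attr(ds$schema, attribute)
  stopifnot(fraction >= 0, fraction < 1)
  n <- nrow(ds$x)
  n_mask <- floor(fraction * n)
  set.seed(as.integer(seed))
  if (n_mask == 0L) {
    return(list(dataset = ds, masked = integer(0)))
  }
  if (stratified && a$kind == "categorical") {
    v <- ds$attribute_values[[attribute]]
    masked <- integer(0)
    classes <- split(seq_len(n), v)
    quota <- vapply(classes, function(ix) length(ix) * fraction, numeric(1))
    take <- floor(quota)
    rem <- n_mask - sum(take)
    if (rem > 0) {
      extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1
    }
    for (ci in seq_along(classes)) {
      masked <- c(masked, sample(classes[[ci]], take[ci]))
    }
    masked <- sort(masked)
  } else {
    masked <- sort(sample.int(n, n_mask))
  }
  if (a$kind == "categorical") {
    ds$attribute_values[[attribute]][masked] <- NA_character_
  } else {
    ds$attribute_values[[attribute]][masked, ] <- NaN
  }
  list(dataset = ds, masked = masked)
}
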