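#' Latent-space and loss specification
#'
#' Collects the architecture and loss hyperparameters of the disentangling
#' model: per-attribute and unknown latent dimensions, the ordered-attribute
#' encoder shape, the decoder shape, the noise scale `sigma` added to the
#' unknown embedding during training, the minimality penalty weight
#' `lambda`, the auxiliary reconstruction weight `tau`, and the output
#' likelihood family.
#'
#' `sigma` is the standard deviation of the additive Gaussian noise
#' `eta ~ N(0, sigma^2 I)` applied to the unknown-attribute code during
#' training only; the default of 1 is this package's choice of a fixed
#' value, documented in the methods vignette.
#'
#' @param n_latent_attr Latent dimension per known attribute.
#' @param n_latent_u Latent dimension of the unknown-attribute code.
#' @param encoder_depth,encoder_width Hidden-layer count and width of the
#'   ordered-attribute encoder MLPs (defaults depth 2, width 256). Depth 0
#'   gives a plain affine map.
#' @param decoder_depth,decoder_width Hidden-layer count and width of the
#'   generator decoder.
#' @param sigma Training noise scale on the unknown code (>= 0).
#' @param lambda Minimality penalty weight on `||z_u||^2` (>= 0).
#' @param tau Weight of the mean-squared-error term added to the negative
#'   log-likelihood in the completeness loss (>= 0).
#' @param family Output likelihood: `"zinb"` or `"poisson"` for raw counts,
#'   `"gaussian"` for log-normalized values.
#' @return An object of class `latent_spec`.
#' @export
latent_spec <- function(n_latent_attr = 32L, n_latent_u = 32L,
                        encoder_depth = 2L, encoder_width = 256L,
                        decoder_depth = 2L, decoder_width = 128L,
                        sigma = 1, lambda = 0.1, tau = 1,
                        family = c("zinb", "gaussian", "poisson")) {
  family <- match.arg(family)
  stopifnot(n_latent_attr >= 1, n_latent_u >= 1,
            encoder_depth >= 0, encoder_width >= 1,
            decoder_depth >= 0, decoder_width >= 1,
            is.finite(sigma), sigma >= 0,
            is.finite(lambda), lambda >= 0,
            is.finite(tau), tau >= 0)
  structure(
    list(n_latent_attr = as.integer(n_latent_attr),
         n_latent_u = as.integer(n_latent_u),
         encoder_depth = as.integer(encoder_depth),
         encoder_width = as.integer(encoder_width),
         decoder_depth = as.integer(decoder_depth),
         decoder_width = as.integer(decoder_width),
         sigma = sigma, lambda = lambda, tau = tau, family = family),
    class = "latent_spec"
  )
}

#' @export
print.latent_spec <- function(x, ...) {
  cat("<latent_spec> family = ", x$family,
      ", d_attr = ", x$n_latent_attr, ", d_u = ", x$n_latent_u,
      ", sigma = ", x$sigma, ", lambda = ", x$lambda, ", tau = ", x$tau, "\n",
      sep = "")
  invisible(x)
}

count_family <- function(family) family %in% c("zinb", "poisson")

# ---------------------------------------------------------------------------
# decoder: shared by training, reconstruction, counterfactuals and refitting

decoder_forward <- function(par, spec, Z, library_size = NULL, cache = FALSE) {
  if (is.null(par$dec)) {
    H <- Z                                    # linear decoder (depth 0)
    fwd <- list(out = Z)
  } else {
    fwd <- mlp_forward(par$dec, Z, cache = cache, activate_last = TRUE)
    H <- if (cache) fwd$out else fwd
  }
  O <- sweep(H %*% par$W_mu, 2L, par$b_mu, `+`)
  if (count_family(spec$family)) {
    if (is.null(library_size)) stop("count families need a per-cell library size")
    P <- row_softmax(O)
    mu <- pmax(P * library_size, 1e-12)
  } else {
    P <- NULL
    mu <- O
  }
  S <- NULL
  if (spec$family == "zinb") S <- sweep(H %*% par$W_pi, 2L, par$b_pi, `+`)
  list(mu = mu, P = P, S = S, H = H, mlp = if (cache) fwd else NULL,
       library_size = library_size)
}

# dmu, dS: gradients of the scalar loss w.r.t. mu and the zero-inflation
# logits. Returns parameter gradients plus d(loss)/dZ.
decoder_backward <- function(par, spec, fw, dmu, dS = NULL) {
  if (count_family(spec$family)) {
    # mu = L * softmax(O); chain rule through the row softmax
    w <- rowSums(dmu * fw$mu)
    dO <- dmu * fw$mu - fw$P * w
  } else {
    dO <- dmu
  }
  g <- list(W_mu = crossprod(fw$H, dO), b_mu = colSums(dO))
  dH <- dO %*% t(par$W_mu)
  if (!is.null(dS)) {
    g$W_pi <- crossprod(fw$H, dS)
    g$b_pi <- colSums(dS)
    dH <- dH + dS %*% t(par$W_pi)
  }
  if (is.null(par$dec)) {
    g$dZ <- dH
  } else {
    bk <- mlp_backward(par$dec, fw$mlp, dH, activate_last = TRUE)
    g$dec <- bk$grads
    g$dZ <- bk$dX
  }
  g
}

make_distribution <- function(par, spec, fw) {
  expression_distribution(
    family = spec$family,
    mean = fw$mu,
    dispersion = switch(spec$family,
                        zinb = exp(par$log_theta),
                        gaussian = exp(par$log_var),
                        NULL),
    zero_inflation_logit = fw$S
  )
}

# completeness-loss pieces on a batch: per-cell NLL sum + tau * MSE,
# with the MSE computed on log1p scale for count families (design choice,
# see the methods vignette) and raw scale for gaussian.
cmp_loss_and_grads <- function(x, par, spec, fw) {
  dist <- make_distribution(par, spec, fw)
  nll_cell <- nll(x, dist)
  mu <- fw$mu
  m <- ncol(x)
  if (count_family(spec$family)) {
    r <- log1p(mu) - log1p(x)
    mse_cell <- rowSums(r^2) / m
    dmse_dmu <- 2 * r / (m * (1 + mu))
  } else {
    r <- mu - x
    mse_cell <- rowSums(r^2) / m
    dmse_dmu <- 2 * r / m
  }
  gr <- nll_grads(x, mu, spec$family,
                  theta = if (spec$family == "zinb") exp(par$log_theta) else NULL,
                  zi = fw$S,
                  variance = if (spec$family == "gaussian") exp(par$log_var) else NULL)
  dmu <- gr$dmu + spec$tau * dmse_dmu
  list(nll = nll_cell, mse = mse_cell, dmu = dmu,
       ds = gr$ds, dlogtheta = gr$dlogtheta, dlogvar = gr$dlogvar)
}

# ---------------------------------------------------------------------------
# training

prep_training_data <- function(ds, spec) {
  schema <- ds$schema
  n <- nrow(ds$x)
  cat_idx <- list(); ord_feat <- list()
  for (a in schema$attributes) {
    v <- ds$attribute_values[[a$name]]
    if (a$kind == "categorical") {
      cat_idx[[a$name]] <- match(v, a$categories)     # NA when missing
    } else {
      ord_feat[[a$name]] <- v                          # NaN rows when missing
    }
  }
  library_size <- if (count_family(spec$family)) pmax(rowSums(ds$x), 1) else NULL
  # classifier / regressor input: standardized log1p counts (or raw values)
  xin <- if (ds$layer_kind == "raw_counts") log1p(ds$x) else ds$x
  center <- colMeans(xin)
  scale_ <- apply(xin, 2L, stats::sd)
  scale_[scale_ < 1e-8] <- 1
  x_cls <- sweep(sweep(xin, 2L, center, `-`), 2L, scale_, `/`)
  list(cat_idx = cat_idx, ord_feat = ord_feat, library_size = library_size,
       x_cls = x_cls, cls_center = center, cls_scale = scale_)
}

init_params <- function(ds, spec, config, semisup_attrs) {
  schema <- ds$schema
  m <- ncol(ds$x)
  n <- nrow(ds$x)
  d_attr <- spec$n_latent_attr
  par <- list(emb = list(), Zu = matrix(0, n, spec$n_latent_u),
              enc = list(), cls = list())
  for (a in schema$attributes) {
    if (a$kind == "categorical") {
      par$emb[[a$name]] <- matrix(rnorm(length(a$categories) * d_attr, sd = 0.1),
                                  length(a$categories), d_attr)
    } else {
      par$enc[[a$name]] <- mlp_init(a$dim, d_attr, spec$encoder_depth, spec$encoder_width)
    }
  }
  d_total <- d_attr * length(schema$attributes) + spec$n_latent_u
  if (spec$decoder_depth == 0L) {
    par["dec"] <- list(NULL)                  # heads act directly on the latent
    hw <- d_total
  } else {
    # trunk of decoder_depth tanh layers of constant width; heads follow
    par$dec <- mlp_init(d_total, spec$decoder_width, spec$decoder_depth - 1L,
                        spec$decoder_width)
    hw <- spec$decoder_width
  }
  par$W_mu <- matrix(rnorm(hw * m, sd = sqrt(1 / hw)), hw, m)
  par$b_mu <- rep(0, m)
  if (spec$family == "zinb") {
    par$W_pi <- matrix(rnorm(hw * m, sd = sqrt(1 / hw)), hw, m)
    par$b_pi <- rep(-2, m)     # start with little zero inflation
    par$log_theta <- rep(log(5), m)
  }
  if (spec$family == "gaussian") par$log_var <- rep(0, m)
  for (a_name in semisup_attrs) {
    a <- schema_attr(schema, a_name)
    d_out <- if (a$kind == "categorical") length(a$categories) else a$dim
    par$cls[[a_name]] <- mlp_init(m, d_out, config$classifier_depth, config$classifier_width)
  }
  par
}

# Assemble the decomposed latent for a batch of training cells, including
# soft completion of semi-supervised attributes, with forward caches kept
# for backpropagation.
assemble_latent_batch <- function(par, spec, schema, prep, rows, semisup_attrs,
                                  noise = NULL, soft = TRUE) {
  blocks <- list(); info <- list()
  for (a in schema$attributes) {
    nm <- a$name
    if (a$kind == "categorical") {
      idx <- prep$cat_idx[[nm]][rows]
      Zy <- matrix(0, length(rows), spec$n_latent_attr)
      obs <- !is.na(idx)
      if (any(obs)) Zy[obs, ] <- par$emb[[nm]][idx[obs], , drop = FALSE]
      cls_fwd <- NULL; probs <- NULL
      if (any(!obs)) {
        if (!nm %in% semisup_attrs) {
          stop("attribute '", nm, "' has missing labels; use disentangle_semisupervised()")
        }
        cls_fwd <- mlp_forward(par$cls[[nm]], prep$x_cls[rows[!obs], , drop = FALSE],
                               cache = TRUE)
        probs <- row_softmax(cls_fwd$out)
        Zy[!obs, ] <- if (soft) {
          probs %*% par$emb[[nm]]
        } else {
          par$emb[[nm]][max.col(probs, ties.method = "first"), , drop = FALSE]
        }
      }
      info[[nm]] <- list(kind = "categorical", idx = idx, obs = obs,
                         cls_fwd = cls_fwd, probs = probs)
    } else {
      Fm <- prep$ord_feat[[nm]][rows, , drop = FALSE]
      miss <- apply(Fm, 1L, function(r) anyNA(r) || any(is.nan(r)))
      reg_fwd <- NULL
      if (any(miss)) {
        if (!nm %in% semisup_attrs) {
          stop("ordered attribute '", nm, "' has missing values; use disentangle_semisupervised()")
        }
        reg_fwd <- mlp_forward(par$cls[[nm]], prep$x_cls[rows[miss], , drop = FALSE],
                               cache = TRUE)
        Fm[miss, ] <- reg_fwd$out
      }
      enc_fwd <- mlp_forward(par$enc[[nm]], Fm, cache = TRUE)
      Zy <- enc_fwd$out
      info[[nm]] <- list(kind = "ordered", features = Fm, miss = miss,
                         enc_fwd = enc_fwd, reg_fwd = reg_fwd)
    }
    blocks[[nm]] <- Zy
  }
  Zu <- par$Zu[rows, , drop = FALSE]
  Zu_eff <- if (is.null(noise)) Zu else Zu + noise
  Z <- do.call(cbind, c(unname(blocks), list(Zu_eff)))
  list(Z = Z, info = info, Zu = Zu)
}

# Route d(loss)/dZ back into embedding tables, encoders, classifiers and the
# unknown embedding. Returns a gradient tree matching init_params().
route_latent_grads <- function(par, spec, schema, prep, rows, asm, dZ, grad,
                               semisup_attrs, soft, cls_scale = 0) {
  d_attr <- spec$n_latent_attr
  off <- 0L
  for (a in schema$attributes) {
    nm <- a$name
    dZy <- dZ[, off + seq_len(d_attr), drop = FALSE]
    off <- off + d_attr
    inf <- asm$info[[nm]]
    if (a$kind == "categorical") {
      obs <- inf$obs
      if (any(obs)) {
        agg <- rowsum(dZy[obs, , drop = FALSE], group = inf$idx[obs])
        gi <- as.integer(rownames(agg))
        grad$emb[[nm]][gi, ] <- grad$emb[[nm]][gi, , drop = FALSE] + agg
      }
      if (any(!obs)) {
        dZy_u <- dZy[!obs, , drop = FALSE]
        if (soft) {
          grad$emb[[nm]] <- grad$emb[[nm]] + crossprod(inf$probs, dZy_u)
          dprobs <- dZy_u %*% t(par$emb[[nm]])
          dlogits <- inf$probs * (dprobs - rowSums(dprobs * inf$probs))
          bk <- mlp_backward(par$cls[[nm]], inf$cls_fwd, dlogits)
          grad$cls[[nm]] <- tree_map2(`+`, grad$cls[[nm]], bk$grads)
        }
        # hard completion: no gradient through the argmax
      }
    } else {
      bk <- mlp_backward(par$enc[[nm]], inf$enc_fwd, dZy)
      grad$enc[[nm]] <- tree_map2(`+`, grad$enc[[nm]], bk$grads)
      if (!is.null(inf$reg_fwd) && any(inf$miss)) {
        dF <- bk$dX[inf$miss, , drop = FALSE]
        bk2 <- mlp_backward(par$cls[[nm]], inf$reg_fwd, dF)
        grad$cls[[nm]] <- tree_map2(`+`, grad$cls[[nm]], bk2$grads)
      }
    }
  }
  dZu <- dZ[, off + seq_len(spec$n_latent_u), drop = FALSE]
  grad$Zu[rows, ] <- grad$Zu[rows, , drop = FALSE] + dZu
  grad
}

# classification loss (cross-entropy / MSE on labeled cells) and its
# gradients, added to an existing gradient tree.
cls_loss_and_grads <- function(par, schema, prep, rows, semisup_attrs, grad,
                               weight = 1) {
  total <- 0
  for (nm in semisup_attrs) {
    a <- schema_attr(schema, nm)
    if (a$kind == "categorical") {
      idx <- prep$cat_idx[[nm]][rows]
      lab <- which(!is.na(idx))
      if (length(lab) == 0L) next
      fwd <- mlp_forward(par$cls[[nm]], prep$x_cls[rows[lab], , drop = FALSE],
                         cache = TRUE)
      probs <- row_softmax(fwd$out)
      tgt <- idx[lab]
      picked <- probs[cbind(seq_along(tgt), tgt)]
      total <- total + weight * mean(-log(pmax(picked, 1e-12)))
      one_hot <- matrix(0, length(tgt), ncol(probs))
      one_hot[cbind(seq_along(tgt), tgt)] <- 1
      dlogits <- weight * (probs - one_hot) / length(tgt)
      bk <- mlp_backward(par$cls[[nm]], fwd, dlogits)
      grad$cls[[nm]] <- tree_map2(`+`, grad$cls[[nm]], bk$grads)
    } else {
      Fm <- prep$ord_feat[[nm]][rows, , drop = FALSE]
      lab <- which(!apply(Fm, 1L, function(r) anyNA(r) || any(is.nan(r))))
      if (length(lab) == 0L) next
      fwd <- mlp_forward(par$cls[[nm]], prep$x_cls[rows[lab], , drop = FALSE],
                         cache = TRUE)
      resid <- fwd$out - Fm[lab, , drop = FALSE]
      total <- total + weight * mean(resid^2)
      dout <- weight * 2 * resid / length(resid)
      bk <- mlp_backward(par$cls[[nm]], fwd, dout)
      grad$cls[[nm]] <- tree_map2(`+`, grad$cls[[nm]], bk$grads)
    }
  }
  list(loss = total, grad = grad)
}

train_impl <- function(ds, spec, config, semisup_attrs) {
  schema <- ds$schema
  n <- nrow(ds$x)
  set.seed(config$seed)
  prep <- prep_training_data(ds, spec)
  par <- init_params(ds, spec, config, semisup_attrs)
  opt <- adam_init(par)
  lr <- list(emb = config$lr_emb, Zu = config$lr_emb, default = config$lr_net)
  bs <- min(config$batch_size, n)
  log_rows <- vector("list", config$epochs)
  soft <- isTRUE(config$soft_completion)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    ep <- c(nll = 0, mse = 0, minimality = 0, classification = 0)
    for (s in starts) {
      rows <- perm[s:min(s + bs - 1L, n)]
      b <- length(rows)
      noise <- if (spec$sigma > 0) {
        matrix(rnorm(b * spec$n_latent_u, sd = spec$sigma), b, spec$n_latent_u)
      } else NULL
      asm <- assemble_latent_batch(par, spec, schema, prep, rows, semisup_attrs,
                                   noise = noise, soft = soft)
      lib <- if (!is.null(prep$library_size)) prep$library_size[rows] else NULL
      fw <- decoder_forward(par, spec, asm$Z, lib, cache = TRUE)
      xb <- ds$x[rows, , drop = FALSE]
      cl <- cmp_loss_and_grads(xb, par, spec, fw)

      grad <- tree_zeros(par)
      dec_g <- decoder_backward(par, spec, fw, cl$dmu / b,
                                dS = if (!is.null(cl$ds)) cl$ds / b else NULL)
      grad$W_mu <- dec_g$W_mu; grad$b_mu <- dec_g$b_mu
      if (!is.null(dec_g$W_pi)) { grad$W_pi <- dec_g$W_pi; grad$b_pi <- dec_g$b_pi }
      if (!is.null(dec_g$dec)) grad$dec <- dec_g$dec
      if (!is.null(cl$dlogtheta)) grad$log_theta <- colSums(cl$dlogtheta) / b
      if (!is.null(cl$dlogvar)) grad$log_var <- colSums(cl$dlogvar) / b
      grad <- route_latent_grads(par, spec, schema, prep, rows, asm, dec_g$dZ,
                                 grad, semisup_attrs, soft)
      # minimality penalty on the stored (noise-free) unknown codes
      grad$Zu[rows, ] <- grad$Zu[rows, , drop = FALSE] + 2 * spec$lambda * asm$Zu / b
      cls <- list(loss = 0, grad = grad)
      if (length(semisup_attrs) > 0L) {
        cls <- cls_loss_and_grads(par, schema, prep, rows, semisup_attrs, grad,
                                  weight = config$cls_weight)
        grad <- cls$grad
      }
      stepped <- adam_step(opt, par, grad, lr)
      par <- stepped$params; opt <- stepped$opt

      ep["nll"] <- ep["nll"] + sum(cl$nll)
      ep["mse"] <- ep["mse"] + sum(cl$mse)
      ep["minimality"] <- ep["minimality"] + spec$lambda * sum(asm$Zu^2)
      ep["classification"] <- ep["classification"] + cls$loss * b
    }
    ep <- ep / n
    total <- ep["nll"] + spec$tau * ep["mse"] + ep["minimality"] + ep["classification"]
    if (!is.finite(total)) {
      stop("non-finite training loss at epoch ", epoch,
           " (nll = ", signif(ep["nll"], 4), "); try a smaller learning rate")
    }
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, total = unname(total), nll = unname(ep["nll"]),
      mse = unname(ep["mse"]), minimality = unname(ep["minimality"]),
      classification = unname(ep["classification"]))
    if (isTRUE(config$verbose) && (epoch %% 25L == 0L || epoch == 1L)) {
      message(sprintf("epoch %4d  total %.3f  nll %.3f  min %.4f  cls %.4f",
                      epoch, total, ep["nll"], ep["minimality"], ep["classification"]))
    }
  }

  structure(
    list(schema = schema, spec = spec, layer_kind = ds$layer_kind,
         par = par, cell_ids = ds$cell_ids,
         library_size = prep$library_size,
         x = ds$x,
         labels = ds$attribute_values,
         feature_names = ds$feature_names,
         semisup = semisup_attrs,
         cls_center = prep$cls_center, cls_scale = prep$cls_scale,
         training_log = dplyr::bind_rows(log_rows),
         config = config, seed = config$seed),
    class = "latentsplit_model"
  )
}

default_train_config <- function(epochs = 300L, batch_size = 256L,
                                 lr_net = 1e-3, lr_emb = 5e-3, seed = 1L,
                                 classifier_depth = 1L, classifier_width = 64L,
                                 cls_weight = 1, soft_completion = TRUE,
                                 verbose = FALSE) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr_net = lr_net, lr_emb = lr_emb, seed = as.integer(seed),
       classifier_depth = as.integer(classifier_depth),
       classifier_width = as.integer(classifier_width),
       cls_weight = cls_weight, soft_completion = soft_completion,
       verbose = verbose)
}

#' Fit the disentangling model
#'
#' Jointly optimizes the decomposed latent space (one embedding table per
#' categorical attribute, one encoder per ordered attribute, one directly
#' optimized code per cell for the unknown attributes) and the generator
#' decoder, minimizing the completeness loss (negative log-likelihood plus a
#' `tau`-weighted MSE on predicted means) plus the minimality penalty
#' `lambda * ||z_u||^2`. Unknown codes start at zero — literally encoding no
#' information — and receive additive Gaussian noise of scale `sigma` during
#' training. Optimization is Adam with separate learning rates for network
#' weights and directly optimized embeddings; runs are bit-reproducible
#' given `seed`.
#'
#' @param ds A fully labeled [cell_dataset()]. Missing labels are an error
#'   here; use [disentangle_semisupervised()] for partially labeled data.
#' @param spec A [latent_spec()].
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size.
#' @param lr_net,lr_emb Adam learning rates for network parameters and for
#'   directly optimized embeddings (embedding tables and per-cell codes).
#' @param seed Integer seed controlling initialization, shuffling and noise.
#' @param verbose Print per-epoch losses.
#' @return A fitted model of class `latentsplit_model` whose `training_log`
#'   is a tibble of per-epoch loss components.
#' @seealso [counterfactual_predict()], [export_latent()],
#'   [fit_new_cell_embedding()]
#' @export
disentangle <- function(ds, spec = latent_spec(), epochs = 300L,
                        batch_size = 256L, lr_net = 1e-3, lr_emb = 5e-3,
                        seed = 1L, verbose = FALSE) {
  stopifnot(inherits(ds, "cell_dataset"), inherits(spec, "latent_spec"))
  for (a in ds$schema$attributes) {
    if (n_missing(ds, a$name) > 0L) {
      stop("attribute '", a$name, "' has missing values; ",
           "disentangle() requires full labels (see disentangle_semisupervised())")
    }
  }
  config <- default_train_config(epochs = epochs, batch_size = batch_size,
                                 lr_net = lr_net, lr_emb = lr_emb, seed = seed,
                                 verbose = verbose)
  train_impl(ds, spec, config, character(0))
}

#' @export
print.latentsplit_model <- function(x, ...) {
  cat("<latentsplit_model> ", length(x$cell_ids), " training cells, ",
      length(x$feature_names), " features, family = ", x$spec$family, "\n", sep = "")
  cat("  attributes: ", paste(schema_names(x$schema), collapse = ", "), "\n", sep = "")
  if (length(x$semisup) > 0L) {
    cat("  semi-supervised: ", paste(x$semisup, collapse = ", "), "\n", sep = "")
  }
  last <- utils::tail(x$training_log, 1L)
  cat(sprintf("  final loss %.4f after %d epochs (seed %d)\n",
              last$total, nrow(x$training_log), x$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# embedding accessors

#' Latent code of a categorical attribute label
#'
#' The code is a learned embedding-table row shared by every cell carrying
#' the label.
#'
#' @param model A fitted `latentsplit_model`.
#' @param attribute Attribute name (categorical).
#' @param label One or more category labels.
#' @return A `length(label)` x `n_latent_attr` matrix.
#' @export
embed_categorical <- function(model, attribute, label) {
  a <- schema_attr(model$schema, attribute)
  if (a$kind != "categorical") stop("attribute '", attribute, "' is not categorical")
  idx <- match(label, a$categories)
  if (anyNA(idx)) {
    stop("unknown label(s) for attribute '", attribute, "': ",
         paste(label[is.na(idx)], collapse = ", "))
  }
  out <- model$par$emb[[attribute]][idx, , drop = FALSE]
  rownames(out) <- label
  out
}

#' Latent code of an ordered attribute value
#'
#' Applies the attribute's trained encoder to a numeric feature vector (or a
#' matrix of rows); unseen values are handled by construction.
#'
#' @param model A fitted `latentsplit_model`.
#' @param attribute Attribute name (ordered).
#' @param features A vector of the declared dimension, or a matrix with one
#'   row per value. Must be finite.
#' @return A matrix of latent codes.
#' @export
embed_ordered <- function(model, attribute, features) {
  a <- schema_attr(model$schema, attribute)
  if (a$kind != "ordered") stop("attribute '", attribute, "' is not ordered")
  Fm <- if (is.matrix(features)) features else matrix(features, ncol = a$dim)
  if (ncol(Fm) != a$dim) stop("attribute '", attribute, "' expects dim ", a$dim)
  if (!all(is.finite(Fm))) {
    stop("ordered attribute '", attribute, "' received non-finite features; ",
         "impute or mark missing upstream")
  }
  mlp_forward(model$par$enc[[attribute]], Fm)
}

#' Unknown-attribute code of a training cell
#'
#' Returns the directly optimized per-cell code. With
#' `training_mode = TRUE` fresh Gaussian noise of scale `sigma` is added
#' (the regularization used during fitting); at evaluation the stored row is
#' returned exactly.
#'
#' @param model A fitted `latentsplit_model`.
#' @param cell_id One or more training-cell ids.
#' @param training_mode Apply the additive training noise.
#' @return A matrix of unknown-attribute codes.
#' @export
embed_unknown <- function(model, cell_id, training_mode = FALSE) {
  idx <- match(cell_id, model$cell_ids)
  if (anyNA(idx)) {
    stop("cell id(s) not in the training set: ",
         paste(cell_id[is.na(idx)], collapse = ", "),
         "; use fit_new_cell_embedding() for unseen cells")
  }
  Z <- model$par$Zu[idx, , drop = FALSE]
  if (isTRUE(training_mode) && model$spec$sigma > 0) {
    Z <- Z + matrix(rnorm(length(Z), sd = model$spec$sigma), nrow(Z), ncol(Z))
  }
  rownames(Z) <- cell_id
  Z
}

#' Assemble a decomposed latent
#'
#' @param z_y Named list of per-attribute codes (vectors or matrices with a
#'   common row count), keys matching the schema exactly.
#' @param z_u Unknown-attribute code (vector or matrix).
#' @param noise_applied Whether training noise was applied (informational).
#' @return An object of class `decomposed_latent`.
#' @export
decomposed_latent <- function(z_y, z_u, noise_applied = FALSE) {
  structure(list(z_y = z_y, z_u = z_u, noise_applied = noise_applied),
            class = "decomposed_latent")
}

#' Generate expression distributions from a decomposed latent
#'
#' Runs the generator decoder on the concatenated latent codes and returns
#' the full output-distribution parametrization. Deterministic given the
#' latent and the trained parameters.
#'
#' @param model A fitted `latentsplit_model`.
#' @param latent A [decomposed_latent()]; every schema attribute must have a
#'   code.
#' @param library_size Per-cell library size (count families). Defaults to
#'   the median training library size.
#' @return An [expression_distribution()].
#' @export
generate_expression <- function(model, latent, library_size = NULL) {
  stopifnot(inherits(latent, "decomposed_latent"))
  nms <- schema_names(model$schema)
  missing_codes <- setdiff(nms, names(latent$z_y))
  if (length(missing_codes) > 0L) {
    stop("latent lacks code(s) for attribute(s): ",
         paste(missing_codes, collapse = ", "))
  }
  as_mat <- function(v, d) if (is.matrix(v)) v else matrix(v, ncol = d)
  blocks <- lapply(nms, function(nm) as_mat(latent$z_y[[nm]], model$spec$n_latent_attr))
  Zu <- as_mat(latent$z_u, model$spec$n_latent_u)
  nr <- vapply(c(blocks, list(Zu)), nrow, integer(1))
  if (length(unique(nr)) != 1L) stop("latent blocks disagree on the number of cells")
  Z <- do.call(cbind, c(blocks, list(Zu)))
  if (count_family(model$spec$family) && is.null(library_size)) {
    library_size <- rep(stats::median(model$library_size), nrow(Z))
  }
  fw <- decoder_forward(model$par, model$spec, Z, library_size)
  make_distribution(model$par, model$spec, fw)
}

#' Completeness loss
#'
#' `NLL(x | G) + tau * MSE(x, mu)`, the reconstruction objective. The MSE is
#' averaged over features and computed on `log1p` scale for count families
#' and on raw values for gaussian.
#'
#' @param x Observation matrix or single-cell vector.
#' @param dist An [expression_distribution()].
#' @param tau MSE weight.
#' @return Per-cell loss values.
#' @export
completeness_loss <- function(x, dist, tau = 1) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  base <- nll(x, dist)
  mu <- dist$mean
  if (count_family(dist$family)) {
    mse <- rowSums((log1p(mu) - log1p(x))^2) / ncol(x)
  } else {
    mse <- rowSums((mu - x)^2) / ncol(x)
  }
  base + tau * mse
}

#' Minimality loss
#'
#' The activation penalty `lambda * ||z_u||^2` limiting the information the
#' unknown-attribute code can carry.
#'
#' @param z_u A code vector or a matrix of codes (one row per cell).
#' @param lambda Penalty weight.
#' @return Per-cell penalty values.
#' @export
minimality_loss <- function(z_u, lambda = 1) {
  z_u <- if (is.matrix(z_u)) z_u else matrix(z_u, nrow = 1L)
  if (!all(is.finite(z_u))) stop("z_u must be finite")
  drop(lambda * rowSums(z_u^2))
}

# latent assembly for a set of training cells using stored labels; no noise.
training_latent <- function(model, idx) {
  z_y <- list()
  for (a in model$schema$attributes) {
    nm <- a$name
    v <- model$labels[[nm]]
    if (a$kind == "categorical") {
      lab <- v[idx]
      if (anyNA(lab)) {
        lab[is.na(lab)] <- impute_categorical_labels(model, nm, idx[is.na(lab)])
      }
      z_y[[nm]] <- embed_categorical(model, nm, lab)
    } else {
      Fm <- v[idx, , drop = FALSE]
      miss <- apply(Fm, 1L, function(r) anyNA(r) || any(is.nan(r)))
      if (any(miss)) {
        Fm[miss, ] <- regress_ordered_features(model, nm, idx[miss])
      }
      z_y[[nm]] <- embed_ordered(model, nm, Fm)
    }
  }
  decomposed_latent(z_y, model$par$Zu[idx, , drop = FALSE], noise_applied = FALSE)
}

#' Reconstruct training cells
#'
#' Generates each cell's expression distribution from its stored labels and
#' unknown code, with noise disabled and the observed library sizes.
#'
#' @param model A fitted `latentsplit_model`.
#' @param cells Cell ids or indices (default: all training cells).
#' @return An [expression_distribution()].
#' @export
reconstruct <- function(model, cells = NULL) {
  idx <- resolve_cells(model, cells)
  latent <- training_latent(model, idx)
  lib <- if (!is.null(model$library_size)) model$library_size[idx] else NULL
  generate_expression(model, latent, lib)
}

resolve_cells <- function(model, cells) {
  if (is.null(cells)) return(seq_along(model$cell_ids))
  if (is.character(cells)) {
    idx <- match(cells, model$cell_ids)
    if (anyNA(idx)) stop("unknown cell id(s): ", paste(cells[is.na(idx)], collapse = ", "))
    return(idx)
  }
  as.integer(cells)
}

#' Fit the unknown-attribute code of a new cell
#'
#' Minimizes the single-cell completeness-plus-minimality objective over
#' `z_u` with every network parameter frozen, using L-BFGS with the analytic
#' gradient from a zero start (plus one small seeded restart, keeping the
#' better optimum). This extends the model to cells outside the training
#' set, which have no stored code by design (there is no amortized encoder).
#'
#' @param model A fitted `latentsplit_model`.
#' @param x Observed expression vector (length M) on the model's layer kind.
#' @param attribute_values Named list giving every attribute's value
#'   (category label, or numeric vector for ordered attributes).
#' @param max_iter L-BFGS iteration cap.
#' @param seed Seed for the restart initialization.
#' @return The fitted `z_u` vector, with the achieved loss as attribute
#'   `"loss"`.
#' @export
fit_new_cell_embedding <- function(model, x, attribute_values, max_iter = 500L,
                                   seed = 1L) {
  spec <- model$spec
  x <- matrix(as.numeric(x), nrow = 1L)
  if (ncol(x) != length(model$feature_names)) {
    stop("x must have length ", length(model$feature_names))
  }
  nms <- schema_names(model$schema)
  if (!setequal(names(attribute_values), nms)) {
    stop("attribute_values must name exactly: ", paste(nms, collapse = ", "))
  }
  z_y <- list()
  for (a in model$schema$attributes) {
    v <- attribute_values[[a$name]]
    z_y[[a$name]] <- if (a$kind == "categorical") {
      embed_categorical(model, a$name, as.character(v))
    } else {
      embed_ordered(model, a$name, as.numeric(v))
    }
  }
  Zy_fixed <- do.call(cbind, z_y[nms])
  lib <- if (count_family(spec$family)) max(sum(x), 1) else NULL

  objective <- function(z) {
    Z <- cbind(Zy_fixed, matrix(z, nrow = 1L))
    fw <- decoder_forward(model$par, spec, Z, lib, cache = TRUE)
    cl <- cmp_loss_and_grads(x, model$par, spec, fw)
    loss <- cl$nll + spec$tau * cl$mse + spec$lambda * sum(z^2)
    dec_g <- decoder_backward(model$par, spec, fw, cl$dmu, dS = cl$ds)
    gz <- dec_g$dZ[1L, ncol(Zy_fixed) + seq_len(spec$n_latent_u)] + 2 * spec$lambda * z
    list(loss = loss, grad = gz)
  }
  fn <- function(z) objective(z)$loss
  gr <- function(z) objective(z)$grad

  run <- function(z0) {
    stats::optim(z0, fn = fn, gr = gr, method = "L-BFGS-B",
                 control = list(maxit = max_iter, factr = 1e4))
  }
  best <- run(rep(0, spec$n_latent_u))
  set.seed(as.integer(seed))
  alt <- run(rnorm(spec$n_latent_u, sd = 0.1))
  if (alt$value < best$value) best <- alt
  structure(best$par, loss = best$value)
}
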