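#' @importFrom generics tidy glance
NULL

#' Tidy a fitted model
#'
#' One row per categorical attribute label (embedding-norm summary) plus
#' one summary row per ordered attribute and for the unknown embedding.
#'
#' @param x A `latentsplit_model`.
#' @param ... Unused.
#' @return A tibble with `attribute`, `label`, `kind` and `code_norm` (the
#'   Euclidean norm of the latent code; for the unknown embedding, the
#'   median per-cell norm).
#' @export
tidy.latentsplit_model <- function(x, ...) {
  rows <- list()
  for (a in x$schema$attributes) {
    if (a$kind == "categorical") {
      E <- x$par$emb[[a$name]]
      rows[[a$name]] <- tibble::tibble(
        attribute = a$name, label = a$categories, kind = "categorical",
        code_norm = sqrt(rowSums(E^2)))
    } else {
      rows[[a$name]] <- tibble::tibble(
        attribute = a$name, label = NA_character_, kind = "ordered",
        code_norm = NA_real_)
    }
  }
  rows[["unknown"]] <- tibble::tibble(
    attribute = "unknown", label = NA_character_, kind = "unknown",
    code_norm = stats::median(sqrt(rowSums(x$par$Zu^2))))
  dplyr::bind_rows(rows)
}

#' Glance at a fitted model
#'
#' @param x A `latentsplit_model`.
#' @param ... Unused.
#' @return A one-row tibble: data size, family, epochs, final loss
#'   components and the median unknown-code norm.
#' @export
glance.latentsplit_model <- function(x, ...) {
  last <- utils::tail(x$training_log, 1L)
  tibble::tibble(
    n_cells = length(x$cell_ids),
    n_features = length(x$feature_names),
    family = x$spec$family,
    epochs = nrow(x$training_log),
    loss_total = last$total, loss_nll = last$nll,
    loss_minimality = last$minimality,
    loss_classification = last$classification,
    median_zu_norm = stats::median(sqrt(rowSums(x$par$Zu^2))),
    seed = x$seed)
}

#' Summarize a counterfactual result per feature
#'
#' @param x A `counterfactual_result`.
#' @param ... Unused.
#' @return A tibble with per-feature mean observed expression, mean
#'   predicted expression under the manipulation, and the mean shift.
#' @export
tidy.counterfactual_result <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_names,
    mean_original = colMeans(x$x_original),
    mean_predicted = colMeans(x$mean),
    mean_shift = colMeans(x$mean) - colMeans(x$x_original))
}

#' Training-curve plot
#'
#' @param object A `latentsplit_model`.
#' @param ... Unused.
#' @return A ggplot of per-epoch loss components.
#' @export
autoplot.latentsplit_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$training_log, -"epoch",
                            names_to = "component", values_to = "loss")
  df <- dplyr::filter(df, !(.data$component == "classification" & .data$loss == 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_bw()
}

#' Volcano-style plot of a feature-state association table
#'
#' @param table A table from [associate_features()].
#' @param alpha FDR level marking significance.
#' @return A ggplot of mean paired difference vs adjusted significance.
#' @export
plot_association <- function(table, alpha = 0.05) {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$mean_diff,
                               y = -log10(pmax(.data$p_adjusted, 1e-300)),
                               colour = .data$p_adjusted <= alpha)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = paste0("FDR <= ", alpha)) +
    ggplot2::labs(x = "mean paired difference (counterfactual - observed)",
                  y = expression(-log[10] ~ "adjusted p")) +
    ggplot2::theme_bw()
}

#' Scatter plot of an exported latent representation
#'
#' @param latent A tibble from [export_latent()].
#' @param dims Two latent dimensions to display.
#' @return A labeled ggplot of the chosen dimensions.
#' @export
plot_latent <- function(latent, dims = c(1L, 2L)) {
  cols <- paste0("latent_", dims)
  ggplot2::ggplot(latent, ggplot2::aes(x = .data[[cols[1L]]],
                                       y = .data[[cols[2L]]],
                                       label = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::theme_bw()
}

#' Per-item uncertainty plot
#'
#' @param u A tibble from [knn_uncertainty()].
#' @return A ggplot of uncertainty by covariate group.
#' @export
plot_uncertainty <- function(u) {
  ggplot2::ggplot(u, ggplot2::aes(x = .data$covariate, y = .data$uncertainty)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "covariate", y = "k-NN uncertainty") +
    ggplot2::theme_bw()
}

#' Save a fitted model
#'
#' Serializes the full model state (parameter arrays, schema, spec,
#' training log, seed and training data references) into a single archive;
#' [read_model()] restores bit-identical inference.
#'
#' @param model A `latentsplit_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "latentsplit_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a fitted model saved with [write_model()]
#'
#' @param path File path.
#' @return The restored `latentsplit_model`.
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "latentsplit_model")) {
    stop("file does not contain a latentsplit model: ", path)
  }
  model
}

#' Export a counterfactual result to an annotated bundle
#'
#' Writes the predicted means as the bundle matrix with the original and
#' target attribute records in the cell annotations (prefixed `original_`
#' and `target_`) and the manipulation provenance in `uns.json`.
#'
#' @param cf A `counterfactual_result`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_counterfactual <- function(cf, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  x <- cf$mean
  dimnames(x) <- list(cf$cell_ids, cf$feature_names)
  sp <- Matrix::Matrix(x, sparse = TRUE)
  Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
  writeLines(cf$cell_ids, file.path(path, "matrix.rows.txt"))
  writeLines(cf$feature_names, file.path(path, "matrix.cols.txt"))
  obs <- dplyr::bind_cols(
    tibble::tibble(cell_id = cf$cell_ids),
    dplyr::rename_with(cf$original[-1L], ~ paste0("original_", .x)),
    dplyr::rename_with(cf$target[-1L], ~ paste0("target_", .x)))
  utils::write.csv(obs, file.path(path, "obs.csv"), row.names = FALSE, na = "")
  jsonlite::write_json(
    list(kind = "counterfactual", manipulated = cf$manipulated,
         family = cf$family, noise_applied = cf$noise_applied),
    file.path(path, "uns.json"), auto_unbox = TRUE)
  invisible(path)
}
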