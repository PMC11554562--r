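#' Declare a categorical attribute
#'
#' A categorical attribute takes one of a fixed set of unordered class labels
#' (cell type, infection status, spatial zone). Each category is represented
#' in the model by a learned embedding row shared by all cells carrying it.
#'
#' @param name Attribute name (unique within a schema).
#' @param categories Character vector of allowed class labels (length >= 1).
#' @return An attribute descriptor used by [attribute_schema()].
#' @export
#' @examples
#' cat_attr("status", c("control", "infected"))
cat_attr <- function(name, categories) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  categories <- as.character(categories)
  if (length(categories) < 1L) {
    stop("categorical attribute '", name, "' needs at least one category")
  }
  if (anyDuplicated(categories)) {
    stop("categorical attribute '", name, "' has duplicated categories")
  }
  structure(
    list(name = name, kind = "categorical", categories = categories,
         dim = length(categories)),
    class = "ls_attribute"
  )
}

#' Declare an ordered attribute
#'
#' An ordered attribute carries a numeric feature vector whose geometry is
#' meaningful (dosage, a precomputed chemical or gene-ontology embedding of a
#' perturbation). It is mapped to its latent code by a learned encoder, so
#' the model can generalize to unseen values.
#'
#' @param name Attribute name.
#' @param dim Dimension of the numeric feature vector (>= 1).
#' @return An attribute descriptor used by [attribute_schema()].
#' @export
#' @examples
#' ord_attr("dose", 1)
ord_attr <- function(name, dim) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L) stop("ordered attribute '", name, "' needs dim >= 1")
  structure(
    list(name = name, kind = "ordered", categories = NULL, dim = dim),
    class = "ls_attribute"
  )
}

#' Build an attribute schema
#'
#' The schema declares every known cell attribute, its kind (categorical or
#' ordered) and its value space. The number of attributes may be zero, in
#' which case all structure is captured by the unknown-attribute embedding.
#'
#' @param ... Attribute descriptors from [cat_attr()] and [ord_attr()].
#' @return An object of class `attribute_schema`.
#' @export
#' @examples
#' attribute_schema(cat_attr("cell_type", c("A549", "K562")), ord_attr("dose", 1))
attribute_schema <- function(...) {
  attrs <- list(...)
  if (length(attrs) == 1L && is.list(attrs[[1L]]) &&
      !inherits(attrs[[1L]], "ls_attribute")) {
    attrs <- attrs[[1L]]
  }
  ok <- vapply(attrs, inherits, logical(1), "ls_attribute")
  if (!all(ok)) stop("all arguments must be created with cat_attr() or ord_attr()")
  nms <- vapply(attrs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("attribute names must be unique; duplicated: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(attrs) <- nms
  structure(list(attributes = attrs), class = "attribute_schema")
}

#' @export
print.attribute_schema <- function(x, ...) {
  cat("<attribute_schema> ", length(x$attributes), " attribute(s)\n", sep = "")
  for (a in x$attributes) {
    if (a$kind == "categorical") {
      cat("  $ ", a$name, ": categorical {",
          paste(a$categories, collapse = ", "), "}\n", sep = "")
    } else {
      cat("  $ ", a$name, ": ordered, dim = ", a$dim, "\n", sep = "")
    }
  }
  invisible(x)
}

schema_names <- function(schema) names(schema$attributes)

schema_attr <- function(schema, name) {
  a <- schema$attributes[[name]]
  if (is.null(a)) {
    stop("unknown attribute '", name, "'; schema has: ",
         paste(schema_names(schema), collapse = ", "))
  }
  a
}

is_categorical <- function(schema, name) schema_attr(schema, name)$kind == "categorical"
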