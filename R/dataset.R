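#' Construct a cell dataset
#'
#' Bundles a cells x features expression matrix with per-cell attribute
#' annotations validated against an [attribute_schema()]. Cells are rows and
#' features are columns everywhere in the package.
#'
#' Missing attribute values use `NA` for categorical attributes and an
#' all-`NaN` row for ordered attributes; both are distinct from any legal
#' value and survive CSV round-trips (written as empty fields).
#'
#' @param x Numeric matrix, n cells x M features. For count likelihood
#'   families entries must be non-negative and finite.
#' @param attributes A data frame with one row per cell: a `cell_id` column
#'   (first column is used if no column is named `cell_id`) plus, per
#'   attribute, either a column named after the attribute (categorical, or
#'   ordered of dimension 1) or columns `name_1 ... name_d` (ordered of
#'   dimension d). May be `NULL` when the schema is empty.
#' @param schema An [attribute_schema()].
#' @param layer_kind Either `"raw_counts"` or `"log_normalized"`; declared by
#'   the caller, never inferred.
#' @return An object of class `cell_dataset`.
#' @export
cell_dataset <- function(x, attributes = NULL, schema = attribute_schema(),
                         layer_kind = c("raw_counts", "log_normalized")) {
  layer_kind <- match.arg(layer_kind)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); m <- ncol(x)
  if (n < 1L || m < 1L) stop("expression matrix must have >= 1 cell and >= 1 feature")
  cell_ids <- rownames(x)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  feature_names <- colnames(x)
  if (is.null(feature_names)) feature_names <- paste0("feature_", seq_len(m))
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids: ",
         paste(utils::head(unique(cell_ids[duplicated(cell_ids)]), 3), collapse = ", "))
  }
  if (!all(is.finite(x))) stop("expression matrix contains non-finite values")

  values <- parse_attribute_table(attributes, schema, cell_ids)

  ds <- structure(
    list(x = unname(x), cell_ids = cell_ids, feature_names = feature_names,
         attribute_values = values, schema = schema, layer_kind = layer_kind),
    class = "cell_dataset"
  )
  validate_dataset(ds)
  ds
}

parse_attribute_table <- function(attributes, schema, cell_ids) {
  n <- length(cell_ids)
  nms <- schema_names(schema)
  values <- list()
  if (is.null(attributes)) {
    # all-missing annotations
    for (a in schema$attributes) {
      values[[a$name]] <- if (a$kind == "categorical") {
        rep(NA_character_, n)
      } else {
        matrix(NaN, n, a$dim)
      }
    }
    return(values)
  }
  attributes <- as.data.frame(attributes, stringsAsFactors = FALSE)
  id_col <- if ("cell_id" %in% names(attributes)) "cell_id" else names(attributes)[1L]
  ids <- as.character(attributes[[id_col]])
  if (anyDuplicated(ids)) stop("duplicate cell ids in attribute table")
  idx <- match(cell_ids, ids)          # NA -> cell absent from table
  extra <- setdiff(ids, cell_ids)
  if (length(extra) > 0L) {
    warning(length(extra), " attribute-table row(s) match no cell in the matrix; ignored")
  }
  for (a in schema$attributes) {
    if (a$kind == "categorical") {
      if (!a$name %in% names(attributes)) {
        values[[a$name]] <- rep(NA_character_, n)
        next
      }
      v <- as.character(attributes[[a$name]])[idx]
      v[!is.na(v) & v == ""] <- NA_character_
      bad <- stats::na.omit(setdiff(unique(v), a$categories))
      if (length(bad) > 0L) {
        stop("attribute '", a$name, "' contains value(s) outside the schema: ",
             paste(bad, collapse = ", "))
      }
      values[[a$name]] <- v
    } else {
      cols <- if (a$dim == 1L && a$name %in% names(attributes)) {
        a$name
      } else {
        paste0(a$name, "_", seq_len(a$dim))
      }
      if (!all(cols %in% names(attributes))) {
        if (a$name %in% names(attributes) && is.matrix(attributes[[a$name]])) {
          mat <- attributes[[a$name]]
          if (ncol(mat) != a$dim) {
            stop("ordered attribute '", a$name, "': expected dim ", a$dim,
                 ", got ", ncol(mat))
          }
          values[[a$name]] <- apply(mat, 2, as.numeric)[idx, , drop = FALSE]
          next
        }
        if (!any(cols %in% names(attributes)) && !a$name %in% names(attributes)) {
          values[[a$name]] <- matrix(NaN, n, a$dim)
          next
        }
        stop("ordered attribute '", a$name, "': missing column(s) ",
             paste(setdiff(cols, names(attributes)), collapse = ", "))
      }
      mat <- vapply(cols, function(cc) as.numeric(attributes[[cc]]), numeric(nrow(attributes)))
      mat <- matrix(mat, nrow = nrow(attributes))
      values[[a$name]] <- mat[idx, , drop = FALSE]
    }
  }
  # cells absent from the table -> all-missing
  absent <- is.na(idx)
  if (any(absent)) {
    for (a in schema$attributes) {
      if (a$kind == "categorical") values[[a$name]][absent] <- NA_character_
      else values[[a$name]][absent, ] <- NaN
    }
  }
  values
}

validate_dataset <- function(ds) {
  n <- nrow(ds$x); m <- ncol(ds$x)
  if (length(ds$cell_ids) != n) stop("cell axis mismatch: ", length(ds$cell_ids), " ids vs ", n, " rows")
  if (length(ds$feature_names) != m) stop("feature axis mismatch: ", length(ds$feature_names), " names vs ", m, " columns")
  if (ds$layer_kind == "raw_counts" && any(ds$x < 0)) {
    stop("raw_counts layer contains negative entries")
  }
  for (a in ds$schema$attributes) {
    v <- ds$attribute_values[[a$name]]
    if (a$kind == "categorical") {
      if (length(v) != n) stop("attribute '", a$name, "' length mismatch along the cell axis")
    } else {
      if (!is.matrix(v) || nrow(v) != n || ncol(v) != a$dim) {
        stop("attribute '", a$name, "' must be an n x ", a$dim, " matrix")
      }
    }
  }
  invisible(ds)
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat("<cell_dataset> ", nrow(x$x), " cells x ", ncol(x$x), " features (",
      x$layer_kind, ")\n", sep = "")
  for (a in x$schema$attributes) {
    miss <- n_missing(x, a$name)
    cat("  attribute ", a$name, " (", a$kind, ")",
        if (miss > 0) paste0(", ", miss, " missing") else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.cell_dataset <- function(x) dim(x$x)

n_missing <- function(ds, name) {
  v <- ds$attribute_values[[name]]
  if (is.matrix(v)) sum(!stats::complete.cases(v) | apply(is.nan(v), 1, all)) else sum(is.na(v))
}

missing_mask <- function(ds, name) {
  v <- ds$attribute_values[[name]]
  if (is.matrix(v)) apply(v, 1, function(r) all(is.nan(r)) || anyNA(r)) else is.na(v)
}

#' Extract the attribute annotations as a tibble
#'
#' @param ds A [cell_dataset()].
#' @return A tibble with `cell_id` and one column per attribute (ordered
#'   attributes of dimension d expand to `name_1 ... name_d`).
#' @export
attribute_table <- function(ds) {
  out <- tibble::tibble(cell_id = ds$cell_ids)
  for (a in ds$schema$attributes) {
    v <- ds$attribute_values[[a$name]]
    if (a$kind == "categorical") {
      out[[a$name]] <- v
    } else if (a$dim == 1L) {
      out[[a$name]] <- as.numeric(v[, 1L])
    } else {
      for (j in seq_len(a$dim)) out[[paste0(a$name, "_", j)]] <- v[, j]
    }
  }
  out
}

subset_cells <- function(ds, idx) {
  if (is.character(idx)) {
    pos <- match(idx, ds$cell_ids)
    if (anyNA(pos)) stop("unknown cell id(s): ", paste(idx[is.na(pos)], collapse = ", "))
    idx <- pos
  }
  vals <- lapply(ds$schema$attributes, function(a) {
    v <- ds$attribute_values[[a$name]]
    if (is.matrix(v)) v[idx, , drop = FALSE] else v[idx]
  })
  names(vals) <- schema_names(ds$schema)
  structure(
    list(x = ds$x[idx, , drop = FALSE], cell_ids = ds$cell_ids[idx],
         feature_names = ds$feature_names, attribute_values = vals,
         schema = ds$schema, layer_kind = ds$layer_kind),
    class = "cell_dataset"
  )
}

#' Load a dataset from disk
#'
#' Accepts a dense matrix (`.csv` / `.tsv`, first column = cell id, header =
#' feature names), a MatrixMarket sparse triplet (`.mtx`, 1-based indices per
#' the MatrixMarket standard, with `<stem>.rows.txt` / `<stem>.cols.txt`
#' sidecars holding cell ids and feature names), or an annotated directory
#' bundle (`matrix.mtx` + `obs.csv` + `var.csv` + `uns.json`) as written by
#' [write_dataset()]. Cells present in the matrix but absent from the
#' attribute table get all-missing attributes.
#'
#' @param matrix_source Path to the matrix file or bundle directory.
#' @param attributes_source Path to an attribute CSV (header row, first
#'   column = cell id), a data frame, or `NULL` (bundle directories embed
#'   their own `obs.csv`).
#' @param schema An [attribute_schema()].
#' @param layer_kind Layer declaration; for bundles the value stored in
#'   `uns.json` is used when this is missing.
#' @return A validated [cell_dataset()].
#' @export
load_dataset <- function(matrix_source, attributes_source = NULL, schema = attribute_schema(),
                         layer_kind = c("raw_counts", "log_normalized")) {
  if (dir.exists(matrix_source)) {
    return(load_bundle(matrix_source, schema, layer_kind))
  }
  if (!file.exists(matrix_source)) stop("matrix source not found: ", matrix_source)
  layer_kind <- match.arg(layer_kind)
  ext <- tolower(tools::file_ext(matrix_source))
  if (ext %in% c("csv", "tsv")) {
    sep <- if (ext == "csv") "," else "\t"
    tab <- utils::read.table(matrix_source, header = TRUE, sep = sep,
                             row.names = 1, check.names = FALSE)
    x <- as.matrix(tab)
  } else if (ext == "mtx") {
    sp <- Matrix::readMM(matrix_source)
    x <- as.matrix(sp)
    stem <- sub("\\.mtx$", "", matrix_source)
    rows_f <- paste0(stem, ".rows.txt"); cols_f <- paste0(stem, ".cols.txt")
    rn <- if (file.exists(rows_f)) readLines(rows_f) else paste0("cell_", seq_len(nrow(x)))
    cn <- if (file.exists(cols_f)) readLines(cols_f) else paste0("feature_", seq_len(ncol(x)))
    if (length(rn) != nrow(x)) stop("cell axis mismatch: ", length(rn),
                                    " row names for ", nrow(x), " matrix rows")
    if (length(cn) != ncol(x)) stop("feature axis mismatch: ", length(cn),
                                    " column names for ", ncol(x), " matrix columns")
    dimnames(x) <- list(rn, cn)
  } else {
    stop("unsupported matrix format: .", ext, " (use .csv, .tsv, .mtx or a bundle directory)")
  }
  attrs <- read_attribute_source(attributes_source)
  cell_dataset(x, attrs, schema, layer_kind)
}

read_attribute_source <- function(src) {
  if (is.null(src) || is.data.frame(src)) return(src)
  if (!file.exists(src)) stop("attribute source not found: ", src)
  utils::read.csv(src, check.names = FALSE, stringsAsFactors = FALSE)
}

load_bundle <- function(dir, schema, layer_kind) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("bundle directory lacks matrix.mtx: ", dir)
  uns <- file.path(dir, "uns.json")
  if (missing(layer_kind) || length(layer_kind) > 1L) {
    layer_kind <- if (file.exists(uns)) jsonlite::read_json(uns)$layer_kind else "raw_counts"
  }
  obs <- file.path(dir, "obs.csv")
  attrs <- if (file.exists(obs)) utils::read.csv(obs, check.names = FALSE) else NULL
  load_dataset(mtx, attrs, schema, layer_kind)
}

#' Write a dataset to disk
#'
#' @param ds A [cell_dataset()].
#' @param path Output path: a directory for `format = "bundle"`, a file stem
#'   otherwise (extensions are appended).
#' @param format `"bundle"` (MTX + obs.csv + var.csv + uns.json), `"csv"`
#'   (dense) or `"mtx"` (sparse triplet with name sidecars).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("bundle", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "bundle") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    write_mtx(ds, file.path(path, "matrix"))
    utils::write.csv(attribute_table(ds), file.path(path, "obs.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(data.frame(feature = ds$feature_names),
                     file.path(path, "var.csv"), row.names = FALSE)
    jsonlite::write_json(list(layer_kind = ds$layer_kind), file.path(path, "uns.json"),
                         auto_unbox = TRUE)
  } else if (format == "csv") {
    tab <- as.data.frame(ds$x)
    colnames(tab) <- ds$feature_names
    tab <- cbind(cell_id = ds$cell_ids, tab)
    utils::write.csv(tab, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(attribute_table(ds), paste0(path, ".attributes.csv"),
                     row.names = FALSE, na = "")
  } else {
    write_mtx(ds, path)
    utils::write.csv(attribute_table(ds), paste0(path, ".attributes.csv"),
                     row.names = FALSE, na = "")
  }
  invisible(path)
}

write_mtx <- function(ds, stem) {
  sp <- Matrix::Matrix(ds$x, sparse = TRUE)
  Matrix::writeMM(sp, paste0(stem, ".mtx"))
  writeLines(ds$cell_ids, paste0(stem, ".rows.txt"))
  writeLines(ds$feature_names, paste0(stem, ".cols.txt"))
  invisible(stem)
}

#' Split a dataset by held-out attribute labels
#'
#' Builds an out-of-distribution split: cells carrying held-out labels form
#' the test set, the rest the training set. With `match = "any"` a cell is
#' held out when it matches the held-out set of *any* listed attribute; with
#' `match = "all"` it must match every listed attribute simultaneously
#' (a combination holdout, e.g. one unseen cell-line x dose pair).
#'
#' @param ds A [cell_dataset()].
#' @param held_out Named list: per attribute, the labels (categorical) or
#'   exact numeric values (ordered, dimension 1) to hold out. May be empty.
#' @param match `"any"` or `"all"` (see above).
#' @param fraction If not `NULL`, ignore `held_out` and draw a random test
#'   set of this fraction of cells.
#' @param seed Integer seed, used only in the random-fraction mode.
#' @return A list with elements `train` and `test`, both [cell_dataset()]s
#'   (a test set of zero cells is returned as `NULL`).
#' @export
split_dataset <- function(ds, held_out = list(), match = c("any", "all"),
                          fraction = NULL, seed = 1L) {
  match <- base::match.arg(match)
  n <- nrow(ds$x)
  if (!is.null(fraction)) {
    stopifnot(fraction >= 0, fraction < 1)
    n_test <- floor(fraction * n)
    set.seed(as.integer(seed))
    test <- sort(sample.int(n, n_test))
    in_test <- logical(n); in_test[test] <- TRUE
  } else {
    if (length(held_out) > 0L && is.null(names(held_out))) {
      stop("held_out must be a named list keyed by attribute name")
    }
    hits <- matrix(FALSE, n, max(1L, length(held_out)))
    j <- 0L
    for (nm in names(held_out)) {
      a <- schema_attr(ds$schema, nm)
      j <- j + 1L
      vals <- held_out[[nm]]
      if (a$kind == "categorical") {
        unknown <- setdiff(as.character(vals), a$categories)
        if (length(unknown) > 0L) {
          stop("held-out label(s) not in schema for '", nm, "': ",
               paste(unknown, collapse = ", "))
        }
        col <- ds$attribute_values[[nm]] %in% as.character(vals)
      } else {
        v <- ds$attribute_values[[nm]]
        if (a$dim != 1L) stop("held-out values are only supported for ordered attributes of dimension 1")
        col <- !is.nan(v[, 1L]) & v[, 1L] %in% as.numeric(vals)
      }
      if (!any(col)) warning("held-out value(s) for '", nm, "' match zero cells")
      hits[, j] <- col
    }
    in_test <- if (length(held_out) == 0L) {
      rep(FALSE, n)
    } else if (match == "any") {
      rowSums(hits[, seq_along(held_out), drop = FALSE]) > 0
    } else {
      rowSums(hits[, seq_along(held_out), drop = FALSE]) == length(held_out)
    }
  }
  train <- subset_cells(ds, which(!in_test))
  test <- if (any(in_test)) subset_cells(ds, which(in_test)) else NULL
  list(train = train, test = test)
}
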