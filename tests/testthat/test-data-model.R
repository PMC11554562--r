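test_that("dense CSV matrix and attribute table load into a validated dataset", {
  dir <- withr::local_tempdir()
  mat <- file.path(dir, "expr.csv")
  writeLines(c("cell_id,g1,g2", "c1,1,2", "c2,0,3", "c3,4,0"), mat)
  att <- file.path(dir, "attrs.csv")
  writeLines(c("cell_id,type", "c1,typeA", "c2,typeB", "c3,typeA"), att)
  schema <- attribute_schema(cat_attr("type", c("typeA", "typeB")))
  ds <- load_dataset(mat, att, schema)
  expect_equal(dim(ds), c(3L, 2L))
  expect_equal(length(ds$schema$attributes), 1L)
  expect_equal(ds$x[3, 1], 4)
  expect_equal(attribute_table(ds)$type, c("typeA", "typeB", "typeA"))
})

test_that("an MTX file with zero stored entries yields a dense zero matrix", {
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "m.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general", "5 4 0"), mtx)
  ds <- load_dataset(mtx, schema = attribute_schema())
  expect_equal(dim(ds), c(5L, 4L))
  expect_true(all(ds$x == 0))
})

test_that("labels outside the schema are rejected by name", {
  dir <- withr::local_tempdir()
  mat <- file.path(dir, "expr.csv")
  writeLines(c("cell_id,g1", "c1,1", "c2,2"), mat)
  att <- file.path(dir, "attrs.csv")
  writeLines(c("cell_id,type", "c1,typeA", "c2,typeZ"), att)
  schema <- attribute_schema(cat_attr("type", c("typeA", "typeB")))
  expect_error(load_dataset(mat, att, schema), "typeZ")
})

test_that("dimension mismatches name the offending axis", {
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "m.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general", "2 2 1", "1 1 3"), mtx)
  writeLines(c("a", "b", "c"), file.path(dir, "m.rows.txt"))
  writeLines(c("g1", "g2"), file.path(dir, "m.cols.txt"))
  expect_error(load_dataset(mtx), "cell axis")
})

test_that("duplicate cell ids are rejected at load", {
  x <- matrix(1:4, 2, 2, dimnames = list(c("c1", "c1"), c("g1", "g2")))
  expect_error(cell_dataset(x, NULL, attribute_schema()), "duplicate cell ids")
})

test_that("datasets round-trip exactly through every on-disk format", {
  ds <- tiny_dataset(seed = 3L)
  dir <- withr::local_tempdir()

  # annotated bundle
  write_dataset(ds, file.path(dir, "bundle"), format = "bundle")
  back <- load_dataset(file.path(dir, "bundle"), schema = tiny_schema())
  expect_identical(back$x, ds$x)
  expect_identical(back$attribute_values, ds$attribute_values)
  expect_identical(back$layer_kind, "raw_counts")

  # dense CSV
  write_dataset(ds, file.path(dir, "dense"), format = "csv")
  back <- load_dataset(file.path(dir, "dense.csv"),
                       file.path(dir, "dense.attributes.csv"), tiny_schema())
  expect_identical(back$x, ds$x)
  expect_identical(back$attribute_values, ds$attribute_values)

  # sparse MTX with sidecars
  write_dataset(ds, file.path(dir, "sparse"), format = "mtx")
  back <- load_dataset(file.path(dir, "sparse.mtx"),
                       file.path(dir, "sparse.attributes.csv"), tiny_schema())
  expect_identical(back$x, ds$x)
  expect_identical(back$cell_ids, ds$cell_ids)
})

test_that("missing attribute values survive a round-trip as the missing marker", {
  ds <- tiny_dataset()
  ds <- mask_labels(ds, "type", 0.4, seed = 2L)$dataset
  dir <- withr::local_tempdir()
  write_dataset(ds, file.path(dir, "b"), format = "bundle")
  back <- load_dataset(file.path(dir, "b"), schema = tiny_schema())
  expect_identical(back$attribute_values$type, ds$attribute_values$type)
})

test_that("cells absent from the attribute table get all-missing attributes", {
  x <- matrix(1:6, 3, 2, dimnames = list(c("c1", "c2", "c3"), c("g1", "g2")))
  attrs <- data.frame(cell_id = c("c1", "c3"), type = c("typeA", "typeB"))
  ds <- cell_dataset(x, attrs, attribute_schema(cat_attr("type", c("typeA", "typeB"))))
  expect_identical(ds$attribute_values$type, c("typeA", NA, "typeB"))
})

test_that("label holdout partitions the dataset exhaustively and disjointly", {
  ds <- tiny_dataset()
  sp <- split_dataset(ds, held_out = list(type = "typeB"))
  expect_equal(nrow(sp$train$x) + nrow(sp$test$x), nrow(ds$x))
  expect_length(intersect(sp$train$cell_ids, sp$test$cell_ids), 0L)
  expect_true(all(attribute_table(sp$test)$type == "typeB"))
  expect_true(all(attribute_table(sp$train)$type != "typeB"))

  # holding out nothing returns the full dataset
  sp0 <- split_dataset(ds, held_out = list())
  expect_equal(nrow(sp0$train$x), nrow(ds$x))
  expect_null(sp0$test)

  # combination holdout requires all listed attributes to match
  spc <- split_dataset(ds, held_out = list(type = "typeB", dose = 0.5),
                       match = "all")
  tabc <- attribute_table(spc$test)
  expect_true(all(tabc$type == "typeB" & tabc$dose == 0.5))
})

test_that("random splits are deterministic given the seed", {
  ds <- tiny_dataset(n = 100L)
  a <- split_dataset(ds, fraction = 0.2, seed = 42L)
  b <- split_dataset(ds, fraction = 0.2, seed = 42L)
  expect_identical(a$test$cell_ids, b$test$cell_ids)
  expect_equal(nrow(a$test$x), 20L)
})

test_that("holding out an unmatched label warns and contributes nothing", {
  ds <- tiny_dataset()
  ds$attribute_values$type <- rep("typeA", nrow(ds$x))
  expect_warning(sp <- split_dataset(ds, held_out = list(type = "typeB")),
                 "zero cells")
  expect_null(sp$test)
})
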