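test_that("expression TSV round-trips to 12 significant digits, order preserved", {
  x <- random_matrix(50, 10, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, path)
  x2 <- read_expression(path)
  expect_identical(dimnames(x2), dimnames(x))
  expect_equal(x2, x, tolerance = 1e-12)
})

test_that("tiny matrix loads with shape and ids intact", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1\tS2", "gA\t1.5\t2.5", "gB\t3\t4", "gC\t5\t6"), path)
  x <- read_expression(path)
  expect_equal(dim(x), c(3L, 2L))
  expect_identical(rownames(x), c("gA", "gB", "gC"))
  expect_identical(colnames(x), c("S1", "S2"))
  expect_equal(x["gB", "S2"], 4)
})

test_that("loader rejects missing cells, naming the location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1\tS2", "gA\t1.5\t", "gB\t3\t4"), path)
  expect_error(read_expression(path), "gA.*S2")
})

test_that("loader rejects duplicate feature and sample ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1\tS2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_expression(path), "duplicate feature")
  writeLines(c("feature_id\tS1\tS1", "gA\t1\t2", "gB\t3\t4"), path)
  expect_error(read_expression(path), "duplicate sample")
})

test_that("annotation CSV round-trips and keeps class counts", {
  co <- generate_cohort(synthetic_config(n_features = 10, effect_size_sd = 0,
                                         seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(co$annotations, path)
  ann <- read_annotations(path)
  expect_equal(nrow(ann), 115)
  expect_equal(sum(ann$phenotype == "NORMAL"), 26)
  expect_equal(sum(ann$phenotype == "IPF"), 89)
  expect_identical(ann$sample_id, co$annotations$sample_id)
  expect_equal(ann$fvc_pct, co$annotations$fvc_pct)
})

test_that("annotation parsing fills fields and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,phenotype,family_history,fvc_pct,dlco_pct,batch",
               "S1,IPF,FAMILIAL,80,70,b1",
               "S2,NORMAL,NONE,,,b2"), path)
  ann <- read_annotations(path)
  expect_equal(ann$fvc_pct[1], 80)
  expect_equal(ann$dlco_pct[1], 70)
  expect_true(is.na(ann$fvc_pct[2]))
  expect_identical(ann$severity, c("UNKNOWN", "UNKNOWN"))

  writeLines(c("sample_id,phenotype,family_history,fvc_pct,dlco_pct",
               "S1,IPF,SPORADIC,80,70", "S1,IPF,SPORADIC,60,50"), path)
  expect_error(read_annotations(path), "duplicate sample")
  writeLines(c("sample_id,phenotype,family_history,fvc_pct,dlco_pct",
               "S1,FIBROSIS,SPORADIC,80,70"), path)
  expect_error(read_annotations(path), "unknown phenotype")
})

test_that("signature model serialization round-trips and reloaded models predict identically", {
  co <- small_cohort(p = 120, effect = 1.5, seed = 21)
  y <- co$annotations$phenotype
  model <- suppressWarnings(
    train_signature(co$expression, y, k = 20, iterations = 1200,
                    burn_in = 200, seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  model2 <- load_model(path)

  expect_identical(model2$feature_ids, model$feature_ids)
  expect_equal(model2$gene_centers, model$gene_centers, tolerance = 1e-12)
  expect_equal(model2$loadings, model$loadings, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(model2$singular_values, model$singular_values, tolerance = 1e-12)
  expect_equal(model2$coefficient_summary$mean, model$coefficient_summary$mean,
               tolerance = 1e-12)
  expect_equal(model2$threshold, model$threshold)

  new_x <- random_matrix(120, 10, seed = 99)
  rownames(new_x) <- rownames(co$expression)
  p1 <- predict(model, new_x)
  p2 <- predict(model2, new_x)
  expect_equal(p2$probability, p1$probability, tolerance = 1e-12)
  expect_identical(p2$call, p1$call)
})

test_that("model loader rejects corrupt files and version mismatches", {
  co <- small_cohort(p = 80, effect = 1.5, seed = 22)
  model <- suppressWarnings(
    train_signature(co$expression, co$annotations$phenotype, k = 10,
                    iterations = 800, burn_in = 100, seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)

  txt <- paste(readLines(path), collapse = "\n")
  writeLines(substr(txt, 1, floor(nchar(txt) / 3)), path)  # truncate mid-stream
  expect_error(load_model(path), "corrupt")

  save_model(model, path)
  txt <- readLines(path)
  txt <- sub('"format_version":"1.0"', '"format_version":"99.0"', txt, fixed = TRUE)
  writeLines(txt, path)
  expect_error(load_model(path), "version mismatch")
})
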