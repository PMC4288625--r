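# End-to-end orchestration: split -> explore -> tune -> train -> predict ->
# evaluate, with every artifact written to disk and reproducible from the
# config alone.

#' Configuration for a full pipeline run
#'
#' @param matrix_path TSV expression matrix (features x samples).
#' @param annotations_path CSV sample annotations.
#' @param out_dir output directory (created if absent).
#' @param split_offset 1-based starting position of the every-third
#'   validation assignment (see [split_cohorts()]).
#' @param k_min,k_max signature-size range swept by [tune_k()].
#' @param iterations,burn_in MCMC settings for the tuning sweeps; the final
#'   model is refit at `final_iterations`/`final_burn_in`.
#' @param final_iterations,final_burn_in MCMC settings for the final model.
#' @param seed base RNG seed (required).
#' @param threshold_source `"youden"` (computed on validation predictions) or
#'   a fixed numeric threshold in [0, 1].
#' @param cov_top_fraction CoV filter fraction used in the exploratory stage.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(matrix_path, annotations_path, out_dir,
                            split_offset = 3, k_min = 50, k_max = 250,
                            iterations = 2000, burn_in = 500,
                            final_iterations = 6000, final_burn_in = 1000,
                            seed, threshold_source = "youden",
                            cov_top_fraction = 0.10) {
  if (missing(seed)) stop("seed is required")
  if (!file.exists(matrix_path)) stop("no such file: ", matrix_path)
  if (!file.exists(annotations_path)) stop("no such file: ", annotations_path)
  if (is.numeric(threshold_source) &&
      !(threshold_source >= 0 && threshold_source <= 1)) {
    stop("fixed threshold must lie in [0, 1]")
  }
  structure(list(matrix_path = matrix_path,
                 annotations_path = annotations_path,
                 out_dir = out_dir, split_offset = split_offset,
                 k_min = k_min, k_max = k_max,
                 iterations = iterations, burn_in = burn_in,
                 final_iterations = final_iterations,
                 final_burn_in = final_burn_in, seed = as.integer(seed),
                 threshold_source = threshold_source,
                 cov_top_fraction = cov_top_fraction),
            class = "run_config")
}

#' Run the whole signature pipeline
#'
#' Stages: severity classification and stratified systematic split; CoV
#' filter + PCA of the full cohort (exploratory); nested LOOCV tuning of the
#' signature size on the training cohort; final model training at the chosen
#' size; prediction of the held-out validation cohort; performance report.
#' Validation samples never enter training (the predict stage refuses any
#' overlap). Artifacts written under `config$out_dir`: `curve.tsv`,
#' `model.json`, `preds.tsv`, `report.json`, `pca.tsv`, `run_log.txt`.
#' Re-running the same config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the split, tuning curve, model, validation
#'   predictions and performance report.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  x <- stage("load", read_expression(config$matrix_path))
  ann <- stage("load", read_annotations(config$annotations_path))
  if (!setequal(ann$sample_id, colnames(x))) {
    stop("pipeline stage 'load' failed: annotation and matrix sample ids differ")
  }
  ann <- ann[match(colnames(x), ann$sample_id), ]

  ann <- stage("split", annotate_severity(ann))
  split <- stage("split", split_cohorts(ann, offset = config$split_offset))
  ann <- apply_split(ann, split)

  filtered <- stage("explore", cov_filter(x, config$cov_top_fraction))
  pca <- stage("explore", run_pca(filtered, 2))
  pca_tab <- data.frame(sample_id = rownames(pca$sample_scores),
                        pc1 = pca$sample_scores[, 1],
                        pc2 = pca$sample_scores[, 2])
  utils::write.table(pca_tab, file.path(config$out_dir, "pca.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tr_ids <- split$training_ids
  va_ids <- split$validation_ids
  x_tr <- x[, tr_ids, drop = FALSE]
  y_tr <- ann$phenotype[match(tr_ids, ann$sample_id)]

  tuning <- stage("tune", tune_k(x_tr, y_tr, k_min = config$k_min,
                                 k_max = config$k_max,
                                 iterations = config$iterations,
                                 burn_in = config$burn_in,
                                 seed = config$seed))
  utils::write.table(tuning$curve, file.path(config$out_dir, "curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  model <- stage("train", train_signature(
    x_tr, y_tr, k = tuning$chosen_k,
    iterations = config$final_iterations, burn_in = config$final_burn_in,
    seed = config$seed))

  if (length(intersect(tr_ids, va_ids)) > 0) {
    stop("pipeline stage 'predict' failed: validation overlaps training")
  }
  preds <- stage("predict", stats::predict(model, x[, va_ids, drop = FALSE]))
  y_va <- ann$phenotype[match(va_ids, ann$sample_id)]

  threshold <- if (identical(config$threshold_source, "youden")) NULL else config$threshold_source
  report <- stage("evaluate", evaluate_performance(preds$probability, y_va,
                                                   threshold = threshold))
  model$threshold <- report$threshold
  preds$call <- ifelse(preds$probability >= report$threshold, "IPF", "NORMAL")

  save_model(model, file.path(config$out_dir, "model.json"))
  utils::write.table(preds, file.path(config$out_dir, "preds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  log_lines <- c(
    paste("bprsig", as.character(utils::packageVersion("bprsig"))),
    paste("seed:", config$seed),
    paste("config_hash:", config_hash(cfg_for_hash)),
    paste("chosen_k:", tuning$chosen_k),
    paste("threshold:", report$threshold, paste0("(", report$threshold_source, ")")),
    paste("training_n:", length(tr_ids), "validation_n:", length(va_ids))
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(annotations = ann, split = split, pca = pca,
                 tuning = tuning, model = model, predictions = preds,
                 report = report))
}

# Stable short hash of the run configuration (order-independent content hash
# built on the serialized key=value lines; no extra dependencies).
config_hash <- function(config) {
  txt <- paste(names(config),
               vapply(config, function(v) paste(format(v, digits = 15), collapse = ","),
                      character(1)),
               sep = "=", collapse = ";")
  raw <- utf8ToInt(txt)
  h <- 5381
  for (c in raw) h <- (h * 33 + c) %% 2^31
  sprintf("%08x", as.integer(h))
}
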