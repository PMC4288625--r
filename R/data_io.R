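# Readers and writers for expression matrices, sample annotations, and
# serialized signature models. All validation happens here, at the boundary:
# downstream code may assume clean inputs.

#' Read a normalized expression matrix
#'
#' Expects a tab-delimited file: first column feature ids, header row sample
#' ids, remaining cells normalized log2 intensities. Missing, non-numeric or
#' duplicated entries are hard errors (no silent imputation); row and column
#' order are preserved exactly as found in the file.
#'
#' @param path path to a TSV file (features x samples).
#' @return numeric matrix with feature ids as rownames, sample ids as colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("expression file needs a feature-id column plus at least one sample")
  feature_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id(s): ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("missing or non-numeric value at feature '%s', sample '%s'",
                 feature_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  }
  dimnames(vals) <- list(feature_ids, sample_ids)
  vals
}

#' Write an expression matrix as TSV
#'
#' @param x numeric matrix, features x samples, with dimnames.
#' @param path output path.
#' @param digits significant digits to keep (default 15, sufficient for a
#'   12-significant-digit round trip).
#' @export
write_expression <- function(x, path, digits = 15) {
  check_expression_matrix(x)
  df <- data.frame(feature_id = rownames(x),
                   signif(x, digits), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample clinical annotations
#'
#' Expects a CSV with columns `sample_id`, `phenotype` (IPF/NORMAL),
#' `family_history` (SPORADIC/FAMILIAL/NONE), `fvc_pct`, `dlco_pct`
#' (empty = not measured), and optionally `batch`, `severity`, `cohort`.
#' Severity is left `UNKNOWN` unless present in the file; apply
#' [classify_severity()] to fill it from pulmonary function.
#'
#' @param path path to a CSV file.
#' @return data.frame with one row per sample.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = ",", check.names = FALSE,
                          colClasses = "character", quote = "")
  required <- c("sample_id", "phenotype", "family_history", "fvc_pct", "dlco_pct")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0) {
    stop("annotation file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ann <- data.frame(
    sample_id = df$sample_id,
    phenotype = toupper(trimws(df$phenotype)),
    family_history = toupper(trimws(df$family_history)),
    fvc_pct = suppressWarnings(as.numeric(df$fvc_pct)),
    dlco_pct = suppressWarnings(as.numeric(df$dlco_pct)),
    batch = if ("batch" %in% colnames(df)) df$batch else NA_character_,
    severity = if ("severity" %in% colnames(df)) toupper(trimws(df$severity)) else "UNKNOWN",
    cohort = if ("cohort" %in% colnames(df)) toupper(trimws(df$cohort)) else "UNASSIGNED",
    stringsAsFactors = FALSE
  )
  validate_annotations(ann)
}

#' Write sample annotations as CSV
#'
#' @param ann annotation data.frame as returned by [read_annotations()].
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

validate_annotations <- function(ann) {
  if (anyDuplicated(ann$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "))
  }
  bad_ph <- setdiff(unique(ann$phenotype), PHENOTYPE_LEVELS)
  if (length(bad_ph) > 0) stop("unknown phenotype label(s): ", paste(bad_ph, collapse = ", "))
  bad_fh <- setdiff(unique(ann$family_history), FAMILY_LEVELS)
  if (length(bad_fh) > 0) stop("unknown family_history label(s): ", paste(bad_fh, collapse = ", "))
  bad_sev <- setdiff(unique(ann$severity), SEVERITY_LEVELS)
  if (length(bad_sev) > 0) stop("unknown severity label(s): ", paste(bad_sev, collapse = ", "))
  bad_co <- setdiff(unique(ann$cohort), COHORT_LEVELS)
  if (length(bad_co) > 0) stop("unknown cohort label(s): ", paste(bad_co, collapse = ", "))
  if (any(ann$phenotype == "NORMAL" & ann$family_history != "NONE")) {
    stop("NORMAL samples must have family_history = NONE")
  }
  neg <- !is.na(ann$fvc_pct) & ann$fvc_pct < 0 | !is.na(ann$dlco_pct) & ann$dlco_pct < 0
  if (any(neg)) stop("negative pulmonary function value for sample(s): ",
                     paste(ann$sample_id[neg], collapse = ", "))
  ann
}

#' Save a fitted signature model
#'
#' Serializes the model to versioned, human-readable JSON. Doubles are written
#' at full precision, so a load of a save reproduces ids exactly and reals to
#' at least 12 significant digits.
#'
#' @param model a `signature_model` (see [train_signature()]).
#' @param path output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    feature_ids = model$feature_ids,
    gene_centers = model$gene_centers,
    loadings = model$loadings,
    singular_values = model$singular_values,
    coefficient_summary = model$coefficient_summary,
    posterior_draws = model$posterior_draws,
    threshold = model$threshold,
    training_metadata = model$training_metadata
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Load a signature model saved by [save_model()]
#'
#' @param path path to the JSON model file.
#' @return a `signature_model` object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop("corrupt model file: ", conditionMessage(e)))
  if (is.null(payload$format_version)) stop("corrupt model file: no format_version field")
  if (!identical(as.character(payload$format_version), MODEL_FORMAT_VERSION)) {
    stop("model format version mismatch: file has ", payload$format_version,
         ", this build reads ", MODEL_FORMAT_VERSION)
  }
  cs <- payload$coefficient_summary
  if (!is.data.frame(cs)) stop("corrupt model file: bad coefficient_summary")
  draws <- payload$posterior_draws
  if (!is.null(draws)) draws <- matrix(as.numeric(draws), nrow = nrow(draws))
  new_signature_model(
    feature_ids = as.character(payload$feature_ids),
    gene_centers = as.numeric(payload$gene_centers),
    loadings = matrix(as.numeric(payload$loadings), ncol = 2),
    singular_values = as.numeric(payload$singular_values),
    coefficient_summary = cs,
    posterior_draws = draws,
    threshold = as.numeric(payload$threshold),
    training_metadata = payload$training_metadata
  )
}
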