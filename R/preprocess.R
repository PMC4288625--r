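# Severity classification from pulmonary function, coefficient-of-variation
# filtering, and the stratified systematic training/validation split.

#' Severity cutoffs on percent-predicted pulmonary function
#'
#' Mild disease requires FVC >= `mild_fvc_min` AND DLCO >= `mild_dlco_min`
#' (both in % predicted); severe disease requires FVC <= `severe_fvc_max` AND
#' DLCO <= `severe_dlco_max`. Everything else is moderate.
#'
#' @param mild_fvc_min,mild_dlco_min lower bounds for mild disease.
#' @param severe_fvc_max,severe_dlco_max upper bounds for severe disease.
#' @return a `severity_rule` list.
#' @export
severity_rule <- function(mild_fvc_min = 75, mild_dlco_min = 65,
                          severe_fvc_max = 50, severe_dlco_max = 35) {
  if (mild_fvc_min <= severe_fvc_max || mild_dlco_min <= severe_dlco_max) {
    stop("mild cutoffs must exceed severe cutoffs")
  }
  structure(list(mild_fvc_min = mild_fvc_min, mild_dlco_min = mild_dlco_min,
                 severe_fvc_max = severe_fvc_max, severe_dlco_max = severe_dlco_max),
            class = "severity_rule")
}

#' Classify disease severity from pulmonary function
#'
#' When both measures are available, mild requires both to meet the mild
#' cutoffs and severe requires both to meet the severe cutoffs (boundary
#' values inclusive). When only one measure is available, that measure's
#' cutoffs alone decide. All other combinations are moderate; severity is
#' unknown only when both measures are absent.
#'
#' @param fvc_pct,dlco_pct percent-predicted values; `NA` = not measured.
#'   Vectorized, recycled to common length.
#' @param rule a [severity_rule()].
#' @return character vector in MILD / MODERATE / SEVERE / UNKNOWN.
#' @export
classify_severity <- function(fvc_pct, dlco_pct, rule = severity_rule()) {
  n <- max(length(fvc_pct), length(dlco_pct))
  fvc <- rep_len(as.numeric(fvc_pct), n)
  dlco <- rep_len(as.numeric(dlco_pct), n)
  if (any(fvc < 0, na.rm = TRUE) || any(dlco < 0, na.rm = TRUE)) {
    stop("percent-predicted pulmonary function cannot be negative")
  }
  mild <- ifelse(is.na(fvc), TRUE, fvc >= rule$mild_fvc_min) &
          ifelse(is.na(dlco), TRUE, dlco >= rule$mild_dlco_min)
  severe <- ifelse(is.na(fvc), TRUE, fvc <= rule$severe_fvc_max) &
            ifelse(is.na(dlco), TRUE, dlco <= rule$severe_dlco_max)
  out <- rep("MODERATE", n)
  out[mild] <- "MILD"
  out[severe] <- "SEVERE"
  out[is.na(fvc) & is.na(dlco)] <- "UNKNOWN"
  out
}

#' Fill the severity column of an annotation table
#'
#' @param ann annotation data.frame.
#' @param rule a [severity_rule()].
#' @return the annotations with `severity` recomputed from FVC/DLCO.
#' @export
annotate_severity <- function(ann, rule = severity_rule()) {
  ann$severity <- classify_severity(ann$fvc_pct, ann$dlco_pct, rule)
  ann
}

#' Keep the most variable features by coefficient of variation
#'
#' Computes CoV = sd / |mean| per feature across all samples (on the
#' normalized log2 scale as supplied) and retains exactly
#' `ceiling(top_fraction * nrow(x))` features with the largest CoV. Retained
#' features are ordered by descending CoV, ties broken by feature id.
#'
#' @param x expression matrix, features x samples.
#' @param top_fraction fraction of features to keep, in (0, 1).
#' @return the filtered expression matrix.
#' @export
cov_filter <- function(x, top_fraction = 0.10) {
  check_expression_matrix(x)
  if (!(top_fraction > 0 && top_fraction < 1)) stop("top_fraction must be in (0, 1)")
  mu <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  zero_mean <- mu == 0 & s > 0
  if (any(zero_mean)) {
    stop("coefficient of variation undefined (zero mean, nonzero sd) for feature(s): ",
         paste(rownames(x)[zero_mean], collapse = ", "))
  }
  cov <- ifelse(s == 0, 0, s / abs(mu))
  keep_n <- ceiling(top_fraction * nrow(x))
  ord <- order(-cov, rownames(x))
  x[ord[seq_len(keep_n)], , drop = FALSE]
}

#' Stratified systematic training/validation split
#'
#' Samples are stratified into healthy controls plus the four severity groups
#' of cases. Within each stratum samples are ordered by sample id and every
#' third one (1-based positions `offset`, `offset + 3`, ...) is assigned to
#' the validation cohort; the remainder form the training cohort. The split
#' is a pure function of the annotation content, so re-running reproduces it.
#'
#' @param ann annotation data.frame with `phenotype` and `severity` filled.
#' @param offset 1-based position of the first validation sample within each
#'   stratum, one of 1, 2, 3 (default 3, i.e. positions 3, 6, 9, ...).
#' @return a `cohort_split` list with `training_ids`, `validation_ids`, and
#'   `strata` (ordered ids per stratum).
#' @export
split_cohorts <- function(ann, offset = 3) {
  if (nrow(ann) == 0) stop("no samples to split")
  if (!offset %in% 1:3) stop("offset must be 1, 2 or 3")
  if (any(ann$phenotype == "IPF" & is.na(ann$severity))) {
    stop("all IPF samples need a severity label before splitting")
  }
  stratum <- ifelse(ann$phenotype == "NORMAL", "NORMAL",
                    paste0("IPF_", ann$severity))
  strata <- split(ann$sample_id, stratum)
  strata <- lapply(strata, sort)
  validation_ids <- character(0)
  for (ids in strata) {
    if (length(ids) < offset) next
    pos <- seq.int(offset, length(ids), by = 3)
    validation_ids <- c(validation_ids, ids[pos])
  }
  training_ids <- sort(setdiff(ann$sample_id, validation_ids))
  structure(list(training_ids = training_ids,
                 validation_ids = sort(validation_ids),
                 strata = strata,
                 offset = offset),
            class = "cohort_split")
}

#' Record a cohort split in the annotation table
#'
#' @param ann annotation data.frame.
#' @param split a [split_cohorts()] result.
#' @return annotations with the `cohort` column set.
#' @export
apply_split <- function(ann, split) {
  stopifnot(inherits(split, "cohort_split"))
  ann$cohort <- ifelse(ann$sample_id %in% split$validation_ids, "VALIDATION",
                       ifelse(ann$sample_id %in% split$training_ids, "TRAINING",
                              "UNASSIGNED"))
  ann
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("Stratified systematic cohort split (offset ", x$offset, ")\n", sep = "")
  cat("  training:  ", length(x$training_ids), " samples\n", sep = "")
  cat("  validation:", length(x$validation_ids), "samples\n")
  for (nm in names(x$strata)) {
    cat(sprintf("  stratum %-13s n = %d\n", nm, length(x$strata[[nm]])))
  }
  invisible(x)
}
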