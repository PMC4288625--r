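# Shared input coercion and validation helpers.

#' Coerce phenotype labels to a 0/1 indicator of disease
#'
#' Accepts a numeric/logical 0-1 vector, a factor, or a character vector
#' using the `"IPF"` / `"NORMAL"` phenotype codes. Disease (IPF) maps to 1.
#'
#' @param labels vector of class labels.
#' @return integer vector of 0 (normal) and 1 (IPF).
#' @export
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), PHENOTYPE_LEVELS)
    if (length(bad) > 0) {
      stop("unknown phenotype label(s): ", paste(bad, collapse = ", "))
    }
    return(as.integer(labels == "IPF"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0/1")
    }
    return(as.integer(labels))
  }
  stop("cannot interpret labels of class ", class(labels)[1])
}

check_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must carry feature ids (rownames) and sample ids (colnames)")
  }
  if (anyDuplicated(rownames(x))) stop(what, ": duplicate feature ids")
  if (anyDuplicated(colnames(x))) stop(what, ": duplicate sample ids")
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: non-finite value at feature '%s', sample '%s'",
                 what, rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
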