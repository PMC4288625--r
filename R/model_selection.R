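# Nested leave-one-out cross-validation over signature sizes, scored by ROC
# AUC and sum of deviance, with the max-AUC -> min-SOD -> min-k selection rule.

#' Nested LOOCV predicted probabilities across signature sizes
#'
#' For each held-out sample, feature selection, the metagene factorization
#' and the probit fit are all redone on the remaining samples (fully nested:
#' the held-out label never informs selection), and the held-out sample is
#' projected and predicted. Because the per-fold t-ranking is shared across
#' sizes, a whole vector of `k_values` is swept in one pass. Fold f uses
#' seed `seed + f` so chains are independent but reproducible.
#'
#' @param x expression matrix, features x samples.
#' @param labels class labels (see [as_binary_labels()]).
#' @param k_values integer vector of signature sizes.
#' @param iterations,burn_in MCMC settings per fold (defaults sized for
#'   tuning sweeps).
#' @param seed base RNG seed.
#' @param fixed_features optional character vector: skip per-fold selection
#'   and use these features in every fold. This deliberately leaks the
#'   selection step and exists to demonstrate/diagnose selection bias; never
#'   use it to report performance.
#' @return samples x length(k_values) matrix of LOOCV probabilities.
#' @export
loocv_sweep <- function(x, labels, k_values, iterations = 2000, burn_in = 500,
                        seed, fixed_features = NULL) {
  check_expression_matrix(x)
  y <- as_binary_labels(labels)
  n <- ncol(x)
  if (n < 6 || sum(y == 1) < 3 || sum(y == 0) < 3) {
    stop("LOOCV needs at least 6 samples with 3 per class")
  }
  k_values <- as.integer(k_values)
  if (any(k_values < 2) || any(k_values > nrow(x))) {
    stop("k_values must lie in 2..n_features")
  }
  probs <- matrix(NA_real_, n, length(k_values),
                  dimnames = list(colnames(x), paste0("k", k_values)))
  for (f in seq_len(n)) {
    x_tr <- x[, -f, drop = FALSE]
    y_tr <- y[-f]
    if (sum(y_tr == 1) < 2 || sum(y_tr == 0) < 2) {
      stop("fold ", f, " leaves a class with < 2 samples")
    }
    if (is.null(fixed_features)) {
      t_tr <- t_statistics(x_tr, y_tr)
      ranking <- rownames(x_tr)[order(-abs(t_tr), rownames(x_tr))]
    } else {
      ranking <- fixed_features
    }
    for (j in seq_along(k_values)) {
      k <- k_values[j]
      feats <- ranking[seq_len(k)]
      fac <- factorize(x_tr[feats, , drop = FALSE])
      post <- fit_bpr(fac$factor_scores, y_tr, iterations = iterations,
                      burn_in = burn_in, seed = seed + f)
      f_new <- project(fac, x[feats, f])
      lin <- cbind(1, f_new) %*% t(post$draws)
      probs[f, j] <- mean(stats::pnorm(lin))
    }
  }
  probs
}

#' Nested LOOCV probabilities for one signature size
#'
#' @inheritParams loocv_sweep
#' @param k signature size.
#' @return numeric vector of length n(samples) of out-of-fold probabilities.
#' @export
loocv_probabilities <- function(x, labels, k, iterations = 2000, burn_in = 500,
                                seed, fixed_features = NULL) {
  drop(loocv_sweep(x, labels, k, iterations = iterations, burn_in = burn_in,
                   seed = seed, fixed_features = fixed_features))
}

#' Sum of deviance between predicted and ideal probabilities
#'
#' Aggregate discrepancy between each sample's predicted probability and the
#' ideal probability (1) of its true phenotype. The default is the absolute
#' form SOD = sum |y - p|; `method = "binomial"` gives the deviance
#' -2 sum [y log p + (1-y) log(1-p)] (probabilities clipped at 1e-12).
#'
#' @param probs predicted probabilities in [0, 1].
#' @param labels class labels (see [as_binary_labels()]).
#' @param method `"absolute"` (default) or `"binomial"`.
#' @return non-negative scalar.
#' @export
sum_of_deviance <- function(probs, labels, method = c("absolute", "binomial")) {
  method <- match.arg(method)
  y <- as_binary_labels(labels)
  if (length(probs) != length(y)) stop("probs and labels differ in length")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (method == "absolute") {
    sum(abs(y - probs))
  } else {
    p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
    -2 * sum(y * log(p) + (1 - y) * log(1 - p))
  }
}

#' Choose a signature size by nested LOOCV
#'
#' Sweeps every size in `k_min:k_max`, computing nested LOOCV probabilities,
#' ROC AUC and sum of deviance per size. The chosen size maximizes AUC; among
#' AUC maximizers it minimizes SOD; any remaining tie goes to the smallest
#' size.
#'
#' @inheritParams loocv_sweep
#' @param k_min,k_max inclusive size range (defaults 50 and 250).
#' @param sod_method passed to [sum_of_deviance()].
#' @return a `tuning_curve`: `curve` data.frame (k, auc, sod, chosen),
#'   `chosen_k`, and `probabilities` (samples x sizes).
#' @export
tune_k <- function(x, labels, k_min = 50, k_max = 250, iterations = 2000,
                   burn_in = 500, seed, sod_method = "absolute") {
  if (k_max < k_min) stop("k_max must be >= k_min")
  if (k_max > nrow(x)) stop("k_max exceeds the number of features")
  y <- as_binary_labels(labels)
  k_values <- k_min:k_max
  probs <- loocv_sweep(x, labels, k_values, iterations = iterations,
                       burn_in = burn_in, seed = seed)
  auc <- apply(probs, 2, roc_auc, labels = y)
  sod <- apply(probs, 2, sum_of_deviance, labels = y, method = sod_method)
  chosen_k <- select_k(k_values, auc, sod)
  curve <- data.frame(k = k_values, auc = unname(auc), sod = unname(sod),
                      chosen = k_values == chosen_k)
  structure(list(curve = curve, chosen_k = chosen_k, probabilities = probs),
            class = "tuning_curve")
}

#' The size-selection rule on precomputed scores
#'
#' Pure function of the per-size AUC and SOD vectors: maximal AUC, then
#' minimal SOD, then minimal k.
#'
#' @param k_values signature sizes.
#' @param auc,sod score vectors aligned with `k_values`.
#' @return the chosen element of `k_values`.
#' @export
select_k <- function(k_values, auc, sod) {
  stopifnot(length(k_values) == length(auc), length(auc) == length(sod))
  best <- which(auc == max(auc))
  best <- best[sod[best] == min(sod[best])]
  k_values[best[which.min(k_values[best])]]
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat("Nested LOOCV tuning over k =", min(x$curve$k), "..", max(x$curve$k), "\n")
  i <- which(x$curve$chosen)
  cat(sprintf("  chosen k = %d (AUC %.3f, SOD %.3f)\n",
              x$chosen_k, x$curve$auc[i], x$curve$sod[i]))
  invisible(x)
}
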