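# The signature's mathematical core: Student-t feature ranking, two-metagene
# SVD summarization with out-of-sample projection, and Bayesian probit
# regression fit by the Albert-Chib data-augmentation Gibbs sampler.

#' Rank features by two-sample Student t-statistics
#'
#' Pooled-variance two-sample t per feature, disease (label 1) minus control
#' (label 0); the top `k` features by |t| are returned in descending |t|
#' order, ties broken by feature id. The pooled standard deviation is floored
#' at 1e-8 so degenerate zero-variance features rank deterministically.
#'
#' @param x expression matrix, features x samples.
#' @param labels class labels (see [as_binary_labels()]).
#' @param k number of features to keep.
#' @return a `feature_selection` list: `feature_ids`, `t_statistics`, `k`.
#' @export
select_features <- function(x, labels, k) {
  check_expression_matrix(x)
  y <- as_binary_labels(labels)
  if (length(y) != ncol(x)) stop("labels must match the number of samples")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 < 2 || n0 < 2) stop("each class needs at least 2 samples (variance undefined)")
  if (k < 1 || k > nrow(x)) stop("k must be in 1..n_features")
  t_all <- t_statistics(x, y)
  ord <- order(-abs(t_all), rownames(x))
  top <- ord[seq_len(k)]
  structure(list(feature_ids = rownames(x)[top],
                 t_statistics = unname(t_all[top]),
                 k = as.integer(k)),
            class = "feature_selection")
}

# Vectorized pooled-variance two-sample t, group 1 minus group 0.
t_statistics <- function(x, y) {
  x1 <- x[, y == 1, drop = FALSE]
  x0 <- x[, y == 0, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  ss1 <- rowSums((x1 - m1)^2)
  ss0 <- rowSums((x0 - m0)^2)
  sp <- sqrt((ss1 + ss0) / (n1 + n0 - 2))
  sp <- pmax(sp, 1e-8)
  (m1 - m0) / (sp * sqrt(1 / n1 + 1 / n0))
}

#' Summarize a gene subset by its first two metagenes
#'
#' Centers each gene across the training samples and takes the singular value
#' decomposition of the centered matrix X = U D V'. The first two left
#' singular vectors define the metagene loadings; training factor scores are
#' the D-scaled projections F = U2' (x - centers) (equivalently the first two
#' columns of V D).
#'
#' @param x expression matrix for the selected genes (k features x n samples).
#' @return a `metagene_factorization`: `feature_ids`, `gene_centers`,
#'   `loadings` (k x 2, orthonormal columns), `singular_values` (2, positive,
#'   decreasing), `factor_scores` (n x 2).
#' @export
factorize <- function(x) {
  check_expression_matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 features and 2 samples")
  centers <- rowMeans(x)
  xc <- x - centers
  sv <- svd(xc, nu = 2, nv = 2)
  if (sv$d[2] <= sv$d[1] * 1e-12) stop("centered matrix has rank < 2")
  scores <- sv$v %*% diag(sv$d[1:2])
  rownames(scores) <- colnames(x)
  colnames(scores) <- c("factor1", "factor2")
  loadings <- sv$u
  dimnames(loadings) <- list(rownames(x), c("factor1", "factor2"))
  structure(list(feature_ids = rownames(x),
                 gene_centers = centers,
                 loadings = loadings,
                 singular_values = sv$d[1:2],
                 factor_scores = scores),
            class = "metagene_factorization")
}

#' Project samples onto fitted metagene loadings
#'
#' Computes U2' (x - gene_centers) for each sample, the same D-scaled factor
#' scores stored for the training samples.
#'
#' @param fac a [factorize()] result, or any object carrying `loadings` and
#'   `gene_centers` in feature order (e.g. a `signature_model`).
#' @param x numeric vector (one sample, feature order as in the
#'   factorization) or matrix (features x samples).
#' @return samples x 2 matrix of factor scores.
#' @export
project <- function(fac, x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) != length(fac$gene_centers)) {
    stop("sample vector length ", nrow(x), " != number of model features ",
         length(fac$gene_centers))
  }
  scores <- crossprod(fac$loadings, x - fac$gene_centers)
  t(scores)
}

#' Fit Bayesian probit regression by data-augmentation Gibbs sampling
#'
#' Model: P(y = 1 | f) = pnorm(b0 + b1 f1 + b2 f2) with a diffuse
#' N(0, prior_var * I) prior on the coefficients and latent variance fixed
#' at 1 (Albert-Chib augmentation: truncated-normal latent draws given beta,
#' conjugate multivariate-normal beta draw given latents). The chain is
#' reproducible bit-for-bit given the seed.
#'
#' @param factors n x 2 matrix of factor scores.
#' @param labels class labels (see [as_binary_labels()]).
#' @param iterations total Gibbs iterations (default 6000).
#' @param burn_in iterations discarded (default 1000).
#' @param seed RNG seed (required).
#' @param prior_var prior variance of each coefficient (default 1e6).
#' @return a `bpr_posterior`: `draws` (retained x 3), `summary` (mean and
#'   central 95% interval per coefficient), `burn_in`, `seed`.
#' @export
fit_bpr <- function(factors, labels, iterations = 6000, burn_in = 1000,
                    seed, prior_var = 1e6) {
  if (missing(seed)) stop("seed is required for a reproducible chain")
  factors <- as.matrix(factors)
  y <- as_binary_labels(labels)
  n <- nrow(factors)
  if (length(y) != n) stop("labels must match the number of rows of factors")
  if (n < 4 || length(unique(y)) < 2) {
    stop("need at least 4 samples with both classes present")
  }
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  X <- cbind(1, factors)
  set.seed(seed)
  draws <- .gibbs_probit_cpp(X, y, as.integer(iterations), as.integer(burn_in),
                             prior_var)
  colnames(draws) <- c("intercept", "factor1", "factor2")
  gz <- geweke_z(draws[, "factor1"])
  if (is.finite(gz) && abs(gz) > 4) {
    warning("possible non-convergence: Geweke z on the first factor coefficient = ",
            round(gz, 2))
  }
  structure(list(draws = draws,
                 summary = summarize_draws(draws),
                 burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations),
                 seed = seed),
            class = "bpr_posterior")
}

summarize_draws <- function(draws) {
  data.frame(term = colnames(draws),
             mean = colMeans(draws),
             lower = apply(draws, 2, stats::quantile, 0.025),
             upper = apply(draws, 2, stats::quantile, 0.975),
             row.names = NULL)
}

# Geweke convergence diagnostic: z-score comparing the means of the first 10%
# and last 50% of the chain. Segment variances come from batch means so chain
# autocorrelation does not inflate the z-score.
geweke_z <- function(chain, first = 0.1, last = 0.5) {
  n <- length(chain)
  a <- chain[seq_len(max(2, floor(first * n)))]
  b <- chain[seq.int(n - floor(last * n) + 1, n)]
  bm_var <- function(v) {
    nb <- max(2, floor(sqrt(length(v))))
    size <- floor(length(v) / nb)
    means <- vapply(seq_len(nb),
                    function(i) mean(v[((i - 1) * size + 1):(i * size)]),
                    numeric(1))
    stats::var(means) / nb
  }
  se <- sqrt(bm_var(a) + bm_var(b))
  if (!is.finite(se) || se == 0) return(0)
  (mean(a) - mean(b)) / se
}

#' Construct a signature model object
#'
#' Validates the invariants of a portable functional gene signature:
#' orthonormal loadings, positive decreasing singular values, threshold in
#' [0, 1].
#'
#' @param feature_ids,gene_centers,loadings,singular_values metagene
#'   factorization components, in feature order.
#' @param coefficient_summary data.frame of posterior mean and 95% interval
#'   per coefficient.
#' @param posterior_draws retained MCMC draws (m x 3) or NULL.
#' @param threshold decision threshold on the predicted probability.
#' @param training_metadata list (seed, MCMC settings, chosen k, ...).
#' @return a `signature_model`.
#' @export
new_signature_model <- function(feature_ids, gene_centers, loadings,
                                singular_values, coefficient_summary,
                                posterior_draws = NULL, threshold = 0.5,
                                training_metadata = list()) {
  loadings <- as.matrix(loadings)
  k <- length(feature_ids)
  stopifnot(length(gene_centers) == k, nrow(loadings) == k, ncol(loadings) == 2)
  gram <- crossprod(loadings)
  if (max(abs(gram - diag(2))) > 1e-6) stop("loadings columns are not orthonormal")
  if (!(singular_values[1] > singular_values[2] && singular_values[2] > 0)) {
    stop("singular values must be positive and strictly decreasing")
  }
  if (!(threshold >= 0 && threshold <= 1)) stop("threshold must lie in [0, 1]")
  structure(list(feature_ids = as.character(feature_ids),
                 gene_centers = as.numeric(gene_centers),
                 loadings = loadings,
                 singular_values = as.numeric(singular_values),
                 coefficient_summary = coefficient_summary,
                 posterior_draws = posterior_draws,
                 threshold = threshold,
                 training_metadata = training_metadata),
            class = "signature_model")
}

#' Train a functional gene signature
#'
#' Runs the full training stack on one cohort: t-statistic selection of the
#' top `k` genes, two-metagene SVD summarization, and the probit Gibbs
#' sampler on the factor scores.
#'
#' @param x training expression matrix, features x samples.
#' @param labels class labels (see [as_binary_labels()]).
#' @param k signature size (number of genes).
#' @param threshold decision threshold (default 0.5; replace with a Youden
#'   threshold after validation if desired).
#' @param iterations,burn_in,seed,prior_var passed to [fit_bpr()].
#' @param keep_draws retain the posterior draws in the model (default TRUE;
#'   needed for credible intervals at prediction time).
#' @return a `signature_model`.
#' @export
train_signature <- function(x, labels, k, threshold = 0.5,
                            iterations = 6000, burn_in = 1000, seed,
                            prior_var = 1e6, keep_draws = TRUE) {
  sel <- select_features(x, labels, k)
  fac <- factorize(x[sel$feature_ids, , drop = FALSE])
  post <- fit_bpr(fac$factor_scores, labels, iterations = iterations,
                  burn_in = burn_in, seed = seed, prior_var = prior_var)
  new_signature_model(
    feature_ids = sel$feature_ids,
    gene_centers = fac$gene_centers,
    loadings = fac$loadings,
    singular_values = fac$singular_values,
    coefficient_summary = post$summary,
    posterior_draws = if (keep_draws) post$draws else NULL,
    threshold = threshold,
    training_metadata = list(seed = seed, iterations = iterations,
                             burn_in = burn_in, k = sel$k,
                             prior_var = prior_var)
  )
}

#' Predict class probabilities with a signature model
#'
#' Each sample is projected onto the metagene loadings; every retained
#' posterior draw gives a probability pnorm(b0 + b1 f1 + b2 f2), and the
#' prediction is the posterior mean with a central 95% credible interval.
#' Samples are called IPF when the probability reaches the model threshold.
#'
#' @param object a `signature_model` with retained posterior draws.
#' @param x expression matrix (features x samples) or named numeric vector
#'   containing at least the model's features.
#' @param ... unused.
#' @return data.frame: `sample_id`, `probability`, `ci_lo`, `ci_hi`, `call`.
#' @export
predict.signature_model <- function(object, x, ...) {
  if (is.null(object$posterior_draws)) {
    stop("model carries no posterior draws; refit with keep_draws = TRUE")
  }
  if (is.vector(x) && !is.matrix(x)) x <- matrix(x, ncol = 1, dimnames = list(names(x), "sample1"))
  missing_feats <- setdiff(object$feature_ids, rownames(x))
  if (length(missing_feats) > 0) {
    stop("sample(s) lack model feature(s): ",
         paste(utils::head(missing_feats, 10), collapse = ", "),
         if (length(missing_feats) > 10) sprintf(" (and %d more)", length(missing_feats) - 10))
  }
  f <- project(object, x[object$feature_ids, , drop = FALSE])  # n x 2
  draws <- object$posterior_draws                              # m x 3
  lin <- cbind(1, f) %*% t(draws)                              # n x m
  pr <- stats::pnorm(lin)
  probability <- rowMeans(pr)
  ci <- t(apply(pr, 1, stats::quantile, c(0.025, 0.975)))
  # under heavy skew the mean can fall just outside the central quantiles;
  # widen so the interval always contains the reported probability
  ci_lo <- pmin(ci[, 1], probability)
  ci_hi <- pmax(ci[, 2], probability)
  data.frame(sample_id = colnames(x),
             probability = probability,
             ci_lo = ci_lo,
             ci_hi = ci_hi,
             call = ifelse(probability >= object$threshold, "IPF", "NORMAL"),
             row.names = NULL)
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Functional gene signature (", length(x$feature_ids), " genes)\n", sep = "")
  cat("  singular values:", signif(x$singular_values, 5), "\n")
  cat("  threshold:", x$threshold, "\n")
  cat("  coefficients (posterior mean [95% CrI]):\n")
  cs <- x$coefficient_summary
  for (i in seq_len(nrow(cs))) {
    cat(sprintf("    %-10s %8.4f [%8.4f, %8.4f]\n",
                cs$term[i], cs$mean[i], cs$lower[i], cs$upper[i]))
  }
  invisible(x)
}
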