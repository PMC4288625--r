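test_that("pooled-variance t-statistic matches the hand formula", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("gA", paste0("s", 1:6)))
  x <- rbind(x, gB = c(0, 0, 0, 0, 0, 0) + 8)  # constant filler row
  y <- c(1, 1, 1, 0, 0, 0)
  sel <- select_features(x, y, k = 2)
  t_gA <- sel$t_statistics[match("gA", sel$feature_ids)]
  # pooled sd = 1, se = sqrt(2/3), t = (2 - 5) / sqrt(2/3)
  expect_equal(t_gA, -3.674, tolerance = 5e-4)
})

test_that("selection returns all features sorted when k = n_features", {
  co <- small_cohort(p = 60, effect = 1, seed = 51)
  y <- co$annotations$phenotype
  sel <- select_features(co$expression, y, k = 60)
  expect_equal(sel$k, 60L)
  expect_setequal(sel$feature_ids, rownames(co$expression))
  expect_true(all(diff(abs(sel$t_statistics)) <= 1e-12))
})

test_that("selection needs two samples per class and k in range", {
  x <- random_matrix(20, 5, seed = 52)
  expect_error(select_features(x, c(1, 0, 0, 0, 0), 5), "at least 2")
  expect_error(select_features(x, c(1, 1, 0, 0, 0), 25), "k must be")
})

test_that("selection is invariant to sample order and equivariant to feature permutation", {
  co <- small_cohort(p = 100, effect = 1, seed = 53)
  x <- co$expression; y <- as_binary_labels(co$annotations$phenotype)
  sel <- select_features(x, y, 15)
  perm <- sample(ncol(x))
  sel2 <- select_features(x[, perm], y[perm], 15)
  expect_identical(sel2$feature_ids, sel$feature_ids)
  expect_equal(sel2$t_statistics, sel$t_statistics, tolerance = 1e-12)
  fperm <- sample(nrow(x))
  sel3 <- select_features(x[fperm, ], y, 15)
  expect_identical(sel3$feature_ids, sel$feature_ids)
})

test_that("two-factor factorization reconstructs rank-2 data and matches the eigen oracle", {
  set.seed(54)
  # exact rank-2 matrix from two outer products
  x <- outer(rnorm(25), rnorm(8)) + outer(rnorm(25), rnorm(8))
  x <- x - rowMeans(x)  # keep it rank 2 after the internal centering
  dimnames(x) <- list(sprintf("g%02d", 1:25), sprintf("s%01d", 1:8))
  fac <- factorize(x)
  recon <- fac$loadings %*% t(fac$factor_scores) + fac$gene_centers
  expect_lt(max(abs(recon - x)), 1e-10)

  # d^2 equals the top-2 eigenvalues of the centered cross-product
  x2 <- random_matrix(30, 10, seed = 55)
  fac2 <- factorize(x2)
  xc <- x2 - rowMeans(x2)
  ev <- eigen(xc %*% t(xc), symmetric = TRUE)$values
  expect_equal(fac2$singular_values^2, ev[1:2], tolerance = 1e-8)
  # loadings orthonormal
  expect_equal(crossprod(fac2$loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(factorize(x2[, 1, drop = FALSE]), "at least 2")
})

test_that("projection reproduces stored training scores and annihilates null-space shifts", {
  x <- random_matrix(40, 12, seed = 56)
  fac <- factorize(x)
  # every training column projects onto its stored factor-score row
  proj <- project(fac, x)
  expect_equal(proj, fac$factor_scores, tolerance = 1e-8, ignore_attr = TRUE)
  # the gene centers themselves sit at the origin
  expect_equal(drop(project(fac, fac$gene_centers)), c(0, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  # a shift orthogonal to both loadings leaves the projection unchanged
  v <- rnorm(40)
  v <- v - fac$loadings %*% crossprod(fac$loadings, v)
  expect_equal(project(fac, x[, 3] + 5 * v), project(fac, x[, 3]),
               tolerance = 1e-8)
  expect_error(project(fac, x[1:10, 1]), "length")
})

test_that("Gibbs posterior agrees with the probit maximum-likelihood oracle", {
  set.seed(57)
  n <- 200
  f <- cbind(rnorm(n), rnorm(n))
  y <- rbinom(n, 1, pnorm(0 + 2 * f[, 1] + 0 * f[, 2]))
  post <- fit_bpr(f, y, iterations = 4000, burn_in = 1000, seed = 58)
  ml <- stats::glm(y ~ f, family = stats::binomial(link = "probit"))
  for (j in 1:3) {
    post_mean <- post$summary$mean[j]
    post_sd <- (post$summary$upper[j] - post$summary$lower[j]) / (2 * 1.96)
    expect_lt(abs(post_mean - unname(coef(ml)[j])), 3 * post_sd)
  }
  # summary is recomputable from the draws
  expect_equal(post$summary$mean, unname(colMeans(post$draws)), tolerance = 1e-12)
  expect_equal(post$summary$lower,
               unname(apply(post$draws, 2, quantile, 0.025)), tolerance = 1e-12)
  expect_gte(nrow(post$draws), 1000)
})

test_that("the chain is bit-for-bit reproducible given the seed", {
  set.seed(59)
  f <- cbind(rnorm(30), rnorm(30))
  y <- rep(c(0, 1), 15)
  a <- fit_bpr(f, y, iterations = 1000, burn_in = 200, seed = 60)
  b <- fit_bpr(f, y, iterations = 1000, burn_in = 200, seed = 60)
  expect_identical(a$draws, b$draws)
  c <- fit_bpr(f, y, iterations = 1000, burn_in = 200, seed = 61)
  expect_false(identical(c$draws, a$draws))
})

test_that("with labels independent of factors, training probabilities sit near prevalence", {
  set.seed(62)
  n <- 120
  f <- cbind(rnorm(n), rnorm(n))
  y <- rbinom(n, 1, 0.4)
  post <- fit_bpr(f, y, iterations = 3000, burn_in = 500, seed = 63)
  p_train <- rowMeans(pnorm(cbind(1, f) %*% t(post$draws)))
  expect_lt(abs(mean(p_train) - mean(y)), 0.1)
})

test_that("flipping labels negates the posterior mean on a symmetric design", {
  set.seed(64)
  n <- 150
  f <- cbind(rnorm(n), rnorm(n))
  y <- rbinom(n, 1, pnorm(0.8 * f[, 1] - 0.4 * f[, 2]))
  a <- fit_bpr(f, y, iterations = 4000, burn_in = 1000, seed = 65)
  b <- fit_bpr(f, 1 - y, iterations = 4000, burn_in = 1000, seed = 66)
  mc_sd <- sqrt(apply(a$draws, 2, var) / 200)  # generous effective-n allowance
  expect_true(all(abs(a$summary$mean + b$summary$mean) < 6 * mc_sd + 0.05))
})

test_that("credible intervals cover the true coefficient at close to nominal rate", {
  set.seed(67)
  beta_true <- c(0.2, 1.0, -0.5)
  hits <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    n <- 150
    f <- cbind(rnorm(n), rnorm(n))
    y <- rbinom(n, 1, pnorm(beta_true[1] + f %*% beta_true[2:3]))
    post <- suppressWarnings(fit_bpr(f, y, iterations = 6000, burn_in = 1000,
                                     seed = 1000 + r))
    hits <- hits + (post$summary$lower[2] <= beta_true[2] &&
                      beta_true[2] <= post$summary$upper[2])
  }
  expect_gte(hits / reps, 0.90)
  expect_lte(hits / reps, 0.99)
})

test_that("a huge single-factor separation drives training probabilities to the labels", {
  # class gap of 6 on factor 1 against unit-scale noise on factor 2; the
  # chain needs a long burn-in here because separation makes the diffuse-
  # prior posterior drift to large coefficients
  set.seed(68)
  n <- 40
  y <- rep(c(1, 0), each = 20)
  f <- cbind(ifelse(y == 1, 3, -3), rnorm(n))
  post <- suppressWarnings(fit_bpr(f, y, iterations = 10000, burn_in = 5000,
                                   seed = 69))
  p_train <- rowMeans(pnorm(cbind(1, f) %*% t(post$draws)))
  expect_true(all(abs(p_train - y) < 0.05))
})

test_that("prediction averages per-draw probabilities with a credible interval", {
  co <- small_cohort(p = 150, effect = 2, seed = 70)
  y <- co$annotations$phenotype
  model <- suppressWarnings(train_signature(co$expression, y, k = 25,
                                            iterations = 2000, burn_in = 500,
                                            seed = 71))
  preds <- predict(model, co$expression)
  expect_true(all(preds$probability >= preds$ci_lo - 1e-12))
  expect_true(all(preds$probability <= preds$ci_hi + 1e-12))
  expect_identical(preds$call, ifelse(preds$probability >= 0.5, "IPF", "NORMAL"))

  # all-zero coefficient draws give probability exactly 0.5
  null_model <- model
  null_model$posterior_draws <- matrix(0, 100, 3)
  p0 <- predict(null_model, co$expression[, 1:3])
  expect_equal(p0$probability, rep(0.5, 3), ignore_attr = TRUE)

  # monotone non-decreasing in factor 1 when all its draws are positive
  pos_model <- model
  pos_model$posterior_draws <- cbind(rnorm(200, 0, 0.1), abs(rnorm(200, 1, 0.3)),
                                     rnorm(200, 0, 0.1))
  base <- co$expression[model$feature_ids, 1]
  probs <- vapply(seq(-2, 2, length.out = 5), function(a) {
    xx <- base + a * model$loadings[, 1]
    predict(pos_model, setNames(xx, model$feature_ids))$probability
  }, numeric(1))
  expect_true(all(diff(probs) >= -1e-12))

  # missing features are reported by name
  expect_error(predict(model, co$expression[-match(model$feature_ids[1],
                                                   rownames(co$expression)), ]),
               model$feature_ids[1])
})
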