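# Small in-code fixtures shared across test files.

# Compact cohort for fast unit tests: p features, n1 disease / n0 control.
small_cohort <- function(p = 300, n1 = 14, n0 = 8, effect = 0,
                         de_fraction = 0.1, seed = 4242) {
  generate_cohort(synthetic_config(
    n_features = p, n_ipf = n1, n_normal = n0,
    de_fraction = de_fraction, effect_size_sd = effect, seed = seed))
}

# Random expression matrix with ids, no class structure.
random_matrix <- function(p, n, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(p * n, mean = 8, sd = 1), p, n,
              dimnames = list(sprintf("g%03d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  x
}

# Annotation table built directly (no generator), for preprocess tests.
toy_annotations <- function(n_per_stratum) {
  rows <- list()
  i <- 0
  for (st in names(n_per_stratum)) {
    for (j in seq_len(n_per_stratum[[st]])) {
      i <- i + 1
      ipf <- st != "NORMAL"
      pft <- switch(st,
                    NORMAL = c(100, 90), IPF_MILD = c(80, 70),
                    IPF_MODERATE = c(60, 50), IPF_SEVERE = c(45, 30),
                    IPF_UNKNOWN = c(NA, NA))
      rows[[i]] <- data.frame(
        sample_id = sprintf("%s_%02d", st, j),
        phenotype = if (ipf) "IPF" else "NORMAL",
        family_history = if (ipf) "SPORADIC" else "NONE",
        fvc_pct = pft[1], dlco_pct = pft[2],
        batch = "b1", severity = "UNKNOWN", cohort = "UNASSIGNED",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Brute-force O(n^3) UPGMA on a distance matrix: returns successive merge
# heights and the leaf composition of each merged cluster. Independent of
# stats::hclust.
brute_upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + n - 1)
  active[(n + 1):(2 * n - 1)] <- FALSE
  dist_fun <- function(a, b) {
    mean(d[clusters[[a]], clusters[[b]]])
  }
  heights <- numeric(n - 1)
  members <- vector("list", n - 1)
  ids <- seq_len(n)
  for (m in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
      dd <- dist_fun(ids[i], ids[j])
      if (dd < best_d) { best_d <- dd; best <- c(ids[j], ids[i]) }
    }
    heights[m] <- best_d
    new_id <- length(clusters) + 1
    clusters[[new_id]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    members[[m]] <- clusters[[new_id]]
    ids <- c(setdiff(ids, best), new_id)
  }
  list(heights = heights, members = members, clusters = clusters)
}

# Leaves composing the cluster formed at merge step m of an hclust object.
cutree_members <- function(hc, m) {
  mem <- function(i) {
    if (i < 0) return(-i)
    c(mem(hc$merge[i, 1]), mem(hc$merge[i, 2]))
  }
  sort(mem(m))
}

# Brute-force AUC by pair enumeration (ties count 1/2).
brute_auc <- function(probs, y) {
  pos <- probs[y == 1]; neg <- probs[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating all assignments.
brute_wilcoxon <- function(a, b) {
  v <- c(a, b)
  n <- length(v); na <- length(a)
  combs <- utils::combn(n, na)
  r <- rank(v)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
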