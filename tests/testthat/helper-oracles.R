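# Independent scalar oracles, deliberately written as plain loops so they
# share no code path with the implementations they check.

oracle_cosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (k in seq_along(a)) {
    num <- num + a[k] * b[k]
    na <- na + a[k]^2
    nb <- nb + b[k]^2
  }
  num / sqrt(na * nb)
}

oracle_contrastive <- function(z_r, z_a, tau) {
  n <- nrow(z_r)
  total <- 0
  for (i in seq_len(n)) {
    num <- exp(oracle_cosine(z_r[i, ], z_a[i, ]) / tau)
    den <- 0
    for (j in seq_len(n))
      den <- den + exp(oracle_cosine(z_r[i, ], z_a[j, ]) / tau)
    total <- total - log(num / den)
  }
  total / n
}

oracle_mse <- function(z_r, z_a, tau) {
  n <- nrow(z_r)
  total <- 0
  for (i in seq_len(n)) {
    num <- exp(oracle_cosine(z_r[i, ], z_a[i, ]) / tau)
    den <- 0
    for (j in seq_len(n))
      den <- den + exp(oracle_cosine(z_r[i, ], z_a[j, ]) / tau)
    total <- total + (num / den - 1)^2
  }
  total / n
}

# Dense normalised adjacency built directly from the edge list (no package
# sparse machinery), then the three-layer forward as dense products.
oracle_dense_adjacency <- function(g, self_loops) {
  n <- g$n_nodes
  a <- matrix(0, n, n)
  for (e in seq_len(nrow(g$edges))) {
    a[g$edges[e, 1L], g$edges[e, 2L]] <- 1
    a[g$edges[e, 2L], g$edges[e, 1L]] <- 1
  }
  if (self_loops) diag(a) <- 1
  deg <- rowSums(a)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  diag(dinv) %*% a %*% diag(dinv)
}

oracle_gcn_dense <- function(model, a_dense, x) {
  rl <- function(m) pmax(m, 0)
  h1 <- rl(a_dense %*% x %*% model$W0)
  h2 <- rl(a_dense %*% h1 %*% model$W1)
  a_dense %*% h2 %*% model$W2
}

oracle_mlp_loop <- function(model, x) {
  rl <- function(m) pmax(m, 0)
  h2 <- rl(rl(x %*% model$W0) %*% model$W1)
  h2 %*% model$W2
}

# Brute-force KNN edge list with the smaller-index tie rule, sorted by
# (source, distance, target).
oracle_knn <- function(d, k) {
  n <- nrow(d)
  out <- NULL
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(d[i, cand], cand)]
    out <- rbind(out, cbind(i, ord[seq_len(k)]))
  }
  unname(out)
}

# ARI by exhaustive pair counting (no contingency table).
oracle_ari_pairs <- function(l1, l2) {
  n <- length(l1)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s1 <- l1[i] == l1[j]
    s2 <- l2[i] == l2[j]
    if (s1 && s2) n11 <- n11 + 1
    else if (!s1 && !s2) n00 <- n00 + 1
    else if (s1) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

oracle_distances <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(ncol(x))) s <- s + (x[i, k] - x[j, k])^2
    d[i, j] <- sqrt(s)
  }
  d
}

random_partition <- function(n, max_classes) {
  sample.int(max_classes, n, replace = TRUE)
}

# Random small cell_graph for adjacency/encoder property tests.
random_graph <- function(n, k = NULL) {
  k <- k %||% sample(1:(n - 1), 1)
  x <- matrix(rnorm(n * 3), n)
  knn_edges(pairwise_distances(x), graph_config(k = k, edge_drop_rate = 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
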