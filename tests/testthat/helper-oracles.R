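# Independent reference implementations used as oracles.

# Explicit least-squares fit of y on x via the normal equations, with the
# residual sd on the n - 1 denominator. Kept deliberately elementary and
# separate from the package's covariance-based fitting path.
ols_oracle <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n
  yb <- sum(y) / n
  beta <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  alpha <- yb - beta * xb
  resid <- y - alpha - beta * x
  # residuals of an OLS fit with intercept have mean zero, so this is their
  # sample standard deviation on the n - 1 denominator
  sigma <- sqrt(sum(resid^2) / (n - 1))
  list(alpha = alpha, beta = beta, sigma = sigma)
}

# Straightforward R implementation of the greedy merge rule, selecting by
# explicit loss comparison (the package's C++ path compares integer keys);
# canonical vertex order obtained through igraph's public API.
ic_oracle <- function(A, canonical = TRUE) {
  A <- (A != 0) * 1L
  diag(A) <- 0L
  n <- nrow(A)
  if (n <= 1) return(0)
  if (all(A[upper.tri(A)] == 1) || all(A[upper.tri(A)] == 0)) return(0)
  if (canonical && n > 2) {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    lab <- igraph::canonical_permutation(g, sh = "fm")$labeling
    A <- A[order(lab), order(lab)]
  }
  H2 <- function(p) if (p <= 0 || p >= 1) 0 else -p * log2(p) - (1 - p) * log2(1 - p)
  alive <- seq_len(n)
  total <- 0
  while (length(alive) > 1) {
    r <- length(alive)
    m <- r - 2
    best <- NULL
    bestloss <- Inf
    for (i in seq_len(r - 1)) {
      for (j in (i + 1):r) {
        u <- alive[i]; v <- alive[j]
        others <- setdiff(alive, c(u, v))
        loss <- if (m > 0) m * H2(sum(A[u, others] != A[v, others]) / m) else 0
        if (loss < bestloss - 1e-12) { bestloss <- loss; best <- c(u, v) }
      }
    }
    u <- best[1]; v <- best[2]
    A[u, ] <- pmax(A[u, ], A[v, ])
    A[, u] <- pmax(A[, u], A[v, ])
    A[u, u] <- 0L
    alive <- alive[alive != v]
    total <- total + bestloss
  }
  total
}

# Symmetric 0/1 adjacency matrix from an edge list.
adj_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (e in edges) { A[e[1], e[2]] <- 1L; A[e[2], e[1]] <- 1L }
  A
}

# Random symmetric adjacency matrix.
random_adjacency <- function(n, p) {
  A <- matrix(stats::runif(n * n) < p, n, n) * 1L
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0L
  A
}

# A hand-built two-feature baseline with prescribed parameters.
manual_baseline <- function(alpha, beta, sigma,
                            features = c("fk", "fl"), n_train = 10L) {
  structure(list(
    feature_names = features,
    pairs = tibble::tibble(feature_k = features[1], feature_l = features[2],
                           alpha = alpha, beta = beta, sigma = sigma,
                           n_train = n_train, degenerate = FALSE),
    sigma_tol = 1e-8, var_tol = 1e-12),
    class = "parenclitic_baseline")
}

# A parenclitic_network over `nodes` with the given upper-triangular edges
# linked (unit weights on links, zero elsewhere), already binarized.
manual_binary_network <- function(n, edges, id = "S1") {
  nodes <- sprintf("n%02d", seq_len(n))
  pr <- parenclitic:::pair_index(n)
  weight <- numeric(length(pr$k))
  for (e in edges) {
    hit <- which(pr$k == min(e) & pr$l == max(e))
    weight[hit] <- 1
  }
  net <- parenclitic:::new_parenclitic_network(id, nodes, pr$k, pr$l, weight)
  binarize(net, 0.5)
}

# Small cohort tibble from a feature matrix and labels.
cohort_from_matrix <- function(F, labels) {
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%05d", seq_len(nrow(F))),
                   DEATH = as.integer(labels)),
    tibble::as_tibble(as.data.frame(F)))
}
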