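# Independent brute-force oracles, written against a plain dense adjacency
# matrix with explicit loops: these deliberately share no code with the
# package's scoring routes.

adj_of <- function(net) igraph::as_adjacency_matrix(net, sparse = FALSE)

# Erdos-Renyi G(n, p) test graph with character labels "1".."n",
# built directly from a sampled adjacency matrix.
rand_net <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  dimnames(A) <- list(as.character(1:n), as.character(1:n))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# deterministic graph with exactly n nodes and the first m pairs of
# combn(n, 2) as edges (for statistics that depend only on |V| and |E|)
net_nm <- function(n, m) {
  stopifnot(m <= choose(n, 2))
  pairs <- utils::combn(n, 2)[, seq_len(m), drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- as.character(1:n)
  igraph::add_edges(g, as.vector(pairs))
}

oracle_cn <- function(A, x, y) sum(A[x, ] * A[y, ])

oracle_ra <- function(A, x, y) {
  k <- unname(rowSums(A))
  s <- 0
  for (z in seq_len(nrow(A))) if (A[x, z] == 1 && A[y, z] == 1) s <- s + 1 / k[z]
  s
}

oracle_aa <- function(A, x, y) {
  k <- unname(rowSums(A))
  s <- 0
  for (z in seq_len(nrow(A))) if (A[x, z] == 1 && A[y, z] == 1) s <- s + 1 / log(k[z])
  s
}

oracle_car <- function(A, x, y) {
  cn <- which(A[x, ] == 1 & A[y, ] == 1)
  if (length(cn) == 0) return(0)
  s <- 0
  for (z in cn) s <- s + sum(A[z, cn]) / 2
  length(cn) * s
}

oracle_pa <- function(A, x, y) sum(A[x, ]) * sum(A[y, ])

oracle_ic <- function(A, i, j, beta) {
  cn <- which(A[i, ] == 1 & A[j, ] == 1)
  base <- A[i, j]
  if (length(cn) > 0) {
    kmax <- max(rowSums(A)[cn])
    base <- base + length(cn) / (kmax - 1)
  }
  if (beta == 0) 1 else base^beta
}

oracle_pic <- function(A, x, y, beta) {
  s <- 0
  for (z in which(A[y, ] == 1)) if (z != x) s <- s + oracle_ic(A, x, z, beta)
  for (z in which(A[x, ] == 1)) if (z != y) s <- s + oracle_ic(A, y, z, beta)
  s
}

# path counting by explicit loops: numbers of 2- and 3-step walks
oracle_lp <- function(A, x, y, alpha) {
  n <- nrow(A)
  p2 <- 0
  for (z in 1:n) p2 <- p2 + A[x, z] * A[z, y]
  p3 <- 0
  for (z in 1:n) for (w in 1:n) p3 <- p3 + A[x, z] * A[z, w] * A[w, y]
  p2 + alpha * p3
}

# truncated power series for the Katz matrix
oracle_katz_matrix <- function(A, eps, tol = 1e-14, max_terms = 1000) {
  S <- matrix(0, nrow(A), ncol(A))
  P <- diag(nrow(A))
  for (l in seq_len(max_terms)) {
    P <- P %*% A * eps
    S <- S + P
    if (max(abs(P)) < tol) break
  }
  S
}

# pseudoinverse via eigendecomposition (invert the nonzero spectrum)
oracle_pinv <- function(M, tol = 1e-9) {
  e <- eigen(M, symmetric = TRUE)
  inv <- ifelse(abs(e$values) > tol, 1 / e$values, 0)
  e$vectors %*% (inv * t(e$vectors))
}

oracle_laplacian_pinv <- function(A) oracle_pinv(diag(rowSums(A)) - A)

oracle_act <- function(A, x, y) {
  Lp <- oracle_laplacian_pinv(A)
  denom <- Lp[x, x] + Lp[y, y] - 2 * Lp[x, y]
  if (denom <= 1e-12) 0 else 1 / denom
}

oracle_cosplus <- function(A, x, y) {
  Lp <- oracle_laplacian_pinv(A)
  if (Lp[x, x] <= 1e-12 || Lp[y, y] <= 1e-12) return(0)
  Lp[x, y] / sqrt(Lp[x, x] * Lp[y, y])
}

# rank AUC recomputed the naive O(np*nn) way
oracle_auc <- function(ps, ns) {
  wins <- 0; ties <- 0
  for (p in ps) {
    wins <- wins + sum(p > ns)
    ties <- ties + sum(p == ns)
  }
  (wins + 0.5 * ties) / (length(ps) * length(ns))
}
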