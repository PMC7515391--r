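#  Matrix routes for whole-network scoring.
#
#  All indices are materialised as dense symmetric n x n score matrices
#  (diagonal fixed at 0); candidate pairs are then read off the upper
#  triangle. Dense algebra is deliberate: evaluation workloads here are
#  networks of up to a few thousand nodes, where BLAS-backed dense products
#  beat sparse bookkeeping.

.INDEX_NAMES <- c("PIC", "CN", "RA", "AA", "CAR", "PA", "LP", "Katz", "ACT", "Cos+")

.adjacency <- function(net) {
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  storage.mode(A) <- "double"
  A
}

# Highest common-neighbor degree for every pair, as a matrix (0 where the
# pair has no common neighbor). Nodes are visited in decreasing degree
# order so the first write into a pair's cell wins.
.max_cn_degree_matrix <- function(A, k) {
  n <- nrow(A)
  M <- matrix(0, n, n)
  for (z in order(k, decreasing = TRUE)) {
    if (k[z] < 2) break
    nb <- which(A[z, ] > 0)
    blk <- M[nb, nb]
    blk[blk == 0] <- k[z]
    M[nb, nb] <- blk
  }
  diag(M) <- 0
  M
}

# The beta-independent base of the information capacity:
# a_ij + n_ij/(k_max - 1), with the no-common-neighbor term defined as 0.
.pic_base <- function(A) {
  k <- rowSums(A)
  N2 <- A %*% A
  M <- .max_cn_degree_matrix(A, k)
  B <- A
  has_cn <- M >= 2
  B[has_cn] <- B[has_cn] + N2[has_cn] / (M[has_cn] - 1)
  diag(B) <- 0
  B
}

# PIC score matrix from a precomputed capacity base: raise to beta
# (0^0 = 1 by R's power, which is the convention the beta = 0 reduction
# needs), zero the diagonal so anchor-equals-endpoint terms are skipped,
# then sum channel capacities through one matrix product.
.pic_matrix_from_base <- function(B, A, beta) {
  IC <- B^beta
  diag(IC) <- 0
  P <- IC %*% A
  S <- P + t(P)
  diag(S) <- 0
  S
}

.car_matrix <- function(A) {
  n <- nrow(A)
  C2 <- A %*% A
  diag(C2) <- 0
  T2 <- matrix(0, n, n)
  # gamma(z) sums: each edge (z, w) contributes to every pair adjacent to
  # both z and w, once from each end of the edge.
  el <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  for (e in seq_len(nrow(el))) {
    cn <- which(A[el[e, 1], ] > 0 & A[el[e, 2], ] > 0)
    if (length(cn) >= 2) T2[cn, cn] <- T2[cn, cn] + 2
  }
  S <- C2 * T2 / 2
  diag(S) <- 0
  S
}

.score_matrix <- function(net, index, beta = 1, alpha = 0.001, epsilon = 0.01) {
  A <- .adjacency(net)
  k <- rowSums(A)
  S <- switch(index,
    "PIC" = .pic_matrix_from_base(.pic_base(A), A, beta),
    "CN" = {
      S <- A %*% A
      diag(S) <- 0
      S
    },
    "RA" = {
      w <- ifelse(k > 0, 1 / k, 0)
      S <- A %*% (w * A)
      diag(S) <- 0
      S
    },
    "AA" = {
      w <- ifelse(k > 1, 1 / log(k), 0)
      S <- A %*% (w * A)
      diag(S) <- 0
      S
    },
    "CAR" = .car_matrix(A),
    "PA" = {
      S <- outer(k, k)
      diag(S) <- 0
      S
    },
    "LP" = {
      if (alpha < 0) stop("`alpha` must be non-negative", call. = FALSE)
      A2 <- A %*% A
      S <- A2 + alpha * (A2 %*% A)
      diag(S) <- 0
      S
    },
    "Katz" = {
      lmax <- .spectral_radius(A)
      if (lmax > 0 && epsilon >= 1 / lmax) {
        stop(sprintf(
          "Katz series diverges: epsilon = %g must be < 1/lambda_max = %g",
          epsilon, 1 / lmax), call. = FALSE)
      }
      if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
      n <- nrow(A)
      S <- solve(diag(n) - epsilon * A) - diag(n)
      S <- (S + t(S)) / 2  # symmetrize away solve() round-off
      diag(S) <- 0
      S
    },
    "ACT" = {
      Lp <- spectral_cache(net)$laplacian_pinv
      d <- diag(Lp)
      denom <- outer(d, d, "+") - 2 * Lp
      S <- ifelse(denom > 1e-12, 1 / denom, 0)
      diag(S) <- 0
      S
    },
    "Cos+" = {
      Lp <- spectral_cache(net)$laplacian_pinv
      d <- diag(Lp)
      ok <- d > 1e-12
      S <- matrix(0, nrow(A), ncol(A))
      if (any(ok)) {
        S[ok, ok] <- Lp[ok, ok] / sqrt(outer(d[ok], d[ok]))
      }
      diag(S) <- 0
      S
    },
    stop("unknown index '", index, "'; valid indices: ",
         paste(.INDEX_NAMES, collapse = ", "), call. = FALSE)
  )
  dimnames(S) <- list(igraph::V(net)$name, igraph::V(net)$name)
  S
}

.spectral_radius <- function(A) {
  if (all(A == 0)) return(0)
  max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
}

#' Laplacian pseudoinverse cache for random-walk indices
#'
#' Computes the Moore–Penrose pseudoinverse \eqn{L^+} of the combinatorial
#' Laplacian \eqn{L = D - A}, the shared ingredient of the average-commute-time
#' and cosine random-walk similarities: \eqn{l^+_{xx} + l^+_{yy} - 2l^+_{xy}}
#' is (up to the factor \eqn{2|E|}) the commute time of a random walk between
#' `x` and `y`, i.e. the effective resistance between them.
#'
#' @param net Undirected simple `igraph` with named vertices, at least 2 nodes.
#' @return An object of class `spectral_cache`: a list with element
#'   `laplacian_pinv` (symmetric matrix with zero row sums, dimnames = node
#'   labels).
#' @seealso [act_score()], [cosplus_score()]
#' @export
spectral_cache <- function(net) {
  .check_network(net)
  n <- igraph::vcount(net)
  if (n < 2) stop("spectral_cache requires at least 2 nodes", call. = FALSE)
  A <- .adjacency(net)
  L <- diag(rowSums(A)) - A
  Lp <- MASS::ginv(L)
  Lp <- (Lp + t(Lp)) / 2
  dimnames(Lp) <- list(igraph::V(net)$name, igraph::V(net)$name)
  structure(list(laplacian_pinv = Lp), class = "spectral_cache")
}

#' Average commute time (ACT) similarity
#'
#' \deqn{s_{xy} = 1/(l^+_{xx} + l^+_{yy} - 2 l^+_{xy})}
#' The denominator is the effective resistance between `x` and `y`; node
#' pairs that a random walk commutes between quickly are considered similar.
#' A degenerate (non-positive, within tolerance) denominator yields 0 so
#' that ranking still works on disconnected training graphs.
#'
#' @param cache A [spectral_cache()] object.
#' @param x,y Distinct node labels.
#' @return A non-negative number.
#' @export
act_score <- function(cache, x, y) {
  Lp <- cache$laplacian_pinv
  stopifnot(inherits(cache, "spectral_cache"))
  i <- match(as.character(x), rownames(Lp))
  j <- match(as.character(y), rownames(Lp))
  if (is.na(i) || is.na(j)) stop("unknown node label", call. = FALSE)
  if (i == j) stop("act_score requires two distinct nodes", call. = FALSE)
  denom <- Lp[i, i] + Lp[j, j] - 2 * Lp[i, j]
  if (denom <= 1e-12) 0 else 1 / denom
}

#' Cosine similarity on the Laplacian pseudoinverse (Cos+)
#'
#' \deqn{s_{xy} = l^+_{xy} / \sqrt{l^+_{xx} \, l^+_{yy}}}
#' the cosine of the angle between the random-walk embedding vectors of the
#' two nodes. Pairs involving an isolated node (zero diagonal entry, within
#' tolerance) score 0.
#'
#' @inheritParams act_score
#' @return A number in \eqn{[-1, 1]}.
#' @export
cosplus_score <- function(cache, x, y) {
  stopifnot(inherits(cache, "spectral_cache"))
  Lp <- cache$laplacian_pinv
  i <- match(as.character(x), rownames(Lp))
  j <- match(as.character(y), rownames(Lp))
  if (is.na(i) || is.na(j)) stop("unknown node label", call. = FALSE)
  if (i == j) stop("cosplus_score requires two distinct nodes", call. = FALSE)
  if (Lp[i, i] <= 1e-12 || Lp[j, j] <= 1e-12) return(0)
  Lp[i, j] / sqrt(Lp[i, i] * Lp[j, j])
}

#' Local-path (LP) score table
#'
#' Scores every candidate pair by \eqn{(A^2)_{xy} + \alpha (A^3)_{xy}}:
#' common neighbors plus \eqn{\alpha}-discounted length-3 paths.
#'
#' @param net Undirected simple `igraph` with named vertices.
#' @param alpha Non-negative weight of length-3 paths (0.001 and 0.01 are
#'   the conventional settings).
#' @param candidates Optional two-column pair specification (see
#'   [score_all()]); defaults to all non-observed pairs.
#' @return A score table, see [score_all()].
#' @export
lp_scores <- function(net, alpha = 0.001, candidates = NULL) {
  score_all(net, "LP", alpha = alpha, candidates = candidates)
}

#' Katz score table
#'
#' Scores pairs by the damped sum over paths of all lengths,
#' \eqn{S = \sum_{l \ge 1} \epsilon^l A^l = (I - \epsilon A)^{-1} - I},
#' computed by a direct linear solve. Requires
#' \eqn{\epsilon < 1/\lambda_{max}(A)} for convergence; violation is an
#' error reporting the computed spectral bound.
#'
#' @param net Undirected simple `igraph` with named vertices.
#' @param epsilon Positive damping factor, strictly below
#'   \eqn{1/\lambda_{max}(A)}.
#' @inheritParams lp_scores
#' @return A score table, see [score_all()].
#' @export
katz_scores <- function(net, epsilon = 0.01, candidates = NULL) {
  score_all(net, "Katz", epsilon = epsilon, candidates = candidates)
}

# Internal: upper-triangle index matrix of the candidate universe
# (all unordered pairs minus observed edges), as a 2-column integer matrix.
.candidate_idx <- function(net) {
  A <- .adjacency(net)
  which(upper.tri(A) & A == 0, arr.ind = TRUE)
}

#' All non-observed node pairs of a network
#'
#' The candidate universe of link prediction: every unordered pair of
#' distinct nodes that is not an observed edge, in lexicographic label
#' order.
#'
#' @param net Undirected simple `igraph` with named vertices.
#' @return A data frame with character columns `node_u`, `node_v`.
#' @export
non_observed_pairs <- function(net) {
  .check_network(net)
  labs <- igraph::V(net)$name
  idx <- .candidate_idx(net)
  u <- labs[idx[, 1]]; v <- labs[idx[, 2]]
  a <- pmin(u, v); b <- pmax(u, v)
  ord <- order(a, b)
  data.frame(node_u = a[ord], node_v = b[ord], stringsAsFactors = FALSE)
}

#' Score candidate node pairs with a chosen similarity index
#'
#' Single entry point over all ten indices. Local indices are read off one
#' sparse-support matrix pass; matrix indices (LP, Katz, ACT, Cos+) are
#' computed once for the whole network and looked up per pair.
#'
#' @param net Undirected simple `igraph` with named vertices (the training
#'   graph when evaluating).
#' @param index One of `"PIC"`, `"CN"`, `"RA"`, `"AA"`, `"CAR"`, `"PA"`,
#'   `"LP"`, `"Katz"`, `"ACT"`, `"Cos+"`.
#' @param beta PIC strength parameter (PIC only).
#' @param alpha Length-3 path weight (LP only).
#' @param epsilon Damping factor (Katz only).
#' @param candidates Pairs to score: a two-column data frame or matrix of
#'   node labels, or `NULL` (default) for all non-observed pairs.
#' @return A data frame of class `score_table` with columns `node_u`,
#'   `node_v` (pair in lexicographic order) and `score`, plus attributes
#'   `index` and `params`.
#' @examples
#' g <- fixture_graph("bucket5")
#' score_all(g, "PIC", beta = 1,
#'           candidates = rbind(c("1", "3"), c("1", "5")))
#' @export
score_all <- function(net, index, beta = 1, alpha = 0.001, epsilon = 0.01,
                      candidates = NULL) {
  .check_network(net)
  if (!index %in% .INDEX_NAMES) {
    stop("unknown index '", index, "'; valid indices: ",
         paste(.INDEX_NAMES, collapse = ", "), call. = FALSE)
  }
  labs <- igraph::V(net)$name
  if (is.null(candidates)) {
    idx <- .candidate_idx(net)
  } else {
    candidates <- as.matrix(candidates)
    if (length(candidates) == 0) {
      idx <- matrix(integer(0), ncol = 2)
    } else {
      if (ncol(candidates) < 2) stop("`candidates` needs two columns", call. = FALSE)
      idx <- cbind(.node_id(net, candidates[, 1]),
                   .node_id(net, candidates[, 2]))
      if (any(idx[, 1] == idx[, 2])) {
        stop("`candidates` contains a self-pair", call. = FALSE)
      }
    }
  }
  if (nrow(idx) == 0) {
    out <- data.frame(node_u = character(0), node_v = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  } else {
    S <- .score_matrix(net, index, beta = beta, alpha = alpha, epsilon = epsilon)
    u <- labs[idx[, 1]]; v <- labs[idx[, 2]]
    a <- pmin(u, v); b <- pmax(u, v)
    ord <- order(a, b)
    out <- data.frame(node_u = a[ord], node_v = b[ord],
                      score = S[idx][ord], stringsAsFactors = FALSE)
  }
  attr(out, "index") <- index
  attr(out, "params") <- list(beta = beta, alpha = alpha, epsilon = epsilon)
  class(out) <- c("score_table", class(out))
  out
}

#' Write a score table as TSV
#'
#' Serialises a [score_all()] result with columns `node_u`, `node_v`,
#' `score` in its deterministic (lexicographic) pair order.
#'
#' @param scores A score table (or any data frame with those columns).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(as.data.frame(scores)[, c("node_u", "node_v", "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
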