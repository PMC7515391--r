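#  Train/probe splitting and the AUC / precision@L protocol.
#
#  The candidate universe for every metric is all unordered node pairs of
#  the full node set minus the training edges: probe ("missing") links are
#  candidates, everything else in the universe is a non-existent link.

# half-up rounding, guarded against binary-float droop (0.1 * 2075 must
# round as 207.5 -> 208 even though it evaluates below 207.5)
.round_half_up <- function(x) floor(x + 0.5 + 1e-9)

#' Split the edge set into training and probe edges
#'
#' Uniform random partition of the observed edges: a fraction
#' `train_fraction` (90% by convention) is kept for scoring and the
#' remainder becomes the probe set of "missing" links to be recovered.
#' The probe size is the half-up rounding of `(1 - train_fraction) * |E|`.
#' No connectivity constraint is imposed; endpoints isolated in training
#' simply score 0 under the local indices and stay in the candidate set.
#'
#' @param net Undirected simple `igraph` with named vertices, at least
#'   10 edges.
#' @param train_fraction Fraction of edges kept for training, in (0, 1).
#' @param seed Integer seed making the partition reproducible.
#' @return An object of class `train_probe_split`: list with two-column
#'   character matrices `train_edges` and `probe_edges`, plus `seed` and
#'   `train_fraction`.
#' @export
split_edges <- function(net, train_fraction = 0.9, seed = 1L) {
  .check_network(net)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  el <- igraph::as_edgelist(net, names = TRUE)
  m <- nrow(el)
  if (m < 10) stop("split_edges requires at least 10 edges", call. = FALSE)
  n_probe <- .round_half_up((1 - train_fraction) * m)
  if (n_probe < 1 || n_probe >= m) {
    stop("degenerate split: probe size ", n_probe, " of ", m, " edges",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  probe_idx <- sample.int(m, n_probe)
  structure(list(
    train_edges = el[-probe_idx, , drop = FALSE],
    probe_edges = el[probe_idx, , drop = FALSE],
    seed = as.integer(seed),
    train_fraction = train_fraction
  ), class = "train_probe_split")
}

# Save/restore the global RNG state so seeded package operations do not
# perturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Training graph of a split
#'
#' The network restricted to the training edges, over the full node set
#' (nodes that lose all their edges stay as isolated vertices).
#'
#' @param net The full network the split was made from.
#' @param split A [split_edges()] result.
#' @return An undirected simple `igraph`.
#' @export
train_network <- function(net, split) {
  .check_network(net)
  stopifnot(inherits(split, "train_probe_split"))
  .make_network(split$train_edges, igraph::V(net)$name)
}

# Internal: logical masks over the dense pair matrix for one split.
# Returns candidate scores split into probe and non-link vectors.
.split_score_vectors <- function(S, net, split) {
  labs <- igraph::V(net)$name
  n <- length(labs)
  el <- cbind(match(split$train_edges[, 1], labs),
              match(split$train_edges[, 2], labs))
  pe <- cbind(match(split$probe_edges[, 1], labs),
              match(split$probe_edges[, 2], labs))
  train <- matrix(FALSE, n, n)
  train[el] <- TRUE; train[el[, 2:1, drop = FALSE]] <- TRUE
  probe <- matrix(FALSE, n, n)
  probe[pe] <- TRUE; probe[pe[, 2:1, drop = FALSE]] <- TRUE
  ut <- upper.tri(train)
  cand <- ut & !train
  is_probe <- probe[cand]
  sc <- S[cand]
  list(probe = sc[is_probe], nonlink = sc[!is_probe],
       cand_scores = sc, cand_is_probe = is_probe)
}

# Internal: dense score matrix from a score-table data frame (absent
# candidate pairs keep score 0).
.table_to_matrix <- function(scores, net) {
  labs <- igraph::V(net)$name
  n <- length(labs)
  S <- matrix(0, n, n)
  if (nrow(scores) > 0) {
    i <- match(as.character(scores[[1]]), labs)
    j <- match(as.character(scores[[2]]), labs)
    if (anyNA(i) || anyNA(j)) stop("score table contains unknown labels", call. = FALSE)
    S[cbind(i, j)] <- scores[[3]]
    S[cbind(j, i)] <- scores[[3]]
  }
  S
}

.auc_from_vectors <- function(ps, ns, mode, n_samples, seed) {
  np <- length(ps); nn <- length(ns)
  if (np == 0) stop("empty probe set: nothing to evaluate", call. = FALSE)
  if (nn == 0) stop("no non-existent links in the candidate universe", call. = FALSE)
  if (mode == "rank") {
    r <- rank(c(ps, ns))
    stat <- sum(r[seq_len(np)]) - np * (np + 1) / 2  # wins + 0.5*ties
    # exact tie mass: pairs of equal probe/non-link scores
    tv <- intersect(unique(ps), unique(ns))
    n_ties <- sum(vapply(tv, function(v) sum(ps == v) * sum(ns == v), numeric(1)))
    n_cmp <- as.numeric(np) * nn
    list(auc = stat / n_cmp, n = n_cmp,
         n_wins = stat - 0.5 * n_ties, n_ties = n_ties, mode = "rank")
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    if (!is.null(seed)) set.seed(seed)
    a <- ps[sample.int(np, n_samples, replace = TRUE)]
    b <- ns[sample.int(nn, n_samples, replace = TRUE)]
    n_wins <- sum(a > b)
    n_ties <- sum(a == b)
    list(auc = (n_wins + 0.5 * n_ties) / n_samples, n = n_samples,
         n_wins = n_wins, n_ties = n_ties, mode = "sampled")
  }
}

#' AUC of a scorer against a train/probe split
#'
#' The AUC is the probability that a randomly chosen probe ("missing")
#' link scores higher than a randomly chosen non-existent link, ties
#' counted half:
#' \deqn{AUC = (n' + 0.5\,n'')/n}
#' over `n` comparisons with `n'` wins and `n''` ties. The default `"rank"`
#' mode computes the exact value over all probe x non-link pairs from
#' ranks; `"sampled"` mode draws `n_samples` comparisons with replacement,
#' which is the literal sampling protocol and converges to the rank value.
#' A scorer assigning i.i.d. random scores has AUC near 0.5; 1.0 is perfect.
#'
#' @param scores A score table over the candidate pairs of the training
#'   graph (see [score_all()]); candidates absent from the table score 0.
#' @param split A [split_edges()] result.
#' @param net The full network the split was made from.
#' @param mode `"rank"` (exact, default) or `"sampled"`.
#' @param n_samples Number of comparisons in sampled mode.
#' @param seed Seed for sampled mode.
#' @return A list with elements `auc`, `n`, `n_wins`, `n_ties`, `mode`.
#' @export
auc_score <- function(scores, split, net, mode = c("rank", "sampled"),
                      n_samples = 1e5, seed = NULL) {
  mode <- match.arg(mode)
  .check_network(net)
  stopifnot(inherits(split, "train_probe_split"))
  S <- .table_to_matrix(scores, net)
  v <- .split_score_vectors(S, net, split)
  .auc_from_vectors(v$probe, v$nonlink, mode, n_samples, seed)
}

.precision_from_vectors <- function(sc, is_probe, cutoff, seed) {
  n_cand <- length(sc)
  if (cutoff < 1) stop("`cutoff` must be at least 1", call. = FALSE)
  if (n_cand < cutoff) {
    stop("precision cutoff ", cutoff, " exceeds the ", n_cand,
         " candidate pairs", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)
  tie_break <- sample.int(n_cand)  # seeded permutation → unbiased tie handling
  top <- order(-sc, tie_break)[seq_len(cutoff)]
  m <- sum(is_probe[top])
  list(precision = m / cutoff, hits = as.integer(m), cutoff = as.integer(cutoff))
}

#' Precision at the top L predicted links
#'
#' Ranks all candidate (non-observed) pairs by descending score and
#' reports the fraction of the top `cutoff` that are probe links:
#' \eqn{precision = m/L}. Ties at the cutoff are broken by a seeded random
#' permutation so that averages over realizations are unbiased.
#'
#' @inheritParams auc_score
#' @param cutoff The list length L (100 by convention).
#' @param seed Seed for the tie-breaking permutation.
#' @return A list with elements `precision`, `hits` (m), `cutoff` (L).
#' @export
precision_at <- function(scores, split, net, cutoff = 100, seed = NULL) {
  .check_network(net)
  stopifnot(inherits(split, "train_probe_split"))
  S <- .table_to_matrix(scores, net)
  v <- .split_score_vectors(S, net, split)
  .precision_from_vectors(v$cand_scores, v$cand_is_probe, cutoff, seed)
}

#' Evaluate a similarity index over repeated train/probe realizations
#'
#' The standard protocol: for each realization, split the edges (90/10 by
#' default), score all candidate pairs on the training graph, and compute
#' AUC and precision@L; report per-realization values and their mean and
#' standard deviation over (by convention) 20 independent splits.
#'
#' @param net Undirected simple `igraph` with named vertices.
#' @param index Index name, see [score_all()].
#' @param beta,alpha,epsilon Index parameters, see [score_all()].
#' @param n_realizations Number of independent splits.
#' @param train_fraction Fraction of edges kept for training.
#' @param cutoff Precision list length L.
#' @param seeds Integer vector of split seeds, one per realization
#'   (default `1:n_realizations`).
#' @param auc_mode `"rank"` or `"sampled"`, see [auc_score()].
#' @param n_samples Comparisons per realization in sampled mode.
#' @return An object of class `eval_result`: list with `per_realization`
#'   (data frame: realization, seed, auc, precision) and `summary`
#'   (data frame: mean/sd of both metrics), plus the call parameters.
#' @export
evaluate_index <- function(net, index, beta = 1, alpha = 0.001, epsilon = 0.01,
                           n_realizations = 20, train_fraction = 0.9,
                           cutoff = 100, seeds = NULL,
                           auc_mode = c("rank", "sampled"), n_samples = 1e5) {
  auc_mode <- match.arg(auc_mode)
  .check_network(net)
  if (n_realizations < 1) stop("`n_realizations` must be at least 1", call. = FALSE)
  if (is.null(seeds)) seeds <- seq_len(n_realizations)
  if (length(seeds) != n_realizations) {
    stop("`seeds` must have one entry per realization", call. = FALSE)
  }
  rows <- lapply(seq_len(n_realizations), function(r) {
    sp <- split_edges(net, train_fraction, seeds[r])
    tr <- train_network(net, sp)
    S <- tryCatch(
      .score_matrix(tr, index, beta = beta, alpha = alpha, epsilon = epsilon),
      error = function(e) stop("realization ", r, ": ", conditionMessage(e),
                               call. = FALSE))
    v <- .split_score_vectors(S, net, sp)
    a <- .auc_from_vectors(v$probe, v$nonlink, auc_mode, n_samples,
                           seed = seeds[r] + 1L)
    p <- .precision_from_vectors(v$cand_scores, v$cand_is_probe, cutoff,
                                 seed = seeds[r] + 2L)
    data.frame(realization = r, seed = seeds[r], auc = a$auc,
               precision = p$precision)
  })
  per <- do.call(rbind, rows)
  structure(list(
    per_realization = per,
    summary = data.frame(
      metric = c("auc", "precision"),
      mean = c(mean(per$auc), mean(per$precision)),
      sd = c(stats::sd(per$auc), stats::sd(per$precision))
    ),
    index = index,
    params = list(beta = beta, alpha = alpha, epsilon = epsilon),
    cutoff = cutoff, train_fraction = train_fraction
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("index %s over %d realization(s):\n", x$index,
              nrow(x$per_realization)))
  cat(sprintf("  AUC       %.4f (sd %.4f)\n", x$summary$mean[1], x$summary$sd[1]))
  cat(sprintf("  precision %.4f (sd %.4f) at L = %d\n",
              x$summary$mean[2], x$summary$sd[2], x$cutoff))
  invisible(x)
}

#' Sweep the PIC strength parameter over a grid
#'
#' Runs the full evaluation protocol for each value of \eqn{\beta} on a
#' shared set of train/probe splits (same seeds at every grid point, so the
#' curves are comparable), and reports the grid curve together with the
#' best-performing grid point ("PIC-Max").
#'
#' @inheritParams evaluate_index
#' @param beta_grid Non-empty vector of non-negative \eqn{\beta} values
#'   (default `seq(0, 5, by = 0.1)`).
#' @return An object of class `sweep_result`: list with `grid` (data frame:
#'   beta, mean_auc, sd_auc, mean_precision, sd_precision), `best_beta_auc`,
#'   `max_auc`, `best_beta_precision`, `max_precision`, `n_realizations`.
#' @export
beta_sweep <- function(net, beta_grid = seq(0, 5, by = 0.1),
                       n_realizations = 20, train_fraction = 0.9,
                       cutoff = 100, seeds = NULL,
                       auc_mode = c("rank", "sampled"), n_samples = 1e5) {
  auc_mode <- match.arg(auc_mode)
  .check_network(net)
  if (length(beta_grid) == 0 || any(beta_grid < 0)) {
    stop("`beta_grid` must be a non-empty vector of non-negative values",
         call. = FALSE)
  }
  if (is.null(seeds)) seeds <- seq_len(n_realizations)
  if (length(seeds) != n_realizations) {
    stop("`seeds` must have one entry per realization", call. = FALSE)
  }
  auc_mat <- matrix(NA_real_, n_realizations, length(beta_grid))
  prec_mat <- matrix(NA_real_, n_realizations, length(beta_grid))
  for (r in seq_len(n_realizations)) {
    sp <- split_edges(net, train_fraction, seeds[r])
    tr <- train_network(net, sp)
    A <- .adjacency(tr)
    B <- .pic_base(A)  # beta-independent: shared across the grid
    for (gi in seq_along(beta_grid)) {
      S <- .pic_matrix_from_base(B, A, beta_grid[gi])
      v <- .split_score_vectors(S, net, sp)
      a <- .auc_from_vectors(v$probe, v$nonlink, auc_mode, n_samples,
                             seed = seeds[r] + 1L)
      p <- .precision_from_vectors(v$cand_scores, v$cand_is_probe, cutoff,
                                   seed = seeds[r] + 2L)
      auc_mat[r, gi] <- a$auc
      prec_mat[r, gi] <- p$precision
    }
  }
  grid <- data.frame(
    beta = beta_grid,
    mean_auc = colMeans(auc_mat),
    sd_auc = apply(auc_mat, 2, stats::sd),
    mean_precision = colMeans(prec_mat),
    sd_precision = apply(prec_mat, 2, stats::sd)
  )
  structure(list(
    grid = grid,
    best_beta_auc = beta_grid[which.max(grid$mean_auc)],
    max_auc = max(grid$mean_auc),
    best_beta_precision = beta_grid[which.max(grid$mean_precision)],
    max_precision = max(grid$mean_precision),
    n_realizations = n_realizations
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("beta sweep over %d grid point(s), %d realization(s):\n",
              nrow(x$grid), x$n_realizations))
  cat(sprintf("  max AUC       %.4f at beta = %g\n", x$max_auc, x$best_beta_auc))
  cat(sprintf("  max precision %.4f at beta = %g\n",
              x$max_precision, x$best_beta_precision))
  invisible(x)
}
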