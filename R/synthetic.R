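#' Generate a Barabasi-Albert preferential-attachment network
#'
#' Grows a scale-free graph: starting from a complete seed on
#' `m_attach + 1` nodes, each new node attaches to `m_attach` distinct
#' existing nodes drawn without replacement with probability proportional
#' to their current degree. The result has
#' `choose(m_attach + 1, 2) + m_attach * (n_nodes - m_attach - 1)` edges and
#' a heavy-tailed degree distribution (heterogeneity well above 1), and is
#' fully reproducible from the seed. This is the stand-in for scale-free
#' benchmark networks; note that plain preferential attachment gives lower
#' clustering than many published scale-free benchmarks, so quantitative
#' results on it are not comparable to theirs.
#'
#' @param n_nodes Number of nodes (at least 3).
#' @param m_attach Edges added per new node (at least 1, below `n_nodes`).
#' @param seed Integer seed.
#' @return An undirected simple `igraph` with nodes named `"1"..."n_nodes"`.
#' @examples
#' g <- generate_ba(100, 2, seed = 42)
#' topology_stats(g)
#' @export
generate_ba <- function(n_nodes, m_attach, seed = 1L) {
  if (n_nodes < 3) stop("`n_nodes` must be at least 3", call. = FALSE)
  if (m_attach < 1 || m_attach >= n_nodes) {
    stop("`m_attach` must be in [1, n_nodes - 1]", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n0 <- m_attach + 1
  seed_pairs <- utils::combn(n0, 2)
  us <- seed_pairs[1, ]; vs <- seed_pairs[2, ]
  deg <- integer(n_nodes)
  deg[seq_len(n0)] <- m_attach
  if (n0 < n_nodes) {
    extra_u <- integer(m_attach * (n_nodes - n0))
    extra_v <- extra_u
    pos <- 0L
    for (v in (n0 + 1):n_nodes) {
      existing <- seq_len(v - 1L)
      # sequential weighted draws without replacement, weights ∝ degree
      targets <- sample(existing, m_attach, prob = deg[existing])
      ix <- pos + seq_len(m_attach)
      extra_u[ix] <- targets
      extra_v[ix] <- v
      pos <- pos + m_attach
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m_attach
    }
    us <- c(us, extra_u); vs <- c(vs, extra_v)
  }
  .make_network(cbind(as.character(us), as.character(vs)),
                as.character(seq_len(n_nodes)))
}

#' Small deterministic fixture networks
#'
#' Named toy graphs with hand-verifiable index values, used throughout the
#' documentation and tests:
#' \describe{
#'   \item{`bucket5`}{5 nodes, edges 1-2, 2-3, 3-4, 4-5, 2-4 (degrees
#'     1, 3, 2, 3, 1); the worked example for the information-capacity
#'     scores.}
#'   \item{`path3`}{the 3-node path 1-2-3, whose Laplacian pseudoinverse is
#'     known in closed form.}
#'   \item{`triangle`}{the 3-cycle.}
#'   \item{`k2`}{a single edge.}
#'   \item{`k4`}{the complete graph on 4 nodes.}
#' }
#'
#' @param name One of `"bucket5"`, `"path3"`, `"triangle"`, `"k2"`, `"k4"`.
#' @return An undirected simple `igraph` with named vertices.
#' @export
fixture_graph <- function(name) {
  edges <- switch(name,
    bucket5 = cbind(c("1", "2", "3", "4", "2"), c("2", "3", "4", "5", "4")),
    path3 = cbind(c("1", "2"), c("2", "3")),
    triangle = cbind(c("1", "2", "3"), c("2", "3", "1")),
    k2 = cbind("1", "2"),
    k4 = {
      p <- utils::combn(4, 2)
      cbind(as.character(p[1, ]), as.character(p[2, ]))
    },
    stop("unknown fixture '", name,
         "'; available: bucket5, path3, triangle, k2, k4", call. = FALSE)
  )
  labels <- as.character(sort(unique(as.integer(c(edges)))))
  .make_network(edges, labels)
}
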