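#' @importFrom stats runif sd
#' @importFrom utils write.table read.table
NULL

# Internal: validate that `net` is an undirected simple igraph with named
# vertices; all package functions assume this shape.
.check_network <- function(net) {
  if (!igraph::is_igraph(net)) {
    stop("`net` must be an igraph object (see read_edge_list(), fixture_graph())",
         call. = FALSE)
  }
  if (igraph::is_directed(net)) {
    stop("`net` must be undirected", call. = FALSE)
  }
  if (is.null(igraph::V(net)$name)) {
    stop("`net` must have named vertices", call. = FALSE)
  }
  invisible(net)
}

# Internal: map node labels to vertex indices, erroring on unknown labels.
.node_id <- function(net, x) {
  idx <- match(as.character(x), igraph::V(net)$name)
  if (anyNA(idx)) {
    bad <- as.character(x)[is.na(idx)]
    stop("unknown node label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}

# Internal: build an undirected simple named graph from a 2-column character
# matrix of edges plus the full label set (keeps isolated nodes).
.make_network <- function(edges, labels) {
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  igraph::V(g)$name <- labels
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(edges[, 1], labels),
                                    match(edges[, 2], labels)))
  }
  g
}

#' Read an undirected simple network from an edge-list file
#'
#' Parses a plain-text edge list: one edge per line, two whitespace- or
#' tab-delimited node labels, `#` starting a comment. An optional third
#' column (e.g. a weight) is ignored. Self-loop lines are dropped and
#' duplicate edges (including reversed duplicates) are collapsed, each with
#' a warning giving the count. Node order is first-appearance order.
#' A comment header of the form `# isolated-nodes: a b c` (as written by
#' [write_edge_list()]) restores isolated vertices so that read/write
#' round-trips preserve the vertex set.
#'
#' @param path Path to the edge-list file (or a connection).
#' @return An undirected simple `igraph` object with named vertices.
#' @seealso [write_edge_list()], [read_graphml()]
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty edge-list input: ", path, call. = FALSE)

  isolated <- character(0)
  iso <- grepl("^#\\s*isolated-nodes:", lines)
  if (any(iso)) {
    payload <- sub("^#\\s*isolated-nodes:\\s*", "", lines[iso])
    isolated <- unlist(strsplit(payload, "\\s+"))
    isolated <- isolated[nzchar(isolated)]
  }

  # strip comments and blank lines, remembering original line numbers
  stripped <- sub("#.*$", "", lines)
  keep <- grepl("\\S", stripped)
  if (!any(keep) && length(isolated) == 0) {
    stop("empty edge-list input (no edges and no isolated-node header): ",
         path, call. = FALSE)
  }
  toks <- strsplit(trimws(stripped[keep]), "\\s+")
  lineno <- which(keep)
  nt <- lengths(toks)
  if (any(nt < 2)) {
    stop("malformed edge-list line ", lineno[which(nt < 2)[1]],
         ": fewer than 2 tokens", call. = FALSE)
  }
  u <- vapply(toks, `[`, character(1), 1L)
  v <- vapply(toks, `[`, character(1), 2L)

  self <- u == v
  if (any(self)) {
    warning(sum(self), " self-loop line(s) dropped", call. = FALSE)
    u <- u[!self]; v <- v[!self]
  }
  # first-appearance node order over the raw token stream
  labels <- unique(c(rbind(u, v), isolated))
  key <- paste(pmin(u, v), pmax(u, v), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge line(s) collapsed", call. = FALSE)
    u <- u[!dup]; v <- v[!dup]
  }
  .make_network(cbind(u, v), labels)
}

#' Read a network from a GraphML file
#'
#' Interoperability reader; the plain edge list is the canonical format.
#' The graph is coerced to an undirected simple graph and vertices without
#' a `name` attribute are labelled by their index.
#'
#' @param path Path to a GraphML file.
#' @return An undirected simple `igraph` object with named vertices.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}

#' Write a network as a plain-text edge list
#'
#' Writes one `u<TAB>v` line per unordered edge, pairs ordered
#' lexicographically within and across lines. Isolated vertices are recorded
#' in a `# isolated-nodes:` comment header so that
#' `read_edge_list(write_edge_list(net))` preserves the vertex set.
#'
#' @param net Undirected simple `igraph` with named vertices.
#' @param path Output file path (or connection).
#' @param header Optional character vector of extra comment lines (written
#'   prefixed with `# `).
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path, header = NULL) {
  .check_network(net)
  el <- igraph::as_edgelist(net, names = TRUE)
  out <- character(0)
  if (!is.null(header)) out <- c(out, paste("#", header))
  deg <- igraph::degree(net)
  if (any(deg == 0)) {
    out <- c(out, paste("# isolated-nodes:",
                        paste(igraph::V(net)$name[deg == 0], collapse = " ")))
  }
  if (nrow(el) > 0) {
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])
    ord <- order(a, b)
    out <- c(out, paste(a[ord], b[ord], sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

#' Common neighbors of a node pair
#'
#' Returns the labels of all nodes adjacent to both `x` and `y`
#' (the relays of length-2 paths between them).
#'
#' @param net Undirected simple `igraph` with named vertices.
#' @param x,y Node labels.
#' @return Character vector of common-neighbor labels (possibly empty).
#' @export
common_neighbors <- function(net, x, y) {
  .check_network(net)
  ix <- .node_id(net, x); iy <- .node_id(net, y)
  nx <- as.integer(igraph::neighbors(net, ix))
  ny <- as.integer(igraph::neighbors(net, iy))
  igraph::V(net)$name[intersect(nx, ny)]
}

#' Topology statistics of a network
#'
#' Computes the standard descriptive statistics used to characterise
#' link-prediction benchmark networks: node and edge counts, mean degree
#' \eqn{\langle k\rangle = 2|E|/|V|}, mean shortest-path distance
#' \eqn{\langle d\rangle} (averaged over connected ordered pairs only),
#' mean local clustering coefficient \eqn{C} (nodes of degree < 2 contribute
#' 0), degree assortativity \eqn{r} (Pearson correlation of degrees over edge
#' endpoints; `NaN` for edgeless graphs) and degree heterogeneity
#' \eqn{H = \langle k^2\rangle/\langle k\rangle^2} (1 for regular graphs,
#' large for power-law networks).
#'
#' @param net Undirected simple `igraph` with named vertices, at least 2 nodes.
#' @return An object of class `topology_stats`: a list with elements
#'   `n_nodes`, `n_edges`, `mean_degree`, `mean_distance`, `clustering`,
#'   `assortativity`, `heterogeneity`.
#' @export
topology_stats <- function(net) {
  .check_network(net)
  n <- igraph::vcount(net)
  if (n < 2) stop("topology_stats requires at least 2 nodes", call. = FALSE)
  m <- igraph::ecount(net)
  k <- igraph::degree(net)
  res <- list(
    n_nodes = n,
    n_edges = m,
    mean_degree = 2 * m / n,
    mean_distance = if (m > 0) igraph::mean_distance(net, unconnected = TRUE) else NaN,
    clustering = if (m > 0)
      igraph::transitivity(net, type = "localaverage", isolates = "zero")
    else 0,
    assortativity = if (m > 0) igraph::assortativity_degree(net) else NaN,
    heterogeneity = if (m > 0) mean(k^2) / mean(k)^2 else NaN
  )
  class(res) <- "topology_stats"
  res
}

#' @export
print.topology_stats <- function(x, ...) {
  cat(sprintf("network: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  <k> = %.2f  <d> = %.2f  C = %.3f  r = %.3f  H = %.2f\n",
              x$mean_degree, x$mean_distance, x$clustering,
              x$assortativity, x$heterogeneity))
  invisible(x)
}

#' @export
format.topology_stats <- function(x, ...) {
  paste(names(unclass(x)), vapply(unclass(x), format, character(1)),
        sep = "\t")
}
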