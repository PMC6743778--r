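# Network input, filtering and the regularised Laplacian kernel.
#
# Graphs are plain undirected igraph objects with a `weight` edge attribute
# in [0, 1]; the kernel is a dense symmetric matrix with gene ids as dimnames.

#' Read a weighted gene network from a TSV edge list
#'
#' Two dialects are supported. `plain` expects columns `node_a`, `node_b`
#' and `weight` (weights already on the \[0, 1\] scale). `string_channels`
#' expects a STRING-style detailed-scores layout: two node columns followed
#' by per-channel evidence scores and a `combined_score`, all on the 0--1000
#' STRING scale; rows are filtered with [filter_string_edges()] and the
#' combined score is rescaled to \[0, 1\].
#'
#' Duplicate edges are collapsed keeping the maximum weight, self-loops are
#' dropped and weights are clamped to \[0, 1\].
#'
#' @param path Path to a tab-separated edge list with a header line.
#' @param dialect `"plain"` or `"string_channels"`.
#' @param min_combined Minimum combined score (strict `>`), STRING dialect only.
#' @param required_channels Character vector of channel column names of which
#'   at least one must be positive, STRING dialect only.
#' @return An undirected, weighted `igraph` graph.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("node_a\tnode_b\tweight", "a\tb\t0.5", "b\tc\t0.9"), tf)
#' g <- read_edge_list(tf)
#' igraph::ecount(g)
#' @export
read_edge_list <- function(path,
                           dialect = c("plain", "string_channels"),
                           min_combined = 700,
                           required_channels = c("experiments", "databases")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("edge list not found: ", path, call. = FALSE)
  rows <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(rows) == 0L) {
    warning("empty edge list: ", path, call. = FALSE)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (dialect == "plain") {
    needed <- c("node_a", "node_b", "weight")
    if (!all(needed %in% names(rows))) {
      stop("plain dialect requires columns node_a, node_b, weight", call. = FALSE)
    }
    w <- suppressWarnings(as.numeric(rows$weight))
    bad <- which(!is.finite(w) | !nzchar(rows$node_a) | !nzchar(rows$node_b))
    if (length(bad) > 0L) {
      stop(sprintf("malformed edge-list row at line %d of %s",
                   bad[1] + 1L, path), call. = FALSE)
    }
    build_weighted_graph(rows$node_a, rows$node_b, pmin(pmax(w, 0), 1))
  } else {
    filter_string_edges(rows, min_combined = min_combined,
                        required_channels = required_channels)
  }
}

#' Filter STRING-style scored edges and build a weighted graph
#'
#' Keeps rows whose combined score strictly exceeds `min_combined` and that
#' have a positive score in at least one of the `required_channels`. Edge
#' weights are the combined score rescaled from the 0--1000 STRING scale
#' to \[0, 1\].
#'
#' @param graph_rows Data frame of raw STRING rows: two node id columns (the
#'   first two columns, or `node_a`/`node_b`), per-channel score columns and
#'   a `combined_score` column, all on the 0--1000 scale.
#' @inheritParams read_edge_list
#' @return An undirected, weighted `igraph` graph.
#' @export
filter_string_edges <- function(graph_rows, min_combined = 700,
                                required_channels = c("experiments", "databases")) {
  stopifnot(is.data.frame(graph_rows))
  nm <- names(graph_rows)
  if (all(c("node_a", "node_b") %in% nm)) {
    a <- graph_rows$node_a; b <- graph_rows$node_b
  } else {
    a <- graph_rows[[1]]; b <- graph_rows[[2]]
  }
  if (!"combined_score" %in% nm) {
    stop("string_channels dialect requires a combined_score column", call. = FALSE)
  }
  missing_ch <- setdiff(required_channels, nm)
  if (length(missing_ch) > 0L) {
    stop("unknown channel name(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  combined <- as.numeric(graph_rows$combined_score)
  if (any(!is.finite(combined) | combined < 0 | combined > 1000)) {
    stop("combined_score outside [0, 1000]", call. = FALSE)
  }
  channel_ok <- rep(FALSE, nrow(graph_rows))
  for (ch in required_channels) {
    channel_ok <- channel_ok | (as.numeric(graph_rows[[ch]]) > 0)
  }
  keep <- combined > min_combined & channel_ok
  build_weighted_graph(as.character(a)[keep], as.character(b)[keep],
                       combined[keep] / 1000)
}

#' Build an undirected weighted graph from parallel edge vectors
#'
#' Collapses duplicate (unordered) edges keeping the maximum weight and
#' drops self-loops.
#' @noRd
build_weighted_graph <- function(a, b, w) {
  keep <- a != b
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  if (length(a) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  wmax <- tapply(w, key, max)
  parts <- strsplit(names(wmax), "\r", fixed = TRUE)
  el <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- as.numeric(wmax)
  g
}

#' Largest connected component of a weighted graph
#'
#' Returns the induced subgraph on the largest connected component. Ties in
#' component size are broken in favour of the component containing the
#' lexicographically smallest gene id.
#'
#' @param g An undirected `igraph` graph.
#' @return The induced subgraph on the winning component.
#' @export
largest_connected_component <- function(g) {
  stopifnot(inherits(g, "igraph"))
  if (igraph::vcount(g) == 0L) stop("empty graph has no components", call. = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    nodes <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
    min_member <- vapply(best, function(ci) min(nodes[comp$membership == ci]), "")
    best <- best[order(min_member)][1]
  } else {
    best <- best[1]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Regularised Laplacian kernel of a connected weighted graph
#'
#' Computes the dense kernel `K = (I + L)^-1` with `L = D - W` the
#' (unnormalised) weighted graph Laplacian, `W` the weighted adjacency matrix
#' and `D` the diagonal matrix of weighted degrees. On a connected graph `K`
#' is symmetric positive definite with strictly positive entries, and every
#' row sums to exactly 1 (since `(I + L) 1 = 1`).
#'
#' The normalised-Laplacian variant `L = I - D^-1/2 W D^-1/2` is available
#' through `normalised = TRUE`; the unnormalised form is the default used
#' throughout the benchmark.
#'
#' @param g A connected, undirected `igraph` graph (weights default to 1
#'   where the `weight` attribute is absent).
#' @param normalised Use the symmetric normalised Laplacian instead.
#' @param node_cap Guard against accidentally inverting huge dense matrices;
#'   graphs above this node count raise an error.
#' @return A dense symmetric matrix with gene ids as dimnames.
#' @export
regularized_laplacian_kernel <- function(g, normalised = FALSE,
                                         node_cap = 20000L) {
  stopifnot(inherits(g, "igraph"))
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph", call. = FALSE)
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected; extract the largest connected component ",
         "with largest_connected_component() first", call. = FALSE)
  }
  if (n > node_cap) {
    stop(sprintf(paste0("graph has %d nodes, above the dense-kernel cap of %d; ",
                        "raise node_cap explicitly if this is intended"),
                 n, node_cap), call. = FALSE)
  }
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = edge_weight_attr(g),
                                             sparse = TRUE))
  d <- rowSums(W)
  if (normalised) {
    inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
    L <- diag(n) - (inv_sqrt %o% inv_sqrt) * W
  } else {
    L <- diag(d, n) - W
  }
  K <- solve(diag(n) + L)
  K <- (K + t(K)) / 2
  nodes <- igraph::V(g)$name %||% as.character(seq_len(n))
  dimnames(K) <- list(nodes, nodes)
  K
}

#' Name of the weight attribute, or NULL for unweighted graphs
#' @noRd
edge_weight_attr <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL
}

#' Node identifiers of a graph or kernel, in index order
#' @noRd
node_index <- function(x) {
  if (inherits(x, "igraph")) {
    igraph::V(x)$name %||% as.character(seq_len(igraph::vcount(x)))
  } else if (is.matrix(x)) {
    rownames(x)
  } else {
    stop("cannot extract a node index from ", class(x)[1], call. = FALSE)
  }
}

#' Write a weighted graph back to a plain TSV edge list
#'
#' @param g Weighted `igraph` graph.
#' @param path Output path.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g)
  w <- if (is.null(edge_weight_attr(g))) rep(1, nrow(el)) else igraph::E(g)$weight
  utils::write.table(
    data.frame(node_a = el[, 1], node_b = el[, 2], weight = w),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
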