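# Fixtures are generated in code; no binary data is stored.

# Connected Erdos-Renyi graph with unit (or supplied) weights.
make_connected_gnp <- function(n, p, seed, weights = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  igraph::E(g)$weight <- rep_len(weights, igraph::ecount(g))
  g
}

# Path graph a-b-c-... with unit weights.
make_path_graph <- function(nodes) {
  g <- igraph::make_ring(length(nodes), circular = FALSE)
  igraph::V(g)$name <- nodes
  igraph::E(g)$weight <- 1
  g
}

# Star graph: first node is the centre.
make_star_graph <- function(n) {
  g <- igraph::make_star(n, mode = "undirected", center = 1)
  igraph::V(g)$name <- sprintf("s%02d", seq_len(n))
  igraph::E(g)$weight <- 1
  g
}

# Direct (I + L)^-1 y solve, independent of the kernel code path.
oracle_diffusion <- function(g, y) {
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  L <- diag(rowSums(W)) - W
  unname(drop(solve(diag(nrow(W)) + L, y)))
}

# Write a small plain edge list TSV and return its path.
write_tmp_edges <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("node_a\tnode_b\tweight", lines), tf)
  tf
}

# Closed-form permutation-null standard deviation of raw diffusion scores.
attr_sd <- function(K, n_pos) {
  n <- ncol(K)
  sqrt(n_pos * (n - n_pos) / (n - 1) * (rowMeans(K^2) - rowMeans(K)^2))
}

# Curated disease-stream overlap table shipped with the package.
overlap_table <- function() {
  utils::read.delim(
    system.file("extdata", "disease_stream_overlap.tsv", package = "netbench"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
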