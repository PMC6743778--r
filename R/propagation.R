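# Diffusion-based prioritisers and input-naive baselines.
#
# All scorers return a named numeric vector over the kernel/graph node index
# with a "method" attribute; higher scores mean stronger predicted
# association.

#' Raw diffusion scores
#'
#' Classical label diffusion: `scores = K y`, with `y` the 0/1 indicator of
#' the training positives and `K` the regularised Laplacian kernel. Because
#' kernel rows sum to 1, raw scores are convex-combination smoothings of the
#' input labels.
#'
#' @param K Regularised Laplacian kernel ([regularized_laplacian_kernel()]).
#' @param labels A `label_set` or character vector of positive gene ids;
#'   positives absent from the kernel index are dropped with a warning.
#' @return Named numeric score vector.
#' @export
diffuse_raw <- function(K, labels) {
  nodes <- node_index(K)
  pos <- restrict_positives(as_positives(labels), nodes)
  if (length(pos) == 0L) {
    stop("no positive genes present in the kernel index", call. = FALSE)
  }
  y <- indicator_vector(nodes, pos)
  score_vector(drop(K %*% y), nodes, "raw")
}

#' GeneMANIA-weighted diffusion scores
#'
#' Diffusion with a three-level input: `+1` on positives, `-1` on known
#' (training) negatives and, on unlabelled genes, the bias term
#' `(n+ - n-) / (n+ + n-)` computed over the labelled genes; the result is
#' `K y'`.
#'
#' @inheritParams diffuse_raw
#' @param training_negatives Character vector of negatively labelled gene
#'   ids (disjoint from the positives).
#' @return Named numeric score vector.
#' @export
diffuse_gm <- function(K, labels, training_negatives = character()) {
  nodes <- node_index(K)
  pos <- restrict_positives(as_positives(labels), nodes)
  neg <- intersect(unique(as.character(training_negatives)), nodes)
  if (length(intersect(pos, neg)) > 0L) {
    stop("positive and negative sets overlap", call. = FALSE)
  }
  if (length(pos) == 0L) {
    stop("no positive genes present in the kernel index", call. = FALSE)
  }
  n_pos <- length(pos); n_neg <- length(neg)
  bias <- (n_pos - n_neg) / (n_pos + n_neg)
  y <- rep(bias, length(nodes))
  names(y) <- nodes
  y[pos] <- 1
  y[neg] <- -1
  score_vector(drop(K %*% y), nodes, "gm")
}

#' Null moments of raw diffusion under label permutation
#'
#' For a binary input with `n_pos` ones permuted uniformly over `n` genes,
#' the raw score of gene i is a sum of `n_pos` kernel entries sampled without
#' replacement from row i of K. Closed-form mean and variance follow from
#' simple random sampling theory.
#' @noRd
permutation_null_moments <- function(K, n_pos) {
  n <- ncol(K)
  row_mean <- rowMeans(K)
  row_var <- rowMeans(K^2) - row_mean^2        # population variance of row entries
  mu <- n_pos * row_mean
  sigma2 <- if (n > 1) n_pos * (n - n_pos) / (n - 1) * row_var else rep(0, n)
  list(mean = mu, var = pmax(sigma2, 0))
}

#' Z-score normalised diffusion scores
#'
#' Standardises each gene's raw diffusion score against its null distribution
#' under uniform permutation of the binary input vector (sampling without
#' replacement), using closed-form moments from the kernel row statistics:
#' `z_i = (raw_i - E raw_i) / sd(raw_i)`. This adjusts for topology-related
#' biases in the raw scores. Genes with a degenerate (constant) kernel row
#' get score 0 with a warning.
#'
#' @inheritParams diffuse_raw
#' @return Named numeric score vector.
#' @export
diffuse_z <- function(K, labels) {
  nodes <- node_index(K)
  pos <- restrict_positives(as_positives(labels), nodes)
  n <- length(nodes)
  if (length(pos) == 0L || length(pos) >= n) {
    stop("z-scores require 0 < n_positives < n_genes", call. = FALSE)
  }
  raw <- drop(K %*% indicator_vector(nodes, pos))
  mom <- permutation_null_moments(K, length(pos))
  sd0 <- sqrt(mom$var)
  degenerate <- sd0 < .Machine$double.eps^0.5
  if (any(degenerate)) {
    warning(sprintf("%d gene(s) with degenerate null variance scored 0",
                    sum(degenerate)), call. = FALSE)
  }
  z <- ifelse(degenerate, 0, (raw - mom$mean) / sd0)
  score_vector(z, nodes, "z")
}

#' Monte Carlo normalised diffusion scores
#'
#' Empirical analogue of [diffuse_z()]: the score of gene i is the fraction
#' of `n_perm` uniform label permutations whose raw diffusion score at i
#' falls strictly below the observed raw score, i.e. an empirical quantile
#' in \[0, 1\] (higher = better, uniformly with the other methods).
#'
#' @inheritParams diffuse_raw
#' @param n_perm Number of label permutations (at least 100).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return Named numeric score vector.
#' @export
diffuse_mc <- function(K, labels, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  nodes <- node_index(K)
  pos <- restrict_positives(as_positives(labels), nodes)
  if (length(pos) == 0L) {
    stop("no positive genes present in the kernel index", call. = FALSE)
  }
  n <- length(nodes)
  y <- indicator_vector(nodes, pos)
  raw <- drop(K %*% y)
  perm_mat <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
  })
  perm_scores <- K %*% perm_mat                 # n x n_perm
  below <- rowSums(perm_scores < raw)
  score_vector(below / n_perm, nodes, "mc")
}

#' Personalised PageRank scores
#'
#' Random walk with restart to the uniform distribution over the positive
#' genes; scores are the stationary distribution (summing to 1).
#'
#' @param g Connected weighted `igraph` graph.
#' @param labels A `label_set` or character vector of positive gene ids.
#' @param damping Continuation probability of the walk, in (0, 1).
#' @return Named numeric score vector.
#' @export
personalized_pagerank <- function(g, labels, damping = 0.85) {
  if (damping <= 0 || damping >= 1) {
    stop("damping must lie in (0, 1)", call. = FALSE)
  }
  nodes <- node_index(g)
  pos <- restrict_positives(as_positives(labels), nodes, "graph")
  if (length(pos) == 0L) {
    stop("no positive genes present in the graph", call. = FALSE)
  }
  reset <- indicator_vector(nodes, pos)
  pr <- igraph::page_rank(g, damping = damping, personalized = reset,
                          weights = NULL)$vector
  score_vector(as.numeric(pr), nodes, "ppr")
}

#' PageRank with a uniform prior (input-naive topology baseline)
#'
#' @inheritParams personalized_pagerank
#' @return Named numeric score vector.
#' @export
pagerank_uniform <- function(g, damping = 0.85) {
  if (damping <= 0 || damping >= 1) {
    stop("damping must lie in (0, 1)", call. = FALSE)
  }
  nodes <- node_index(g)
  pr <- igraph::page_rank(g, damping = damping, weights = NULL)$vector
  score_vector(as.numeric(pr), nodes, "pr")
}

#' Raw diffusion of a randomly permuted input (topology-bias baseline)
#'
#' Applies [diffuse_raw()] to a uniform permutation of the label indicator,
#' quantifying how much of the raw-diffusion signal is attributable to the
#' network topology alone.
#'
#' @inheritParams diffuse_mc
#' @return Named numeric score vector.
#' @export
randomraw_scores <- function(K, labels, seed = 1L) {
  nodes <- node_index(K)
  pos <- restrict_positives(as_positives(labels), nodes)
  if (length(pos) == 0L) {
    stop("no positive genes present in the kernel index", call. = FALSE)
  }
  y <- indicator_vector(nodes, pos)
  y_perm <- with_seed(seed, sample(y))
  score_vector(drop(K %*% y_perm), nodes, "randomraw")
}

#' Uniform random scores (pure-chance baseline)
#'
#' @param nodes Character vector of gene ids to score.
#' @param seed Integer seed.
#' @return Named numeric score vector of i.i.d. Uniform(0, 1) draws.
#' @export
random_scores <- function(nodes, seed = 1L) {
  score_vector(with_seed(seed, stats::runif(length(nodes))), nodes, "random")
}

#' Neighbour-voting scores (EGAD-style guilt by association)
#'
#' The score of gene i is the weighted fraction of its neighbours that are
#' positive: `sum_j w_ij y_j / sum_j w_ij` over neighbours j. A gene whose
#' neighbours are all positive scores 1; one with no positive neighbour
#' scores 0. Isolated nodes (impossible after LCC extraction) score 0 with
#' a warning.
#'
#' @inheritParams personalized_pagerank
#' @return Named numeric score vector.
#' @export
egad_neighbor_voting <- function(g, labels) {
  nodes <- node_index(g)
  pos <- restrict_positives(as_positives(labels), nodes, "graph")
  W <- igraph::as_adjacency_matrix(g, attr = edge_weight_attr(g), sparse = TRUE)
  y <- indicator_vector(nodes, pos)
  votes <- as.numeric(W %*% y)
  strength <- as.numeric(W %*% rep(1, length(nodes)))
  isolated <- strength == 0
  if (any(isolated)) {
    warning(sprintf("%d isolated node(s) scored 0", sum(isolated)),
            call. = FALSE)
  }
  s <- ifelse(isolated, 0, votes / pmax(strength, .Machine$double.xmin))
  score_vector(s, nodes, "egad")
}
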