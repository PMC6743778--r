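# Semi-supervised kernel scorers and supervised classifiers on
# diffusion-derived features.

#' Eligible positive columns for kernel scorers
#'
#' For gene i the eligible positives are the training positives other than i
#' itself; a positive gene with no other positive falls back to its own
#' self-similarity so every gene receives a finite score.
#' @noRd
kernel_to_positives <- function(K, positives) {
  nodes <- node_index(K)
  pos <- restrict_positives(unique(as.character(positives)), nodes)
  if (length(pos) == 0L) stop("no positive genes in the kernel index", call. = FALSE)
  list(nodes = nodes, pos = pos, Kp = K[, pos, drop = FALSE])
}

#' k-nearest-positives kernel score
#'
#' Scores gene i by the mean of the k largest kernel similarities
#' `K(i, j)` over training positives j (excluding i itself). With
#' `k = n_positives` this is the average similarity to all positives; with
#' `k = 1` it is the similarity to the closest positive.
#'
#' @param K Regularised Laplacian kernel.
#' @param positives Character vector of training positive gene ids.
#' @param k Number of nearest positives to average (default 3); values above
#'   the number of eligible positives are truncated with a warning.
#' @return Named numeric score vector.
#' @export
knn_score <- function(K, positives, k = 3L) {
  ctx <- kernel_to_positives(K, positives)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k > length(ctx$pos)) {
    warning(sprintf("k = %d exceeds the %d positives; truncated", k,
                    length(ctx$pos)), call. = FALSE)
    k <- length(ctx$pos)
  }
  s <- vapply(seq_along(ctx$nodes), function(i) {
    sims <- ctx$Kp[i, ]
    self <- match(ctx$nodes[i], ctx$pos)
    if (!is.na(self)) sims <- sims[-self]
    if (length(sims) == 0L) return(K[i, i])
    mean(sort(sims, decreasing = TRUE)[seq_len(min(k, length(sims)))])
  }, numeric(1))
  score_vector(s, ctx$nodes, "knn")
}

#' Weighted-sum-with-linear-decay kernel score
#'
#' Uses all kernel similarities to the training positives, ordered for each
#' gene by decreasing similarity, with linearly decaying weights
#' `w_m = (n+ - m + 1) / n+` so the nearest positive counts fully and the
#' furthest counts `1/n+`. With a single positive this reduces to the raw
#' kernel similarity to it (and coincides with [knn_score()] at `k = 1`).
#'
#' @inheritParams knn_score
#' @return Named numeric score vector.
#' @export
wsld_score <- function(K, positives) {
  ctx <- kernel_to_positives(K, positives)
  s <- vapply(seq_along(ctx$nodes), function(i) {
    sims <- ctx$Kp[i, ]
    self <- match(ctx$nodes[i], ctx$pos)
    if (!is.na(self)) sims <- sims[-self]
    if (length(sims) == 0L) return(K[i, i])
    m <- length(sims)
    sum(sort(sims, decreasing = TRUE) * (m - seq_len(m) + 1) / m)
  }, numeric(1))
  score_vector(s, ctx$nodes, "wsld")
}

#' Train one C-SVC on a precomputed kernel and return oriented decision values
#'
#' Decision values are sign-corrected so that training positives score higher
#' on average than training negatives.
#' @noRd
kernel_svm_decision <- function(K, train_idx, y_train, C = 1) {
  Ktr <- kernlab::as.kernelMatrix(K[train_idx, train_idx, drop = FALSE])
  fit <- kernlab::ksvm(Ktr, factor(y_train, levels = c("neg", "pos")),
                       type = "C-svc", C = C, scaled = FALSE)
  sv <- kernlab::SVindex(fit)
  Ktest <- kernlab::as.kernelMatrix(K[, train_idx, drop = FALSE][, sv, drop = FALSE])
  dec <- as.numeric(kernlab::predict(fit, Ktest, type = "decision"))
  pos_mean <- mean(dec[train_idx][y_train == "pos"])
  neg_mean <- mean(dec[train_idx][y_train == "neg"])
  if (pos_mean < neg_mean) dec <- -dec
  dec
}

#' Bagging support vector machine on the graph kernel (ProDiGe-style)
#'
#' Positive-unlabelled learning: each bag pairs the training positives with
#' an equally sized pseudo-negative sample drawn uniformly without
#' replacement from the unlabelled genes, trains a kernel C-SVC directly on
#' the precomputed graph kernel, and records decision values for every gene;
#' the final score is the mean decision value across bags.
#'
#' @inheritParams knn_score
#' @param n_bags Number of bags (default 30).
#' @param seed Integer seed; bag sampling is deterministic given the seed.
#' @param C Soft-margin cost passed to the C-SVC.
#' @return Named numeric score vector.
#' @export
bagging_svm <- function(K, positives, n_bags = 30L, seed = 1L, C = 1) {
  nodes <- node_index(K)
  pos <- restrict_positives(unique(as.character(positives)), nodes)
  if (length(pos) < 2L) stop("bagging SVM needs at least 2 positives", call. = FALSE)
  if (n_bags < 1L) stop("n_bags must be at least 1", call. = FALSE)
  unlabelled <- setdiff(nodes, pos)
  if (length(unlabelled) < length(pos)) {
    stop("fewer unlabelled genes than positives; cannot draw pseudo-negatives",
         call. = FALSE)
  }
  pos_idx <- match(pos, nodes)
  bag_negatives <- with_seed(seed, {
    lapply(seq_len(n_bags), function(b) sample(unlabelled, length(pos)))
  })
  acc <- numeric(length(nodes))
  for (b in seq_len(n_bags)) {
    neg_idx <- match(bag_negatives[[b]], nodes)
    train_idx <- c(pos_idx, neg_idx)
    y_train <- rep(c("pos", "neg"), times = c(length(pos_idx), length(neg_idx)))
    acc <- acc + kernel_svm_decision(K, train_idx, y_train, C = C)
  }
  score_vector(acc / n_bags, nodes, "bagsvm")
}

#' Diffusion-state network embedding (MashUp-style, single network)
#'
#' Computes each node's random-walk-with-restart stationary distribution
#' (restart probability `restart` to the node itself), applies a log
#' transform with pseudocount `1/n`, and takes a rank-`d` truncated singular
#' value decomposition of the resulting n-by-n log-diffusion-state matrix.
#' Features are the left singular vectors scaled by the square root of the
#' singular values, so inner products with the companion context vectors
#' (attribute `"context"`) reconstruct the log-diffusion-state matrix at
#' full rank.
#'
#' @param g Connected weighted `igraph` graph.
#' @param d Embedding dimension, `1 <= d < n`; default `min(n %/% 2, 100)`.
#' @param restart Restart probability in (0, 1].
#' @return n-by-d numeric matrix with gene ids as rownames and attributes
#'   `"context"` (n-by-d) and `"singular_values"`.
#' @export
diffusion_state_features <- function(g, d = NULL, restart = 0.5) {
  stopifnot(inherits(g, "igraph"))
  if (!igraph::is_connected(g)) stop("graph must be connected", call. = FALSE)
  nodes <- node_index(g)
  n <- length(nodes)
  d <- d %||% min(n %/% 2L, 100L)
  if (d < 1L || d >= n) stop("d must satisfy 1 <= d < n", call. = FALSE)
  if (restart <= 0 || restart > 1) stop("restart must lie in (0, 1]", call. = FALSE)
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = edge_weight_attr(g),
                                             sparse = TRUE))
  P <- W / rowSums(W)
  # column i of S is the stationary RWR distribution restarting at node i
  S <- restart * solve(diag(n) - (1 - restart) * t(P))
  M <- t(log(S + 1 / n))                       # row i = node i's log diffusion state
  sv <- svd(M, nu = d, nv = d)
  scale <- sqrt(sv$d[seq_len(d)])
  features <- sv$u * rep(scale, each = n)
  rownames(features) <- nodes
  context <- sv$v * rep(scale, each = n)
  rownames(context) <- nodes
  attr(features, "context") <- context
  attr(features, "singular_values") <- sv$d
  attr(features, "restart") <- restart
  features
}

#' Classifier on network-embedding features (random forest / SVM)
#'
#' Fits a binary classifier to the labelled genes (training positives versus
#' supplied training negatives) on the embedding rows and scores every gene:
#' predicted positive-class probability for the forest, oriented decision
#' value for the max-margin model. Hyperparameters are library defaults.
#'
#' @param features Matrix from [diffusion_state_features()] (gene rownames).
#' @param labels A `label_set` or character vector of training positives.
#' @param training_negatives Character vector of training negative gene ids.
#' @param model `"forest"` (random forest) or `"max_margin"` (SVM).
#' @param seed Integer seed controlling the stochastic parts of the fit.
#' @return Named numeric score vector.
#' @export
train_feature_classifier <- function(features, labels, training_negatives,
                                     model = c("forest", "max_margin"),
                                     seed = 1L) {
  model <- match.arg(model)
  nodes <- rownames(features)
  pos <- restrict_positives(as_positives(labels), nodes, "feature matrix")
  neg <- intersect(unique(as.character(training_negatives)), nodes)
  neg <- setdiff(neg, pos)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("training set must contain both positives and negatives", call. = FALSE)
  }
  train <- c(pos, neg)
  y <- factor(rep(c("pos", "neg"), c(length(pos), length(neg))),
              levels = c("neg", "pos"))
  if (model == "forest") {
    s <- with_seed(seed, {
      fit <- randomForest::randomForest(features[train, , drop = FALSE], y)
      stats::predict(fit, features, type = "prob")[, "pos"]
    })
  } else {
    train_idx <- match(train, nodes)
    s <- with_seed(seed, {
      fit <- kernlab::ksvm(features[train, , drop = FALSE], y,
                           type = "C-svc", scaled = FALSE)
      dec <- as.numeric(kernlab::predict(fit, features, type = "decision"))
      if (mean(dec[train_idx][y == "pos"]) < mean(dec[train_idx][y == "neg"])) {
        dec <- -dec
      }
      dec
    })
  }
  score_vector(as.numeric(s), nodes,
               if (model == "forest") "rf" else "svm")
}
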