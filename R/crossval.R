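# Classic, block and representative cross-validation over genes, with
# protein-complex awareness, plus the repeated-CV driver.

#' Read a protein-complex catalog from TSV
#'
#' @param path TSV with columns `complex_id` and `gene_id` (one membership
#'   per row).
#' @return Named list mapping complex id to a character vector of gene ids.
#' @export
read_complex_catalog <- function(path) {
  rows <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("complex_id", "gene_id") %in% names(rows))) {
    stop("complex catalog requires columns complex_id, gene_id", call. = FALSE)
  }
  lapply(split(as.character(rows$gene_id), rows$complex_id), unique)
}

#' Merge overlapping positive-containing complexes into pseudo-complexes
#'
#' Complexes containing at least one positive gene are merged along the
#' complex-overlap relation (sharing any gene) into indivisible
#' pseudo-complexes: the connected components of the overlap graph.
#' Complexes without positives are discarded, and positives belonging to no
#' complex become singleton units. The returned units are pairwise disjoint
#' and jointly cover every positive.
#'
#' @param catalog Named list mapping complex id to gene-id vectors.
#' @param positives Character vector of positive gene ids.
#' @return Named list of pseudo-complex gene sets (`pc*` for merged
#'   complexes, `singleton.<gene>` for complex-free positives).
#' @export
merge_overlapping_complexes <- function(catalog, positives) {
  positives <- unique(as.character(positives))
  keep <- Filter(function(genes) any(genes %in% positives), catalog)
  units <- list()
  if (length(keep) > 0L) {
    # connected components of the complex-overlap graph via igraph
    gene_of <- stack_memberships(keep)
    edges <- character(0)
    if (length(keep) > 1L) {
      by_gene <- split(gene_of$complex, gene_of$gene)
      for (cx in by_gene) {
        cx <- unique(cx)
        if (length(cx) > 1L) {
          edges <- c(edges, as.character(t(cbind(cx[1], cx[-1]))))
        }
      }
    }
    og <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(names(keep))
    if (length(edges) > 0L) og <- og + igraph::edges(edges)
    comp <- igraph::components(og)$membership
    for (ci in sort(unique(comp))) {
      members <- names(comp)[comp == ci]
      units[[paste0("pc", ci)]] <-
        sort(unique(unlist(keep[members], use.names = FALSE)))
    }
  }
  uncovered <- setdiff(positives, unlist(units, use.names = FALSE))
  for (gene in uncovered) {
    units[[paste0("singleton.", gene)]] <- gene
  }
  units
}

#' @noRd
stack_memberships <- function(catalog) {
  data.frame(
    complex = rep(names(catalog), lengths(catalog)),
    gene = unlist(catalog, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Assemble a fold_assignment object
#' @noRd
fold_assignment <- function(fold_of, k, scheme, excluded = character(),
                            repetition = 1L) {
  structure(
    list(fold_of = fold_of, k = as.integer(k), scheme = scheme,
         excluded = excluded, repetition = as.integer(repetition)),
    class = "fold_assignment"
  )
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold_assignment: %s scheme, k = %d, %d genes, %d excluded\n",
              x$scheme, x$k, length(x$fold_of), length(x$excluded)))
  invisible(x)
}

#' Balanced assignment of shuffled items to k folds (uses current RNG)
#' @noRd
spread_evenly <- function(items, k) {
  if (length(items) == 0L) return(integer(0))
  shuffled <- sample(items)
  f <- ((seq_along(shuffled) - 1L) %% k) + 1L
  names(f) <- shuffled
  f
}

#' Classic stratified fold construction using the current RNG state
#' @noRd
classic_folds_impl <- function(positives, universe, k) {
  fold_of <- c(spread_evenly(positives, k),
               spread_evenly(setdiff(universe, positives), k))
  fold_of[universe]
}

#' Classic stratified k-fold assignment
#'
#' Regular stratified cross-validation: positives and non-positives are each
#' split as evenly as possible across the k folds, ignoring any complex
#' structure.
#'
#' @param positives Character vector of positive gene ids.
#' @param universe Character vector of all genes to assign (must contain the
#'   positives).
#' @param k Fold count.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return A `fold_assignment`.
#' @export
classic_folds <- function(positives, universe, k = 3L, seed = 1L) {
  positives <- unique(as.character(positives))
  universe <- unique(as.character(universe))
  stopifnot(all(positives %in% universe))
  if (length(positives) < k) {
    stop("fewer positives than folds would leave empty folds", call. = FALSE)
  }
  fold_of <- with_seed(seed, classic_folds_impl(positives, universe, k))
  fold_assignment(fold_of, k, "classic")
}

#' Block (complex-aware) k-fold assignment
#'
#' Shuffling happens at the pseudo-complex level: merged units (see
#' [merge_overlapping_complexes()]) are shuffled uniformly and fold
#' boundaries are placed on the shuffled sequence at the cut points that
#' minimise the deviation of cumulative positive counts from a perfectly
#' balanced partition, so that no unit is ever split across folds. All genes
#' of a unit inherit its fold; remaining non-positive genes are distributed
#' evenly at random. Large complexes can therefore produce imbalanced folds
#' by design.
#'
#' @param merged Pseudo-complex list from [merge_overlapping_complexes()].
#' @inheritParams classic_folds
#' @return A `fold_assignment`.
#' @export
block_folds <- function(merged, positives, universe, k = 3L, seed = 1L) {
  positives <- unique(as.character(positives))
  universe <- unique(as.character(universe))
  stopifnot(all(positives %in% universe))
  if (length(merged) < k) {
    stop("fewer pseudo-complex units than folds", call. = FALSE)
  }
  fold_of <- with_seed(seed, {
    units <- merged[sample(length(merged))]
    unit_pos <- vapply(units, function(genes) sum(genes %in% positives),
                       numeric(1))
    cuts <- balanced_cuts(unit_pos, k)
    segment <- findInterval(seq_along(units), c(1, cuts + 1))
    fold_of <- integer(0)
    for (j in seq_along(units)) {
      genes <- intersect(units[[j]], universe)
      f <- rep(segment[j], length(genes))
      names(f) <- genes
      fold_of <- c(fold_of, f)
    }
    rest <- setdiff(universe, names(fold_of))
    fold_of <- c(fold_of, spread_evenly(rest, k))
    fold_of[universe]
  })
  fold_assignment(fold_of, k, "block")
}

#' Greedy boundary placement minimising |cumulative positives - ideal|
#'
#' Cut i is chosen after cut i-1, leaving at least one unit per remaining
#' segment, at the position whose cumulative positive count is closest to
#' the balanced value i * total / k.
#' @noRd
balanced_cuts <- function(unit_pos, k) {
  m <- length(unit_pos)
  csum <- cumsum(unit_pos)
  total <- csum[m]
  cuts <- integer(k - 1L)
  prev <- 0L
  for (i in seq_len(k - 1L)) {
    lo <- prev + 1L
    hi <- m - (k - i)
    j <- lo:hi
    best <- j[which.min(abs(csum[j] - total * i / k))]
    cuts[i] <- best
    prev <- best
  }
  cuts
}

#' Representative (complex-aware) k-fold assignment
#'
#' One positive gene per pseudo-complex is retained uniformly at random as
#' that complex's representative; every other member of the complex is
#' excluded from training and validation alike (neither labelled nor
#' evaluated). Classic stratified folds are then built on the
#' representatives plus the complex-free positives. With an empty catalog
#' this reduces exactly to [classic_folds()] at the same seed.
#'
#' @inheritParams block_folds
#' @return A `fold_assignment` with a non-empty `excluded` set whenever a
#'   pseudo-complex has more than one member.
#' @export
representative_folds <- function(merged, positives, universe, k = 3L, seed = 1L) {
  positives <- unique(as.character(positives))
  universe <- unique(as.character(universe))
  stopifnot(all(positives %in% universe))
  if (length(merged) < k) {
    stop("fewer pseudo-complex units than folds", call. = FALSE)
  }
  with_seed(seed, {
    reps <- character(0)
    excluded <- character(0)
    for (genes in merged) {
      pos_in <- intersect(genes, positives)
      if (length(genes) == 1L) {
        reps <- c(reps, genes)
      } else {
        pick <- if (length(pos_in) == 1L) pos_in else sample(pos_in, 1L)
        reps <- c(reps, pick)
        excluded <- c(excluded, setdiff(genes, pick))
      }
    }
    excluded <- intersect(unique(excluded), universe)
    reduced <- setdiff(universe, excluded)
    if (length(reps) < k) {
      stop("fewer retained positives than folds", call. = FALSE)
    }
    fold_of <- classic_folds_impl(reps, reduced, k)
    fold_assignment(fold_of, k, "representative", excluded = excluded)
  })
}

#' Build one fold assignment under a named scheme
#'
#' @param scheme `"classic"`, `"block"` or `"representative"`.
#' @param catalog Complex catalog (ignored by the classic scheme).
#' @inheritParams classic_folds
#' @return A `fold_assignment`.
#' @export
build_folds <- function(scheme = c("classic", "block", "representative"),
                        positives, universe, catalog = list(), k = 3L,
                        seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "classic") {
    return(classic_folds(positives, universe, k, seed))
  }
  merged <- merge_overlapping_complexes(catalog, positives)
  switch(scheme,
         block = block_folds(merged, positives, universe, k, seed),
         representative = representative_folds(merged, positives, universe,
                                               k, seed))
}

#' Prioritiser identifiers known to the benchmark driver
#' @export
available_methods <- function() {
  c("ppr", "raw", "gm", "mc", "z", "knn", "wsld", "bagsvm", "rf", "svm",
    "egad", "pr", "random", "randomraw")
}

#' Score every gene with one prioritiser
#'
#' Uniform dispatcher over the method panel; kernel methods require `K`,
#' walk/voting methods require `g`, and the feature classifiers require a
#' `features` matrix from [diffusion_state_features()].
#'
#' @param method One of [available_methods()].
#' @param g Weighted `igraph` graph (walk/voting methods).
#' @param K Regularised Laplacian kernel (kernel methods).
#' @param train_pos Character vector of training positive genes.
#' @param train_neg Character vector of training negative genes (methods
#'   `gm`, `rf`, `svm`).
#' @param features Diffusion-state embedding (methods `rf`, `svm`).
#' @param seed Integer seed for the stochastic methods.
#' @param opts Named list of per-method options (`damping`, `n_perm`, `knn_k`,
#'   `n_bags`).
#' @return Named numeric score vector.
#' @export
method_scores <- function(method, g = NULL, K = NULL, train_pos,
                          train_neg = character(), features = NULL,
                          seed = 1L, opts = list()) {
  method <- match.arg(method, available_methods())
  damping <- opts$damping %||% 0.85
  switch(
    method,
    ppr = personalized_pagerank(g, train_pos, damping),
    raw = diffuse_raw(K, train_pos),
    gm = diffuse_gm(K, train_pos, train_neg),
    mc = diffuse_mc(K, train_pos, n_perm = opts$n_perm %||% 1000L, seed = seed),
    z = diffuse_z(K, train_pos),
    knn = knn_score(K, train_pos, k = opts$knn_k %||% 3L),
    wsld = wsld_score(K, train_pos),
    bagsvm = bagging_svm(K, train_pos, n_bags = opts$n_bags %||% 30L,
                         seed = seed),
    rf = train_feature_classifier(features, train_pos, train_neg,
                                  model = "forest", seed = seed),
    svm = train_feature_classifier(features, train_pos, train_neg,
                                   model = "max_margin", seed = seed),
    egad = egad_neighbor_voting(g, train_pos),
    pr = pagerank_uniform(g, damping),
    random = random_scores(node_index(if (is.null(g)) K else g), seed = seed),
    randomraw = randomraw_scores(K, train_pos, seed = seed)
  )
}

#' Run one repetition of cross-validation for one method
#'
#' For each fold, the validation-fold genes are hidden from the input label
#' vector (left unlabelled), every gene is scored, and each metric is
#' evaluated on the validation-fold genes only; excluded genes (representative
#' scheme) are never labelled nor evaluated. Per-fold values are averaged
#' into one record per metric. Folds are always built from the drugs stream;
#' `input_labels` may be the drugs or the genetic stream and is hidden on
#' the validation fold either way. Evaluation truth is always
#' `eval_labels` (the drugs stream).
#'
#' @param method One of [available_methods()].
#' @param g,K,features Network, kernel and embedding inputs as required by
#'   the method (see [method_scores()]).
#' @param input_labels `label_set` seeding the method.
#' @param eval_labels `label_set` defining the evaluation truth.
#' @param folds A `fold_assignment` (one repetition).
#' @param metrics Character vector of metric names ([metric_names()]).
#' @param seed Integer seed for stochastic methods and top-k tie-breaks.
#' @param network Network label recorded in the output.
#' @param opts Per-method options, see [method_scores()].
#' @return Data frame of metric records: `disease`, `method`, `network`,
#'   `cv_scheme`, `repetition`, `metric`, `value` (fold-averaged).
#' @export
run_cv <- function(method, g = NULL, K = NULL, input_labels, eval_labels,
                   folds, metrics = c("auroc", "top20"), seed = 1L,
                   network = "network", features = NULL, opts = list()) {
  stopifnot(inherits(folds, "fold_assignment"))
  metrics <- match.arg(metrics, metric_names(), several.ok = TRUE)
  nodes <- names(folds$fold_of)
  input_pos <- as_positives(input_labels)
  eval_pos <- as_positives(eval_labels)
  per_fold <- matrix(NA_real_, nrow = folds$k, ncol = length(metrics),
                     dimnames = list(NULL, metrics))
  for (f in seq_len(folds$k)) {
    val_genes <- nodes[folds$fold_of == f]
    train_pos <- setdiff(input_pos, c(val_genes, folds$excluded))
    train_genes <- setdiff(nodes, val_genes)
    train_neg <- setdiff(train_genes, input_pos)
    # leakage audit: the input indicator must be zero on validation genes
    stopifnot(length(intersect(train_pos, val_genes)) == 0L)
    if (length(train_pos) == 0L) {
      warning("fold with no training positives skipped", call. = FALSE)
      next
    }
    scores <- method_scores(method, g = g, K = K, train_pos = train_pos,
                            train_neg = train_neg, features = features,
                            seed = seed + f, opts = opts)
    val_scores <- scores[val_genes]
    val_pos <- intersect(eval_pos, val_genes)
    if (length(val_pos) == 0L) {
      warning("validation fold with no positives skipped", call. = FALSE)
      next
    }
    for (m in metrics) {
      per_fold[f, m] <- compute_metric(m, val_scores, val_pos, seed = seed + f)
    }
  }
  value <- colMeans(per_fold, na.rm = TRUE)
  data.frame(
    disease = if (inherits(eval_labels, "label_set")) eval_labels$disease else "disease",
    method = method,
    network = network,
    cv_scheme = folds$scheme,
    repetition = folds$repetition,
    metric = metrics,
    value = as.numeric(value),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Repeated cross-validation for one method under one scheme
#'
#' Builds one fold assignment per repetition (per-repetition seed
#' `seed + repetition`) and concatenates the [run_cv()] records.
#'
#' @inheritParams run_cv
#' @inheritParams build_folds
#' @param repeats Number of repetitions.
#' @return Data frame of metric records, one row per (metric, repetition).
#' @export
repeated_cv <- function(method, g = NULL, K = NULL, input_labels, eval_labels,
                        scheme = "classic", catalog = list(), k = 3L,
                        repeats = 25L, metrics = c("auroc", "top20"),
                        seed = 1L, network = "network", features = NULL,
                        opts = list()) {
  nodes <- node_index(if (is.null(g)) K else g)
  fold_pos <- intersect(as_positives(eval_labels), nodes)
  records <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- build_folds(scheme, fold_pos, nodes, catalog = catalog, k = k,
                         seed = seed + r)
    folds$repetition <- r
    records[[r]] <- run_cv(method, g = g, K = K, input_labels = input_labels,
                           eval_labels = eval_labels, folds = folds,
                           metrics = metrics, seed = seed + r,
                           network = network, features = features, opts = opts)
  }
  do.call(rbind, records)
}
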