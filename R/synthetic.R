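# Synthetic benchmark fixtures: modular networks with planted all-positive
# complexes and two overlapping gene-disease label streams.

#' Generate a synthetic benchmark fixture
#'
#' Draws a planted-partition (stochastic block model) graph with
#' `n_modules` equal modules (within-module edge probability `p_intra`,
#' between-module `p_inter`), reduces it to its largest connected
#' component, plants disease positives so that a fraction
#' `positive_modularity` of them fall in one designated module (the rest
#' spread uniformly over the other modules), and realises protein
#' complexes as cliques of all-positive genes whose memberships are
#' recorded in the complex catalog. All-positive cliques reproduce the
#' leakage mechanism that classic cross-validation suffers from: complex
#' members are densely connected and co-labelled, so splitting a complex
#' across folds leaks the validation labels into training.
#'
#' Edge weights are 1 (OmniPath-like binary interactions) unless
#' `weighted = TRUE`, in which case they are drawn Uniform(0.5, 1).
#'
#' @param n_genes Number of genes before LCC extraction.
#' @param n_modules Number of planted modules.
#' @param p_intra,p_inter Within- and between-module edge probabilities
#'   (`p_intra > p_inter`).
#' @param n_positives Number of drugs-stream positive genes.
#' @param complex_sizes Integer vector of planted complex sizes; their sum
#'   must not exceed `n_positives`.
#' @param positive_modularity Fraction of positives placed in the
#'   designated module, in \[0, 1\].
#' @param weighted Draw Uniform(0.5, 1) edge weights instead of 1.
#' @param seed Integer seed; the benchmark is bit-identical given the seed.
#' @return An object of class `synthetic_benchmark`: `graph` (weighted
#'   igraph), `catalog` (complex list), `drugs_labels` (`label_set`), and
#'   `truth` (module assignment, complex members, generation parameters).
#' @export
generate_benchmark <- function(n_genes = 1500L, n_modules = 5L,
                               p_intra = 0.1, p_inter = 0.005,
                               n_positives = 60L,
                               complex_sizes = c(8L, 8L, 8L),
                               positive_modularity = 0.75,
                               weighted = FALSE, seed = 1L) {
  if (sum(complex_sizes) > n_positives) {
    stop("sum of complex sizes exceeds n_positives", call. = FALSE)
  }
  if (n_positives > n_genes) stop("more positives than genes", call. = FALSE)
  if (p_intra < p_inter) stop("p_intra must be >= p_inter", call. = FALSE)
  if (positive_modularity < 0 || positive_modularity > 1) {
    stop("positive_modularity must lie in [0, 1]", call. = FALSE)
  }
  for (attempt in 1:2) {
    bench <- with_seed(seed + (attempt - 1L) * 10000L, {
      build_synthetic(n_genes, n_modules, p_intra, p_inter, n_positives,
                      complex_sizes, positive_modularity, weighted)
    })
    if (!is.null(bench)) {
      bench$truth$seed <- seed
      return(bench)
    }
  }
  stop("largest connected component smaller than n_positives; ",
       "increase edge probabilities", call. = FALSE)
}

#' @noRd
build_synthetic <- function(n_genes, n_modules, p_intra, p_inter,
                            n_positives, complex_sizes, positive_modularity,
                            weighted) {
  sizes <- rep(n_genes %/% n_modules, n_modules)
  sizes[seq_len(n_genes %% n_modules)] <- sizes[seq_len(n_genes %% n_modules)] + 1L
  pref <- matrix(p_inter, n_modules, n_modules)
  diag(pref) <- p_intra
  g <- igraph::sample_sbm(n_genes, pref.matrix = pref, block.sizes = sizes)
  igraph::V(g)$name <- sprintf("g%04d", seq_len(n_genes))
  module <- rep(seq_len(n_modules), sizes)
  names(module) <- igraph::V(g)$name
  g <- largest_connected_component(g)
  nodes <- node_index(g)
  if (length(nodes) < n_positives) return(NULL)
  module <- module[nodes]

  # positives: a fraction in the designated module, the rest spread uniformly
  target_module <- 1L
  in_target <- nodes[module == target_module]
  n_mod_pos <- min(round(positive_modularity * n_positives), length(in_target))
  pos_mod <- sample(in_target, n_mod_pos)
  pos_rest <- sample(setdiff(nodes, pos_mod), n_positives - n_mod_pos)
  positives <- c(pos_mod, pos_rest)

  # complexes: disjoint all-positive cliques, preferring co-modular members
  catalog <- list()
  pool <- positives[order(module[positives])]
  offset <- 0L
  for (ci in seq_along(complex_sizes)) {
    members <- pool[offset + seq_len(complex_sizes[ci])]
    offset <- offset + complex_sizes[ci]
    catalog[[sprintf("cx%d", ci)]] <- members
    idx <- match(members, nodes)
    pairs <- utils::combn(idx, 2)
    for (p in seq_len(ncol(pairs))) {
      if (!igraph::are_adjacent(g, pairs[1, p], pairs[2, p])) {
        g <- igraph::add_edges(g, pairs[, p])
      }
    }
  }
  igraph::E(g)$weight <- if (weighted) {
    stats::runif(igraph::ecount(g), 0.5, 1)
  } else {
    rep(1, igraph::ecount(g))
  }
  structure(
    list(
      graph = g,
      catalog = catalog,
      drugs_labels = label_set(positives, disease = "synthetic",
                               stream = "drugs"),
      genetic_labels = NULL,
      truth = list(module = module, positives = positives,
                   complex_members = unlist(catalog, use.names = FALSE),
                   target_module = target_module,
                   params = list(n_genes = n_genes, n_modules = n_modules,
                                 p_intra = p_intra, p_inter = p_inter,
                                 n_positives = n_positives,
                                 complex_sizes = complex_sizes,
                                 positive_modularity = positive_modularity))
    ),
    class = "synthetic_benchmark"
  )
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf(paste0("synthetic_benchmark: %d genes, %d edges, ",
                     "%d positives, %d complexes\n"),
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$drugs_labels$positives), length(x$catalog)))
  invisible(x)
}

#' Generate the genetic label stream of a synthetic benchmark
#'
#' Draws a genetic-stream positive set that overlaps the drugs stream by
#' a configured fraction: `round(overlap_fraction * n_genetic)` genes are
#' sampled from the drugs positives and the remainder from the non-drug
#' genes, with sampling weights biased (3:1) toward the modules that
#' contain drugs positives, mimicking the partial dependence between the
#' two evidence streams.
#'
#' @param bench A `synthetic_benchmark`.
#' @param overlap_fraction Target fraction of genetic positives shared with
#'   the drugs stream, in \[0, 1\].
#' @param n_genetic Number of genetic-stream positives.
#' @param seed Integer seed.
#' @return A `label_set` with stream `"genetic"`.
#' @export
generate_genetic_stream <- function(bench, overlap_fraction = 0.05,
                                    n_genetic = 60L, seed = 1L) {
  stopifnot(inherits(bench, "synthetic_benchmark"))
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must lie in [0, 1]", call. = FALSE)
  }
  nodes <- node_index(bench$graph)
  drugs <- bench$drugs_labels$positives
  n_shared <- round(overlap_fraction * n_genetic)
  n_new <- n_genetic - n_shared
  candidates <- setdiff(nodes, drugs)
  if (n_shared > length(drugs) || n_new > length(candidates)) {
    stop("insufficient candidate genes for the requested stream", call. = FALSE)
  }
  module <- bench$truth$module
  drug_modules <- unique(module[drugs])
  w <- ifelse(module[candidates] %in% drug_modules, 3, 1)
  genetic <- with_seed(seed, {
    shared <- if (n_shared > 0L) sample(drugs, n_shared) else character(0)
    fresh <- if (n_new > 0L) sample(candidates, n_new, prob = w) else character(0)
    c(shared, fresh)
  })
  label_set(genetic, disease = bench$drugs_labels$disease, stream = "genetic")
}

#' Write a synthetic benchmark to TSV fixtures
#'
#' Writes `graph.tsv` (plain edge list), `complexes.tsv` and one label TSV
#' per available stream, in the formats the readers of this package accept.
#'
#' @param bench A `synthetic_benchmark`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_benchmark <- function(bench, out_dir) {
  stopifnot(inherits(bench, "synthetic_benchmark"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(bench$graph, file.path(out_dir, "graph.tsv"))
  cat_rows <- stack_memberships(bench$catalog)
  utils::write.table(
    data.frame(complex_id = cat_rows$complex, gene_id = cat_rows$gene),
    file.path(out_dir, "complexes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  streams <- list(drugs = bench$drugs_labels, genetic = bench$genetic_labels)
  for (st in names(streams)) {
    ls <- streams[[st]]
    if (is.null(ls)) next
    utils::write.table(
      data.frame(gene = ls$positives, disease = ls$disease, stream = st,
                 score = 1),
      file.path(out_dir, paste0("labels_", st, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(out_dir)
}
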