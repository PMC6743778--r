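# Ranking metrics on evaluated genes: AUROC, partial AUROC, AUPRC, top-k.
#
# `scores` is a named numeric vector over the evaluated genes; `positives`
# names the true-positive genes among them. ROC-family metrics handle ties
# by midranks (tied score groups contribute trapezoids); top-k breaks
# boundary ties by a seeded uniform shuffle.

#' Validate metric inputs and return the 0/1 truth vector
#' @noRd
metric_truth <- function(scores, positives, need_negative = TRUE) {
  if (is.null(names(scores))) stop("scores must be named by gene", call. = FALSE)
  truth <- as.integer(names(scores) %in% as_positives(positives))
  if (sum(truth) == 0L) {
    stop("no positive genes among the evaluated scores", call. = FALSE)
  }
  if (need_negative && sum(truth) == length(truth)) {
    stop("no negative genes among the evaluated scores", call. = FALSE)
  }
  truth
}

#' Tie-grouped ROC points
#'
#' Returns cumulative (FPR, TPR) after each distinct score threshold,
#' descending, starting at (0, 0).
#' @noRd
roc_points <- function(scores, truth) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  group_last <- which(!duplicated(s, fromLast = TRUE))   # last index of each tie group
  tp <- cumsum(t)[group_last]
  fp <- cumsum(1 - t)[group_last]
  list(fpr = c(0, fp / sum(1 - truth)), tpr = c(0, tp / sum(truth)))
}

#' Area under the ROC curve
#'
#' Probability that a uniformly drawn positive outscores a uniformly drawn
#' negative, counting ties one half (midrank / Mann--Whitney convention).
#'
#' @param scores Named numeric score vector over the evaluated genes.
#' @param positives Character vector (or `label_set`) of true positives.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, positives) {
  truth <- metric_truth(scores, positives)
  n_pos <- sum(truth); n_neg <- sum(1 - truth)
  r <- rank(scores)                                      # midranks for ties
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Partial area under the ROC curve
#'
#' Area under the ROC curve restricted to false positive rates in
#' \[0, p\], renormalised by `1/p` so the metric again lies in \[0, 1\];
#' `pauroc(scores, positives, p = 1)` equals [auroc()].
#'
#' @inheritParams auroc
#' @param p False-positive-rate ceiling in (0, 1\].
#' @return Normalised partial AUROC in \[0, 1\].
#' @export
pauroc <- function(scores, positives, p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stop("p must lie in (0, 1]", call. = FALSE)
  }
  truth <- metric_truth(scores, positives)
  pts <- roc_points(scores, truth)
  area <- 0
  for (i in seq_len(length(pts$fpr) - 1L)) {
    x0 <- pts$fpr[i];  x1 <- pts$fpr[i + 1L]
    y0 <- pts$tpr[i];  y1 <- pts$tpr[i + 1L]
    if (x0 >= p) break
    if (x1 > p) {                                        # interpolate at FPR = p
      y1 <- y0 + (y1 - y0) * (p - x0) / (x1 - x0)
      x1 <- p
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area / p
}

#' Area under the precision--recall curve (step-wise)
#'
#' Step-wise estimator: precision is treated as a step function of recall,
#' with tied score groups contributing a single step. A perfect ranking
#' yields 1; random scores average the positive prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, positives) {
  truth <- metric_truth(scores, positives, need_negative = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  group_last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(t)[group_last]
  n_at <- group_last                                     # genes at or above threshold
  recall <- tp / sum(truth)
  precision <- tp / n_at
  sum(diff(c(0, recall)) * precision)
}

#' True positives among the k top-ranked genes
#'
#' Counts positives among the `k` highest-scoring evaluated genes. Ties at
#' the cut boundary are broken by a seeded uniform shuffle, making the count
#' deterministic given the seed.
#'
#' @inheritParams auroc
#' @param k Size of the candidate list; values above the number of evaluated
#'   genes are truncated with a warning.
#' @param seed Integer seed for the tie-breaking shuffle.
#' @return Integer count in `0..k`.
#' @export
top_k_hits <- function(scores, positives, k = 20L, seed = 1L) {
  truth <- metric_truth(scores, positives, need_negative = FALSE)
  n <- length(scores)
  if (k > n) {
    warning(sprintf("k = %d exceeds the %d evaluated genes; truncated", k, n),
            call. = FALSE)
    k <- n
  }
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  ord <- with_seed(seed, order(-scores, stats::runif(n)))
  sum(truth[ord[seq_len(k)]])
}

#' Metric names understood by the benchmark driver
#' @export
metric_names <- function() {
  c("auroc", "pauroc05", "pauroc10", "auprc", "top20", "top100")
}

#' Evaluate one named metric
#'
#' Dispatch helper used by the cross-validation driver: `pauroc05`/`pauroc10`
#' are partial AUROC at 5%/10% FPR; `top20`/`top100` are top-k hit counts.
#'
#' @inheritParams auroc
#' @param metric One of [metric_names()].
#' @param seed Seed forwarded to the top-k tie-break.
#' @return Metric value.
#' @export
compute_metric <- function(metric, scores, positives, seed = 1L) {
  switch(match.arg(metric, metric_names()),
         auroc = auroc(scores, positives),
         pauroc05 = pauroc(scores, positives, 0.05),
         pauroc10 = pauroc(scores, positives, 0.10),
         auprc = auprc(scores, positives),
         top20 = top_k_hits(scores, positives, 20L, seed = seed),
         top100 = top_k_hits(scores, positives, 100L, seed = seed))
}
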