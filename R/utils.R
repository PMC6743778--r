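# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves the caller's RNG state, seeds with `seed`, evaluates `expr` and
#' restores the previous state, so seeded operations never perturb the
#' session RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce a label argument to a character vector of positive gene ids
#' @noRd
as_positives <- function(labels) {
  if (inherits(labels, "label_set")) {
    return(labels$positives)
  }
  if (is.character(labels)) {
    return(unique(labels))
  }
  if (is.numeric(labels) && !is.null(names(labels))) {
    return(names(labels)[labels != 0])
  }
  stop("labels must be a label_set, a character vector of gene ids, ",
       "or a named 0/1 vector", call. = FALSE)
}

#' Indicator vector of positives over a node index
#' @noRd
indicator_vector <- function(nodes, positives) {
  y <- as.numeric(nodes %in% positives)
  names(y) <- nodes
  y
}

#' Restrict positives to the kernel/graph node index, warning on losses
#' @noRd
restrict_positives <- function(positives, nodes, what = "kernel index") {
  missing <- setdiff(positives, nodes)
  if (length(missing) > 0L) {
    warning(sprintf("dropping %d positive gene(s) absent from the %s",
                    length(missing), what), call. = FALSE)
  }
  intersect(positives, nodes)
}

#' Construct a score vector result
#' @noRd
score_vector <- function(scores, nodes, method) {
  stopifnot(length(scores) == length(nodes))
  scores <- as.numeric(scores)
  if (any(!is.finite(scores))) {
    stop("non-finite scores produced by method '", method, "'", call. = FALSE)
  }
  names(scores) <- nodes
  attr(scores, "method") <- method
  scores
}
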