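# Binarised per-gene disease labels for one evidence stream.

#' Construct a label set
#'
#' A label set holds the binarised positives of one gene--disease evidence
#' stream ("drugs": any non-zero association; "genetic": association score
#' above a threshold, see [binarise_inputs()]).
#'
#' @param positives Character vector of positive gene ids.
#' @param disease Disease identifier.
#' @param stream `"drugs"` or `"genetic"`.
#' @return An object of class `label_set`.
#' @export
label_set <- function(positives, disease = "disease",
                      stream = c("drugs", "genetic")) {
  stream <- match.arg(stream)
  positives <- unique(as.character(positives))
  structure(
    list(disease = disease, stream = stream, positives = positives),
    class = "label_set"
  )
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set: %s [%s stream], %d positives\n",
              x$disease, x$stream, length(x$positives)))
  invisible(x)
}

#' Read gene--disease score tables and binarise them into label sets
#'
#' Input rows carry `gene`, `disease`, `stream` and `score` columns with
#' scores in \[0, 1\]. Drugs-stream positives are genes with any non-zero
#' score; genetic-stream positives require a score strictly above
#' `genetic_threshold`.
#'
#' @param score_table Data frame with columns `gene`, `disease`, `stream`,
#'   `score`, or a path to such a TSV.
#' @param genetic_threshold Strict lower bound for genetic positives.
#' @return Named list of `label_set` objects, one per (disease, stream),
#'   named `"<disease>.<stream>"`.
#' @export
binarise_inputs <- function(score_table, genetic_threshold = 0.16) {
  if (is.character(score_table)) {
    score_table <- utils::read.delim(score_table, stringsAsFactors = FALSE)
  }
  needed <- c("gene", "disease", "stream", "score")
  if (!all(needed %in% names(score_table))) {
    stop("score table requires columns gene, disease, stream, score",
         call. = FALSE)
  }
  s <- as.numeric(score_table$score)
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("scores must be finite and non-negative", call. = FALSE)
  }
  if (!all(score_table$stream %in% c("drugs", "genetic"))) {
    stop("stream must be 'drugs' or 'genetic'", call. = FALSE)
  }
  out <- list()
  for (dz in unique(score_table$disease)) {
    for (st in unique(score_table$stream[score_table$disease == dz])) {
      rows <- score_table$disease == dz & score_table$stream == st
      cut <- if (st == "drugs") 0 else genetic_threshold
      pos <- unique(score_table$gene[rows & s > cut])
      out[[paste(dz, st, sep = ".")]] <- label_set(pos, disease = dz, stream = st)
    }
  }
  out
}
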