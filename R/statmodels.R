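# Explanatory performance models, overlap statistics and rank-distance
# method comparison.

#' Fit an additive quasi-likelihood explanatory model to metric records
#'
#' Models fold-averaged performance values as an additive function of the
#' benchmark design factors: the main formula is
#' `value ~ cv_scheme + network + method + disease`, the reduced formula
#' `value ~ method + disease`. Bounded metrics (AUROC, partial AUROC, AUPRC)
#' use a quasi-binomial family with logit link; top-k hit counts use
#' quasi-Poisson with log link. The quasi-likelihood dispersion parameter
#' guards the Wald inference against over- and under-dispersion.
#'
#' Factors with a single observed level are dropped from the formula with a
#' warning (they carry no contrast); a rank-deficient design over the
#' remaining factors raises an error naming the aliased coefficients.
#'
#' @param records Metric-record data frame from [run_cv()] /
#'   [repeated_cv()] (columns `disease`, `method`, `network`, `cv_scheme`,
#'   `metric`, `value`).
#' @param metric Which metric's records to model (one of [metric_names()]).
#' @param formula `"main"` or `"reduced"`.
#' @return An object of class `perf_model` wrapping the `glm` fit, with a
#'   `coefficients` table (estimate, dispersion-adjusted SE, Wald 95% CI),
#'   the `dispersion` estimate and the reference level of each factor.
#' @export
fit_additive_model <- function(records, metric, formula = c("main", "reduced")) {
  formula <- match.arg(formula)
  metric <- match.arg(metric, metric_names())
  dat <- records[records$metric == metric, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no records for metric '", metric, "'", call. = FALSE)
  factors <- if (formula == "main") {
    c("cv_scheme", "network", "method", "disease")
  } else {
    c("method", "disease")
  }
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  usable <- factors[vapply(factors, function(f) nlevels(dat[[f]]) >= 2L,
                           logical(1))]
  dropped <- setdiff(factors, usable)
  if (length(dropped) > 0L) {
    warning("dropping single-level factor(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(usable) == 0L) {
    usable <- "1"
  }
  family <- if (metric %in% c("top20", "top100")) {
    stats::quasipoisson(link = "log")
  } else {
    stats::quasibinomial(link = "logit")
  }
  if (family$family == "quasibinomial") {
    # keep strictly inside (0, 1) so the logit is finite
    eps <- 1e-6
    dat$value <- pmin(pmax(dat$value, eps), 1 - eps)
  }
  fml <- stats::as.formula(paste("value ~", paste(usable, collapse = " + ")))
  fit <- stats::glm(fml, family = family, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; aliased coefficients: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  est <- sm$coefficients[, "Estimate"]
  se <- sm$coefficients[, "Std. Error"]
  coef_table <- data.frame(
    term = rownames(sm$coefficients),
    estimate = est,
    std_error = se,
    ci_lower = est - stats::qnorm(0.975) * se,
    ci_upper = est + stats::qnorm(0.975) * se,
    stringsAsFactors = FALSE, row.names = NULL
  )
  refs <- vapply(setdiff(usable, "1"),
                 function(f) levels(dat[[f]])[1], "")
  structure(
    list(fit = fit, metric = metric, formula = formula,
         family = family$family, coefficients = coef_table,
         dispersion = sm$dispersion, reference_levels = refs,
         factors = setdiff(usable, "1"), data = dat),
    class = "perf_model"
  )
}

#' @export
print.perf_model <- function(x, ...) {
  cat(sprintf("perf_model: %s ~ %s [%s], dispersion %.3f\n",
              x$metric, paste(x$factors, collapse = " + "),
              x$family, x$dispersion))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Response-scale prediction averaged over one factor
#'
#' Predicts the metric on the response scale at the given covariate levels,
#' averaging over all observed levels of `average_over` (e.g. a method by
#' scheme prediction averaged over diseases). The 95% confidence interval is
#' obtained by the delta method on the averaged inverse-link.
#'
#' @param fit A `perf_model` from [fit_additive_model()].
#' @param covariates Named list of factor levels to predict at (all model
#'   factors except `average_over`).
#' @param average_over Factor whose observed levels are averaged over.
#' @return One-row data frame: `mean`, `ci_lower`, `ci_upper`.
#' @export
predict_performance <- function(fit, covariates = list(), average_over = NULL) {
  stopifnot(inherits(fit, "perf_model"))
  newdata <- data.frame(row.names = 1)
  for (f in fit$factors) {
    if (!is.null(average_over) && f == average_over) next
    lev <- covariates[[f]]
    if (is.null(lev)) {
      stop("covariates must name a level for factor '", f, "'", call. = FALSE)
    }
    if (!lev %in% levels(fit$data[[f]])) {
      stop("unknown level '", lev, "' for factor '", f, "'", call. = FALSE)
    }
    newdata[[f]] <- factor(lev, levels = levels(fit$data[[f]]))
  }
  if (!is.null(average_over)) {
    if (!average_over %in% fit$factors) {
      stop("unknown factor '", average_over, "'", call. = FALSE)
    }
    levs <- levels(fit$data[[average_over]])
    newdata <- newdata[rep(1, length(levs)), , drop = FALSE]
    newdata[[average_over]] <- factor(levs, levels = levs)
  }
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit$fit)),
                           newdata)
  beta <- stats::coef(fit$fit)
  eta <- drop(X %*% beta)
  linkinv <- fit$fit$family$linkinv
  mu_eta <- fit$fit$family$mu.eta
  mu <- mean(linkinv(eta))
  grad <- colMeans(X * mu_eta(eta))
  V <- stats::vcov(fit$fit)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  data.frame(mean = mu,
             ci_lower = mu - stats::qnorm(0.975) * se,
             ci_upper = mu + stats::qnorm(0.975) * se)
}

#' Tukey all-pairs contrasts on one model factor
#'
#' All pairwise level differences on the link scale with single-step
#' (max-t, multivariate normal) multiplicity-adjusted p-values, as in the
#' multcomp machinery; a Bonferroni fallback is available.
#'
#' @param fit A `perf_model`.
#' @param factor Factor whose levels are compared.
#' @param adjustment `"single-step"` or `"bonferroni"`.
#' @return Data frame: `contrast`, `estimate`, `std_error`, `p_adjusted`,
#'   `significant` (at 0.05).
#' @export
pairwise_contrasts <- function(fit, factor,
                               adjustment = c("single-step", "bonferroni")) {
  stopifnot(inherits(fit, "perf_model"))
  adjustment <- match.arg(adjustment)
  if (!factor %in% fit$factors) {
    stop("factor '", factor, "' is not in the model", call. = FALSE)
  }
  if (nlevels(fit$data[[factor]]) < 2L) {
    stop("factor '", factor, "' has fewer than 2 levels", call. = FALSE)
  }
  spec <- list("Tukey"); names(spec) <- factor
  gh <- multcomp::glht(fit$fit, linfct = do.call(multcomp::mcp, spec))
  sm <- summary(gh, test = multcomp::adjusted(
    type = if (adjustment == "single-step") "single-step" else "bonferroni"))
  data.frame(
    contrast = names(sm$test$coefficients),
    estimate = as.numeric(sm$test$coefficients),
    std_error = as.numeric(sm$test$sigma),
    p_adjusted = as.numeric(sm$test$pvalues),
    significant = as.numeric(sm$test$pvalues) < 0.05,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' One-sided Fisher overlap (enrichment) test for two gene lists
#'
#' Hypergeometric upper-tail probability of observing at least the given
#' overlap between a genetic-stream and a drugs-stream gene list drawn from
#' a common gene universe.
#'
#' @param n_genetic,n_drugs Sizes of the two gene lists.
#' @param overlap Observed intersection size.
#' @param universe Size of the background gene universe.
#' @return One-sided p-value.
#' @export
fisher_overlap_test <- function(n_genetic, n_drugs, overlap, universe) {
  if (overlap > min(n_genetic, n_drugs) ||
      universe < n_genetic + n_drugs - overlap ||
      min(n_genetic, n_drugs, overlap, universe) < 0) {
    stop("inconsistent overlap counts", call. = FALSE)
  }
  stats::phyper(overlap - 1, n_genetic, universe - n_genetic, n_drugs,
                lower.tail = FALSE)
}

#' Benjamini--Hochberg step-up false discovery rate
#'
#' Step-up adjusted q-values `q_(i) = min_(j >= i) p_(j) * n / j`, clipped
#' at 1 and mapped back to the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Spearman's footrule distance between two top-N rankings
#'
#' Sums `|rank_a(g) - rank_b(g)|` over the union of the two top-N gene
#' sets, assigning rank `top_n + 1` to a gene missing from one list (the
#' mismatch penalty). Also reports the mismatch fraction, the size of the
#' symmetric difference of the two top-N sets divided by `2 * top_n`.
#' Seed genes should be removed by the caller beforehand.
#'
#' @param ranking_a,ranking_b Character vectors of genes ordered from best
#'   to worst (no duplicates; at least `top_n` genes each).
#' @param top_n Depth of the compared lists.
#' @return List with elements `distance` and `mismatch_fraction`.
#' @export
footrule_distance <- function(ranking_a, ranking_b, top_n = 100L) {
  if (anyDuplicated(ranking_a) || anyDuplicated(ranking_b)) {
    stop("rankings must not contain duplicate genes", call. = FALSE)
  }
  if (length(ranking_a) < top_n || length(ranking_b) < top_n) {
    stop("rankings must contain at least top_n genes", call. = FALSE)
  }
  top_a <- ranking_a[seq_len(top_n)]
  top_b <- ranking_b[seq_len(top_n)]
  genes <- union(top_a, top_b)
  ra <- match(genes, top_a); ra[is.na(ra)] <- top_n + 1L
  rb <- match(genes, top_b); rb[is.na(rb)] <- top_n + 1L
  list(
    distance = sum(abs(ra - rb)),
    mismatch_fraction = length(c(setdiff(top_a, top_b),
                                 setdiff(top_b, top_a))) / (2 * top_n)
  )
}

#' All-pairs footrule distance matrix between method rankings
#'
#' @param rankings Named list of ordered gene vectors, one per method.
#' @inheritParams footrule_distance
#' @return List of two symmetric matrices: `distance`, `mismatch_fraction`.
#' @export
footrule_matrix <- function(rankings, top_n = 100L) {
  m <- length(rankings)
  nm <- names(rankings)
  D <- matrix(0, m, m, dimnames = list(nm, nm))
  M <- D
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      fr <- footrule_distance(rankings[[i]], rankings[[j]], top_n)
      D[i, j] <- D[j, i] <- fr$distance
      M[i, j] <- M[j, i] <- fr$mismatch_fraction
    }
  }
  list(distance = D, mismatch_fraction = M)
}

#' Classical MDS embedding of a method-distance matrix
#'
#' Classical (Torgerson) multidimensional scaling to two dimensions; the
#' configuration is centred at the origin.
#'
#' @param distance_matrix Symmetric matrix with zero diagonal.
#' @return n-by-2 coordinate matrix (rownames preserved).
#' @export
embed_distances <- function(distance_matrix) {
  D <- as.matrix(distance_matrix)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (all(D == 0)) {
    coords <- matrix(0, nrow(D), 2)
  } else {
    coords <- stats::cmdscale(stats::as.dist(D), k = 2)
    if (ncol(coords) < 2) {
      coords <- cbind(coords, matrix(0, nrow(coords), 2 - ncol(coords)))
    }
  }
  coords <- sweep(coords, 2, colMeans(coords))
  rownames(coords) <- rownames(D)
  colnames(coords) <- c("dim1", "dim2")
  coords
}
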