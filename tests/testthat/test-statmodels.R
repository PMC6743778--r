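make_records <- function(eta_fun, n_rep = 40, metric = "auroc",
                         methods = c("m1", "m2"), diseases = c("d1", "d2"),
                         noise = 0.05, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(method = methods, disease = diseases,
                      repetition = seq_len(n_rep), stringsAsFactors = FALSE)
  mu <- plogis(eta_fun(grid))
  value <- pmin(pmax(mu + rnorm(nrow(grid), 0, noise), 0.01), 0.99)
  data.frame(disease = grid$disease, method = grid$method, network = "net",
             cv_scheme = "classic", repetition = grid$repetition,
             metric = metric, value = value, stringsAsFactors = FALSE)
}

test_that("quasi-binomial model recovers known factor effects on the link scale", {
  rec <- make_records(function(g) -1 + 0.5 * (g$method == "m2"), seed = 2)
  fit <- suppressWarnings(fit_additive_model(rec, "auroc", "reduced"))
  expect_equal(fit$family, "quasibinomial")
  coef_m2 <- fit$coefficients[fit$coefficients$term == "methodm2", ]
  expect_lt(abs(coef_m2$estimate - 0.5), 3 * coef_m2$std_error)
  expect_true(coef_m2$ci_lower < coef_m2$estimate &&
                coef_m2$estimate < coef_m2$ci_upper)
  expect_gt(fit$dispersion, 0)
  expect_equal(fit$reference_levels[["method"]], "m1")
})

test_that("balanced single-factor fits reproduce group-mean differences on the link scale", {
  set.seed(3)
  v1 <- pmin(pmax(rnorm(60, 0.4, 0.03), 0.01), 0.99)
  v2 <- pmin(pmax(rnorm(60, 0.6, 0.03), 0.01), 0.99)
  rec <- data.frame(disease = "d", method = rep(c("m1", "m2"), each = 60),
                    network = "net", cv_scheme = "classic",
                    repetition = rep(1:60, 2), metric = "auroc",
                    value = c(v1, v2), stringsAsFactors = FALSE)
  fit <- suppressWarnings(fit_additive_model(rec, "auroc", "reduced"))
  # closed form: logit of group means (GLM with saturated one-factor design)
  est <- fit$coefficients$estimate
  expect_equal(est[1], qlogis(mean(v1)), tolerance = 1e-6)
  expect_equal(est[1] + est[2], qlogis(mean(v2)), tolerance = 1e-6)
})

test_that("constant records yield null effects and counts use quasi-Poisson", {
  rec <- make_records(function(g) 0, noise = 0, seed = 4)
  rec$value <- 0.5
  fit <- suppressWarnings(fit_additive_model(rec, "auroc", "reduced"))
  non_int <- fit$coefficients$estimate[-1]
  expect_true(all(abs(non_int) < 1e-8))

  rec2 <- make_records(function(g) 0, seed = 5, metric = "top20")
  rec2$value <- rpois(nrow(rec2), 3)
  fit2 <- suppressWarnings(fit_additive_model(rec2, "top20", "reduced"))
  expect_equal(fit2$family, "quasipoisson")
  # quasi-Poisson coefficients coincide with plain Poisson (dispersion only
  # affects the standard errors)
  pois <- stats::glm(value ~ method + disease, poisson(), data = fit2$data)
  expect_equal(unname(coef(fit2$fit)), unname(coef(pois)), tolerance = 1e-8)
})

test_that("response-scale predictions average correctly over a factor", {
  rec <- make_records(function(g) {
    -0.5 + 0.8 * (g$method == "m2") + 0.4 * (g$disease == "d2")
  }, seed = 6)
  fit <- suppressWarnings(fit_additive_model(rec, "auroc", "reduced"))
  pred <- predict_performance(fit, list(method = "m2"),
                              average_over = "disease")
  # manual average of per-level response predictions
  b <- coef(fit$fit)
  manual <- mean(plogis(c(b[1] + b["methodm2"],
                          b[1] + b["methodm2"] + b["diseased2"])))
  expect_equal(pred$mean, manual, tolerance = 1e-10)
  expect_true(pred$ci_lower < pred$mean && pred$mean < pred$ci_upper)

  # prediction at reference levels of a null fit is inverse-link(intercept)
  rec0 <- make_records(function(g) -0.3, noise = 0.02, seed = 7)
  fit0 <- suppressWarnings(fit_additive_model(rec0, "auroc", "reduced"))
  pred0 <- predict_performance(fit0, list(method = "m1", disease = "d1"))
  expect_equal(pred0$mean, plogis(coef(fit0$fit)[[1]]), tolerance = 1e-6)

  expect_error(predict_performance(fit, list(method = "nope"),
                                   average_over = "disease"), "unknown level")
})

test_that("Tukey contrasts flag the shifted level and dominate unadjusted p-values", {
  rec <- make_records(function(g) {
    0.9 * (g$method == "m3")
  }, methods = c("m1", "m2", "m3"), noise = 0.03, seed = 8)
  fit <- suppressWarnings(fit_additive_model(rec, "auroc", "reduced"))
  ct <- pairwise_contrasts(fit, "method")
  expect_equal(nrow(ct), 3)
  shifted <- grepl("m3", ct$contrast)
  expect_true(all(ct$significant[shifted]))
  expect_false(any(ct$significant[!shifted]))

  # single-step adjusted p-values never undercut the unadjusted ones
  sm <- summary(multcomp::glht(fit$fit,
                               linfct = multcomp::mcp(method = "Tukey")),
                test = multcomp::adjusted("none"))
  expect_true(all(ct$p_adjusted >= as.numeric(sm$test$pvalues) - 1e-12))

  expect_error(pairwise_contrasts(fit, "network"), "not in the model")
})

test_that("the overlap test equals the hypergeometric tail and behaves at the extremes", {
  enum <- sum(dhyper(5:10, 10, 90, 10))
  expect_equal(fisher_overlap_test(10, 10, 5, 100), enum, tolerance = 1e-12)
  expect_gt(fisher_overlap_test(10, 10, 0, 10000), 0.99)
  expect_lt(fisher_overlap_test(10, 10, 10, 10000), 1e-20)
  expect_error(fisher_overlap_test(10, 10, 11, 100), "inconsistent")
  expect_error(fisher_overlap_test(10, 10, 5, 10), "inconsistent")

  # uniform-or-conservative under the null at fixed margins
  set.seed(9)
  pvals <- replicate(2000, {
    x <- rhyper(1, 30, 470, 40)
    fisher_overlap_test(30, 40, x, 500)
  })
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(pvals <= alpha), alpha + 0.02)
  }
})

test_that("BH adjustment is a step-up, order-invariant, monotone procedure", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- bh_fdr(p)
  expect_equal(q, pmin(1, cummin(rev(p * 4 / 1:4))[4:1])[order(order(p))])
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))

  set.seed(10)
  p2 <- runif(30)
  perm <- sample(30)
  expect_equal(bh_fdr(p2)[perm], bh_fdr(p2[perm]))
  expect_true(all(diff(bh_fdr(p2)[order(p2)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("footrule distance and mismatch fraction follow the top-n conventions", {
  r <- paste0("g", 1:10)
  same <- footrule_distance(r, r, 10)
  expect_equal(same$distance, 0)
  expect_equal(same$mismatch_fraction, 0)

  rev10 <- footrule_distance(r, rev(r), 10)
  expect_equal(rev10$distance, floor(10^2 / 2))      # reversal closed form
  rev7 <- footrule_distance(paste0("x", 1:7), paste0("x", 7:1), 7)
  expect_equal(rev7$distance, floor(7^2 / 2))

  disjoint <- footrule_distance(paste0("a", 1:5), paste0("b", 1:5), 5)
  expect_equal(disjoint$mismatch_fraction, 1)
  expect_equal(disjoint$distance, sum(abs(1:5 - 6)) * 2)

  # symmetry
  set.seed(11)
  ra <- sample(paste0("g", 1:30)); rb <- sample(paste0("g", 1:30))
  expect_equal(footrule_distance(ra, rb, 15), footrule_distance(rb, ra, 15))
  expect_error(footrule_distance(c("a", "a", "b"), c("a", "b", "c"), 3),
               "duplicate")

  fm <- footrule_matrix(list(A = ra, B = rb, C = ra), top_n = 15)
  expect_true(isSymmetric(fm$distance))
  expect_equal(fm$distance["A", "C"], 0)
})

test_that("classical MDS embeds equidistant points and round-trips planar configurations", {
  D3 <- matrix(1, 3, 3) - diag(3)
  xy <- embed_distances(D3)
  d_out <- as.matrix(dist(xy))
  off <- d_out[upper.tri(d_out)]
  expect_lt(max(abs(off - off[1])), 1e-8)            # equilateral triangle
  expect_equal(colMeans(xy), c(dim1 = 0, dim2 = 0), tolerance = 1e-10)

  set.seed(12)
  pts <- matrix(rnorm(16), 8, 2)
  D <- as.matrix(dist(pts))
  emb <- embed_distances(D)
  expect_lt(max(abs(as.matrix(dist(emb)) - D)), 1e-6)  # rigid-motion recovery

  expect_equal(unname(embed_distances(matrix(0, 4, 4))), matrix(0, 4, 2))
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(embed_distances(bad), "symmetric")
})
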