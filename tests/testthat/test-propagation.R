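test_that("raw diffusion equals the linear-system oracle and conserves mass", {
  g <- make_path_graph(c("a", "b"))
  K <- regularized_laplacian_kernel(g)
  expect_equal(as.numeric(diffuse_raw(K, "a")), c(2 / 3, 1 / 3), tolerance = 1e-12)

  g2 <- make_connected_gnp(15, 0.3, seed = 2, weights = runif(200, 0.2, 1))
  K2 <- regularized_laplacian_kernel(g2)
  pos <- sprintf("n%03d", 1:4)
  y <- as.numeric(igraph::V(g2)$name %in% pos)
  expect_equal(as.numeric(diffuse_raw(K2, pos)), oracle_diffusion(g2, y),
               tolerance = 1e-10)

  expect_error(diffuse_raw(K2, character(0)), "positive")
  all_pos <- diffuse_raw(K2, igraph::V(g2)$name)
  expect_equal(as.numeric(all_pos), rep(1, 15), tolerance = 1e-10)
  expect_warning(diffuse_raw(K2, c(pos, "absent_gene")), "dropping")
})

test_that("gm diffusion handles the three-level input and its bias term", {
  g <- make_path_graph(c("a", "b", "c"))
  K <- regularized_laplacian_kernel(g)
  s <- diffuse_gm(K, "a", training_negatives = "c")
  expect_equal(as.numeric(s), oracle_diffusion(g, c(1, 0, -1)), tolerance = 1e-10)

  # n+ = n- makes the unlabelled bias exactly zero
  g2 <- make_connected_gnp(12, 0.4, seed = 3)
  K2 <- regularized_laplacian_kernel(g2)
  nodes <- igraph::V(g2)$name
  s2 <- diffuse_gm(K2, nodes[1:3], nodes[4:6])
  y <- rep(0, 12); y[1:3] <- 1; y[4:6] <- -1
  expect_equal(as.numeric(s2), oracle_diffusion(g2, y), tolerance = 1e-10)

  # all labelled positive: bias 1, scores all 1
  s3 <- diffuse_gm(K2, nodes)
  expect_equal(as.numeric(s3), rep(1, 12), tolerance = 1e-10)
  expect_error(diffuse_gm(K2, nodes[1:3], nodes[3:5]), "overlap")
})

test_that("z-score closed-form null moments match explicit label permutation", {
  g <- make_connected_gnp(20, 0.3, seed = 4, weights = runif(200, 0.3, 1))
  K <- regularized_laplacian_kernel(g)
  nodes <- igraph::V(g)$name
  pos <- nodes[1:6]
  y <- as.numeric(nodes %in% pos)

  n_perm <- 20000
  set.seed(99)
  perm <- vapply(seq_len(n_perm), function(i) drop(K %*% sample(y)),
                 numeric(20))
  emp_mean <- rowMeans(perm)
  emp_sd <- apply(perm, 1, sd)

  cf_mean <- length(pos) * rowMeans(K)
  cf_var <- length(pos) * (20 - length(pos)) / 19 *
    (rowMeans(K^2) - rowMeans(K)^2)

  se_mean <- emp_sd / sqrt(n_perm)
  expect_true(all(abs(cf_mean - emp_mean) < 3 * se_mean))
  se_sd <- emp_sd / sqrt(2 * (n_perm - 1))
  expect_true(all(abs(sqrt(cf_var) - emp_sd) < 3 * se_sd))

  # z itself standardises the raw score with those moments
  z <- diffuse_z(K, pos)
  raw <- drop(K %*% y)
  expect_equal(as.numeric(z), as.numeric((raw - cf_mean) / sqrt(cf_var)), tolerance = 1e-12)
})

test_that("null moments are invariant to which genes are labelled", {
  g <- make_connected_gnp(15, 0.35, seed = 5)
  K <- regularized_laplacian_kernel(g)
  nodes <- igraph::V(g)$name
  z1 <- diffuse_z(K, nodes[1:5])
  z2 <- diffuse_z(K, nodes[6:10])
  # same null (same count of positives): difference comes only from raw scores
  raw1 <- drop(K %*% as.numeric(nodes %in% nodes[1:5]))
  raw2 <- drop(K %*% as.numeric(nodes %in% nodes[6:10]))
  expect_equal(as.numeric(z1 - z2), as.numeric((raw1 - raw2) / attr_sd(K, 5)),
               tolerance = 1e-10)
})

test_that("z relabelling along a cycle automorphism permutes the scores accordingly", {
  n <- 8
  g <- igraph::make_ring(n)
  igraph::V(g)$name <- sprintf("c%d", 1:n)
  igraph::E(g)$weight <- 1
  K <- regularized_laplacian_kernel(g)
  pos <- c("c1", "c4")
  rotate <- function(x, by) sprintf("c%d", ((as.integer(sub("c", "", x)) - 1 + by) %% n) + 1)
  z1 <- diffuse_z(K, pos)
  z2 <- diffuse_z(K, rotate(pos, 2))
  expect_equal(as.numeric(z2[rotate(names(z1), 2)]), as.numeric(z1), tolerance = 1e-10)
})

test_that("Monte Carlo normalisation is a seeded empirical quantile converging to z", {
  g <- make_connected_gnp(15, 0.35, seed = 6)
  K <- regularized_laplacian_kernel(g)
  nodes <- igraph::V(g)$name
  pos <- nodes[1:4]

  expect_error(diffuse_mc(K, pos, n_perm = 50), "at least 100")
  s1 <- diffuse_mc(K, pos, n_perm = 200, seed = 7)
  s2 <- diffuse_mc(K, pos, n_perm = 200, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))

  mc <- diffuse_mc(K, pos, n_perm = 10000, seed = 8)
  z <- diffuse_z(K, pos)
  expect_gt(cor(mc, z, method = "spearman"), 0.95)
})

test_that("personalised PageRank matches power iteration and sums to one", {
  g <- make_star_graph(4)
  centre <- igraph::V(g)$name[1]
  s <- personalized_pagerank(g, centre, damping = 0.85)
  expect_equal(sum(s), 1, tolerance = 1e-10)

  # power-iteration oracle on the weighted walk with restart to the centre
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  P <- W / rowSums(W)
  v <- rep(1 / 4, 4); reset <- c(1, 0, 0, 0)
  for (i in 1:500) v <- 0.85 * drop(v %*% P) + 0.15 * reset
  expect_equal(as.numeric(s), as.numeric(v), tolerance = 1e-8)

  g2 <- make_path_graph(c("a", "b"))
  s2 <- personalized_pagerank(g2, c("a", "b"))
  expect_equal(as.numeric(s2), c(0.5, 0.5), tolerance = 1e-10)
  expect_error(personalized_pagerank(g2, "a", damping = 1.2), "damping")
})

test_that("uniform PageRank reflects topology only", {
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- letters[1:6]
  igraph::E(ring)$weight <- 1
  expect_equal(as.numeric(pagerank_uniform(ring)), rep(1 / 6, 6), tolerance = 1e-10)

  star <- make_star_graph(7)
  s <- pagerank_uniform(star)
  expect_true(all(s[1] > s[-1]))

  g <- make_connected_gnp(10, 0.4, seed = 7)
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  P <- W / rowSums(W)
  v <- rep(1 / 10, 10)
  for (i in 1:1000) v <- 0.85 * drop(v %*% P) + 0.15 / 10
  expect_equal(as.numeric(pagerank_uniform(g)), as.numeric(v), tolerance = 1e-8)
})

test_that("input-naive baselines behave as permutations and uniform draws", {
  g <- make_connected_gnp(20, 0.25, seed = 8)
  K <- regularized_laplacian_kernel(g)
  nodes <- igraph::V(g)$name
  pos <- nodes[1:5]

  rr <- randomraw_scores(K, pos, seed = 3)
  expect_identical(rr, randomraw_scores(K, pos, seed = 3))
  # permuted input preserves total mass: scores sum to the positive count
  expect_equal(sum(rr), length(pos), tolerance = 1e-8)
  expect_equal(as.numeric(randomraw_scores(K, nodes, seed = 1)),
               as.numeric(diffuse_raw(K, nodes)), tolerance = 1e-12)

  # averaged over seeds, randomraw converges to the z-score null mean
  avg <- rowMeans(vapply(1:1000, function(s) {
    as.numeric(randomraw_scores(K, pos, seed = s))
  }, numeric(20)))
  null_mean <- length(pos) * rowMeans(K)
  null_sd <- attr_sd(K, length(pos))
  expect_true(all(abs(avg - null_mean) < 3 * null_sd / sqrt(1000)))

  r1 <- random_scores(nodes, seed = 5)
  expect_identical(r1, random_scores(nodes, seed = 5))
  expect_false(identical(order(r1), order(random_scores(nodes, seed = 6))))
  expect_true(all(r1 >= 0 & r1 <= 1))
})

test_that("neighbour voting scores the weighted fraction of positive neighbours", {
  g <- make_path_graph(c("a", "b", "c"))
  s <- egad_neighbor_voting(g, "a")
  # a's only neighbour (b) is unlabelled, b has one positive of two
  # neighbours, c has none
  expect_equal(as.numeric(s), c(0, 0.5, 0))

  g2 <- make_star_graph(5)
  leaves <- igraph::V(g2)$name[-1]
  s2 <- egad_neighbor_voting(g2, leaves)
  expect_equal(as.numeric(s2[1]), 1)      # centre sees only positives
  expect_equal(as.numeric(s2[-1]), rep(0, 4))  # leaves see only the centre
})

test_that("raw diffusion ranking is invariant under positive rescaling of the kernel input", {
  g <- make_connected_gnp(12, 0.4, seed = 9)
  K <- regularized_laplacian_kernel(g)
  nodes <- igraph::V(g)$name
  y <- as.numeric(nodes %in% nodes[1:3])
  r1 <- rank(drop(K %*% y))
  r2 <- rank(drop(K %*% (7.3 * y)))
  expect_equal(r1, r2)
})
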