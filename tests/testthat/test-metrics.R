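test_that("MSE and Spearman reduce to their identities", {
  X <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(mse(X, X), 0)
  expect_equal(spearman(X, X), 1)
  expect_equal(spearman(matrix(1:3, 1), matrix(3:1, 1)), -1)
  expect_error(spearman(matrix(1, 2, 2), matrix(1:4, 2, 2)), "constant")

  set.seed(3)
  A <- matrix(rnorm(25), 5, 5); B <- matrix(rnorm(25), 5, 5)
  # brute-force rank computation
  ra <- rank(as.vector(A)); rb <- rank(as.vector(B))
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(spearman(A, B), oracle, tolerance = 1e-12)
})

test_that("coverage-restricted MSE picks exactly the most covered columns", {
  X <- rbind(c(1, 0, 2), c(3, 4, 0), c(5, 0, 0))   # coverage 3, 1, 1
  Xh <- X + 1
  expect_equal(mse_top_covered(X, Xh, "observed", top_frac = 1/3),
               mean((X[, 1] - Xh[, 1])^2))
  expect_equal(mse_top_covered(X, X, "observed"), 0)
  expect_equal(mse_top_covered(X, X, "imputed"), 0)
  set.seed(4)
  A <- matrix(rpois(60, 2), 6, 10); B <- matrix(rnorm(60), 6, 10)
  expect_equal(mse_top_covered(A, B, "observed", top_frac = 1), mse(A, B))
  # imputed basis uses the reconstruction's coverage
  Bz <- B; Bz[, 1:9] <- 0
  expect_equal(mse_top_covered(A, Bz, "imputed", top_frac = 1/10),
               mean((A[, 10] - Bz[, 10])^2))
})

test_that("the NB loss matches closed forms and limits", {
  expect_equal(nb_loss(matrix(0), matrix(1), theta = 1), log(2),
               tolerance = 1e-9)
  # Poisson limit
  for (x in 0:5) for (mu in c(0.5, 2, 5)) {
    expect_equal(nb_loss(matrix(x), matrix(mu), theta = 1e6),
                 -dpois(x, mu, log = TRUE), tolerance = 1e-3)
  }
  # minimised at mu = x over a grid scan
  x <- matrix(4)
  grid <- seq(0.5, 10, by = 0.1)
  nll <- sapply(grid, function(mu) nb_loss(x, matrix(mu), theta = 2))
  expect_equal(grid[which.min(nll)], 4, tolerance = 0.051)
  expect_error(nb_loss(matrix(1), matrix(1), theta = -1), "positive")
  # moment estimator recovers the generating dispersion on a large sample
  set.seed(5)
  big <- matrix(rnbinom(20000, size = 2, mu = 3), 200, 100)
  expect_equal(estimate_nb_theta(big), 2, tolerance = 0.4)
})

test_that("homogeneity reproduces its closed forms", {
  # pure neighbourhoods: 5 blocks of 20 cells, neighbours within block
  labels <- rep(1:5, each = 20)
  neighbors <- t(sapply(1:100, function(i) {
    block <- setdiff(which(labels == labels[i]), i)
    block[1:15]
  }))
  g <- structure(list(n_nodes = 100, neighbors = neighbors, k = 15L,
                      edges = cbind(1L, 2L), source = "craft"),
                 class = "cell_graph")
  expect_equal(homogeneity(g, labels), 1 - 1 / 75, tolerance = 1e-12)

  # every neighbourhood holds all 15 types
  labels2 <- rep(1:15, 10)
  neighbors2 <- t(sapply(1:150, function(i)
    sapply(1:15, function(t) setdiff(which(labels2 == t), i)[1])))
  g2 <- structure(list(n_nodes = 150, neighbors = neighbors2, k = 15L,
                       edges = cbind(1L, 2L), source = "craft"),
                  class = "cell_graph")
  expect_equal(homogeneity(g2, labels2), 14 / 15, tolerance = 1e-12)
})

test_that("homogeneity agrees with a brute-force recount", {
  set.seed(6)
  X <- matrix(rnorm(90 * 3), 90, 3)
  labels <- sample(1:4, 90, replace = TRUE)
  g <- knn_graph(X, k = 7)
  D <- as.matrix(dist(X)); diag(D) <- Inf
  het <- sapply(1:90, function(i) {
    nb <- order(D[i, ], seq_len(90))[1:7]
    length(unique(labels[nb])) / (7 * 4)
  })
  expect_equal(homogeneity(g, labels, C = 4), 1 - mean(het), tolerance = 1e-12)
})

test_that("specificity and stability reproduce their calibration values", {
  ids <- sprintf("f%d", 1:200)
  same <- list(a = ids[1:50], b = ids[1:50], c = ids[1:50])
  expect_equal(specificity(same), 0)
  disjoint <- list(a = ids[1:50], b = ids[51:100], c = ids[101:150])
  expect_equal(specificity(disjoint), 1)
  half <- list(a = ids[1:50], b = ids[26:75])
  expect_equal(specificity(half), 0.5)
  expect_error(specificity(list(a = ids[1:10], b = ids[1:50])), "size")

  runs_same <- list(list(a = ids[1:50]), list(a = ids[1:50]))
  expect_equal(stability(runs_same), 1)
  runs_disj <- list(list(a = ids[1:50]), list(a = ids[51:100]))
  expect_equal(stability(runs_disj), 0)
  runs3 <- list(list(a = ids[1:50]), list(a = ids[1:50]), list(a = ids[26:75]))
  expect_equal(stability(runs3), 2 / 3)
  expect_error(stability(list(list(a = ids[1:50]), list(b = ids[1:50]))),
               "missing class")
})

test_that("coverage, expression and bias overlap follow their definitions", {
  m <- count_matrix(cbind(c(1, 0, 2), c(0, 0, 0), c(4, 4, 4)))
  expect_equal(unname(feature_coverage(m)), c(2, 0, 3))
  expect_equal(unname(feature_expression(m)), c(3, 0, 12))
  expect_lte(max(feature_coverage(m)), n_cells(m))

  set.seed(7)
  counts <- matrix(rpois(50 * 30, 3), 50, 30)
  mm <- count_matrix(counts)
  val <- colSums(counts)
  top10 <- mm$feature_ids[order(-val, seq_along(val))[1:10]]
  expect_equal(bias_overlap(top10, mm, "expression"), 1)
  bottom <- mm$feature_ids[order(val, -seq_along(val))[1:10]]
  expect_equal(bias_overlap(bottom, mm, "expression"),
               length(intersect(bottom, top10)) / 10)
  cov <- colSums(counts != 0)
  topc <- mm$feature_ids[order(-cov, seq_along(cov))[1:5]]
  expect_equal(bias_overlap(topc, mm, "coverage"), 1)
})

test_that("signal-to-noise ratio behaves at its limits and on markers", {
  vals <- c(1, 3, 2, 1, 3, 2)
  m <- count_matrix(matrix(vals, 6, 1), labels = rep(c("in", "out"), each = 3))
  expect_equal(stn_ratio("feat_1", m, class = "in"), 0)

  m2 <- count_matrix(matrix(rep(c(5, 0), each = 3), 6, 1),
                     labels = rep(c("in", "out"), each = 3))
  expect_gt(stn_ratio("feat_1", m2, class = "in"), 1e6)

  r <- small_fixture()
  mk <- r$matrix$feature_ids[r$truth$marker_sets[[1]]]
  bg <- r$matrix$feature_ids[setdiff(seq_len(120), unlist(r$truth$marker_sets))][1:10]
  expect_gt(stn_ratio(mk, r$matrix, class = "type_1"),
            stn_ratio(bg, r$matrix, class = "type_1"))
})

test_that("explainer/differential similarity is the normalised overlap", {
  ids <- sprintf("f%d", 1:100)
  expect_equal(xai_da_similarity(ids[1:50], ids[1:50]), 1)
  expect_equal(xai_da_similarity(ids[1:50], ids[51:100]), 0)
  expect_equal(xai_da_similarity(ids[1:50], ids[41:90]), 0.2)
  expect_equal(xai_da_similarity(ids[1:50], ids[41:90], method = "jaccard"),
               10 / 90)
  expect_error(xai_da_similarity(ids[1:10], ids[1:50]), "size")
})

test_that("bounded metrics stay in range on fuzzed inputs", {
  set.seed(8)
  for (i in 1:5) {
    n <- sample(40:80, 1)
    labels <- sample(1:3, n, replace = TRUE)
    g <- knn_graph(matrix(rnorm(n * 3), n, 3), k = 5)
    h <- homogeneity(g, labels)
    expect_gte(h, 0); expect_lte(h, 1)
    sets <- lapply(1:3, function(j) sample(sprintf("f%d", 1:60), 20))
    names(sets) <- c("a", "b", "c")
    s <- specificity(sets, n = 20)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})
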