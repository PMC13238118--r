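# a hand-built 3-node graph: nodes 2-3 linked, node 1 isolated (self-loop only)
.toy_gat <- function(seed = 5, d = 4, hd = 3, H = 2, C = 2) {
  set.seed(seed)
  params <- graphmarkers:::.gat_init_params(d, hd, H, C)
  ea <- graphmarkers:::.edge_arrays(cbind(2L, 3L), 3L)
  list(params = params, ea = ea, d = d, hd = hd, H = H)
}

test_that("an isolated node attends only to itself", {
  toy <- .toy_gat()
  set.seed(1)
  X <- matrix(rnorm(12), 3, toy$d)
  fw <- graphmarkers:::.gat_forward(toy$params, X, toy$ea, toy$hd, toy$H,
                                    keep_cache = TRUE)
  self_edge <- which(toy$ea$is_self & toy$ea$dst == 1)
  for (h in seq_len(toy$H))
    expect_equal(fw$cache$cache_h[[h]]$alpha[self_edge], 1, tolerance = 1e-12)
  # its output is independent of the other nodes' features
  X2 <- X; X2[2:3, ] <- X2[2:3, ] + 5
  fw2 <- graphmarkers:::.gat_forward(toy$params, X2, toy$ea, toy$hd, toy$H)
  expect_equal(fw$probs[1, ], fw2$probs[1, ], tolerance = 1e-12)
})

test_that("identical neighbour features yield uniform attention", {
  set.seed(6)
  params <- graphmarkers:::.gat_init_params(4, 3, 2, 2)
  # node 1 linked to 2 and 3; all feature vectors identical
  ea <- graphmarkers:::.edge_arrays(rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)), 3L)
  X <- matrix(rep(c(0.3, -1, 2, 0.5), each = 3), 3, 4)
  fw <- graphmarkers:::.gat_forward(params, X, ea, 3, 2, keep_cache = TRUE)
  into1 <- which(ea$dst == 1)
  for (h in 1:2)
    expect_equal(fw$cache$cache_h[[h]]$alpha[into1], rep(1 / 3, 3),
                 tolerance = 1e-12)
})

test_that("attention normalises to one over each neighbourhood", {
  m <- small_processed()
  g <- knn_graph(pca_embed(m), k = 8)
  ea <- graphmarkers:::.edge_arrays(g$edges, g$n_nodes)
  set.seed(7)
  params <- graphmarkers:::.gat_init_params(n_features(m), 4, 3, 3)
  fw <- graphmarkers:::.gat_forward(params, m$counts, ea, 4, 3, keep_cache = TRUE)
  for (h in 1:3) {
    sums <- rowsum(fw$cache$cache_h[[h]]$alpha, ea$dst)[, 1]
    expect_lt(max(abs(sums - 1)), 1e-6)
  }
  sums2 <- rowsum(fw$cache$alpha2, ea$dst)[, 1]
  expect_lt(max(abs(sums2 - 1)), 1e-6)
  expect_lt(max(abs(rowSums(fw$probs) - 1)), 1e-6)
})

test_that("GAT and GCN both learn the separable fixture", {
  m <- separable_processed()
  g <- knn_graph(pca_embed(m), k = 15)
  for (arch in c("GAT", "GCN")) {
    out <- train_classifier(g, m, gat_config(seed = 2), arch)
    expect_gte(out$report$f1, 0.9)
  }
})

test_that("predictions are permutation-equivariant", {
  m <- small_processed()
  g <- knn_graph(pca_embed(m), k = 6)
  out <- train_classifier(g, m, gat_config(max_epochs = 15, patience = 15,
                                           seed = 3), "GAT")
  probs <- predict_cells(out$model, m$counts)
  set.seed(8)
  perm <- sample(n_cells(m))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  edges_p <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
  g_p <- g
  g_p$edges <- cbind(pmin(edges_p[, 1], edges_p[, 2]),
                     pmax(edges_p[, 1], edges_p[, 2]))
  probs_p <- predict_cells(out$model, m$counts[perm, ], g = g_p)
  expect_equal(unname(probs_p), unname(probs[perm, ]), tolerance = 1e-8)
})

test_that("classification metrics reduce to their closed forms", {
  classes <- c("a", "b")
  perfect <- classification_report(c(1, 1, 2, 2), c(1, 1, 2, 2), classes)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  constant <- classification_report(c(1, 1, 2, 2), c(1, 1, 1, 1), classes)
  expect_equal(constant$accuracy, 0.5)
  expect_equal(constant$f1, 1 / 3)
  expect_equal(unname(rowSums(constant$confusion)), c(2, 2))
})

test_that("training validates labels and alignment", {
  m <- small_processed()
  g <- knn_graph(pca_embed(m), k = 6)
  bare <- m; bare$labels <- NULL
  expect_error(train_classifier(g, bare, gat_config()), "labels")
  short <- count_matrix(m$counts[1:100, ], labels = m$labels[1:100],
                        is_normalised = TRUE, is_log = TRUE)
  expect_error(train_classifier(g, short, gat_config()), "mismatch")
})

test_that("classification reports serialise to JSON", {
  rep <- classification_report(c(1, 2, 1, 2), c(1, 2, 2, 2), c("x", "y"))
  path <- withr::local_tempfile(fileext = ".json")
  write_classification_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$accuracy, rep$accuracy, tolerance = 1e-12)
})
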