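test_that("all-ones masks reproduce the unmasked prediction exactly", {
  m <- small_processed()
  g <- knn_graph(pca_embed(m), k = 6)
  ea <- graphmarkers:::.edge_arrays(g$edges, g$n_nodes)
  set.seed(4)
  params <- graphmarkers:::.gat_init_params(n_features(m), 4, 2, 3)
  plain <- graphmarkers:::.gat_forward(params, m$counts, ea, 4, 2)
  ones_f <- sweep(m$counts, 2, rep(1, n_features(m)), "*")
  masked <- graphmarkers:::.gat_forward(params, ones_f, ea, 4, 2,
                                        em1 = rep(1, length(ea$src)),
                                        em2 = rep(1, length(ea$src)))
  expect_equal(masked$probs, plain$probs, tolerance = 1e-12)
  # all-zero feature mask collapses to the zero-input prediction
  zeroed <- graphmarkers:::.gat_forward(params, m$counts * 0, ea, 4, 2)
  masked0 <- graphmarkers:::.gat_forward(
    params, sweep(m$counts, 2, rep(0, n_features(m)), "*"), ea, 4, 2)
  expect_equal(masked0$probs, zeroed$probs, tolerance = 1e-12)
})

test_that("explanations are deterministic and stay in bounds", {
  pipe <- sep_pipeline(1)
  m <- separable_processed()
  cfg <- explainer_config(epochs = 60, seed = 2)
  v <- which(m$labels == "type_1")[2]
  a <- explain_node(pipe$model, pipe$graph, m$counts, v, cfg)
  b <- explain_node(pipe$model, pipe$graph, m$counts, v, cfg)
  expect_identical(a$feature_mask, b$feature_mask)
  expect_true(all(a$feature_mask >= 0 & a$feature_mask <= 1))
  expect_true(all(a$edge_mask$value >= 0 & a$edge_mask$value <= 1))
  expect_equal(sum(a$masked_prediction), 1, tolerance = 1e-6)
})

test_that("node masks rank planted markers above background", {
  pipe <- sep_pipeline(1)
  m <- separable_processed()
  cfg <- explainer_config(epochs = 150, seed = 3)
  hits <- 0
  nodes <- which(m$labels == "type_1")[c(5, 25, 45)]
  for (v in nodes) {
    ex <- explain_node(pipe$model, pipe$graph, m$counts, v, cfg)
    if (mean(ex$feature_mask[1:20]) > mean(ex$feature_mask[41:200])) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("class explanations average node masks and rank monotonically", {
  pipe <- sep_pipeline(1)
  m <- separable_processed()
  cfg <- explainer_config(epochs = 40, seed = 5)
  ex <- explain_class(pipe$model, pipe$graph, m, m$labels, cfg, n_top = 20,
                      max_nodes_per_class = 2)
  e1 <- ex$type_1
  expect_length(e1$ranking, n_features(m))
  expect_length(unique(e1$top), 20)
  imp_sorted <- e1$importance[e1$ranking]
  expect_true(all(diff(unname(imp_sorted)) <= 1e-12))

  # averaging identity: importance equals the mean of the node masks
  set.seed(cfg$seed + 1)            # the class-1 subsample seed
  nodes <- sort(sample(which(m$labels == "type_1"), 2))
  adj <- graphmarkers:::.adjacency_list(pipe$graph)
  masks <- sapply(nodes, function(v)
    explain_node(pipe$model, pipe$graph, m$counts, v, cfg, adj = adj)$feature_mask)
  expect_equal(unname(e1$importance), unname(rowMeans(masks)), tolerance = 1e-10)
  expect_true(e1$subsampled)
})

test_that("importance decay is the absolute first difference along rank", {
  e <- structure(list(class = "x",
                      importance = c(f1 = 10, f2 = 1, f3 = 1),
                      ranking = c("f1", "f2", "f3"),
                      top = c("f1"), n_top = 1),
                 class = "class_explanation")
  expect_equal(importance_decay(e), c(9, 0))
  e$importance[] <- 2
  expect_equal(importance_decay(e), c(0, 0))
  set.seed(9)
  imp <- sort(runif(15), decreasing = TRUE)
  names(imp) <- sprintf("f%d", 1:15)
  e2 <- structure(list(class = "y", importance = imp,
                       ranking = names(imp), top = names(imp)[1:5], n_top = 5),
                  class = "class_explanation")
  expect_equal(importance_decay(e2), abs(diff(unname(imp))))
})

test_that("explaining requires a trained attention model", {
  m <- small_processed()
  g <- knn_graph(pca_embed(m), k = 6)
  gcn <- train_classifier(g, m, gat_config(max_epochs = 5, patience = 5,
                                           seed = 1), "GCN")
  expect_error(explain_node(gcn$model, g, m$counts, 1), "attention")
})

test_that("per-class explanation files carry n_top rows", {
  pipe <- sep_pipeline(1)
  m <- separable_processed()
  cfg <- explainer_config(epochs = 15, seed = 6)
  ex <- explain_class(pipe$model, pipe$graph, m, m$labels, cfg, n_top = 10,
                      max_nodes_per_class = 1)
  dir <- withr::local_tempdir()
  write_class_explanations(ex, dir, cfg)
  for (cl in c("type_1", "type_2")) {
    tab <- read.table(file.path(dir, sprintf("explanation_%s.tsv", cl)),
                      header = TRUE, sep = "\t")
    expect_equal(nrow(tab), 10)
  }
  expect_true(file.exists(file.path(dir, "explanations.json")))
})
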