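#' Explainer configuration
#'
#' Settings for the mask-learning explainer: it maximises the mutual
#' information between the frozen classifier's prediction and a masked
#' (sub-graph, sub-feature) input, realised as cross-entropy between the
#' original and masked predictions plus size and entropy penalties that
#' drive the masks towards small, near-binary sets.
#'
#' @param epochs optimisation steps per node (default 300).
#' @param lr Adam learning rate for the mask parameters.
#' @param feat_size_weight,feat_entropy_weight penalty weights on the mean
#'   and element-wise entropy of the feature mask.
#' @param edge_size_weight,edge_entropy_weight same for the edge mask.
#' @param seed integer seed (controls per-class node subsampling).
#' @return an object of class `explainer_config`.
#' @export
explainer_config <- function(epochs = 300, lr = 0.01,
                             feat_size_weight = 1.0, feat_entropy_weight = 0.1,
                             edge_size_weight = 0.005, edge_entropy_weight = 0.1,
                             seed = 1L) {
  .assert(epochs >= 1, "epochs must be >= 1")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 feat_size_weight = feat_size_weight,
                 feat_entropy_weight = feat_entropy_weight,
                 edge_size_weight = edge_size_weight,
                 edge_entropy_weight = edge_entropy_weight,
                 seed = as.integer(seed)),
            class = "explainer_config")
}

# restricted computation graph of node v for a two-layer GNN: v, its
# neighbours (whose layer-1 outputs feed v) and their neighbours (whose
# features feed those outputs). Edges between pure 2-hop nodes do not enter
# v's prediction and are dropped.
.node_subgraph <- function(g, v) {
  e <- g$edges
  adj <- vector("list", g$n_nodes)
  for (r in seq_len(nrow(e))) {
    adj[[e[r, 1]]] <- c(adj[[e[r, 1]]], e[r, 2])
    adj[[e[r, 2]]] <- c(adj[[e[r, 2]]], e[r, 1])
  }
  n1 <- adj[[v]]
  inner <- sort(unique(c(v, n1)))
  keep <- e[, 1] %in% inner | e[, 2] %in% inner
  sub_e <- e[keep, , drop = FALSE]
  nodes <- sort(unique(c(v, as.integer(sub_e))))
  lookup <- integer(g$n_nodes)
  lookup[nodes] <- seq_along(nodes)
  local_e <- cbind(lookup[sub_e[, 1]], lookup[sub_e[, 2]])
  list(nodes = nodes, edges_local = local_e, edges_global = sub_e,
       v_local = lookup[v])
}

# adjacency list reused across many explain_node calls
.adjacency_list <- function(g) {
  adj <- rep(list(integer(0)), g$n_nodes)
  for (r in seq_len(nrow(g$edges))) {
    a <- g$edges[r, 1]; b <- g$edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

.node_subgraph_adj <- function(g, v, adj) {
  n1 <- adj[[v]]
  inner <- sort(unique(c(v, n1)))
  in_inner <- logical(g$n_nodes); in_inner[inner] <- TRUE
  keep <- in_inner[g$edges[, 1]] | in_inner[g$edges[, 2]]
  sub_e <- g$edges[keep, , drop = FALSE]
  nodes <- sort(unique(c(v, as.integer(sub_e))))
  lookup <- integer(g$n_nodes)
  lookup[nodes] <- seq_along(nodes)
  list(nodes = nodes,
       edges_local = cbind(lookup[sub_e[, 1]], lookup[sub_e[, 2]]),
       edges_global = sub_e, v_local = lookup[v])
}

.mask_entropy_grad <- function(x) {
  x <- pmin(pmax(x, 1e-7), 1 - 1e-7)
  log((1 - x) / x)
}

.mask_entropy <- function(x) {
  x <- pmin(pmax(x, 1e-7), 1 - 1e-7)
  -(x * log(x) + (1 - x) * log(1 - x))
}

#' Learn feature and edge masks explaining one node's prediction
#'
#' With the trained attention classifier frozen, learns a sigmoid-squashed
#' feature mask (shared across the node's computation graph) and an edge
#' mask (one parameter per undirected edge, self-loops unmasked) by gradient
#' ascent on the mutual-information objective: minimise the cross-entropy
#' between the model's original prediction at `v` and its prediction under
#' the masked graph and features, plus size and entropy penalties. Masks are
#' initialised near 1, so optimisation starts from the identity masking.
#' Deterministic given the configuration.
#'
#' @param model a `trained_classifier` with `arch == "GAT"`.
#' @param g the `cell_graph` the model was trained on.
#' @param X node feature matrix row-aligned with `g`.
#' @param v node index to explain.
#' @param cfg an [explainer_config()].
#' @param adj optional precomputed [.adjacency_list()] (internal reuse).
#' @return an object of class `node_explanation`: `node`, `feature_mask`
#'   (values in \[0, 1\], named by feature ids when available), `edge_mask`
#'   (data.frame `from`, `to`, `value` on global node indices),
#'   `masked_prediction`, `original_prediction`, `predicted_class`, `loss`
#'   (per-step trace).
#' @export
explain_node <- function(model, g, X, v, cfg = explainer_config(), adj = NULL) {
  stopifnot(inherits(model, "trained_classifier"))
  .assert(model$arch == "GAT", "the explainer targets the attention classifier (arch GAT)")
  X <- .as_feature_matrix(X)
  .assert(v >= 1 && v <= g$n_nodes, "invalid node index")
  .assert(nrow(X) == g$n_nodes, "node count mismatch")
  sub <- if (is.null(adj)) .node_subgraph(g, v) else .node_subgraph_adj(g, v, adj)
  Xs <- X[sub$nodes, , drop = FALSE]
  ns <- length(sub$nodes)
  ea <- .edge_arrays(sub$edges_local, ns)
  hd <- model$hidden_dim; H <- model$n_heads; slope <- model$cfg$leaky_slope
  params <- model$params
  f <- ncol(X)
  nu <- ea$n_undirected

  fw0 <- .gat_forward(params, Xs, ea, hd, H, slope)
  p0 <- fw0$probs[sub$v_local, ]
  yhat <- which.max(p0)

  set.seed(cfg$seed)
  phi <- list(f = rep(3, f), e = rep(3, nu))   # sigmoid(3) ~ 0.95: near-identity start
  state <- .adam_init(phi)
  loss_trace <- numeric(cfg$epochs)
  nonself <- !ea$is_self
  for (step in seq_len(cfg$epochs)) {
    mf <- .sigmoid(phi$f); me <- .sigmoid(phi$e)
    emdir <- rep(1, length(ea$src))
    emdir[nonself] <- me[ea$ue[nonself]]
    Xm <- sweep(Xs, 2, mf, "*")
    fw <- .gat_forward(params, Xm, ea, hd, H, slope,
                       em1 = emdir, em2 = emdir, keep_cache = TRUE)
    pv <- fw$probs[sub$v_local, ]
    ce <- -log(max(pv[yhat], 1e-12))
    loss_trace[step] <- ce +
      cfg$feat_size_weight * mean(mf) +
      cfg$feat_entropy_weight * mean(.mask_entropy(mf)) +
      cfg$edge_size_weight * mean(me) +
      cfg$edge_entropy_weight * mean(.mask_entropy(me))
    dlogits <- matrix(0, ns, length(pv))
    dlogits[sub$v_local, ] <- pv
    dlogits[sub$v_local, yhat] <- pv[yhat] - 1
    bw <- .gat_backward(fw, dlogits, params, ea, want_dX = TRUE,
                        want_dmask = TRUE, want_param_grads = FALSE)
    dmf <- colSums(bw$dX * Xs) +
      cfg$feat_size_weight / f +
      cfg$feat_entropy_weight / f * .mask_entropy_grad(mf)
    dme <- bw$dmask +
      cfg$edge_size_weight / nu +
      cfg$edge_entropy_weight / nu * .mask_entropy_grad(me)
    grads <- list(f = dmf * mf * (1 - mf), e = dme * me * (1 - me))
    upd <- .adam_step(phi, grads, state, cfg$lr)
    phi <- upd$params; state <- upd$state
  }
  mf <- .sigmoid(phi$f); me <- .sigmoid(phi$e)
  emdir <- rep(1, length(ea$src))
  emdir[nonself] <- me[ea$ue[nonself]]
  fwm <- .gat_forward(params, sweep(Xs, 2, mf, "*"), ea, hd, H, slope,
                      em1 = emdir, em2 = emdir)
  masked_pred <- fwm$probs[sub$v_local, ]
  names(masked_pred) <- model$classes
  names(p0) <- model$classes
  if (!is.null(colnames(X))) names(mf) <- colnames(X)
  structure(list(node = v, feature_mask = mf,
                 edge_mask = data.frame(from = sub$edges_global[, 1],
                                        to = sub$edges_global[, 2],
                                        value = me),
                 masked_prediction = masked_pred, original_prediction = p0,
                 predicted_class = model$classes[yhat], loss = loss_trace),
            class = "node_explanation")
}

#' Per-cell-type feature importance from node explanations
#'
#' Runs [explain_node()] over the nodes of each class (or a seeded
#' stratified subsample of at most `max_nodes_per_class`, recorded in the
#' result), averages the learned feature masks within each class, and ranks
#' features by the averaged importance (descending; ties broken by
#' ascending feature index). The top-`n_top` set per class is the
#' explainer-derived feature list compared against differential analysis.
#'
#' @inheritParams explain_node
#' @param labels per-node class labels (factor or character).
#' @param n_top size of the reported top set.
#' @param max_nodes_per_class subsampling cap per class (`Inf` to explain
#'   every node).
#' @return a named list of `class_explanation` objects (one per class),
#'   with class `class_explanation_set`. Each element carries `class`,
#'   `importance` (mean feature mask, aligned to feature ids), `ranking`
#'   (feature ids by decreasing importance), `top` (first `n_top`),
#'   `n_explained`, `subsampled`, `fidelity` (fraction of explained nodes
#'   whose masked argmax equals the unmasked one).
#' @export
explain_class <- function(model, g, X, labels, cfg = explainer_config(),
                          n_top = 50, max_nodes_per_class = 500) {
  X <- .as_feature_matrix(X)
  labels <- factor(labels)
  .assert(nrow(X) == g$n_nodes, "labels/features must cover all nodes")
  feature_ids <- colnames(X) %||% sprintf("feat_%d", seq_len(ncol(X)))
  adj <- .adjacency_list(g)
  out <- list()
  for (ci in seq_along(levels(labels))) {
    cl <- levels(labels)[ci]
    nodes <- which(labels == cl)
    .assert(length(nodes) > 0, "class '%s' has no nodes", cl)
    subsampled <- FALSE
    if (length(nodes) > max_nodes_per_class) {
      set.seed(cfg$seed + ci)
      nodes <- sort(sample(nodes, max_nodes_per_class))
      subsampled <- TRUE
    }
    masks <- matrix(0, length(nodes), ncol(X))
    fid <- logical(length(nodes))
    for (i in seq_along(nodes)) {
      ex <- explain_node(model, g, X, nodes[i], cfg, adj = adj)
      masks[i, ] <- ex$feature_mask
      fid[i] <- which.max(ex$masked_prediction) == which.max(ex$original_prediction)
    }
    importance <- colMeans(masks)
    names(importance) <- feature_ids
    ord <- order(-importance, seq_along(importance))
    out[[cl]] <- structure(list(class = cl, importance = importance,
                                ranking = feature_ids[ord],
                                top = feature_ids[ord][seq_len(min(n_top, length(ord)))],
                                n_top = n_top, n_explained = length(nodes),
                                subsampled = subsampled,
                                fidelity = mean(fid)),
                           class = "class_explanation")
  }
  structure(out, class = c("class_explanation_set", "list"))
}

#' @export
print.class_explanation <- function(x, ...) {
  cat(sprintf("<class_explanation> %s: %d nodes explained%s, fidelity %.2f\n",
              x$class, x$n_explained,
              if (x$subsampled) " (subsampled)" else "", x$fidelity))
  cat("  top:", paste(utils::head(x$top, 8), collapse = ", "), "...\n")
  invisible(x)
}

#' Top-n features of a class explanation
#' @param e a `class_explanation`.
#' @param n set size (defaults to the stored `n_top`).
#' @return character vector of feature ids.
#' @export
top_features <- function(e, n = NULL) {
  n <- n %||% e$n_top
  e$ranking[seq_len(min(n, length(e$ranking)))]
}

#' Importance decay along the ranking
#'
#' Absolute first differences of the importance ordered by rank — the decay
#' rate used to judge how many features carry signal (the importance of the
#' rank-importance curve flattens where the decay reaches zero).
#'
#' @param e a `class_explanation`.
#' @return numeric vector of length `F - 1`.
#' @export
importance_decay <- function(e) {
  v <- e$importance[e$ranking]
  abs(diff(unname(v)))
}

#' Write per-class explanations as TSV + JSON manifest
#'
#' One `explanation_<class>.tsv` (rank, feature_id, importance) per class
#' plus an `explanations.json` manifest recording configuration and
#' subsampling.
#'
#' @param set a `class_explanation_set`.
#' @param dir output directory.
#' @param cfg the [explainer_config()] used (echoed into the manifest).
#' @return `dir`, invisibly.
#' @export
write_class_explanations <- function(set, dir, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  for (e in set) {
    n_keep <- min(e$n_top, length(e$ranking))
    df <- data.frame(rank = seq_len(n_keep),
                     feature_id = e$ranking[seq_len(n_keep)],
                     importance = unname(e$importance[e$ranking[seq_len(n_keep)]]))
    safe <- gsub("[^A-Za-z0-9_.-]", "_", e$class)
    utils::write.table(df, file.path(dir, sprintf("explanation_%s.tsv", safe)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    meta[[e$class]] <- list(n_explained = e$n_explained,
                            subsampled = e$subsampled, fidelity = e$fidelity)
  }
  .write_json(list(config = if (!is.null(cfg)) unclass(cfg) else NULL,
                   classes = meta),
              file.path(dir, "explanations.json"))
  invisible(dir)
}
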