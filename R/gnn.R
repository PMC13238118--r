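#' Graph neural network training configuration
#'
#' @param hidden_dim hidden dimension of the first layer (per attention
#'   head); default `ceiling(F^(1/3))`, the autoencoder latent dimension.
#' @param n_heads number of attention heads in layer 1 (concatenated);
#'   layer 2 uses a single head producing the class logits.
#' @param lr,weight_decay Adam settings.
#' @param max_epochs,patience early-stopping schedule (defaults 300 / 30);
#'   best-validation weights are restored.
#' @param split named train/val/test fractions, summing to 1 (defaults
#'   0.70 / 0.10 / 0.20, stratified by class and seeded).
#' @param seed integer seed.
#' @param dropout dropout rate applied to input features and, as seeded
#'   pre-softmax edge dropout, to the attention coefficients during
#'   training (attention rows remain probability distributions).
#' @param leaky_slope negative slope of the LeakyReLU inside the attention
#'   score (the usual 0.2) and of the layer nonlinearities.
#' @return an object of class `gat_config`.
#' @export
gat_config <- function(hidden_dim = NULL, n_heads = 4, lr = 5e-3,
                       weight_decay = 5e-4, max_epochs = 300, patience = 30,
                       split = c(train = 0.7, val = 0.1, test = 0.2),
                       seed = 1L, dropout = 0.3, leaky_slope = 0.2) {
  .assert(abs(sum(split) - 1) < 1e-9, "split fractions must sum to 1")
  .assert(patience <= max_epochs, "patience must be <= max_epochs")
  structure(list(hidden_dim = hidden_dim, n_heads = as.integer(n_heads),
                 lr = lr, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 split = split, seed = as.integer(seed), dropout = dropout,
                 leaky_slope = leaky_slope),
            class = "gat_config")
}

# directed message-passing edge arrays: both directions of every undirected
# edge plus a self-loop per node. `ue` maps each directed edge to its
# undirected parent (0 for self-loops), letting an explainer share one mask
# parameter per undirected edge. `dsplit` holds, per destination node, the
# indices of its incoming edges (the softmax groups).
.edge_arrays <- function(edges, n) {
  ne <- nrow(edges)
  src <- c(edges[, 1], edges[, 2], seq_len(n))
  dst <- c(edges[, 2], edges[, 1], seq_len(n))
  ue <- c(seq_len(ne), seq_len(ne), rep(0L, n))
  dsplit <- split(seq_along(dst), dst)
  list(src = src, dst = dst, ue = ue, n = n, n_undirected = ne,
       is_self = ue == 0L, dsplit = dsplit)
}

.seg_max <- function(x, dsplit) {
  vapply(dsplit, function(ix) max(x[ix]), numeric(1))
}

# weighted softmax over incoming edges of each node; w_mult >= 0 rescales
# the numerator (edge masks / edge dropout); groups where everything but the
# self-loop is removed still normalise (self-loop weight is kept positive)
.edge_softmax <- function(s, ea, w_mult = NULL) {
  gmax <- .seg_max(s, ea$dsplit)
  w <- exp(s - gmax[ea$dst])
  if (!is.null(w_mult)) w <- w * w_mult
  denom <- rowsum(w, ea$dst, reorder = TRUE)[, 1]
  unname(w / denom[ea$dst])
}

# backward of the weighted softmax: given d(alpha), return d(score) and the
# shared d(log w_mult) term (both equal alpha * (dalpha - sum_g alpha*dalpha))
.edge_softmax_backward <- function(alpha, dalpha, ea) {
  sg <- rowsum(alpha * dalpha, ea$dst, reorder = TRUE)[, 1]
  alpha * (dalpha - sg[ea$dst])
}

# fold the per-directed-edge d(log mask) back onto the undirected mask
# parameters (self-loops carry no mask)
.accumulate_mask_grad <- function(ds, em, ea) {
  nz <- !ea$is_self
  contrib <- ds[nz] / pmax(em[nz], 1e-12)
  s <- rowsum(contrib, ea$ue[nz], reorder = TRUE)
  acc <- rep(0, ea$n_undirected)
  acc[as.integer(rownames(s))] <- s[, 1]
  acc
}

.gat_init_params <- function(d, hd, H, C) {
  list(Ws1 = .glorot(d, hd * H), Wt1 = .glorot(d, hd * H),
       a1 = matrix(stats::rnorm(hd * H, sd = sqrt(1 / hd)), hd, H),
       b1 = rep(0, hd * H),
       Ws2 = .glorot(hd * H, C), Wt2 = .glorot(hd * H, C),
       a2 = stats::rnorm(C, sd = sqrt(1 / C)),
       b2 = rep(0, C))
}

# two-layer GAT forward pass. Layer 1: multi-head attention, heads
# concatenated, LeakyReLU; layer 2: single-head attention emitting class
# logits. Attention score of edge (j -> i): a' LeakyReLU(Ws x_i + Wt x_j),
# softmax-normalised over N(i) u {i}. em1/em2 are optional per-edge
# multiplicative weights (masks or dropout keep indicators).
.gat_forward <- function(params, X, ea, hd, H, slope = 0.2,
                         em1 = NULL, em2 = NULL, keep_cache = FALSE) {
  n <- nrow(X)
  S1 <- X %*% params$Ws1
  T1 <- X %*% params$Wt1
  O <- matrix(0, n, hd * H)
  cache_h <- if (keep_cache) vector("list", H) else NULL
  for (h in seq_len(H)) {
    cols <- ((h - 1) * hd + 1):(h * hd)
    M <- S1[ea$dst, cols, drop = FALSE] + T1[ea$src, cols, drop = FALSE]
    Zl <- .leaky_relu(M, slope)
    s <- drop(Zl %*% params$a1[, h])
    alpha <- .edge_softmax(s, ea, em1)
    O[, cols] <- rowsum(alpha * T1[ea$src, cols, drop = FALSE], ea$dst,
                        reorder = TRUE)
    if (keep_cache) cache_h[[h]] <- list(M = M, Zl = Zl, alpha = alpha)
  }
  A1 <- sweep(O, 2, params$b1, "+")
  H1 <- .leaky_relu(A1, slope)
  S2 <- H1 %*% params$Ws2
  T2 <- H1 %*% params$Wt2
  M2 <- S2[ea$dst, , drop = FALSE] + T2[ea$src, , drop = FALSE]
  Z2 <- .leaky_relu(M2, slope)
  s2 <- drop(Z2 %*% params$a2)
  alpha2 <- .edge_softmax(s2, ea, em2)
  logits <- rowsum(alpha2 * T2[ea$src, , drop = FALSE], ea$dst, reorder = TRUE)
  logits <- sweep(logits, 2, params$b2, "+")
  probs <- .row_softmax(logits)
  out <- list(logits = logits, probs = probs)
  if (keep_cache) {
    out$cache <- list(X = X, S1 = S1, T1 = T1, cache_h = cache_h, A1 = A1,
                      H1 = H1, S2 = S2, T2 = T2, M2 = M2, Z2 = Z2,
                      alpha2 = alpha2, em1 = em1, em2 = em2, hd = hd, H = H,
                      slope = slope)
  }
  out
}

# backward pass; returns parameter gradients and optionally gradients with
# respect to the input features (dX) and the per-undirected-edge mask
.gat_backward <- function(fw, dlogits, params, ea, want_dX = FALSE,
                          want_dmask = FALSE, want_param_grads = TRUE) {
  cc <- fw$cache
  hd <- cc$hd; H <- cc$H; slope <- cc$slope
  n <- nrow(cc$X)
  g <- list()
  dmask_acc <- if (want_dmask) rep(0, ea$n_undirected) else NULL

  g$b2 <- colSums(dlogits)
  dl_dst <- dlogits[ea$dst, , drop = FALSE]
  T2src <- cc$T2[ea$src, , drop = FALSE]
  dalpha2 <- rowSums(dl_dst * T2src)
  dT2 <- rowsum(cc$alpha2 * dl_dst, ea$src, reorder = TRUE)
  ds2 <- .edge_softmax_backward(cc$alpha2, dalpha2, ea)
  if (want_dmask) {
    dmask_acc <- dmask_acc +
      .accumulate_mask_grad(ds2, cc$em2 %||% rep(1, length(ds2)), ea)
  }
  dZ2 <- outer(ds2, params$a2)
  g$a2 <- colSums(cc$Z2 * ds2)
  dM2 <- dZ2 * .leaky_relu_grad(cc$M2, slope)
  dS2 <- rowsum(dM2, ea$dst, reorder = TRUE)
  dT2 <- dT2 + rowsum(dM2, ea$src, reorder = TRUE)
  if (want_param_grads) {
    g$Ws2 <- crossprod(cc$H1, dS2)
    g$Wt2 <- crossprod(cc$H1, dT2)
  }
  dH1 <- tcrossprod(dS2, params$Ws2) + tcrossprod(dT2, params$Wt2)

  dA1 <- dH1 * .leaky_relu_grad(cc$A1, slope)
  g$b1 <- colSums(dA1)
  dS1 <- matrix(0, n, hd * H)
  dT1 <- matrix(0, n, hd * H)
  g$a1 <- matrix(0, hd, H)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * hd + 1):(h * hd)
    ch <- cc$cache_h[[h]]
    dO <- dA1[, cols, drop = FALSE]
    dO_dst <- dO[ea$dst, , drop = FALSE]
    T1src <- cc$T1[ea$src, cols, drop = FALSE]
    dalpha <- rowSums(dO_dst * T1src)
    dT1[, cols] <- dT1[, cols] + rowsum(ch$alpha * dO_dst, ea$src, reorder = TRUE)
    ds <- .edge_softmax_backward(ch$alpha, dalpha, ea)
    if (want_dmask) {
      dmask_acc <- dmask_acc +
        .accumulate_mask_grad(ds, cc$em1 %||% rep(1, length(ds)), ea)
    }
    dZl <- outer(ds, params$a1[, h])
    g$a1[, h] <- colSums(ch$Zl * ds)
    dM <- dZl * .leaky_relu_grad(ch$M, slope)
    dS1[, cols] <- dS1[, cols] + rowsum(dM, ea$dst, reorder = TRUE)
    dT1[, cols] <- dT1[, cols] + rowsum(dM, ea$src, reorder = TRUE)
  }
  if (want_param_grads) {
    g$Ws1 <- crossprod(cc$X, dS1)
    g$Wt1 <- crossprod(cc$X, dT1)
  }
  out <- list(grads = g)
  if (want_dX) out$dX <- tcrossprod(dS1, params$Ws1) + tcrossprod(dT1, params$Wt1)
  if (want_dmask) out$dmask <- dmask_acc
  out
}

# ---- GCN baseline -----------------------------------------------------------

.gcn_adjacency <- function(edges, n) {
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2], seq_len(n)),
                            j = c(edges[, 2], edges[, 1], seq_len(n)),
                            x = 1, dims = c(n, n))
  dinv <- 1 / sqrt(Matrix::rowSums(A))
  Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
}

.gcn_init_params <- function(d, hd, C) {
  list(W1 = .glorot(d, hd), b1 = rep(0, hd),
       W2 = .glorot(hd, C), b2 = rep(0, C))
}

.gcn_forward <- function(params, X, Ahat, slope = 0.2, keep_cache = FALSE) {
  AX <- as.matrix(Ahat %*% X)
  A1 <- sweep(AX %*% params$W1, 2, params$b1, "+")
  H1 <- .leaky_relu(A1, slope)
  AH <- as.matrix(Ahat %*% H1)
  logits <- sweep(AH %*% params$W2, 2, params$b2, "+")
  out <- list(logits = logits, probs = .row_softmax(logits))
  if (keep_cache) out$cache <- list(AX = AX, A1 = A1, H1 = H1, AH = AH, slope = slope)
  out
}

.gcn_backward <- function(fw, dlogits, params, Ahat, X) {
  cc <- fw$cache
  g <- list()
  g$b2 <- colSums(dlogits)
  g$W2 <- crossprod(cc$AH, dlogits)
  dAH <- tcrossprod(dlogits, params$W2)
  dH1 <- as.matrix(Ahat %*% dAH)        # Ahat is symmetric
  dA1 <- dH1 * .leaky_relu_grad(cc$A1, cc$slope)
  g$b1 <- colSums(dA1)
  g$W1 <- crossprod(cc$AX, dA1)
  list(grads = g)
}

# ---- training ---------------------------------------------------------------

.cross_entropy <- function(probs, y_idx, rows) {
  p <- probs[cbind(rows, y_idx[rows])]
  -mean(log(pmax(p, 1e-12)))
}

#' Train a GAT or GCN node classifier on the cell graph
#'
#' Splits the cells into stratified, seeded train/validation/test sets
#' (70/10/20 by default), minimises the cross-entropy of the training nodes
#' with Adam, early-stops on validation loss (patience 30, at most 300
#' epochs, best weights restored), and evaluates accuracy and macro-averaged
#' precision/recall/F1 on the test nodes only.
#'
#' The GAT uses two attention layers (multi-head concatenated, then a
#' single-head layer emitting the class logits); the GCN baseline replaces
#' attention with symmetric-normalised adjacency convolutions.
#'
#' @param g a [knn_graph()] `cell_graph`.
#' @param m a labelled, processed [count_matrix()] row-aligned with `g` (its
#'   matrix provides the node feature vectors).
#' @param cfg a [gat_config()].
#' @param arch `"GAT"` or `"GCN"`.
#' @return list `(model, report)`: a `trained_classifier` and a
#'   `classification_report` (accuracy, macro precision/recall/F1, per-class
#'   values, confusion matrix, split indices).
#' @export
train_classifier <- function(g, m, cfg = gat_config(), arch = c("GAT", "GCN")) {
  arch <- match.arg(arch)
  stopifnot(inherits(g, "cell_graph"))
  X <- .as_feature_matrix(m)
  labels <- if (inherits(m, "count_matrix")) m$labels else NULL
  .assert(!is.null(labels), "train_classifier requires labels on the count matrix")
  .assert(nrow(X) == g$n_nodes, "node count mismatch between graph and matrix")
  .assert(nlevels(labels) >= 2, "need >= 2 classes")
  classes <- levels(labels)
  y <- as.integer(labels)
  C <- length(classes)
  n <- nrow(X); d <- ncol(X)
  hd <- cfg$hidden_dim %||% .ceil_root(d, 3)

  split <- .stratified_split(labels, cfg$split, cfg$seed)
  tr <- split[[1]]; va <- split[[2]]; te <- split[[3]]
  missing_cl <- setdiff(seq_len(C), unique(y[tr]))
  .assert(length(missing_cl) == 0,
          "class '%s' absent from the training split", classes[missing_cl[1]])

  set.seed(cfg$seed)
  ea <- if (arch == "GAT") .edge_arrays(g$edges, n) else NULL
  Ahat <- if (arch == "GCN") .gcn_adjacency(g$edges, n) else NULL
  params <- if (arch == "GAT") .gat_init_params(d, hd, cfg$n_heads, C)
            else .gcn_init_params(d, hd, C)
  state <- .adam_init(params)

  onehot <- matrix(0, n, C); onehot[cbind(seq_len(n), y)] <- 1
  history <- data.frame(epoch = integer(), train_loss = numeric(), val_loss = numeric())
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  ne <- if (arch == "GAT") length(ea$src) else 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    Xin <- X
    if (cfg$dropout > 0) {
      mask <- .dropout_mask(dim(X), cfg$dropout)
      Xin <- X * mask
    }
    if (arch == "GAT") {
      em <- NULL
      if (cfg$dropout > 0) {
        keep1 <- ifelse(ea$is_self, 1, stats::rbinom(ne, 1L, 1 - cfg$dropout))
        keep2 <- ifelse(ea$is_self, 1, stats::rbinom(ne, 1L, 1 - cfg$dropout))
        fw <- .gat_forward(params, Xin, ea, hd, cfg$n_heads, cfg$leaky_slope,
                           em1 = keep1, em2 = keep2, keep_cache = TRUE)
      } else {
        fw <- .gat_forward(params, Xin, ea, hd, cfg$n_heads, cfg$leaky_slope,
                           keep_cache = TRUE)
      }
    } else {
      fw <- .gcn_forward(params, Xin, Ahat, cfg$leaky_slope, keep_cache = TRUE)
    }
    train_loss <- .cross_entropy(fw$probs, y, tr)
    .assert(is.finite(train_loss), "non-finite training loss at epoch %d", epoch)
    dlogits <- matrix(0, n, C)
    dlogits[tr, ] <- (fw$probs[tr, , drop = FALSE] - onehot[tr, , drop = FALSE]) / length(tr)
    bw <- if (arch == "GAT") .gat_backward(fw, dlogits, params, ea)
          else .gcn_backward(fw, dlogits, params, Ahat, Xin)
    upd <- .adam_step(params, bw$grads, state, cfg$lr, cfg$weight_decay)
    params <- upd$params; state <- upd$state

    ev <- if (arch == "GAT") .gat_forward(params, X, ea, hd, cfg$n_heads, cfg$leaky_slope)
          else .gcn_forward(params, X, Ahat, cfg$leaky_slope)
    val_loss <- .cross_entropy(ev$probs, y, va)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                         val_loss = val_loss))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_params <- params; best_epoch <- epoch
    }
    if (epoch - best_epoch >= cfg$patience) break
  }
  params <- best_params
  fw <- if (arch == "GAT") .gat_forward(params, X, ea, hd, cfg$n_heads, cfg$leaky_slope)
        else .gcn_forward(params, X, Ahat, cfg$leaky_slope)
  pred <- max.col(fw$probs, ties.method = "first")
  report <- classification_report(y[te], pred[te], classes)
  report$split <- list(train = tr, val = va, test = te)
  model <- structure(list(arch = arch, params = params, classes = classes,
                          cfg = cfg, hidden_dim = hd, n_heads = cfg$n_heads,
                          input_dim = d, graph = g, history = history,
                          best_epoch = best_epoch),
                     class = "trained_classifier")
  list(model = model, report = report)
}

#' Per-node class probabilities from a trained classifier
#'
#' @param model a `trained_classifier`.
#' @param g a `cell_graph` (defaults to the training graph).
#' @param X node feature matrix row-aligned with `g`.
#' @return an `n x C` matrix of probabilities (rows sum to 1).
#' @export
predict_cells <- function(model, X, g = NULL) {
  g <- g %||% model$graph
  X <- .as_feature_matrix(X)
  .assert(nrow(X) == g$n_nodes, "node count mismatch")
  .assert(ncol(X) == model$input_dim, "feature dimension mismatch")
  fw <- if (model$arch == "GAT") {
    ea <- .edge_arrays(g$edges, g$n_nodes)
    .gat_forward(model$params, X, ea, model$hidden_dim, model$n_heads,
                 model$cfg$leaky_slope)
  } else {
    .gcn_forward(model$params, X, .gcn_adjacency(g$edges, g$n_nodes),
                 model$cfg$leaky_slope)
  }
  probs <- fw$probs
  colnames(probs) <- model$classes
  probs
}

#' Classification metrics on a labelled test set
#'
#' Accuracy, per-class precision/recall/F1 (0 when undefined) and their
#' macro averages, plus the confusion matrix (rows: true classes).
#'
#' @param y_true,y_pred integer class indices (1-based) or factors.
#' @param classes class name vector.
#' @return an object of class `classification_report`.
#' @export
classification_report <- function(y_true, y_pred, classes) {
  C <- length(classes)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  conf <- matrix(0L, C, C, dimnames = list(true = classes, pred = classes))
  for (i in seq_along(y_true)) conf[y_true[i], y_pred[i]] <- conf[y_true[i], y_pred[i]] + 1L
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(accuracy = mean(y_true == y_pred),
                 precision = mean(prec), recall = mean(rec), f1 = mean(f1),
                 per_class = data.frame(class = classes, precision = prec,
                                        recall = rec, f1 = f1,
                                        support = rowSums(conf)),
                 confusion = conf),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> acc %.3f | macro P %.3f R %.3f F1 %.3f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Write per-node predictions and split assignments as TSV
#'
#' One row per cell: predicted label, its probability, and (when the report
#' carries the split) the partition the node fell into.
#'
#' @param model a `trained_classifier`.
#' @param X node feature matrix the model was trained on.
#' @param path output TSV path.
#' @param report optional `classification_report` providing split indices.
#' @param cell_ids optional identifiers (defaults to row names / indices).
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(model, X, path, report = NULL,
                                  cell_ids = NULL) {
  probs <- predict_cells(model, X)
  pred <- max.col(probs, ties.method = "first")
  df <- data.frame(
    cell_id = cell_ids %||% rownames(.as_feature_matrix(X)) %||%
      seq_len(nrow(probs)),
    predicted_label = model$classes[pred],
    probability = probs[cbind(seq_len(nrow(probs)), pred)])
  if (!is.null(report) && !is.null(report$split)) {
    part <- rep(NA_character_, nrow(probs))
    for (nm in names(report$split)) part[report$split[[nm]]] <- nm
    df$split <- part
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a classification report as JSON
#'
#' @param report a `classification_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_classification_report <- function(report, path) {
  out <- list(accuracy = report$accuracy, precision = report$precision,
              recall = report$recall, f1 = report$f1,
              per_class = report$per_class,
              confusion = as.data.frame.matrix(report$confusion))
  if (!is.null(report$split))
    out$split_sizes <- lapply(report$split, length)
  .write_json(out, path)
  invisible(path)
}
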