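#' Encoder layer sizes from the input dimension
#'
#' The architecture scales with data-set complexity: one hidden layer of
#' dimension `ceiling(sqrt(d))` and a latent layer of dimension
#' `ceiling(d^(1/3))`, where `d` is the number of features.
#'
#' @param d input dimension (number of features), `>= 1`.
#' @param activation nonlinearity name (informational; the implementation
#'   uses LeakyReLU with slope 0.2 and a linear output layer).
#' @return an object of class `encoder_spec` with `input_dim`, `hidden_dim`,
#'   `latent_dim`, `activation`.
#' @export
layer_sizes <- function(d, activation = "leaky_relu") {
  .assert(d >= 1, "d must be >= 1")
  structure(list(input_dim = as.integer(d),
                 hidden_dim = .ceil_root(d, 2),
                 latent_dim = .ceil_root(d, 3),
                 activation = activation),
            class = "encoder_spec")
}

#' Autoencoder training configuration
#'
#' @param lambda_geo weight of the geometric regularisation term (ignored by
#'   the plain AE/VAE); the geometric sum is averaged over cells so the
#'   default is data-set-size independent.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty applied to all weights.
#' @param max_epochs,patience early-stopping schedule: training stops when
#'   the validation loss has not improved for `patience` epochs, or at
#'   `max_epochs`; the best-validation weights are restored.
#' @param val_frac fraction of cells held out for validation (stratified by
#'   label when labels exist).
#' @param seed integer seed controlling initialisation and the split.
#' @param input_dropout probability of dropping input entries during
#'   training (regularisation inside the network; 0 disables).
#' @return an object of class `train_config`.
#' @export
train_config <- function(lambda_geo = 0.1, lr = 3e-3, weight_decay = 1e-3,
                         max_epochs = 300, patience = 30, val_frac = 0.15,
                         seed = 1L, input_dropout = 0) {
  .assert(lambda_geo >= 0, "lambda_geo must be >= 0")
  .assert(val_frac > 0 && val_frac < 1, "val_frac must be in (0,1)")
  .assert(patience <= max_epochs, "patience must be <= max_epochs")
  .assert(input_dropout >= 0 && input_dropout < 1, "input_dropout must be in [0,1)")
  structure(list(lambda_geo = lambda_geo, lr = lr, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 val_frac = val_frac, seed = as.integer(seed),
                 input_dropout = input_dropout),
            class = "train_config")
}

# ---- forward / backward for the dense autoencoder ---------------------------

.ae_init_params <- function(d, h, l, vae = FALSE) {
  p <- list(W1 = .glorot(d, h), b1 = rep(0, h),
            W2 = .glorot(h, l), b2 = rep(0, l),
            W3 = .glorot(l, h), b3 = rep(0, h),
            W4 = .glorot(h, d), b4 = rep(0, d))
  if (vae) { p$W2v <- .glorot(h, l); p$b2v <- rep(0, l) }
  p
}

.ae_encode <- function(params, X, slope = 0.2) {
  A1 <- sweep(X %*% params$W1, 2, params$b1, "+")
  H1 <- .leaky_relu(A1, slope)
  Z <- sweep(H1 %*% params$W2, 2, params$b2, "+")
  list(A1 = A1, H1 = H1, Z = Z)
}

.ae_decode <- function(params, Z, slope = 0.2) {
  A2 <- sweep(Z %*% params$W3, 2, params$b3, "+")
  H2 <- .leaky_relu(A2, slope)
  Xhat <- sweep(H2 %*% params$W4, 2, params$b4, "+")
  list(A2 = A2, H2 = H2, Xhat = Xhat)
}

# one full-batch gradient step; returns loss components and gradients.
# dZ_extra injects the geometric (or KL) gradient at the latent layer.
.ae_grads <- function(params, X, Xi, lambda, slope = 0.2, vae = FALSE,
                      beta = 0, eps_noise = NULL) {
  n <- nrow(X); d <- ncol(X)
  enc <- .ae_encode(params, X, slope)
  kl <- 0; mu <- enc$Z; lv <- NULL
  if (vae) {
    lv <- sweep(enc$H1 %*% params$W2v, 2, params$b2v, "+")
    lv <- pmin(pmax(lv, -10), 10)
    Zs <- mu + exp(0.5 * lv) * eps_noise
    kl <- mean(rowSums(0.5 * (exp(lv) + mu^2 - 1 - lv)))
  } else {
    Zs <- enc$Z
  }
  dec <- .ae_decode(params, Zs, slope)
  recon <- mean((X - dec$Xhat)^2)
  geo <- if (!is.null(Xi)) mean(rowSums((Zs - Xi)^2)) else 0
  loss <- recon + lambda * geo + beta * kl

  dXhat <- 2 * (dec$Xhat - X) / (n * d)
  gW4 <- crossprod(dec$H2, dXhat); gb4 <- colSums(dXhat)
  dH2 <- tcrossprod(dXhat, params$W4) * .leaky_relu_grad(dec$A2, slope)
  gW3 <- crossprod(Zs, dH2); gb3 <- colSums(dH2)
  dZs <- tcrossprod(dH2, params$W3)
  if (!is.null(Xi) && lambda > 0) dZs <- dZs + lambda * 2 * (Zs - Xi) / n

  grads <- list(W4 = gW4, b4 = gb4, W3 = gW3, b3 = gb3)
  if (vae) {
    dmu <- dZs + beta * mu / n
    dlv <- dZs * (0.5 * exp(0.5 * lv) * eps_noise) + beta * 0.5 * (exp(lv) - 1) / n
    grads$W2 <- crossprod(enc$H1, dmu); grads$b2 <- colSums(dmu)
    grads$W2v <- crossprod(enc$H1, dlv); grads$b2v <- colSums(dlv)
    dH1 <- tcrossprod(dmu, params$W2) + tcrossprod(dlv, params$W2v)
  } else {
    grads$W2 <- crossprod(enc$H1, dZs); grads$b2 <- colSums(dZs)
    dH1 <- tcrossprod(dZs, params$W2)
  }
  dA1 <- dH1 * .leaky_relu_grad(enc$A1, slope)
  grads$W1 <- crossprod(X, dA1); grads$b1 <- colSums(dA1)

  list(loss = loss, recon = recon, geo = geo, kl = kl, grads = grads)
}

.ae_eval_loss <- function(params, X, Xi, lambda, slope = 0.2, vae = FALSE, beta = 0) {
  enc <- .ae_encode(params, X, slope)
  mu <- enc$Z; kl <- 0
  if (vae) {
    lv <- sweep(enc$H1 %*% params$W2v, 2, params$b2v, "+")
    lv <- pmin(pmax(lv, -10), 10)
    kl <- mean(rowSums(0.5 * (exp(lv) + mu^2 - 1 - lv)))
  }
  dec <- .ae_decode(params, mu, slope)
  recon <- mean((X - dec$Xhat)^2)
  geo <- if (!is.null(Xi)) mean(rowSums((mu - Xi)^2)) else 0
  list(loss = recon + lambda * geo + beta * kl, recon = recon, geo = geo, kl = kl)
}

.train_ae_engine <- function(X, labels, Xi, kind, cfg) {
  n <- nrow(X); d <- ncol(X)
  spec <- layer_sizes(d)
  vae <- kind == "VAE"
  lambda <- if (kind == "GRAE") cfg$lambda_geo else 0
  if (kind != "GRAE") Xi <- NULL
  if (!is.null(Xi)) {
    .assert(nrow(Xi) == n, "geometry embedding rows (%d) != cells (%d)", nrow(Xi), n)
    .assert(ncol(Xi) == spec$latent_dim,
            "geometry embedding dimension (%d) != latent dimension (%d)",
            ncol(Xi), spec$latent_dim)
    # centre and globally rescale the geometric target so lambda is
    # scale-free (mean squared row norm 1); a single scalar preserves the
    # embedding's anisotropy, which carries its neighbourhood structure
    Xi <- sweep(Xi, 2, colMeans(Xi))
    rms <- sqrt(mean(rowSums(Xi^2)))
    if (rms > 0) Xi <- Xi / rms
  }

  strat <- labels %||% rep(1L, n)
  split <- .stratified_split(strat, c(1 - cfg$val_frac, cfg$val_frac), cfg$seed)
  tr <- split[[1]]; va <- split[[2]]
  Xtr <- X[tr, , drop = FALSE]; Xva <- X[va, , drop = FALSE]
  Xitr <- if (!is.null(Xi)) Xi[tr, , drop = FALSE] else NULL
  Xiva <- if (!is.null(Xi)) Xi[va, , drop = FALSE] else NULL

  set.seed(cfg$seed)
  params <- .ae_init_params(d, spec$hidden_dim, spec$latent_dim, vae)
  state <- .adam_init(params)
  half <- max(1, cfg$max_epochs / 2)

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), recon = numeric(),
                        geo = numeric(), kl = numeric())
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    beta <- if (vae) min(1, (epoch - 1) / half) else 0
    Xin <- Xtr
    if (cfg$input_dropout > 0) {
      mask <- .dropout_mask(dim(Xtr), cfg$input_dropout)
      Xin <- Xtr * mask
    }
    eps_noise <- if (vae) matrix(stats::rnorm(nrow(Xtr) * spec$latent_dim),
                                 nrow(Xtr), spec$latent_dim) else NULL
    step <- .ae_grads(params, Xin, Xitr, lambda, vae = vae, beta = beta,
                      eps_noise = eps_noise)
    .assert(is.finite(step$loss), "non-finite training loss at epoch %d", epoch)
    upd <- .adam_step(params, step$grads, state, cfg$lr, cfg$weight_decay)
    params <- upd$params; state <- upd$state
    val <- .ae_eval_loss(params, Xva, Xiva, lambda, vae = vae, beta = beta)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = step$loss, val_loss = val$loss,
      recon = step$recon, geo = step$geo, kl = step$kl))
    if (val$loss < best_val - 1e-12) {
      best_val <- val$loss; best_params <- params; best_epoch <- epoch
    }
    if (epoch - best_epoch >= cfg$patience) break
  }
  params <- best_params
  latent <- .ae_encode(params, X)$Z
  rownames(latent) <- rownames(X)
  structure(list(spec = spec, kind = kind, cfg = cfg, params = params,
                 latent = latent, history = history, best_epoch = best_epoch,
                 split = list(train = tr, val = va)),
            class = "trained_autoencoder")
}

#' Train the geometry-regularised autoencoder
#'
#' Minimises `L = MSE(X, f^-1(f(X))) + lambda * mean_i ||xi_i - f(x_i)||^2`
#' with Adam: a reconstruction term plus a geometric term pulling the latent
#' code of each cell towards its manifold-embedding coordinate. The
#' geometric sum is averaged over cells so `lambda`'s scale does not depend
#' on data-set size. Training uses an 85/15 seeded (label-stratified)
#' train/validation split and early stopping; the returned latent matrix
#' covers all cells.
#'
#' @param m a processed [count_matrix()] (or numeric matrix).
#' @param xi a `geometry_embedding` from [phate_embed()], row-aligned with
#'   `m` and with `p` equal to the latent dimension.
#' @param cfg a [train_config()].
#' @return an object of class `trained_autoencoder` (kind `"GRAE"`) with
#'   fields `spec`, `latent`, `history` (per-epoch train/val loss and the
#'   reconstruction/geometric decomposition), `params`, `best_epoch`.
#' @export
train_grae <- function(m, xi, cfg = train_config()) {
  X <- .as_feature_matrix(m)
  Xi <- if (inherits(xi, "geometry_embedding")) xi$coords else as.matrix(xi)
  labels <- if (inherits(m, "count_matrix")) m$labels else NULL
  .train_ae_engine(X, labels, Xi, "GRAE", cfg)
}

#' Train the baseline autoencoder / variational autoencoder
#'
#' `train_ae()` optimises the reconstruction MSE alone (the `lambda = 0`
#' limit of the geometry-regularised objective, sharing its code path so
#' per-epoch losses coincide for equal seeds). `train_vae()` adds a
#' `beta(t) * KL(q || N(0, I))` term with `beta` linearly annealed from 0 to
#' 1 over the first half of `max_epochs`.
#'
#' @inheritParams train_grae
#' @return a `trained_autoencoder` of kind `"AE"` / `"VAE"`.
#' @export
train_ae <- function(m, cfg = train_config()) {
  X <- .as_feature_matrix(m)
  labels <- if (inherits(m, "count_matrix")) m$labels else NULL
  .train_ae_engine(X, labels, NULL, "AE", cfg)
}

#' @rdname train_ae
#' @export
train_vae <- function(m, cfg = train_config()) {
  X <- .as_feature_matrix(m)
  labels <- if (inherits(m, "count_matrix")) m$labels else NULL
  .train_ae_engine(X, labels, NULL, "VAE", cfg)
}

#' PCA baseline embedding
#'
#' Linear baseline: the latent space is the top principal-component scores
#' and decoding is the inverse transform (rotation transpose plus centring).
#'
#' @inheritParams train_grae
#' @param latent_dim latent dimension; default `ceiling(F^(1/3))`. Must be
#'   below `min(n_cells, n_features)`.
#' @return a `trained_autoencoder` of kind `"PCA"`.
#' @export
pca_embed <- function(m, latent_dim = NULL) {
  X <- .as_feature_matrix(m)
  d <- ncol(X)
  latent_dim <- latent_dim %||% .ceil_root(d, 3)
  .assert(latent_dim < min(nrow(X), d),
          "latent_dim must be < min(n_cells, n_features)")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = latent_dim)
  latent <- pc$x
  rownames(latent) <- rownames(X)
  spec <- layer_sizes(d); spec$latent_dim <- as.integer(latent_dim)
  structure(list(spec = spec, kind = "PCA",
                 params = list(rotation = pc$rotation, center = pc$center),
                 latent = latent,
                 history = data.frame(epoch = integer(), train_loss = numeric(),
                                      val_loss = numeric())),
            class = "trained_autoencoder")
}

#' @export
print.trained_autoencoder <- function(x, ...) {
  cat(sprintf("<trained_autoencoder> kind %s, %d -> %d -> %d, %d epochs\n",
              x$kind, x$spec$input_dim, x$spec$hidden_dim, x$spec$latent_dim,
              nrow(x$history)))
  invisible(x)
}

#' Encode cells into the latent space
#' @param model a `trained_autoencoder`.
#' @param m a [count_matrix()] or numeric matrix with matching features.
#' @return an `n x latent_dim` matrix.
#' @export
encode_cells <- function(model, m) {
  X <- .as_feature_matrix(m)
  .assert(ncol(X) == model$spec$input_dim, "feature dimension mismatch")
  if (model$kind == "PCA") {
    return(sweep(X, 2, model$params$center) %*% model$params$rotation)
  }
  .ae_encode(model$params, X)$Z
}

#' Reconstruct the input through the autoencoder
#'
#' Computes `f^-1(f(X))`: encode then decode.
#'
#' @inheritParams encode_cells
#' @return a matrix of the same shape as the input.
#' @export
reconstruct <- function(model, m) {
  X <- .as_feature_matrix(m)
  .assert(ncol(X) == model$spec$input_dim,
          "input has %d features, model expects %d", ncol(X), model$spec$input_dim)
  Z <- encode_cells(model, X)
  out <- if (model$kind == "PCA") {
    sweep(Z %*% t(model$params$rotation), 2, model$params$center, "+")
  } else {
    .ae_decode(model$params, Z)$Xhat
  }
  .assert(all(is.finite(out)), "non-finite reconstruction")
  dimnames(out) <- dimnames(X)
  out
}

#' Corrupt a matrix by feature dropout
#'
#' Uniformly samples `ceiling(fraction * F)` feature columns (seeded) and
#' sets all their entries to zero — the corruption used by the denoising
#' benchmark, where the features to drop vary with the seed at each level.
#'
#' @param m a [count_matrix()] or numeric matrix.
#' @param fraction fraction of features to zero, in \[0, 1\].
#' @param seed integer seed.
#' @return a list `(matrix, dropped)`: the corrupted copy (same class as the
#'   input) and the dropped column indices.
#' @export
corrupt_dropout <- function(m, fraction, seed = 1L) {
  .assert(fraction >= 0 && fraction <= 1, "fraction must be in [0,1]")
  X <- .as_feature_matrix(m)
  n_drop <- ceiling(fraction * ncol(X))
  dropped <- if (n_drop > 0) {
    set.seed(seed)
    sort(sample.int(ncol(X), n_drop))
  } else integer(0)
  X[, dropped] <- 0
  out <- if (inherits(m, "count_matrix")) { m$counts <- X; m } else X
  list(matrix = out, dropped = dropped)
}

#' Random-search hyper-parameter optimisation for the autoencoders
#'
#' Optional small random search (default 25 trials) over learning rate
#' (log-uniform on \[1e-4, 1e-2\]), weight decay (uniform on \[0, 1e-3\]) and,
#' for the GRAE, `lambda_geo` (log-uniform on \[1e-2, 10\]); each trial is
#' scored by final validation loss. Defaults of [train_config()] are fixed,
#' so routine use never requires this.
#'
#' @inheritParams train_grae
#' @param kind which model to tune: `"GRAE"`, `"AE"` or `"VAE"`.
#' @param n_trials number of random configurations.
#' @param base_cfg configuration template supplying epochs/patience/seed.
#' @return list with `best_cfg` ([train_config()]), `trials` data.frame.
#' @export
random_search_ae <- function(m, xi = NULL, kind = c("GRAE", "AE", "VAE"),
                             n_trials = 25, base_cfg = train_config()) {
  kind <- match.arg(kind)
  set.seed(base_cfg$seed)
  trials <- data.frame(lr = 10^stats::runif(n_trials, -4, -2),
                       weight_decay = stats::runif(n_trials, 0, 1e-3),
                       lambda_geo = 10^stats::runif(n_trials, -2, 1))
  trials$val_loss <- NA_real_
  for (i in seq_len(n_trials)) {
    cfg <- train_config(lambda_geo = trials$lambda_geo[i], lr = trials$lr[i],
                        weight_decay = trials$weight_decay[i],
                        max_epochs = base_cfg$max_epochs,
                        patience = base_cfg$patience,
                        val_frac = base_cfg$val_frac, seed = base_cfg$seed,
                        input_dropout = base_cfg$input_dropout)
    fit <- switch(kind,
                  GRAE = train_grae(m, xi, cfg),
                  AE = train_ae(m, cfg),
                  VAE = train_vae(m, cfg))
    trials$val_loss[i] <- min(fit$history$val_loss)
  }
  best <- which.min(trials$val_loss)
  best_cfg <- train_config(lambda_geo = trials$lambda_geo[best],
                           lr = trials$lr[best],
                           weight_decay = trials$weight_decay[best],
                           max_epochs = base_cfg$max_epochs,
                           patience = base_cfg$patience,
                           val_frac = base_cfg$val_frac, seed = base_cfg$seed,
                           input_dropout = base_cfg$input_dropout)
  list(best_cfg = best_cfg, trials = trials)
}

#' Export a latent matrix as TSV with a JSON manifest
#'
#' @param model a `trained_autoencoder`.
#' @param path output TSV path; manifest written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_latent_tsv <- function(model, path) {
  df <- data.frame(cell_id = rownames(model$latent) %||% seq_len(nrow(model$latent)),
                   model$latent)
  names(df)[-1] <- sprintf("latent_%d", seq_len(ncol(model$latent)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(kind = model$kind, spec = unclass(model$spec))
  if (!is.null(model$cfg)) manifest$config <- unclass(model$cfg)
  .write_json(manifest, paste0(path, ".json"))
  invisible(path)
}
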