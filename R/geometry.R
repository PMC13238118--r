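#' Diffusion-potential manifold embedding (geometric target)
#'
#' Computes the PHATE-style embedding used as the geometric regularisation
#' target of the autoencoder. Pipeline: pairwise Euclidean distances ->
#' adaptive-bandwidth alpha-decay kernel
#' `K_ij = (exp(-(d_ij/sigma_i)^alpha) + exp(-(d_ij/sigma_j)^alpha)) / 2`
#' with `sigma_i` the distance to the `knn_bandwidth_k`-th neighbour ->
#' row-normalised diffusion operator `P` -> diffusion to power `t` (chosen
#' automatically at the knee of the von Neumann entropy over t in \[1, 100\])
#' -> potential `U = -log(P^t + eps)` -> metric MDS on the pairwise potential
#' distances, initialised from classical MDS and refined by stress
#' majorisation (stress is non-increasing over iterations).
#'
#' Duplicate cells that collapse a bandwidth to zero have `sigma_i` floored
#' at the smallest positive pairwise distance; a fully degenerate input (all
#' cells identical) embeds every cell at the origin.
#'
#' @param m a processed [count_matrix()] or a plain numeric matrix.
#' @param p embedding dimension; default the autoencoder latent dimension
#'   `ceiling(F^(1/3))` so target and latent coordinates are commensurate.
#' @param knn_bandwidth_k neighbour index for the adaptive bandwidth.
#' @param alpha_decay exponent of the alpha-decay kernel.
#' @param diffusion_time_t positive integer, or `"auto"` (entropy knee).
#' @param mds_max_iter maximum stress-majorisation iterations.
#' @param mds_tol relative stress-decrease tolerance for early exit.
#' @param seed integer seed (controls degenerate-initialisation jitter).
#' @return an object of class `geometry_embedding`: `coords` (n x p),
#'   `p`, `t_used`, `stress` (per-iteration stress trace), `params`.
#' @export
phate_embed <- function(m, p = NULL, knn_bandwidth_k = 5, alpha_decay = 40,
                        diffusion_time_t = "auto", mds_max_iter = 300,
                        mds_tol = 1e-5, seed = 1L) {
  X <- .as_feature_matrix(m)
  n <- nrow(X)
  p <- p %||% .ceil_root(ncol(X), 3)
  .assert(n > p, "n_cells must exceed the embedding dimension")
  .assert(n > knn_bandwidth_k, "need n_cells >= knn_bandwidth_k + 1")
  .assert(all(is.finite(X)), "input contains non-finite values")

  D <- .pairwise_dist(X)
  if (max(D) == 0) {
    coords <- matrix(0, n, p)
    rownames(coords) <- rownames(X)
    return(structure(list(coords = coords, p = p, t_used = 1L, stress = 0,
                          vne = NULL,
                          params = list(knn_bandwidth_k = knn_bandwidth_k,
                                        alpha_decay = alpha_decay,
                                        diffusion_time_t = diffusion_time_t,
                                        mds_max_iter = mds_max_iter, seed = seed)),
                     class = "geometry_embedding"))
  }

  pot <- .potential_distances(D, knn_bandwidth_k, alpha_decay, diffusion_time_t)
  t_used <- pot$t_used
  Dpot <- pot$Dpot

  mds <- .metric_mds(Dpot, p, max_iter = mds_max_iter, tol = mds_tol, seed = seed)
  coords <- mds$coords
  rownames(coords) <- rownames(X)
  structure(list(coords = coords, p = p, t_used = t_used, stress = mds$stress,
                 params = list(knn_bandwidth_k = knn_bandwidth_k,
                               alpha_decay = alpha_decay,
                               diffusion_time_t = diffusion_time_t,
                               mds_max_iter = mds_max_iter, seed = seed)),
            class = "geometry_embedding")
}

#' @export
print.geometry_embedding <- function(x, ...) {
  cat(sprintf("<geometry_embedding> %d cells -> %d dims, t = %d, final stress %.4g\n",
              nrow(x$coords), x$p, x$t_used, utils::tail(x$stress, 1)))
  invisible(x)
}

# diffusion-potential pairwise distances from a distance matrix; the core of
# the embedding, shared with the permutation-equivariance checks.
# P^t is computed by binary exponentiation (dense BLAS products); the
# spectrum of the symmetric conjugate is only needed when t is "auto".
.potential_distances <- function(D, k, alpha, diffusion_time_t = "auto") {
  n <- nrow(D)
  op <- .diffusion_kernel(D, k, alpha)
  # P = S A S^{-1} with S = diag(1/sqrt(rowsums)) and A symmetric, so one
  # symmetric eigendecomposition yields the spectrum (for the entropy-based
  # choice of t) and P^t at two BLAS products, independent of t
  Asym <- op$K / tcrossprod(op$sqrt_rs)
  eig <- eigen(Asym, symmetric = TRUE)
  lam <- pmin(pmax(eig$values, -1), 1)
  t_used <- if (identical(diffusion_time_t, "auto")) {
    .vne_knee(lam, t_max = 100L)
  } else {
    .assert(is.numeric(diffusion_time_t) && diffusion_time_t >= 1,
            "diffusion_time_t must be a positive integer or 'auto'")
    as.integer(diffusion_time_t)
  }
  lam_t <- sign(lam) * abs(lam)^t_used
  V <- eig$vectors / op$sqrt_rs
  W <- eig$vectors * op$sqrt_rs
  Pt <- tcrossprod(V * rep(lam_t, each = n), W)
  Pt[Pt < 0] <- 0
  U <- -log(Pt + .Machine$double.eps)
  list(Dpot = .pairwise_dist(U), t_used = t_used)
}

# adaptive-bandwidth alpha-decay kernel
.diffusion_kernel <- function(D, k, alpha) {
  # sigma_i = distance to the k-th neighbour (self excluded)
  sorted <- apply(D, 1, function(r) sort(r, partial = k + 1L)[k + 1L])
  pos <- D[D > 0]
  floor_sigma <- if (length(pos)) min(pos) else 1
  sigma <- pmax(sorted, floor_sigma)
  A1 <- exp(-(D / sigma)^alpha)          # rows scaled by sigma_i
  K <- (A1 + t(A1)) / 2
  rs <- rowSums(K)
  list(K = K, rowsums = rs, sqrt_rs = sqrt(rs))
}

# von Neumann entropy of the diffusion spectrum as a function of t; the knee
# (max distance from the chord between the endpoints) picks t
.vne_knee <- function(lam, t_max = 100L) {
  a <- abs(lam)
  a <- a[a > .Machine$double.eps]
  h <- vapply(seq_len(t_max), function(t) {
    w <- a^t
    pr <- w / sum(w)
    pr <- pr[pr > 0]
    -sum(pr * log(pr))
  }, numeric(1))
  ts <- seq_len(t_max)
  x1 <- ts[1]; y1 <- h[1]; x2 <- ts[t_max]; y2 <- h[t_max]
  dx <- x2 - x1; dy <- y2 - y1
  dist_line <- abs(dy * ts - dx * h + x2 * y1 - y2 * x1) / sqrt(dx^2 + dy^2)
  as.integer(ts[which.max(dist_line)])
}

# dominant eigenpairs by seeded subspace iteration (enough accuracy for an
# MDS starting configuration at a fraction of a full decomposition's cost)
.top_eigen <- function(B, p, iters = 30, seed = 1L) {
  n <- nrow(B)
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(n * p), n, p)))
  for (i in seq_len(iters)) Q <- qr.Q(qr(B %*% Q))
  M <- crossprod(Q, B %*% Q)
  e <- eigen(M, symmetric = TRUE)
  list(values = e$values, vectors = Q %*% e$vectors)
}

# classical-MDS initialisation followed by SMACOF stress majorisation
.metric_mds <- function(Delta, p, max_iter = 300, tol = 1e-6, seed = 1L) {
  n <- nrow(Delta)
  # classical MDS: dominant eigenpairs of the double-centred squared distances
  D2 <- Delta^2
  rm <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (D2 - outer(rm, rm, "+") + gm)
  eig <- .top_eigen(B, p, seed = seed)
  ev <- pmax(eig$values[seq_len(p)], 0)
  X <- eig$vectors[, seq_len(p), drop = FALSE] * rep(sqrt(ev), each = n)
  if (all(ev == 0)) {               # degenerate start: tiny seeded jitter
    set.seed(seed)
    X <- matrix(stats::rnorm(n * p, sd = 1e-8), n, p)
  }
  stress_trace <- numeric(0)
  d <- .pairwise_dist(X)
  stress <- sum((Delta - d)^2) / 2
  stress_trace <- stress
  for (it in seq_len(max_iter)) {
    ratio <- ifelse(d > 0, Delta / d, 0)
    Bm <- -ratio
    diag(Bm) <- 0
    diag(Bm) <- -rowSums(Bm)
    X <- (Bm %*% X) / n
    d <- .pairwise_dist(X)
    stress_new <- sum((Delta - d)^2) / 2
    stress_trace <- c(stress_trace, stress_new)
    if (stress > 0 && (stress - stress_new) / max(stress, .Machine$double.eps) < tol) {
      stress <- stress_new
      break
    }
    stress <- stress_new
  }
  list(coords = X, stress = stress_trace)
}

#' Write embedding coordinates to TSV (+ JSON parameter sidecar)
#'
#' @param e a `geometry_embedding`.
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_embedding_tsv <- function(e, path) {
  df <- data.frame(cell_id = rownames(e$coords) %||% seq_len(nrow(e$coords)),
                   e$coords)
  names(df)[-1] <- sprintf("dim_%d", seq_len(ncol(e$coords)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_json(c(e$params, list(p = e$p, t_used = e$t_used)),
              paste0(path, ".json"))
  invisible(path)
}
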