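#' Reconstruction error and rank correlation
#'
#' `mse()` is the mean squared error over all entries; `spearman()` is the
#' Spearman rank correlation over the flattened entry pairs (midrank ties).
#' A constant matrix makes the rank correlation undefined and raises an
#' error.
#'
#' @param X,Xhat matrices of equal shape (original and reconstruction).
#' @return a single number.
#' @export
mse <- function(X, Xhat) {
  X <- .as_feature_matrix(X); Xhat <- .as_feature_matrix(Xhat)
  .assert(all(dim(X) == dim(Xhat)), "shape mismatch")
  mean((X - Xhat)^2)
}

#' @rdname mse
#' @export
spearman <- function(X, Xhat) {
  X <- .as_feature_matrix(X); Xhat <- .as_feature_matrix(Xhat)
  .assert(all(dim(X) == dim(Xhat)), "shape mismatch")
  x <- as.vector(X); y <- as.vector(Xhat)
  .assert(stats::sd(x) > 0 && stats::sd(y) > 0,
          "Spearman undefined for a constant matrix")
  stats::cor(x, y, method = "spearman")
}

#' MSE restricted to the most covered features
#'
#' Coverage of a feature is the number of cells detecting it (non-zero
#' entries), computed on the observed matrix (`basis = "observed"`) or on
#' the reconstruction (`basis = "imputed"`). The MSE is then restricted to
#' the `ceiling(top_frac * F)` most covered features — an outlier-robust
#' variant of the plain reconstruction MSE. Coverage ties are broken by
#' ascending feature index.
#'
#' @inheritParams mse
#' @param basis which matrix defines coverage.
#' @param top_frac fraction of features kept (default 0.01).
#' @return a single number.
#' @export
mse_top_covered <- function(X, Xhat, basis = c("observed", "imputed"),
                            top_frac = 0.01) {
  basis <- match.arg(basis)
  X <- .as_feature_matrix(X); Xhat <- .as_feature_matrix(Xhat)
  .assert(all(dim(X) == dim(Xhat)), "shape mismatch")
  B <- if (basis == "observed") X else Xhat
  coverage <- colSums(B != 0)
  n_keep <- ceiling(top_frac * ncol(X))
  keep <- order(-coverage, seq_along(coverage))[seq_len(n_keep)]
  mean((X[, keep, drop = FALSE] - Xhat[, keep, drop = FALSE])^2)
}

#' Negative-binomial reconstruction loss
#'
#' Mean negative log-likelihood of the observed counts under a negative
#' binomial with mean `mu` (the reconstruction, floored at `eps`) and a
#' global inverse-dispersion `theta` (`Var = mu + mu^2 / theta` — the same
#' convention as the synthetic generator). When `theta` is `NULL` it is
#' estimated from the observed matrix by method of moments.
#'
#' @param X observed non-negative integer matrix.
#' @param mu reconstructed means (same shape).
#' @param theta positive inverse-dispersion, or `NULL` to estimate.
#' @param eps floor applied to `mu`.
#' @return a single number (mean NLL per entry).
#' @export
nb_loss <- function(X, mu, theta = NULL, eps = 1e-8) {
  X <- .as_feature_matrix(X); mu <- .as_feature_matrix(mu)
  .assert(all(dim(X) == dim(mu)), "shape mismatch")
  theta <- theta %||% estimate_nb_theta(X)
  .assert(is.numeric(theta) && theta > 0, "theta must be positive")
  mu <- pmax(mu, eps)
  -mean(stats::dnbinom(round(X), size = theta, mu = mu, log = TRUE))
}

#' @rdname nb_loss
#' @export
estimate_nb_theta <- function(X) {
  X <- .as_feature_matrix(X)
  m <- mean(X); v <- stats::var(as.vector(X))
  if (v <= m) return(1e6)      # at or under Poisson dispersion
  m^2 / (v - m)
}

#' Homogeneity of the cell graph with respect to cell types
#'
#' For each cell, counts the distinct label values among its `k` directed
#' nearest neighbours (self excluded), normalises by `k * C` to obtain a
#' heterogeneity score, and returns one minus the mean heterogeneity. A
#' latent space that groups same-type cells yields values close to
#' `1 - 1/(k*C)`.
#'
#' @param g a [knn_graph()] `cell_graph` (its directed neighbour matrix is
#'   used, so the divisor `k` is exact).
#' @param labels per-node labels.
#' @param k neighbourhood size (defaults to `g$k`).
#' @param C number of cell types (defaults to the number of label levels).
#' @return a number in \[0, 1\].
#' @export
homogeneity <- function(g, labels, k = NULL, C = NULL) {
  stopifnot(inherits(g, "cell_graph"))
  labels <- factor(labels)
  .assert(length(labels) == g$n_nodes, "labels must cover all nodes")
  k <- k %||% g$k
  C <- C %||% nlevels(labels)
  .assert(C >= 1, "C must be >= 1")
  lab <- as.integer(labels)
  nb <- g$neighbors[, seq_len(k), drop = FALSE]
  distinct <- apply(nb, 1, function(ix) length(unique(lab[ix])))
  het <- distinct / (k * C)
  1 - mean(het)
}

.check_sets <- function(sets, n) {
  for (i in seq_along(sets)) {
    .assert(length(sets[[i]]) == n,
            "set %s has size %d, expected %d",
            names(sets)[i] %||% i, length(sets[[i]]), n)
  }
}

# accept a class_explanation_set or a plain list of id vectors
.as_top_sets <- function(x, n) {
  if (inherits(x, "class_explanation_set"))
    x <- lapply(x, top_features, n = n)
  x
}

#' Specificity of per-class explanations
#'
#' One minus the mean pairwise overlap `|A n B| / n` of the per-class top-n
#' feature sets over all unordered class pairs: 1 when classes receive
#' disjoint explanations, 0 when all classes share the same set.
#'
#' @param explanations a `class_explanation_set` or a list of per-class
#'   feature-id vectors, each of size `n`.
#' @param n set size (default 50).
#' @return a number in \[0, 1\].
#' @export
specificity <- function(explanations, n = 50) {
  sets <- .as_top_sets(explanations, n)
  .assert(length(sets) >= 2, "need >= 2 classes")
  .check_sets(sets, n)
  pairs <- utils::combn(length(sets), 2)
  ov <- apply(pairs, 2, function(p)
    length(intersect(sets[[p[1]]], sets[[p[2]]])) / n)
  1 - mean(ov)
}

#' Stability of explanations across repeated runs
#'
#' For each class, the mean pairwise overlap `|A n B| / n` of its top-n set
#' across all unordered run pairs; stability is the mean over classes: 1
#' when every run reproduces the same sets, 0 when runs are disjoint.
#'
#' @param runs a list of runs; each run is a `class_explanation_set` or a
#'   named list of per-class feature-id vectors with a consistent class
#'   vocabulary.
#' @param n set size (default 50).
#' @return a number in \[0, 1\].
#' @export
stability <- function(runs, n = 50) {
  .assert(length(runs) >= 2, "need >= 2 runs")
  runs <- lapply(runs, .as_top_sets, n = n)
  classes <- names(runs[[1]])
  .assert(!is.null(classes), "runs must carry class names")
  for (r in seq_along(runs)) {
    missing <- setdiff(classes, names(runs[[r]]))
    .assert(length(missing) == 0, "run %d is missing class '%s'", r, missing[1])
    .check_sets(runs[[r]], n)
  }
  pairs <- utils::combn(length(runs), 2)
  per_class <- vapply(classes, function(cl) {
    mean(apply(pairs, 2, function(p)
      length(intersect(runs[[p[1]]][[cl]], runs[[p[2]]][[cl]])) / n))
  }, numeric(1))
  mean(per_class)
}

#' Per-feature coverage and expression
#'
#' Coverage: number of cells in which a feature is detected (non-zero).
#' Expression (or openness): total reads mapping to the feature (column
#' sum). Typically computed on the raw counts.
#'
#' @param m a [count_matrix()] or numeric matrix.
#' @return a named numeric vector over features.
#' @export
feature_coverage <- function(m) {
  X <- .as_feature_matrix(m)
  out <- colSums(X != 0)
  names(out) <- colnames(X)
  out
}

#' @rdname feature_coverage
#' @export
feature_expression <- function(m) {
  X <- .as_feature_matrix(m)
  out <- colSums(X)
  names(out) <- colnames(X)
  out
}

#' Technical-bias overlap of a feature set
#'
#' Fraction of a top-n feature set that also ranks in the top n by a
#' technical criterion (total expression/openness or coverage) — measuring
#' how much a selection is biased towards highly expressed or highly
#' covered features. Ties in the criterion are broken by ascending index.
#'
#' @param feature_set character vector of n feature ids.
#' @param m the [count_matrix()] providing the criterion (document whether
#'   raw or normalised counts are passed).
#' @param criterion `"expression"` or `"coverage"`.
#' @return a number in \[0, 1\].
#' @export
bias_overlap <- function(feature_set, m, criterion = c("expression", "coverage")) {
  criterion <- match.arg(criterion)
  X <- .as_feature_matrix(m)
  ids <- colnames(X) %||% sprintf("feat_%d", seq_len(ncol(X)))
  .assert(length(feature_set) <= ncol(X), "feature_set larger than the matrix")
  val <- if (criterion == "expression") colSums(X) else colSums(X != 0)
  n <- length(feature_set)
  top <- ids[order(-val, seq_along(val))[seq_len(n)]]
  length(intersect(feature_set, top)) / n
}

#' Signal-to-noise ratio of a feature set for one class
#'
#' Per feature: `(mean within class - mean outside class) /
#' (sd within + sd outside + eps)`; the reported value is the mean over the
#' set. Positive values mean the set is up-regulated in the class relative
#' to the rest, scaled by the pooled spread.
#'
#' @param feature_set character vector of feature ids.
#' @param m a [count_matrix()] with matching feature ids.
#' @param labels per-cell labels (defaults to `m$labels`).
#' @param class the class of interest.
#' @param eps denominator floor (default 1e-8).
#' @return a single number.
#' @export
stn_ratio <- function(feature_set, m, labels = NULL, class, eps = 1e-8) {
  X <- .as_feature_matrix(m)
  labels <- labels %||% (if (inherits(m, "count_matrix")) m$labels else NULL)
  .assert(!is.null(labels), "labels required")
  labels <- factor(labels)
  .assert(class %in% levels(labels), "class '%s' absent from labels", class)
  ids <- colnames(X) %||% sprintf("feat_%d", seq_len(ncol(X)))
  idx <- match(feature_set, ids)
  .assert(!anyNA(idx), "unknown feature id in feature_set")
  inc <- labels == class
  Xi <- X[inc, idx, drop = FALSE]; Xo <- X[!inc, idx, drop = FALSE]
  m_in <- colMeans(Xi); m_out <- colMeans(Xo)
  sd_in <- apply(Xi, 2, stats::sd); sd_out <- apply(Xo, 2, stats::sd)
  mean((m_in - m_out) / (sd_in + sd_out + eps))
}

#' Similarity between explainer and differential feature sets
#'
#' Overlap `|XAIF n DAF| / n` between the explainer-derived top-n set and
#' the differential-analysis top-n set of the same class (or Jaccard,
#' `|A n B| / |A u B|`, when `method = "jaccard"`).
#'
#' @param xaif,daf character vectors of n feature ids.
#' @param n set size (default 50).
#' @param method normaliser: `"fraction"` (by n) or `"jaccard"`.
#' @return a number in \[0, 1\].
#' @export
xai_da_similarity <- function(xaif, daf, n = 50, method = c("fraction", "jaccard")) {
  method <- match.arg(method)
  .assert(length(xaif) == n && length(daf) == n,
          "both sets must have size n = %d", n)
  inter <- length(intersect(xaif, daf))
  if (method == "fraction") inter / n
  else inter / length(union(xaif, daf))
}
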