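#' Specification of a synthetic single-cell count matrix
#'
#' Describes the planted structure used by [generate_counts()] and
#' [generate_trajectory_counts()]: discrete cell types, per-type marker
#' features with a log2 fold-change, negative-binomial sampling noise and
#' technical dropout. Defaults are the fixture conditions used throughout the
#' test-suite: 2000 cells, 500 features, 4 balanced types with 20 markers
#' each at a 4-fold effect, NB mean 2 with inverse-dispersion 2, 30% dropout.
#'
#' The negative binomial is parameterised by mean `mu` and inverse-dispersion
#' `theta` with `Var = mu + mu^2 / theta`, the same convention as [nb_loss()].
#'
#' @param n_cells,n_features matrix dimensions.
#' @param n_types number of planted cell types `C`.
#' @param markers_per_type number of marker features per type; marker sets are
#'   pairwise disjoint, so `markers_per_type * n_types <= n_features`.
#' @param effect_log2fc log2 fold-change of a marker's NB mean within its own
#'   type (`>= 0`).
#' @param base_mean NB mean of background features (`> 0`).
#' @param nb_dispersion inverse-dispersion `theta` (`> 0`).
#' @param dropout_p probability of independently zeroing each entry after NB
#'   sampling (technical dropout).
#' @param type_proportions simplex vector of length `n_types` (sums to 1, all
#'   positive); default balanced.
#' @param seed integer seed; identical specs reproduce identical matrices.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 2000, n_features = 500, n_types = 4,
                           markers_per_type = 20, effect_log2fc = 2,
                           base_mean = 2, nb_dispersion = 2, dropout_p = 0.3,
                           type_proportions = NULL, seed = 1L) {
  type_proportions <- type_proportions %||% rep(1 / n_types, n_types)
  .assert(n_cells >= 1 && n_features >= 1 && n_types >= 1, "dimensions must be positive")
  .assert(markers_per_type >= 0, "markers_per_type must be non-negative")
  .assert(effect_log2fc >= 0, "effect_log2fc must be >= 0")
  .assert(base_mean > 0, "base_mean must be positive")
  .assert(nb_dispersion > 0, "nb_dispersion must be positive")
  .assert(dropout_p >= 0 && dropout_p <= 1, "dropout_p must be in [0,1]")
  .assert(length(type_proportions) == n_types, "type_proportions must have length n_types")
  .assert(all(type_proportions > 0), "type_proportions entries must be > 0")
  .assert(abs(sum(type_proportions) - 1) <= 1e-9, "type_proportions must sum to 1")
  .assert(markers_per_type * n_types <= n_features,
          "markers_per_type * n_types (%d) exceeds n_features (%d): disjoint marker sets impossible",
          markers_per_type * n_types, n_features)
  structure(list(n_cells = as.integer(n_cells), n_features = as.integer(n_features),
                 n_types = as.integer(n_types), markers_per_type = as.integer(markers_per_type),
                 effect_log2fc = effect_log2fc, base_mean = base_mean,
                 nb_dispersion = nb_dispersion, dropout_p = dropout_p,
                 type_proportions = type_proportions, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic label assignment honouring the proportions: floor counts,
# leftovers to the largest types, then every type is guaranteed >= 1 cell
.assign_labels <- function(n, props) {
  counts <- floor(props * n)
  counts <- pmax(counts, 1L)
  while (sum(counts) > n) {
    i <- which.max(counts); counts[i] <- counts[i] - 1L
  }
  while (sum(counts) < n) {
    i <- which.max(props * n - counts); counts[i] <- counts[i] + 1L
  }
  rep(seq_along(props), counts)
}

#' Generate a seeded count matrix with planted cell types and markers
#'
#' Samples entries independently from a negative binomial: background
#' features have mean `base_mean` everywhere; marker feature `j` of type `c`
#' has mean `base_mean * 2^effect_log2fc` in cells of type `c` and
#' `base_mean` elsewhere. Each entry is then independently zeroed with
#' probability `dropout_p`. The marker sets are disjoint, consecutive blocks
#' of the first `markers_per_type * n_types` feature indices.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with
#' \describe{
#'   \item{matrix}{a [count_matrix()] with labels `type_1..type_C`,}
#'   \item{truth}{ground truth: `labels` (integer type index per cell),
#'     `marker_sets` (per-type feature-index sets), `mean_matrix`
#'     (`C x n_features` expected NB means before dropout).}
#' }
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells; f <- spec$n_features; C <- spec$n_types
  labels <- .assign_labels(n, spec$type_proportions)
  marker_sets <- if (spec$markers_per_type > 0) {
    lapply(seq_len(C), function(c)
      ((c - 1L) * spec$markers_per_type + 1L):(c * spec$markers_per_type))
  } else rep(list(integer(0)), C)
  mean_matrix <- matrix(spec$base_mean, C, f)
  for (c in seq_len(C))
    mean_matrix[c, marker_sets[[c]]] <- spec$base_mean * 2^spec$effect_log2fc
  mu <- mean_matrix[labels, , drop = FALSE]
  counts <- matrix(stats::rnbinom(n * f, size = spec$nb_dispersion, mu = mu), n, f)
  if (spec$dropout_p > 0) {
    keep <- matrix(stats::rbinom(n * f, 1L, 1 - spec$dropout_p), n, f)
    counts <- counts * keep
  }
  m <- count_matrix(counts, labels = sprintf("type_%d", labels), modality = "GEX")
  list(matrix = m,
       truth = list(labels = labels, marker_sets = marker_sets,
                    mean_matrix = mean_matrix))
}

#' Generate a branching-trajectory count matrix
#'
#' Places cells on a 1-D pseudotime per branch (uniform on \[0, 1\]). Each
#' branch owns `markers_per_type` trajectory features whose NB mean rises
#' sigmoidally along that branch's pseudotime from `base_mean` to
#' `base_mean * 2^effect_log2fc`, with logistic midpoints staggered across
#' \[0.15, 0.85\] (steepness 12) — an activation cascade, so the cells lie on
#' a curved 1-D manifold rather than a linear gradient; all
#' other features (and other branches' cells) stay at `base_mean`. Labels are
#' `branch x pseudotime-bin` with `n_bins` equal-width bins. `noise = 0`
#' returns the rounded expected means with no dropout; `noise = 1` (default)
#' applies the spec's NB sampling and dropout.
#'
#' @param spec a [synthetic_spec()]; `n_types` is ignored (classes are
#'   branch-bin combinations).
#' @param n_branches number of branches (`>= 1`).
#' @param n_bins pseudotime bins per branch used for labelling.
#' @param noise noise multiplier: effective inverse-dispersion is
#'   `nb_dispersion / noise`; 0 disables sampling and dropout.
#' @return as [generate_counts()], with `truth` additionally carrying
#'   `pseudotime` and `branch` per cell; `marker_sets` holds each branch's
#'   trajectory features (recycled over that branch's bins).
#' @export
generate_trajectory_counts <- function(spec, n_branches = 2L, n_bins = 2L,
                                       noise = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .assert(n_branches >= 1, "n_branches must be >= 1")
  .assert(noise >= 0, "noise must be >= 0")
  .assert(spec$markers_per_type * n_branches <= spec$n_features,
          "markers_per_type * n_branches exceeds n_features")
  set.seed(spec$seed)
  n <- spec$n_cells; f <- spec$n_features
  branch <- rep(seq_len(n_branches), length.out = n)
  pseudotime <- stats::runif(n)
  bin <- pmin(floor(pseudotime * n_bins) + 1L, n_bins)
  labels <- (branch - 1L) * n_bins + bin
  marker_sets <- lapply(seq_len(n_branches), function(b)
    if (spec$markers_per_type > 0)
      ((b - 1L) * spec$markers_per_type + 1L):(b * spec$markers_per_type)
    else integer(0))
  amp <- spec$base_mean * (2^spec$effect_log2fc - 1)
  mu <- matrix(spec$base_mean, n, f)
  for (b in seq_len(n_branches)) {
    rows <- which(branch == b)
    mk <- marker_sets[[b]]
    if (length(mk)) {
      # staggered activation midpoints: a cascade along pseudotime
      mid <- if (length(mk) > 1) seq(0.15, 0.85, length.out = length(mk)) else 0.5
      for (i in seq_along(mk)) {
        s <- 1 / (1 + exp(-12 * (pseudotime[rows] - mid[i])))
        mu[rows, mk[i]] <- spec$base_mean + amp * s
      }
    }
  }
  if (noise == 0) {
    counts <- round(mu)
  } else {
    counts <- matrix(stats::rnbinom(n * f, size = spec$nb_dispersion / noise, mu = mu), n, f)
    if (spec$dropout_p > 0) {
      keep <- matrix(stats::rbinom(n * f, 1L, 1 - spec$dropout_p), n, f)
      counts <- counts * keep
    }
  }
  m <- count_matrix(counts, labels = sprintf("branch%d_bin%d", branch, bin),
                    modality = "GEX")
  list(matrix = m,
       truth = list(labels = labels, marker_sets = marker_sets,
                    mean_matrix = NULL, pseudotime = pseudotime, branch = branch))
}

#' Write ground truth to plain-text files
#'
#' Writes a `cell_id` / `label` TSV and a JSON manifest of the per-type
#' marker feature ids.
#'
#' @param result a list as returned by [generate_counts()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- result$matrix; truth <- result$truth
  utils::write.table(
    data.frame(cell_id = m$cell_ids, label = as.character(m$labels)),
    file.path(dir, "ground_truth_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  markers <- lapply(truth$marker_sets, function(idx) m$feature_ids[idx])
  names(markers) <- sprintf("set_%d", seq_along(markers))
  .write_json(markers, file.path(dir, "ground_truth_markers.json"))
  invisible(dir)
}
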