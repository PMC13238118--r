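#' Quantile quality control for gene-expression matrices
#'
#' Removes cells whose number of detected (non-zero) genes or mitochondrial
#' read count falls strictly outside the \[5%, 95%\] quantiles of the
#' respective per-cell distributions, then removes genes detected in fewer
#' cells than the 5% quantile or more cells than the 95% quantile of the
#' per-gene detection distribution. Quantiles use linear interpolation
#' between order statistics (R type 7), and only strictly-outside values are
#' removed, so degenerate all-equal distributions pass untouched.
#'
#' When the `mito_count` QC column is absent the mitochondrial rule is
#' skipped and the skip is recorded in the report (use [add_mito_counts()]
#' to derive the column from feature prefixes).
#'
#' @param m a raw (unnormalised) GEX [count_matrix()].
#' @param lower,upper quantile bounds (defaults 0.05 and 0.95).
#' @return a list `(matrix, report)`: the filtered [count_matrix()] and a
#'   `qc_report` recording thresholds and per-rule removal counts.
#' @export
qc_filter_gex <- function(m, lower = 0.05, upper = 0.95) {
  stopifnot(inherits(m, "count_matrix"))
  .assert(m$modality == "GEX", "qc_filter_gex expects modality GEX")
  .assert(!m$is_normalised, "qc_filter_gex expects raw counts")
  rules <- list()
  keep_cell <- rep(TRUE, n_cells(m))

  detected <- rowSums(m$counts > 0)
  q <- stats::quantile(detected, c(lower, upper), names = FALSE)
  # cells with no detected gene are junk regardless of the quantile band
  out <- detected < q[1] | detected > q[2] | detected == 0
  rules$detected_genes <- list(lower = q[1], upper = q[2], removed = sum(out & keep_cell))
  keep_cell <- keep_cell & !out

  if (!is.null(m$qc) && "mito_count" %in% names(m$qc)) {
    mito <- m$qc$mito_count
    qm <- stats::quantile(mito, c(lower, upper), names = FALSE)
    outm <- mito < qm[1] | mito > qm[2]
    rules$mito_count <- list(lower = qm[1], upper = qm[2], removed = sum(outm & keep_cell))
    keep_cell <- keep_cell & !outm
  } else {
    rules$mito_count <- list(skipped = TRUE)
  }
  .assert(any(keep_cell), "no cells survive QC")
  m2 <- .subset_cm(m, cells = which(keep_cell))

  det_cells <- colSums(m2$counts > 0)
  qf <- stats::quantile(det_cells, c(lower, upper), names = FALSE)
  keep_feat <- det_cells >= qf[1] & det_cells <= qf[2]
  rules$feature_detection <- list(lower = qf[1], upper = qf[2], removed = sum(!keep_feat))
  .assert(any(keep_feat), "no features survive QC")
  m2 <- .subset_cm(m2, features = which(keep_feat))

  report <- structure(list(
    n_cells_in = n_cells(m), n_cells_out = n_cells(m2),
    n_features_in = n_features(m), n_features_out = n_features(m2),
    quantiles = c(lower = lower, upper = upper), rules = rules),
    class = "qc_report")
  list(matrix = m2, report = report)
}

#' Quantile quality control for peak / window matrices
#'
#' As [qc_filter_gex()] for the per-cell feature-count and per-feature
#' detection quantile rules, plus the chromatin-specific absolute cut-offs:
#' cells with TSS enrichment score below `tss_min` (default 2) or nucleosome
#' signal above `nucleosome_max` (default 2) are removed when those QC
#' columns are present (skips are recorded in the report).
#'
#' @inheritParams qc_filter_gex
#' @param tss_min minimum TSS enrichment score.
#' @param nucleosome_max maximum nucleosome signal.
#' @return a list `(matrix, report)`, see [qc_filter_gex()].
#' @export
qc_filter_peaks <- function(m, lower = 0.05, upper = 0.95, tss_min = 2,
                            nucleosome_max = 2) {
  stopifnot(inherits(m, "count_matrix"))
  .assert(m$modality %in% c("PEAKS", "WINDOWS"),
          "qc_filter_peaks expects modality PEAKS or WINDOWS")
  .assert(!m$is_normalised, "qc_filter_peaks expects raw counts")
  rules <- list()
  keep_cell <- rep(TRUE, n_cells(m))

  detected <- rowSums(m$counts > 0)
  q <- stats::quantile(detected, c(lower, upper), names = FALSE)
  out <- detected < q[1] | detected > q[2] | detected == 0
  rules$detected_features <- list(lower = q[1], upper = q[2], removed = sum(out & keep_cell))
  keep_cell <- keep_cell & !out

  if (!is.null(m$qc) && "tss_enrichment" %in% names(m$qc)) {
    out_t <- m$qc$tss_enrichment < tss_min
    rules$tss_enrichment <- list(threshold = tss_min, removed = sum(out_t & keep_cell))
    keep_cell <- keep_cell & !out_t
  } else rules$tss_enrichment <- list(skipped = TRUE)

  if (!is.null(m$qc) && "nucleosome_signal" %in% names(m$qc)) {
    out_n <- m$qc$nucleosome_signal > nucleosome_max
    rules$nucleosome_signal <- list(threshold = nucleosome_max, removed = sum(out_n & keep_cell))
    keep_cell <- keep_cell & !out_n
  } else rules$nucleosome_signal <- list(skipped = TRUE)

  .assert(any(keep_cell), "no cells survive QC")
  m2 <- .subset_cm(m, cells = which(keep_cell))

  det_cells <- colSums(m2$counts > 0)
  qf <- stats::quantile(det_cells, c(lower, upper), names = FALSE)
  keep_feat <- det_cells >= qf[1] & det_cells <= qf[2]
  rules$feature_detection <- list(lower = qf[1], upper = qf[2], removed = sum(!keep_feat))
  .assert(any(keep_feat), "no features survive QC")
  m2 <- .subset_cm(m2, features = which(keep_feat))

  report <- structure(list(
    n_cells_in = n_cells(m), n_cells_out = n_cells(m2),
    n_features_in = n_features(m), n_features_out = n_features(m2),
    quantiles = c(lower = lower, upper = upper), rules = rules),
    class = "qc_report")
  list(matrix = m2, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> cells %d -> %d, features %d -> %d\n",
              x$n_cells_in, x$n_cells_out, x$n_features_in, x$n_features_out))
  for (nm in names(x$rules)) {
    r <- x$rules[[nm]]
    if (isTRUE(r$skipped)) cat(sprintf("  %s: skipped (column absent)\n", nm))
    else cat(sprintf("  %s: removed %d\n", nm, r$removed))
  }
  invisible(x)
}

#' Serialise a QC report to JSON
#' @param report a `qc_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  .write_json(unclass(report), path)
  invisible(path)
}

#' Library-size normalisation
#'
#' Scales each cell so its total count equals `target_sum` (default: the
#' median of per-cell totals). Cells with zero total are rejected with a
#' pointer to QC.
#'
#' @param m a raw [count_matrix()].
#' @param target_sum positive number, or `"median"`.
#' @return the normalised [count_matrix()] (`is_normalised` set).
#' @export
normalize_library_size <- function(m, target_sum = "median") {
  stopifnot(inherits(m, "count_matrix"))
  .assert(!m$is_normalised, "matrix is already normalised")
  totals <- rowSums(m$counts)
  .assert(all(totals > 0),
          "%d cell(s) have zero total counts; run QC filtering first",
          sum(totals == 0))
  target <- if (identical(target_sum, "median")) stats::median(totals) else {
    .assert(is.numeric(target_sum) && target_sum > 0, "target_sum must be positive")
    target_sum
  }
  m$counts <- m$counts * (target / totals)
  m$is_normalised <- TRUE
  m
}

#' Select highly variable genes
#'
#' Keeps the `ceiling(top_frac * F)` genes of highest variance, computed on
#' the normalised (pre-log) counts. Ties are broken by ascending feature
#' index, so the selection is deterministic.
#'
#' @param m a normalised, not yet log-transformed [count_matrix()].
#' @param top_frac fraction of genes to keep, in (0, 1\]; default 0.10.
#' @return the reduced [count_matrix()].
#' @export
select_hvg_gex <- function(m, top_frac = 0.10) {
  stopifnot(inherits(m, "count_matrix"))
  .assert(top_frac > 0 && top_frac <= 1, "top_frac must be in (0, 1]")
  .assert(m$is_normalised && !m$is_log,
          "HVG selection expects normalised, pre-log counts")
  v <- apply(m$counts, 2, stats::var)
  n_keep <- ceiling(top_frac * length(v))
  ord <- order(-v, seq_along(v))
  .subset_cm(m, features = sort(ord[seq_len(n_keep)]))
}

#' Select highly variable peaks / windows
#'
#' Keeps features whose variance lies strictly above the `var_quantile`
#' quantile of the variance distribution, truncated to the `max_features`
#' highest-variance features.
#'
#' @param m a normalised peak/window [count_matrix()].
#' @param var_quantile variance quantile threshold (default 0.80).
#' @param max_features hard cap on the number of retained features.
#' @return the reduced [count_matrix()].
#' @export
select_hv_peaks <- function(m, var_quantile = 0.80, max_features = 30000) {
  stopifnot(inherits(m, "count_matrix"))
  .assert(var_quantile > 0 && var_quantile < 1, "var_quantile must be in (0, 1)")
  .assert(m$is_normalised && !m$is_log,
          "HV-peak selection expects normalised, pre-log counts")
  v <- apply(m$counts, 2, stats::var)
  thr <- stats::quantile(v, var_quantile, names = FALSE)
  pass <- which(v > thr)
  .assert(length(pass) > 0,
          "no feature has variance strictly above the %.0f%% quantile; lower var_quantile",
          100 * var_quantile)
  if (length(pass) > max_features) {
    ord <- order(-v[pass], pass)
    pass <- pass[ord[seq_len(max_features)]]
  }
  .subset_cm(m, features = sort(pass))
}

#' Log-transform a normalised matrix
#'
#' Entrywise natural `log(1 + x)`. Guards against double transformation.
#'
#' @param m a normalised [count_matrix()].
#' @return the transformed [count_matrix()] (`is_log` set).
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  .assert(m$is_normalised, "log_transform expects a normalised matrix")
  .assert(!m$is_log, "matrix is already log-transformed")
  m$counts <- log1p(m$counts)
  m$is_log <- TRUE
  m
}

# standardised Wilcoxon rank-sum statistic for a one-vs-rest split, with
# midranks and tie correction; positive when the class is up-regulated
.wilcox_z <- function(ranks_mat, in_class, n) {
  n1 <- sum(in_class); n2 <- n - n1
  r1 <- colSums(ranks_mat[in_class, , drop = FALSE])
  mu <- n1 * (n + 1) / 2
  # per-feature tie correction: sum over tie groups of (t^3 - t)
  tie_term <- apply(ranks_mat, 2, function(r) {
    t <- table(r); sum(t^3 - t)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (r1 - mu) / sqrt(pmax(sigma2, .Machine$double.eps))
  z[sigma2 <= 0] <- 0
  z
}

#' One-vs-rest Wilcoxon differential analysis
#'
#' For each class, runs a two-sided Wilcoxon rank-sum test of every feature
#' against all other cells, ranks features by the standardised rank-sum
#' statistic (descending: most up-regulated first) and returns the top
#' `n_top` per class — the differential features (DAFs) used as the
#' comparison baseline for the explainer. P-values are exact (enumeration)
#' when the total sample is at most 20 cells without ties, and use the
#' normal approximation with midranks and tie correction otherwise.
#'
#' @param m a log-transformed, labelled [count_matrix()] with at least two
#'   classes.
#' @param n_top number of top features to report per class.
#' @return an object of class `da_result`: `tables` (per-class data.frame of
#'   `feature_id`, `statistic`, `p_value` sorted by decreasing statistic),
#'   `top` (per-class character vector of the `n_top` feature ids), `n_top`.
#' @export
wilcoxon_da <- function(m, n_top = 50) {
  stopifnot(inherits(m, "count_matrix"))
  .assert(!is.null(m$labels), "wilcoxon_da requires labels")
  .assert(nlevels(m$labels) >= 2, "wilcoxon_da requires >= 2 classes")
  sizes <- table(m$labels)
  small <- names(sizes)[sizes < 2]
  .assert(length(small) == 0, "class '%s' has fewer than 2 cells", small[1])
  X <- m$counts
  n <- nrow(X)
  ranks_mat <- apply(X, 2, rank)  # midranks
  exact <- n <= 20
  res <- list(); top <- list()
  for (cl in levels(m$labels)) {
    in_class <- m$labels == cl
    z <- .wilcox_z(ranks_mat, in_class, n)
    if (exact) {
      p <- vapply(seq_len(ncol(X)), function(j) {
        suppressWarnings(stats::wilcox.test(X[in_class, j], X[!in_class, j],
                                            exact = TRUE)$p.value)
      }, numeric(1))
    } else {
      p <- 2 * stats::pnorm(-abs(z))
    }
    ord <- order(-z, seq_along(z))
    tab <- data.frame(feature_id = m$feature_ids[ord], statistic = z[ord],
                      p_value = p[ord], stringsAsFactors = FALSE)
    res[[cl]] <- tab
    top[[cl]] <- tab$feature_id[seq_len(min(n_top, nrow(tab)))]
  }
  structure(list(tables = res, top = top, n_top = n_top, classes = levels(m$labels)),
            class = "da_result")
}

#' @export
print.da_result <- function(x, ...) {
  cat(sprintf("<da_result> %d classes, top %d features each\n",
              length(x$classes), x$n_top))
  for (cl in x$classes)
    cat(sprintf("  %s: %s ...\n", cl, paste(utils::head(x$top[[cl]], 5), collapse = ", ")))
  invisible(x)
}
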