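# brute-force oracle for the cell-level detected-feature quantile rule
.oracle_cell_rule <- function(detected, lower = 0.05, upper = 0.95) {
  q <- quantile(detected, c(lower, upper), names = FALSE)
  which(detected >= q[1] & detected <= q[2])
}

test_that("identical cells survive QC untouched (strict-outside rule)", {
  m <- count_matrix(matrix(2, 20, 10))
  out <- qc_filter_gex(m)
  expect_equal(n_cells(out$matrix), 20)
})

test_that("detected-gene quantile rule matches brute-force enumeration on 1..100", {
  # cell i expresses exactly i genes
  counts <- matrix(0, 100, 100)
  for (i in 1:100) counts[i, seq_len(i)] <- 1
  m <- count_matrix(counts)
  out <- qc_filter_gex(m)
  keep <- .oracle_cell_rule(1:100)
  expect_setequal(out$matrix$cell_ids, sprintf("cell_%d", keep))
  expect_equal(out$report$rules$detected_genes$removed, 100 - length(keep))
  expect_true(isTRUE(out$report$rules$mito_count$skipped))
  # surviving features equal the brute-force application of the second rule
  sub <- counts[keep, ]
  det <- colSums(sub > 0)
  qf <- quantile(det, c(0.05, 0.95), names = FALSE)
  expect_setequal(out$matrix$feature_ids,
                  sprintf("feat_%d", which(det >= qf[1] & det <= qf[2])))
})

test_that("all-zero matrices are rejected by QC", {
  expect_error(qc_filter_gex(count_matrix(matrix(0, 10, 5))), "survive")
})

test_that("peak QC applies the chromatin score cut-offs", {
  counts <- matrix(rpois(30 * 12, 3), 30, 12)
  counts[counts == 0] <- 1   # keep the quantile rules inert
  qc <- data.frame(tss_enrichment = rep(5, 30), nucleosome_signal = rep(1, 30))
  m <- count_matrix(counts, modality = "PEAKS", qc = qc)
  out <- qc_filter_peaks(m)
  expect_equal(out$report$rules$tss_enrichment$removed, 0)
  expect_equal(out$report$rules$nucleosome_signal$removed, 0)

  qc$tss_enrichment[7] <- 1.9
  m2 <- count_matrix(counts, modality = "PEAKS", qc = qc)
  out2 <- qc_filter_peaks(m2)
  expect_equal(out2$report$rules$tss_enrichment$removed, 1)
  expect_false("cell_7" %in% out2$matrix$cell_ids)
})

test_that("peak detection-quantile filter matches a brute-force oracle", {
  set.seed(9)
  counts <- matrix(rbinom(200 * 50, 4, 0.4), 200, 50)
  m <- count_matrix(counts, modality = "PEAKS")
  out <- qc_filter_peaks(m)
  kept_cells <- match(out$matrix$cell_ids, m$cell_ids)
  det <- colSums(counts[kept_cells, ] > 0)
  qf <- quantile(det, c(0.05, 0.95), names = FALSE)
  expect_setequal(out$matrix$feature_ids,
                  sprintf("feat_%d", which(det >= qf[1] & det <= qf[2])))
})

test_that("QC is idempotent when the quantile boundaries land on tied mass", {
  # 5 sparse cells, 90 identical mid cells, 5 saturated cells: after one
  # pass only the tied mid block remains, so a second pass removes nothing
  counts <- rbind(
    t(sapply(1:5, function(i) c(rep(1, 2), rep(0, 58)))),
    matrix(rep(c(rep(1, 30), rep(0, 30)), 90), 90, 60, byrow = TRUE),
    matrix(1, 5, 60))
  m <- count_matrix(counts)
  once <- qc_filter_gex(m)
  expect_equal(n_cells(once$matrix), 90)
  twice <- qc_filter_gex(
    count_matrix(once$matrix$counts, cell_ids = once$matrix$cell_ids))
  expect_identical(twice$matrix$cell_ids, once$matrix$cell_ids)
})

test_that("library-size normalisation hits the target exactly", {
  m <- count_matrix(matrix(c(10, 40, 50, 30, 70, 100), 2, 3, byrow = TRUE))
  # totals 100 and 200, median 150
  out <- normalize_library_size(m)
  expect_equal(unname(rowSums(out$counts)), c(150, 150), tolerance = 1e-9)
  out2 <- normalize_library_size(m, target_sum = 200)
  expect_equal(out2$counts[1, ], m$counts[1, ] * 2, tolerance = 1e-12)
  expect_equal(out2$counts[2, ], m$counts[2, ] * 2 / 2, tolerance = 1e-12)

  same <- count_matrix(matrix(5, 4, 5))
  expect_equal(normalize_library_size(same)$counts, same$counts)
  expect_error(normalize_library_size(count_matrix(rbind(c(1, 1), c(0, 0)))),
               "QC")
})

test_that("HVG selection keeps the top-variance decile deterministically", {
  set.seed(13)
  counts <- matrix(rpois(50 * 100, 5), 50, 100)
  m <- normalize_library_size(count_matrix(counts))
  kept <- select_hvg_gex(m)
  expect_equal(n_features(kept), 10)
  v <- apply(m$counts, 2, var)
  oracle <- sort(order(-v, seq_along(v))[1:10])
  expect_identical(kept$feature_ids, m$feature_ids[oracle])

  const <- count_matrix(matrix(3, 30, 40), is_normalised = TRUE)
  expect_identical(select_hvg_gex(const)$feature_ids,
                   const$feature_ids[1:4])     # all-tied: first by index
  expect_error(select_hvg_gex(m, top_frac = 1.2), "top_frac")
})

test_that("HV-peak selection uses a strict variance quantile with a cap", {
  set.seed(17)
  counts <- matrix(rpois(60 * 100, 4), 60, 100) +
    matrix(rep(0:99, each = 60), 60, 100) %% 7   # make variances distinct-ish
  m <- count_matrix(counts, modality = "PEAKS")
  m <- normalize_library_size(m)
  v <- apply(m$counts, 2, var)
  expect_equal(length(unique(v)), 100)   # fixture sanity: no ties
  kept <- select_hv_peaks(m)
  expect_equal(n_features(kept), 20)
  expect_setequal(kept$feature_ids,
                  m$feature_ids[v > quantile(v, 0.8, names = FALSE)])
  capped <- select_hv_peaks(m, var_quantile = 0.5, max_features = 10)
  expect_equal(n_features(capped), 10)

  flat <- count_matrix(matrix(3, 20, 30), modality = "PEAKS",
                       is_normalised = TRUE)
  expect_error(select_hv_peaks(flat), "quantile")
})

test_that("log transform is log1p with a double-transform guard", {
  m <- count_matrix(matrix(c(0, exp(1) - 1, 3, 9), 2, 2),
                    is_normalised = TRUE)
  out <- log_transform(m)
  expect_equal(out$counts[1, 1], 0)
  expect_equal(out$counts[2, 1], 1)
  expect_true(all(diff(order(m$counts)) == diff(order(out$counts))))  # monotone
  expect_error(log_transform(out), "already")
  expect_error(log_transform(count_matrix(matrix(1, 2, 2))), "normalised")
})

test_that("Wilcoxon DA: exact small-sample p-value and tie behaviour", {
  counts <- cbind(c(1, 2, 3, 4, 5, 6), rep(2, 6))
  m <- count_matrix(counts, labels = c("A", "A", "A", "B", "B", "B"),
                    is_normalised = TRUE, is_log = TRUE)
  da <- wilcoxon_da(m, n_top = 2)
  tabA <- da$tables$A
  expect_equal(tabA$p_value[tabA$feature_id == "feat_1"], 0.1, tolerance = 1e-12)
  expect_lt(tabA$statistic[tabA$feature_id == "feat_1"], 0)  # A holds low values
  expect_equal(tabA$statistic[tabA$feature_id == "feat_2"], 0)  # constant feature
})

test_that("Wilcoxon DA agrees with exact permutation enumeration (n = 7)", {
  x <- c(0.3, 1.9, 2.5, 0.7, 1.1, 3.2, 0.2)
  labels <- c("A", "A", "A", "B", "B", "B", "B")
  m <- count_matrix(matrix(x, 7, 1), labels = labels,
                    is_normalised = TRUE, is_log = TRUE)
  da <- wilcoxon_da(m, n_top = 1)
  # enumeration oracle: all assignments of 3 ranks out of 7 to class A
  r <- rank(x)
  w_obs <- sum(r[labels == "A"])
  combos <- combn(7, 3)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]))
  mu <- 3 * 8 / 2
  p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(da$tables$A$p_value[1], p_exact, tolerance = 1e-12)
})

test_that("Wilcoxon DA recovers every planted marker in the top set", {
  m <- default_processed()
  da <- wilcoxon_da(m, n_top = 50)
  truth <- default_fixture()$truth
  for (c in seq_along(truth$marker_sets)) {
    ids <- m$feature_ids[truth$marker_sets[[c]]]
    expect_length(setdiff(ids, da$top[[sprintf("type_%d", c)]]), 0)
  }
})

test_that("Wilcoxon DA rejects unusable inputs", {
  m <- count_matrix(matrix(1:4, 2, 2), labels = c("A", "B"),
                    is_normalised = TRUE, is_log = TRUE)
  expect_error(wilcoxon_da(m), "fewer than 2")
  m2 <- count_matrix(matrix(1:4, 2, 2), is_normalised = TRUE, is_log = TRUE)
  expect_error(wilcoxon_da(m2), "labels")
})
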