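test_that("layer sizes follow the square-root / cube-root rules", {
  s <- layer_sizes(1000)
  expect_equal(s$latent_dim, 10L)
  expect_equal(layer_sizes(10000)$hidden_dim, 100L)
  s27 <- layer_sizes(27)
  expect_equal(s27$hidden_dim, 6L)
  expect_equal(s27$latent_dim, 3L)
  expect_true(s27$latent_dim < s27$hidden_dim && s27$hidden_dim < 27)
})

test_that("total loss decomposes into reconstruction + weighted geometric term", {
  m <- small_processed()
  xi <- phate_embed(m, seed = 3, mds_max_iter = 10)
  cfg <- train_config(lambda_geo = 0.25, max_epochs = 40, patience = 40, seed = 3)
  fit <- train_grae(m, xi, cfg)
  expect_lt(max(abs(fit$history$train_loss -
                    (fit$history$recon + 0.25 * fit$history$geo))), 1e-6)
})

test_that("zero geometric weight reproduces the vanilla AE epoch by epoch", {
  m <- small_processed()
  xi <- phate_embed(m, seed = 3, mds_max_iter = 10)
  cfg <- train_config(lambda_geo = 0, max_epochs = 60, patience = 60, seed = 9)
  g0 <- train_grae(m, xi, cfg)
  ae <- train_ae(m, cfg)
  expect_equal(nrow(g0$history), nrow(ae$history))
  expect_lt(max(abs(g0$history$train_loss - ae$history$train_loss)), 1e-6)
  expect_lt(max(abs(g0$history$val_loss - ae$history$val_loss)), 1e-6)
})

test_that("a dominant geometric weight pins the latent to the target", {
  r <- generate_counts(synthetic_spec(n_cells = 150, n_features = 60,
                                      n_types = 2, markers_per_type = 10,
                                      effect_log2fc = 3, seed = 5))
  m <- log_transform(normalize_library_size(r$matrix))
  xi <- phate_embed(m, seed = 5, mds_max_iter = 20)
  fit <- train_grae(m, xi, train_config(lambda_geo = 1e6, max_epochs = 300,
                                        patience = 300, seed = 5))
  expect_lt(tail(fit$history$geo, 1), fit$history$geo[1] / 10)
})

test_that("training history respects the early-stopping contract", {
  m <- small_processed()
  xi <- phate_embed(m, seed = 3, mds_max_iter = 10)
  fit <- train_grae(m, xi, train_config(seed = 3))
  expect_lte(nrow(fit$history), 300)
  best_so_far <- cummin(fit$history$val_loss)
  expect_true(all(diff(best_so_far) <= 0))
  # best-epoch weights are restored: the recorded best epoch is where the
  # minimum validation loss occurred
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
})

test_that("identical configurations reproduce identical histories", {
  m <- small_processed()
  xi <- phate_embed(m, seed = 3, mds_max_iter = 10)
  cfg <- train_config(max_epochs = 30, patience = 30, seed = 12)
  a <- train_grae(m, xi, cfg)
  b <- train_grae(m, xi, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$latent, b$latent)
})

test_that("PCA is exact on data lying in a low-dimensional affine subspace", {
  set.seed(6)
  basis <- matrix(runif(3 * 20), 3, 20)
  scores <- matrix(runif(80 * 3, 1, 4), 80, 3)
  m <- count_matrix(scores %*% basis, is_normalised = TRUE)
  fit <- pca_embed(m, latent_dim = 3)
  expect_lt(mse(m$counts, reconstruct(fit, m)), 1e-8)
  expect_error(pca_embed(count_matrix(matrix(1:12, 4, 3)), latent_dim = 3),
               "latent_dim")
})

test_that("the VAE anneals its KL weight from zero", {
  m <- small_processed()
  fit <- train_vae(m, train_config(max_epochs = 20, patience = 20, seed = 4))
  h <- fit$history
  # at epoch 1 beta = 0: the objective is the reconstruction term alone
  expect_equal(h$train_loss[1], h$recon[1], tolerance = 1e-12)
  expect_true(all(h$kl >= 0))
})

test_that("the AE drives a constant matrix to near-zero reconstruction error", {
  m <- count_matrix(matrix(1, 60, 20), is_normalised = TRUE)
  fit <- train_ae(m, train_config(lr = 0.01, seed = 2))
  expect_lt(mse(m$counts, reconstruct(fit, m)), 1e-3)
})

test_that("reconstruction keeps shapes and beats the zero predictor", {
  m <- separable_processed()
  pipe <- sep_pipeline(1)
  xh <- reconstruct(pipe$grae, m)
  expect_equal(dim(xh), dim(m$counts))
  expect_lt(mse(m$counts, xh), mean(m$counts^2))
  expect_error(reconstruct(pipe$grae, m$counts[, 1:10]), "features")
})

test_that("row-misaligned geometry targets are rejected", {
  m <- small_processed()
  xi <- phate_embed(m, seed = 3, mds_max_iter = 10)
  bad <- xi; bad$coords <- bad$coords[1:100, ]
  expect_error(train_grae(m, bad), "rows")
})

test_that("feature corruption zeroes exactly the sampled columns", {
  m <- count_matrix(matrix(rpois(40 * 100, 4), 40, 100))
  none <- corrupt_dropout(m, 0, seed = 1)
  expect_identical(none$matrix$counts, m$counts)
  expect_length(none$dropped, 0)

  crp <- corrupt_dropout(m, 0.3, seed = 1)
  zero_cols <- which(colSums(crp$matrix$counts) == 0)
  expect_length(crp$dropped, 30)
  expect_setequal(zero_cols, crp$dropped)
  # closed-form MSE of the corruption itself
  expect_equal(mse(m$counts, crp$matrix$counts),
               sum(m$counts[, crp$dropped]^2) / length(m$counts),
               tolerance = 1e-12)
  # same seed, same columns
  expect_identical(corrupt_dropout(m, 0.3, seed = 1)$dropped, crp$dropped)
})
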