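test_that("patch extraction honors labels, edges and invalid neighbors", {
  toy <- calib_toy_data(n_slices = 1, h = 10, seed = 2)
  cfg <- calib_config(patch_size = 5L, width_base = 2L)
  ps <- extract_patches(toy$t1, toy$labels, cfg, target = toy$t1)
  expect_equal(ps$n, 100L)          # one sample per (all-WM) voxel
  expect_equal(dim(ps$x), c(1L, 25L * 100L))
  expect_equal(ps$y, toy$t1[cbind(ps$meta$row, ps$meta$col, ps$meta$slice)])
  # degenerate 1x1 patches equal the center value
  cfg1 <- calib_config(patch_size = 1L, width_base = 2L)
  ps1 <- extract_patches(toy$t1, toy$labels, cfg1, target = toy$t1)
  expect_equal(as.numeric(ps1$x), ps1$y)
  # CSF centers are excluded
  labels2 <- toy$labels
  labels2[1:5, , 1] <- tissue_codes["CSF"]
  ps2 <- extract_patches(toy$t1, labels2, cfg, target = toy$t1)
  expect_equal(ps2$n, 50L)
  expect_true(all(ps2$meta$tissue == "WM"))
  # an invalid neighbor is replaced by the center value
  t1map <- mapt1:::new_t1_map(toy$t1, array(TRUE, toy$shape), "sir")
  t1map$valid_mask[3, 3, 1] <- FALSE
  t1map$t1_s[3, 3, 1] <- NA
  ps3 <- extract_patches(t1map, toy$labels, cfg)
  i44 <- which(ps3$meta$row == 4 & ps3$meta$col == 4)
  patch <- ps3$x[1, (i44 - 1) * 25 + 1:25]
  # offset (-1, -1) is the 7th pixel of the (row-fastest) 5x5 window
  expect_equal(patch[7], toy$t1[4, 4, 1])
  expect_error(extract_patches(toy$t1, array(0L, toy$shape), cfg),
               "no eligible patch centers")
})

test_that("channel contracts are enforced end to end", {
  toy <- calib_toy_data(n_slices = 1, h = 10)
  cfg2 <- calib_config(patch_size = 5L, in_channels = 2L, width_base = 2L)
  expect_error(extract_patches(toy$t1, toy$labels, cfg2), "no sigma")
  cfg1 <- calib_config(patch_size = 5L, width_base = 2L)
  expect_error(extract_patches(toy$t1, toy$labels, cfg1, sigma = toy$t1),
               "in_channels is 1")
  m1 <- build_regressor(cfg1)
  expect_error(apply_calibrator(m1, toy$t1, toy$labels, cfg2),
               "patch")
  # a 2-channel extraction feeds a 2-channel model
  ps2 <- extract_patches(toy$t1, toy$labels, cfg2, sigma = toy$t1 * 0.1)
  expect_equal(nrow(ps2$x), 2L)
})

test_that("training learns the identity mapping on patch centers", {
  toy <- calib_toy_data(n_slices = 2, h = 20, seed = 4)
  cfg <- calib_config(patch_size = 5L, width_base = 2L, batch_size = 64L,
                      learning_rate = 3e-3, max_steps = 600L,
                      val_every = 50L, patience_steps = 600L, seed = 2L)
  ps <- extract_patches(toy$t1, toy$labels, cfg, target = toy$t1)
  idx_tr <- seq_len(500); idx_va <- 501:700
  split <- function(ps, idx) list(
    x = ps$x[, mapt1:::.patch_cols(idx, 25L), drop = FALSE],
    y = ps$y[idx], n = length(idx), patch = 5L, channels = 1L)
  tr <- train_calibrator(split(ps, idx_tr), split(ps, idx_va), cfg)
  expect_lt(tr$best_val, 0.1 * stats::var(ps$y[idx_va]))
  expect_lte(tr$best_step, tr$steps_run)
  # early stopping never returns a checkpoint worse than the best observed
  expect_equal(tr$best_val, min(tr$history$val_mse))
})

test_that("training recovers a constant offset on held-out samples", {
  toy <- calib_toy_data(n_slices = 2, h = 20, seed = 6)
  cfg <- calib_config(patch_size = 5L, width_base = 2L, batch_size = 64L,
                      learning_rate = 3e-3, max_steps = 600L,
                      val_every = 50L, patience_steps = 600L, seed = 3L)
  target <- toy$t1 + 0.3
  ps <- extract_patches(toy$t1, toy$labels, cfg, target = target)
  idx_tr <- seq_len(450); idx_va <- 451:600; idx_te <- 601:800
  split <- function(idx) list(
    x = ps$x[, mapt1:::.patch_cols(idx, 25L), drop = FALSE],
    y = ps$y[idx], n = length(idx), patch = 5L, channels = 1L)
  tr <- train_calibrator(split(idx_tr), split(idx_va), cfg)
  pred <- mapt1:::nn_predict(tr$model, split(idx_te)$x, length(idx_te))
  expect_lt(abs(mean(pred - ps$y[idx_te])), 0.05)
})

test_that("flat validation loss exhausts patience before max_steps", {
  toy <- calib_toy_data(n_slices = 1, h = 14, seed = 8)
  cfg <- calib_config(patch_size = 5L, width_base = 2L, batch_size = 32L,
                      learning_rate = 1e-9, max_steps = 5000L,
                      val_every = 50L, patience_steps = 200L, seed = 4L)
  set.seed(1)
  target <- array(rnorm(prod(toy$shape)), toy$shape)  # unlearnable noise
  ps <- extract_patches(toy$t1, toy$labels, cfg, target = target)
  idx <- seq_len(ps$n)
  half <- split(idx, idx <= ps$n / 2)
  mk <- function(ii) list(x = ps$x[, mapt1:::.patch_cols(ii, 25L), drop = FALSE],
                          y = ps$y[ii], n = length(ii), patch = 5L,
                          channels = 1L)
  tr <- train_calibrator(mk(half[[2]]), mk(half[[1]]), cfg)
  expect_lt(tr$steps_run, cfg$max_steps)
})

test_that("calibrator application is deterministic and masks non-brain", {
  toy <- calib_toy_data(n_slices = 1, h = 12, seed = 5)
  labels <- toy$labels
  labels[, 1:3, 1] <- tissue_codes["CSF"]
  cfg <- calib_config(patch_size = 5L, width_base = 2L, seed = 6L)
  m <- build_regressor(cfg)
  a <- apply_calibrator(m, toy$t1, labels, cfg)
  b <- apply_calibrator(m, toy$t1, labels, cfg)
  expect_identical(a$t1_s, b$t1_s)
  expect_false(any(a$valid_mask[, 1:3, 1]))
  expect_true(all(a$valid_mask[, 4:12, 1]))
  expect_equal(a$method, "calibrated")
  # all-CSF labels leave nothing to calibrate
  expect_error(apply_calibrator(m, toy$t1,
                                array(tissue_codes["CSF"], toy$shape), cfg),
               "no eligible")
})

test_that("cross-validation rotates folds without subject leakage", {
  spec <- tiny_spec()
  subs <- synth_subjects(spec, n = 4)
  cfg <- calib_config(patch_size = 5L, width_base = 2L, batch_size = 32L,
                      learning_rate = 1e-3, max_steps = 60L, val_every = 30L,
                      patience_steps = 60L, seed = 9L)
  cv <- loo_cv(subs, cfg, val_max = 300)
  expect_setequal(unique(cv$folds$test_subject), 1:4)
  expect_equal(nrow(cv$folds), 12L)  # 4 folds x 3 tissues
  expect_false(cv$ttest$degenerate)
  expect_error(loo_cv(subs[1:3], cfg), ">= 4 subjects")
  # same data and seeds reproduce identical metrics
  cv2 <- loo_cv(subs, cfg, val_max = 300)
  expect_identical(cv$folds$rmse_calibrated_s, cv2$folds$rmse_calibrated_s)
})
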