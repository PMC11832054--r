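test_that("cube erosion matches brute-force morphology", {
  labels <- array(0L, c(9, 9, 9))
  labels[3:7, 3:7, 3:7] <- tissue_codes["CGM"]  # 5^3 solid cube
  er <- erode_labels(labels, "CGM", 3L)
  expect_equal(sum(er == tissue_codes["CGM"]), 27L)  # 3^3 core
  oracle <- erode_bruteforce(labels == tissue_codes["CGM"], 1L)
  expect_identical(er == tissue_codes["CGM"], oracle)
  # identity at cube side 1
  expect_identical(erode_labels(labels, "CGM", 1L), labels)
  # a slab thinner than the cube erodes away entirely
  thin <- array(0L, c(9, 9, 3))
  thin[2:8, 2:8, 1:2] <- tissue_codes["CGM"]
  expect_equal(sum(erode_labels(thin, "CGM", 3L) == tissue_codes["CGM"]), 0L)
  expect_warning(er2 <- erode_labels(labels, "WM", 3L), "absent")
  expect_identical(er2, labels)
  # random shapes against the oracle
  set.seed(7)
  m <- array(runif(5 * 6 * 4) > 0.4, c(5, 6, 4))
  lr <- array(0L, dim(m)); lr[m] <- tissue_codes["WM"]
  expect_identical(erode_labels(lr, "WM", 3L) == tissue_codes["WM"],
                   erode_bruteforce(m, 1L))
})

test_that("per-tissue RMSE behaves on exact, biased and noisy errors", {
  spec <- tiny_spec()
  ph <- make_phantom(spec, 1)
  expect_equal(unname(rmse_by_tissue(ph$true_t1, ph$true_t1, ph$labels)),
               c(0, 0, 0))
  shifted <- ph$true_t1 + 0.3
  expect_equal(unname(rmse_by_tissue(shifted, ph$true_t1, ph$labels)),
               rep(0.3, 3), tolerance = 1e-12)
  set.seed(8)
  big <- array(1.5, c(40, 50, 5)); labs <- array(tissue_codes["WM"],
                                                 c(40, 50, 5))
  noisy <- big + rnorm(1e4, 0, 0.1)
  expect_equal(unname(rmse_by_tissue(noisy, big, labs)["WM"]), 0.1,
               tolerance = 0.05)
})

test_that("relative values reproduce configured ratios", {
  spec <- tiny_spec()
  ph <- make_phantom(spec, 1)
  expect_equal(unname(relative_value_by_tissue(ph$true_t1, ph$true_t1,
                                               ph$labels)),
               rep(100, 3))
  expect_equal(unname(relative_value_by_tissue(0.828 * ph$true_t1,
                                               ph$true_t1, ph$labels)),
               rep(82.8, 3), tolerance = 1e-9)
  expect_equal(unname(relative_value_by_tissue(1.016 * ph$true_t1,
                                               ph$true_t1, ph$labels)),
               rep(101.6, 3), tolerance = 1e-9)
})

test_that("Bland-Altman components satisfy the exact decomposition", {
  spec <- tiny_spec()
  ph <- make_phantom(spec, 1)
  ba0 <- bland_altman(ph$true_t1, ph$true_t1, ph$labels)
  expect_equal(ba0$bias_s, rep(0, 3))
  expect_equal(ba0$loa_low_s, rep(0, 3))
  ba <- bland_altman(ph$true_t1 + 0.2, ph$true_t1, ph$labels)
  expect_equal(ba$bias_s, rep(0.2, 3), tolerance = 1e-12)
  expect_equal(ba$sd_s, rep(0, 3))
  expect_equal(ba$rmse_s, rep(0.2, 3), tolerance = 1e-12)
  # sampling oracle with known bias and spread
  set.seed(9)
  big <- array(2, c(40, 50, 5)); labs <- array(tissue_codes["SGM"],
                                               c(40, 50, 5))
  err <- rnorm(1e4, 0.1, 0.05)
  ba2 <- bland_altman(big + err, big, labs, tissues = "SGM")
  expect_equal(ba2$bias_s, 0.1, tolerance = 0.05)
  expect_equal(ba2$sd_s, 0.05, tolerance = 0.05)
  expect_lt(abs(ba2$rmse_s^2 - (ba2$bias_s^2 + ba2$error_variance_s2)),
            1e-12)
  expect_equal(ba2$loa_high_s - ba2$loa_low_s, 2 * 1.96 * ba2$sd_s,
               tolerance = 1e-12)
})

test_that("the paired test matches its closed form and flags degeneracy", {
  d <- c(0.19, 0.16, 0.20, 0.21)
  res <- paired_t(d, rep(0, 4))
  t_manual <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t_statistic, t_manual)
  expect_equal(res$p_value,
               2 * stats::pt(-abs(t_manual), df = 3))
  expect_true(res$significant_at_0p05)
  # antisymmetry
  swapped <- paired_t(rep(0, 4), d)
  expect_equal(swapped$t_statistic, -res$t_statistic)
  expect_equal(swapped$p_value, res$p_value)
  # identical vectors are degenerate, not significant
  dg <- paired_t(d, d)
  expect_true(dg$degenerate)
  expect_false(dg$significant_at_0p05)
})

test_that("masked voxels are excluded via the validity intersection", {
  spec <- tiny_spec()
  ph <- make_phantom(spec, 1)
  a <- mapt1:::new_t1_map(ph$true_t1 + 1, array(TRUE, spec$shape), "sir")
  wm <- which(ph$labels == tissue_codes["WM"])
  a$valid_mask[wm[1:10]] <- FALSE
  ba <- bland_altman(a, ph$true_t1, ph$labels)
  expect_equal(ba$n_voxels[ba$tissue == "WM"], length(wm) - 10L)
})
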