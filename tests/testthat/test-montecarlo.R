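protocol <- default_protocol()

test_that("histogram counts are conserved and normalizations hold", {
  cfg <- mc_config(n_trials = 1e5, noise_sigma = 0.005, seed = 4)
  pg <- run_monte_carlo(protocol, 1, cfg, "pair")
  expect_identical(sum(pg$counts), 1e5L)  # uniform-image bound: no draw dropped
  L <- posterior_likelihood(pg)
  expect_lt(max(abs(rowSums(L) - 1)), 1e-9)
  P <- posterior_distribution(pg)
  cs <- colSums(P)
  expect_lt(max(abs(cs[is.finite(cs)] - 1)), 1e-6)
  expect_true(all(pg$counts >= 0))
})

test_that("identical seed and config reproduce bit-identical grids", {
  cfg <- mc_config(n_trials = 5e4, noise_sigma = 0.005, seed = 11)
  a <- run_monte_carlo(protocol, 1, cfg, "pair")
  b <- run_monte_carlo(protocol, 1, cfg, "pair")
  expect_identical(a$counts, b$counts)
  expect_identical(a$map_t1, b$map_t1)
})

test_that("near-zero noise concentrates each T1 row on its noiseless bin", {
  cfg <- mc_config(n_trials = 2e4, noise_sigma = 1e-6, seed = 5)
  pg <- run_monte_carlo(protocol, 1, cfg, "pair")
  s0 <- forward_s12(cfg$t1_grid, protocol)
  bin0 <- mapt1:::.s_bin(s0, cfg$signal_bins)
  for (i in seq(1, length(cfg$t1_grid), by = 7)) {
    expect_identical(unname(which(pg$counts[i, ] > 0)), unname(bin0[i]))
    expect_identical(unname(pg$counts[i, bin0[i]]), unname(sum(pg$counts[i, ])))
  }
})

test_that("argmax ties break toward the smaller T1", {
  # two close T1 values whose noiseless signals share one bin, equal trials
  cfg <- mc_config(n_trials = 2000, noise_sigma = 1e-6,
                   t1_grid = c(1.50, 1.502), seed = 6)
  pg <- run_monte_carlo(protocol, 1, cfg, "pair")
  j <- which(pg$bin_colsum > 0)
  expect_length(j, 1L)
  expect_identical(unname(pg$counts[1, j]), unname(pg$counts[2, j]))
  expect_equal(pg$map_t1[j], 1.50)
})

test_that("noise-dominated posteriors approach the uniform-prior spread", {
  # at absurd noise the signal carries no information, so each posterior
  # column tends to the uniform distribution over (0, 5]: sd -> 5/sqrt(12)
  cfg <- mc_config(n_trials = 4e5, noise_sigma = 50, seed = 7)
  pg <- run_monte_carlo(protocol, 1, cfg, "pair")
  med <- stats::median(pg$map_sigma[pg$valid_bin])
  expect_equal(med, 5 / sqrt(12), tolerance = 0.02)
})

test_that("MAP agrees with the point estimate in the low-noise limit", {
  cfg <- mc_config(n_trials = 1e5, noise_sigma = 1e-4, seed = 8)
  pg <- run_monte_carlo(protocol, 1, cfg, "pair")
  lk <- build_lookup(protocol)
  tt <- seq(0.5, 3.5, by = 0.02)
  s <- forward_s12(tt, protocol)
  est <- map_estimate(pg, s)
  pe <- lookup_t1(lk, s)
  expect_true(all(est$valid))
  step <- diff(cfg$t1_grid)[1]
  expect_lte(max(abs(est$t1 - pe)), 2 * step)
})

test_that("posterior uncertainty grows monotonically with the noise level", {
  meds <- vapply(c(0.001, 0.005, 0.01, 0.015, 0.02), function(sg) {
    cfg <- mc_config(n_trials = 2e5, noise_sigma = sg, seed = 13)
    pg <- run_monte_carlo(protocol, 1, cfg, "pair")
    stats::median(pg$map_sigma[pg$valid_bin])
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("MAP volume mapping recovers truth and the joint mode tightens it", {
  spec <- tiny_spec()
  ph <- make_phantom(spec, 1)
  g <- simulate_mp3rage(ph$true_t1, ph$b1, protocol, 0.005, seed = 21)
  cfg <- mc_config(n_trials = 1e6, noise_sigma = 0.005, seed = 21)
  mp <- map_t1_volume(g, ph$b1, protocol, cfg, "pair")
  vox <- mp$valid_mask & ph$labels > 0 & ph$labels != tissue_codes["CSF"]
  expect_gt(mean(vox[ph$labels > 0]), 0.5)
  med_err <- stats::median(abs(mp$t1_s[vox] - ph$true_t1[vox]))
  expect_lt(med_err, 0.5)  # sigma = 0.005 is noisy; tightness tested at 0.001
  mj <- map_t1_volume(g, ph$b1, protocol, cfg, "joint")
  both <- mp$valid_mask & mj$valid_mask
  expect_lte(stats::median(mj$sigma_t1_s[both]),
             stats::median(mp$sigma_t1_s[both]))
  # all-zero acquisitions yield no valid voxel
  z <- lapply(1:3, function(k) array(0 + 0i, dim(ph$b1)))
  mz <- map_t1_volume(z, ph$b1, protocol, cfg, "pair")
  expect_false(any(mz$valid_mask))
})

test_that("a mismatched B1 table biases the MAP estimate", {
  cfg <- mc_config(n_trials = 2e5, noise_sigma = 1e-3, seed = 3)
  pg <- run_monte_carlo(protocol, 1.0, cfg, "pair")
  s <- forward_s12(1.5, protocol, b1 = 0.8)  # acquired at B1 = 0.8
  est <- map_estimate(pg, s)
  expect_true(est$valid)
  expect_gte(abs(est$t1 - 1.5), 0.03)
})

test_that("ROI noise estimation takes the scaled channel maximum", {
  dims <- c(10, 10, 10)
  set.seed(31)
  g1 <- array(complex(real = 5 + rnorm(1000, 0, 0.01),
                      imaginary = rnorm(1000, 0, 0.005)), dims)
  g2 <- array(complex(real = 5 + rnorm(1000, 0, 0.02),
                      imaginary = rnorm(1000, 0, 0.01)), dims)
  roi <- array(TRUE, dims)
  est <- estimate_noise_roi(list(g1, g2), roi)
  expect_equal(est$sigma, 0.02, tolerance = 0.1)
  expect_equal(est$roi_voxel_count, 1000L)
  expect_equal(dim(est$per_channel_sds), c(2L, 2L))
  expect_equal(est$sigma, max(est$per_channel_sds))
  # degenerate constant ROI
  gc <- array(1 + 0i, dims)
  expect_error(estimate_noise_roi(list(gc), roi), "zero variance")
  expect_error(estimate_noise_roi(list(g1), array(FALSE, dims)), "ROI too small")
})

test_that("posterior tables round-trip through the cache format", {
  cfg <- mc_config(n_trials = 2e4, noise_sigma = 0.005, seed = 2)
  pg <- run_monte_carlo(protocol, 1, cfg, "pair")
  path <- tempfile(fileext = ".rds")
  write_posterior(pg, path)
  back <- read_posterior(path)
  expect_identical(back$counts, pg$counts)
  # corrupt the cache: fingerprint must reject it
  bad <- readRDS(path)
  bad$counts[1, 1] <- bad$counts[1, 1] + 5L
  saveRDS(bad, path)
  expect_error(read_posterior(path), "fingerprint")
})
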