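protocol <- default_protocol()

test_that("phantom geometry is deterministic with all tissues represented", {
  spec <- phantom_spec(seed = 3)
  a <- make_phantom(spec, 1)
  b <- make_phantom(spec, 1)
  expect_identical(a$labels, b$labels)
  expect_identical(a$true_t1, b$true_t1)
  expect_identical(a$b1, b$b1)
  counts <- table(a$labels)
  expect_true(all(counts[as.character(tissue_codes)] >= 50))
  expect_true(all(a$b1 >= 0.7 & a$b1 <= 1.3))
  c2 <- make_phantom(spec, 2)
  expect_false(identical(a$true_t1, c2$true_t1))  # subject jitter differs
})

test_that("zero jitter reproduces the configured tissue truths exactly", {
  spec <- phantom_spec(inter_subject_jitter = 0, seed = 3)
  ph <- make_phantom(spec, 1)
  expect_true(all(ph$true_t1[ph$labels == tissue_codes["WM"]] == 1.48))
  expect_true(all(ph$true_t1[ph$labels == tissue_codes["CGM"]] == 2.05))
  expect_true(all(is.na(ph$true_t1[ph$labels == 0])))
})

test_that("noiseless simulated GREs reproduce the forward model exactly", {
  spec <- tiny_spec()
  ph <- make_phantom(spec, 1)
  g <- simulate_mp3rage(ph$true_t1, ph$b1, protocol, sigma = 0, seed = 1)
  s12 <- uniform_signal(g[[1]], g[[2]])
  vox <- which(ph$labels > 0)[seq(1, 400, by = 23)]
  expect_equal(s12[vox],
               vapply(vox, function(v) forward_s12(ph$true_t1[v], protocol,
                                                   ph$b1[v]), numeric(1)),
               tolerance = 1e-12)
  # background is exactly zero without noise
  expect_true(all(g[[1]][ph$labels == 0] == 0))
})

test_that("noise draws differ by seed while ideal signals are shared", {
  spec <- tiny_spec()
  ph <- make_phantom(spec, 1)
  g1 <- simulate_mp3rage(ph$true_t1, ph$b1, protocol, 0.005, seed = 1)
  g2 <- simulate_mp3rage(ph$true_t1, ph$b1, protocol, 0.005, seed = 2)
  g1b <- simulate_mp3rage(ph$true_t1, ph$b1, protocol, 0.005, seed = 1)
  expect_false(identical(g1[[1]], g2[[1]]))
  expect_identical(g1[[1]], g1b[[1]])
  g0a <- simulate_mp3rage(ph$true_t1, ph$b1, protocol, 0, seed = 1)
  g0b <- simulate_mp3rage(ph$true_t1, ph$b1, protocol, 0, seed = 2)
  expect_identical(g0a, g0b)
})

test_that("tissue bias injection applies the configured factors", {
  spec <- phantom_spec(inter_subject_jitter = 0, bias_field_amplitude = 0,
                       seed = 3)
  ph <- make_phantom(spec, 1)
  biased <- inject_tissue_bias(ph$true_t1, ph$labels, spec)
  wm <- ph$labels == tissue_codes["WM"]
  expect_equal(unique(biased[wm]), 1.48 * 0.828, tolerance = 1e-12)
  # CSF and background untouched
  expect_identical(biased[ph$labels == tissue_codes["CSF"]],
                   ph$true_t1[ph$labels == tissue_codes["CSF"]])
  expect_identical(biased[ph$labels == 0], ph$true_t1[ph$labels == 0])
  # identity configuration
  spec1 <- phantom_spec(inter_subject_jitter = 0, bias_field_amplitude = 0,
                        bias_factors = c(WM = 1, SGM = 1, CGM = 1), seed = 3)
  expect_equal(inject_tissue_bias(ph$true_t1, ph$labels, spec1), ph$true_t1)
})

test_that("measured relative values close on the configured bias factors", {
  # the bias field is zero-mean within each tissue, so the ratio of tissue
  # means must equal the configured factor to float precision
  spec <- phantom_spec(seed = 9)
  ph <- make_phantom(spec, 2)
  biased <- inject_tissue_bias(ph$true_t1, ph$labels, spec)
  rel <- relative_value_by_tissue(biased, ph$true_t1, ph$labels)
  expect_equal(unname(rel), c(82.8, 89.1, 95.3), tolerance = 1e-9)
})

test_that("simulated SIR volumes recover truth and saturate at long TI", {
  spec <- tiny_spec(tissue_sir = list(
    WM = list(psr = 0, kmf = 0, sf = -0.95),
    SGM = list(psr = 0, kmf = 0, sf = -0.95),
    CGM = list(psr = 0, kmf = 0, sf = -0.95),
    CSF = list(psr = 0, kmf = 0, sf = -0.95)))
  ph <- make_phantom(spec, 1)
  sirv <- simulate_sir(ph$true_t1, ph$labels, spec, sigma = 0, seed = 1)
  expect_identical(sirv, simulate_sir(ph$true_t1, ph$labels, spec,
                                      sigma = 0, seed = 1))
  # single-pool round trip on a few voxels
  vox <- which(ph$labels %in% tissue_codes[c("WM", "CGM")])[c(1, 40, 200)]
  shp <- prod(spec$shape)
  for (v in vox) {
    sig <- sirv[cbind(arrayInd(v, spec$shape)[rep(1, 13), ], 1:13)]
    ft <- fit_sir(sig, sm = 0.83)
    expect_lt(abs(ft$t1_s - ph$true_t1[v]) / ph$true_t1[v], 0.005)
  }
  # recovery at ti = 8 s: the residual deviation from m0f is exp(-8/T1)
  # (inversion starts near saturation), i.e. < 1% only for T1 below ~1.7 s
  last <- sirv[, , , 13]
  wm <- ph$labels == tissue_codes["WM"]
  expect_true(all(abs(last[wm] - 1) < 0.01))
  tis <- ph$labels %in% tissue_codes[c("WM", "SGM", "CGM")]
  dev_bound <- exp(-8 / (ph$true_t1 * 1.01)) + 1e-3
  expect_true(all(abs(last[tis] - 1) <= dev_bound[tis]))
})

test_that("subject cohorts are reproducible and manifest round-trips", {
  spec <- tiny_spec()
  subs <- synth_subjects(spec, n = 4)
  expect_length(subs, 4)
  jits <- vapply(subs, function(s) s$true_t1[which(s$labels == 2)[1]],
                 numeric(1))
  expect_equal(length(unique(jits)), 4)  # distinct per-subject jitter
  dir <- tempfile("cohort_")
  man <- write_subjects(subs, dir, spec)
  back <- read_subjects(man)
  expect_equal(back[[2]]$labels, subs[[2]]$labels)
  expect_equal(back[[2]]$mp2rage_biased, subs[[2]]$mp2rage_biased,
               tolerance = 1e-6)
  expect_equal(Re(back[[3]]$gres[[1]]), Re(subs[[3]]$gres[[1]]),
               tolerance = 1e-6)
})
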