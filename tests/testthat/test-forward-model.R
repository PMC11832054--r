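test_that("block timing decomposition reproduces the printed protocol", {
  p <- default_protocol()
  tm <- derive_block_timing(p)
  expect_equal(tm$pre_first_block_s, 0.335, tolerance = 1e-12)
  expect_equal(tm$inter_block_gaps_s, c(1.323, 1.322), tolerance = 1e-12)
  expect_equal(tm$post_last_block_s, 1.220, tolerance = 1e-12)
  expect_equal(tm$block_duration_s, 1.350, tolerance = 1e-12)
  total <- tm$pre_first_block_s + 3 * tm$block_duration_s +
    sum(tm$inter_block_gaps_s) + tm$post_last_block_s
  expect_equal(total, p$cycle_tr_s, tolerance = 1e-12)
})

test_that("timing handles the exactly-zero gap and rejects negative delays", {
  p <- acq_params(c(1.0, 2.0), 0.004, 4.0, 250, 4)
  tm <- derive_block_timing(p)
  expect_equal(tm$block_duration_s, 1.0)
  expect_equal(tm$pre_first_block_s, 0.5)
  expect_equal(tm$inter_block_gaps_s, 0)
  expect_equal(tm$post_last_block_s, 1.5)
  expect_error(acq_params(c(0.5, 2.0), 0.006, 8.25, 225, 4),
               "TA.*< 0")
  expect_error(acq_params(c(1.0, 0.5), 0.006, 8.25, 225, 4),
               "strictly increasing")
})

test_that("closed-form steady state matches per-excitation cycle iteration", {
  p <- default_protocol()
  t1 <- seq(0.05, 5, length.out = 120)  # the full 500-point sweep runs in
  # the acceptance suite; this spot-checks the oracle wiring
  mss <- mp2rage_steady_state(t1, p)
  it <- iterate_cycles_mz(t1, p, ncycles = 60)
  expect_lt(max(abs(mss - it)), 1e-10)
})

test_that("signals vanish for zero flip angle or zero B1", {
  p0 <- acq_params(c(1.010, 3.683, 6.355), 0.006, 8.25, 225, 0, 0.84)
  expect_equal(mp2rage_signals(c(0.5, 1.5, 3), p0),
               matrix(0, 3, 3))
  p <- default_protocol()
  expect_equal(mp2rage_signals(1.5, p, b1 = 0), rep(0, 3))
  expect_error(mp2rage_signals(-1, p), "> 0")
})

test_that("S1,2 is strictly monotone and continuous in T1", {
  p <- default_protocol()
  grid <- seq(0.3, 5, length.out = 500)
  s <- forward_s12(grid, p)
  expect_true(all(diff(s) < 0))
  expect_lt(max(abs(diff(s))), 0.05)
})

test_that("uniform image evaluates the complex combination with its bound", {
  expect_equal(uniform_signal(1 + 0i, 1 + 0i), 0.5)
  expect_equal(uniform_signal(0 + 1i, 1 + 0i), 0.0)
  expect_equal(uniform_signal(3 + 0i, -4 + 0i), -0.48)
  expect_equal(uniform_signal(0 + 0i, 0 + 0i), 0)  # 0/0 convention
  set.seed(12)
  n <- 1e4
  a <- complex(real = rnorm(n), imaginary = rnorm(n))
  b <- complex(real = rnorm(n), imaginary = rnorm(n))
  expect_true(all(abs(uniform_signal(a, b)) <= 0.5))
  expect_error(uniform_signal(matrix(1 + 0i, 2, 2), matrix(1 + 0i, 2, 3)),
               "shape")
})

test_that("robust uniform image reduces to the plain one and damps zeros", {
  set.seed(3)
  a <- complex(real = rnorm(8), imaginary = rnorm(8))
  b <- complex(real = rnorm(8), imaginary = rnorm(8))
  expect_equal(robust_uniform_signal(a, b, beta_fraction = 0),
               uniform_signal(a, b))
  z <- complex(real = numeric(4))
  expect_equal(robust_uniform_signal(z, z, beta_fraction = 0.25), rep(0, 4))
  expect_equal(robust_uniform_signal(1 + 0i, 1 + 0i, beta = 2), 1 / 4)
})

test_that("acquisition config round-trips through YAML with ms-to-s ingest", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "inversion_times_ms: [1010, 3683, 6355]",
    "excitation_tr_ms: 6",
    "cycle_tr_ms: 8250",
    "n_excitations: 225",
    "flip_deg: [4, 4, 4]",
    "inversion_efficiency: 0.84"), path)
  p <- read_acq_config(path)
  expect_s3_class(p, "acq_params")
  expect_equal(p$inversion_times_s, c(1.010, 3.683, 6.355))
  expect_equal(p$cycle_tr_s, 8.25)
  writeLines("inversion_times_ms: [1000]", path)
  expect_error(read_acq_config(path), "missing keys")
})
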