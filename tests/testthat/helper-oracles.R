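# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form code paths: the cycle oracle iterates every
# excitation pulse explicitly, the SIR oracle integrates the coupled ODEs
# numerically, and the erosion oracle is brute-force morphology.

# Steady-state Mz before inversion by explicit per-excitation iteration of
# `ncycles` full inversion cycles from Mz = 1. Vectorized over t1.
iterate_cycles_mz <- function(t1, params, b1 = 1, ncycles = 60) {
  tm <- derive_block_timing(params)
  eff <- params$inversion_efficiency
  E1 <- exp(-params$excitation_tr_s / t1)
  th <- b1 * params$flip_deg * pi / 180
  K <- length(th)
  M <- rep(1, length(t1))
  for (cyc in seq_len(ncycles)) {
    M <- -eff * M
    e <- exp(-tm$pre_first_block_s / t1); M <- M * e + (1 - e)
    for (k in seq_len(K)) {
      ck <- cos(th[k])
      for (j in seq_len(params$n_excitations))
        M <- M * ck * E1 + (1 - E1)
      tg <- if (k < K) tm$inter_block_gaps_s[k] else tm$post_last_block_s
      e <- exp(-tg / t1); M <- M * e + (1 - e)
    }
  }
  M
}

# S1,2 of the noiseless forward model for scalar inputs.
forward_s12 <- function(t1, params, b1 = 1) {
  sg <- mp2rage_signals(t1, params, b1 = b1)
  if (is.matrix(sg)) {
    uniform_signal(complex(real = sg[1, ]), complex(real = sg[2, ]))
  } else {
    uniform_signal(complex(real = sg[1]), complex(real = sg[2]))
  }
}

# Two-pool SIR free-pool signal by numerical integration of the coupled
# ODEs (deSolve), tight tolerances on both the pre-delay and recovery legs.
sir_signal_ode <- function(p, ti, td) {
  A <- p$r1_per_s * diag(2) +
    matrix(c(p$psr * p$kmf_per_s, -p$psr * p$kmf_per_s,
             -p$kmf_per_s, p$kmf_per_s), 2, 2)
  minf <- c(p$m0f, p$psr * p$m0f)
  deriv <- function(t, y, parms) list(as.numeric(-A %*% (y - minf)))
  ctrl <- list(rtol = 1e-11, atol = 1e-13)
  y1 <- deSolve::ode(c(0, 0), c(0, td), deriv, NULL,
                     rtol = ctrl$rtol, atol = ctrl$atol)[2, 2:3]
  y1 <- c(p$sf * y1[1], p$sm * y1[2])
  vapply(ti, function(t) {
    deSolve::ode(y1, c(0, t), deriv, NULL,
                 rtol = ctrl$rtol, atol = ctrl$atol)[2, 2]
  }, numeric(1))
}

# Brute-force binary erosion by a cube: a voxel survives iff every voxel of
# the cube neighborhood (clipped at the border) is inside the mask.
erode_bruteforce <- function(mask, r) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    xs <- max(1, x - r):min(d[1], x + r)
    ys <- max(1, y - r):min(d[2], y + r)
    zs <- max(1, z - r):min(d[3], z + r)
    full <- length(xs) == 2 * r + 1 && length(ys) == 2 * r + 1 &&
      length(zs) == 2 * r + 1
    out[x, y, z] <- full && all(mask[xs, ys, zs])
  }
  out
}

# Small phantom spec used by several tests (two slices, no B1 gradient).
tiny_spec <- function(...) {
  phantom_spec(shape = c(24, 24, 2), b1_amplitude = 0, seed = 99, ...)
}

# Smooth random volumes + labels for calibration unit tests: a slab with an
# all-WM interior so patch extraction is dense and predictable. Values are
# spatially smooth (low-frequency harmonics plus small noise) because the
# regression head pools spatially — identifying the center of an i.i.d.
# noise patch is not a learnable task for this architecture.
calib_toy_data <- function(n_slices = 2, h = 20, seed = 1) {
  set.seed(seed)
  shp <- c(h, h, n_slices)
  x <- matrix(seq_len(h), h, h) / h
  y <- t(x)
  ph <- stats::runif(4, 0, 2 * pi)
  base <- array(0, shp)
  for (z in seq_len(n_slices)) {
    base[, , z] <- 1.5 +
      0.4 * sin(2 * pi * x + ph[1] + 0.3 * z) * cos(2 * pi * y + ph[2]) +
      0.2 * sin(4 * pi * y + ph[3]) +
      0.03 * matrix(stats::rnorm(h * h), h, h)
  }
  labels <- array(tissue_codes["WM"], shp)
  list(t1 = base, labels = labels, shape = shp)
}
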