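# Seeded digital brain phantom: concentric-shell tissue geometry, ground
# truth T1, smooth B1+ field, simulated MP3RAGE GREs and SIR volumes, and an
# injected tissue-dependent bias emulating the systematic MP2RAGE-vs-IR
# discrepancy that the calibration network must learn to undo.

#' Phantom specification
#'
#' Defines the study conditions of the synthetic benchmark. Tissue T1 truths
#' are the multi-TI IR tissue means (WM 1.48, SGM 1.74, CGM 2.05 s); bias
#' factors are the observed MAP-MP2RAGE-to-IR relative values (WM 0.828,
#' SGM 0.891, CGM 0.953). CSF T1 (4.3 s) is a documented placeholder inside
#' the prior support and is excluded from all metrics.
#'
#' @param shape 3-D grid, default `c(48, 48, 5)` (five axial slices).
#' @param tissue_t1_s named list/vector of tissue T1 truths (seconds).
#' @param tissue_sir per-tissue two-pool parameters (psr, kmf, sf);
#'   literature-typical placeholders, configurable.
#' @param b1_center,b1_amplitude smooth multiplicative B1+ field: a low-order
#'   in-plane polynomial with the given center value and amplitude, constant
#'   across slices, range within `[0.7, 1.3]`.
#' @param bias_factors multiplicative per-tissue bias applied by
#'   [inject_tissue_bias()].
#' @param bias_field_amplitude amplitude of the smooth zero-mean spatial
#'   modulation of the bias (fraction, default 0.02).
#' @param noise_sigma Gaussian noise SD for simulated GREs (signal units).
#' @param n_subjects number of subjects generated by [synth_subjects()].
#' @param inter_subject_jitter per-subject, per-tissue multiplicative T1
#'   perturbation half-width (default 0.02, i.e. +/- 2 percent).
#' @param seed base seed; all simulators derive substreams from it.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48, 48, 5),
                         tissue_t1_s = c(WM = 1.48, SGM = 1.74, CGM = 2.05,
                                         CSF = 4.3),
                         tissue_sir = list(
                           WM = list(psr = 0.12, kmf = 10, sf = -0.95),
                           SGM = list(psr = 0.06, kmf = 10, sf = -0.95),
                           CGM = list(psr = 0.06, kmf = 10, sf = -0.95),
                           CSF = list(psr = 0, kmf = 0, sf = -0.95)),
                         b1_center = 1, b1_amplitude = 0.3,
                         bias_factors = c(WM = 0.828, SGM = 0.891,
                                          CGM = 0.953),
                         bias_field_amplitude = 0.02,
                         noise_sigma = 0.005, n_subjects = 4,
                         inter_subject_jitter = 0.02, seed = 1L) {
  stopifnot(length(shape) == 3, shape[3] >= 1,
            all(unlist(tissue_t1_s) > 0),
            all(bias_factors > 0 & bias_factors <= 1.2))
  structure(list(shape = as.integer(shape),
                 tissue_t1_s = tissue_t1_s, tissue_sir = tissue_sir,
                 b1_center = b1_center, b1_amplitude = b1_amplitude,
                 bias_factors = bias_factors,
                 bias_field_amplitude = bias_field_amplitude,
                 noise_sigma = noise_sigma, n_subjects = n_subjects,
                 inter_subject_jitter = inter_subject_jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Normalized in-plane coordinates in [-1, 1] for a shape.
.plane_coords <- function(shape) {
  x <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / ((shape[1] - 1) / 2)
  y <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / ((shape[2] - 1) / 2)
  list(x = matrix(x, shape[1], shape[2]),
       y = matrix(y, shape[1], shape[2], byrow = TRUE))
}

#' Generate one phantom subject: labels, true T1, B1+ field
#'
#' Concentric in-plane geometry on every axial slice — CSF core, SGM ring,
#' WM bulk, CGM shell, background outside — with per-subject, per-tissue
#' multiplicative T1 jitter and a smooth low-order polynomial B1+ field
#' (identical across slices, mirroring the axial-equivalence assumption).
#' Fully deterministic given `(spec$seed, subject_index)`.
#'
#' @param spec a [phantom_spec()].
#' @param subject_index positive integer.
#' @return List with `labels` (integer array, [tissue_codes]), `true_t1`
#'   (array, `NA` in background) and `b1` (array).
#' @export
make_phantom <- function(spec, subject_index = 1L) {
  shp <- spec$shape
  if (min(shp[1:2]) < 24)
    stop_mapt1("in-plane shape %dx%d too small for the shell geometry",
               shp[1], shp[2])
  co <- .plane_coords(shp)
  r <- sqrt(co$x^2 + co$y^2)
  plane <- matrix(tissue_codes["background"], shp[1], shp[2])
  plane[r < 0.92] <- tissue_codes["CGM"]
  plane[r < 0.72] <- tissue_codes["WM"]
  plane[r < 0.40] <- tissue_codes["SGM"]
  plane[r < 0.22] <- tissue_codes["CSF"]
  labels <- array(rep(plane, shp[3]), shp)
  storage.mode(labels) <- "integer"

  set.seed(substream_seed(spec$seed, 11L, subject_index))
  tis <- names(spec$tissue_t1_s)
  jit <- 1 + stats::runif(length(tis), -spec$inter_subject_jitter,
                          spec$inter_subject_jitter)
  names(jit) <- tis
  t1 <- array(NA_real_, shp)
  for (t in tis)
    t1[labels == tissue_codes[t]] <- spec$tissue_t1_s[[t]] * jit[[t]]

  b1_plane <- spec$b1_center + spec$b1_amplitude *
    (0.4 * co$x + 0.2 * co$y - 0.2 * (co$x^2 + co$y^2 - 2 / 3))
  if (any(b1_plane < 0.7 | b1_plane > 1.3)) {
    warning("B1 field clipped to [0.7, 1.3]")
    b1_plane <- clamp(b1_plane, 0.7, 1.3)
  }
  b1 <- array(rep(b1_plane, shp[3]), shp)
  list(labels = labels, true_t1 = t1, b1 = b1, jitter = jit)
}

#' Simulate noisy complex MP3RAGE readouts
#'
#' Per voxel, the ideal real GRE signals come from the forward model at the
#' voxel's (T1, B1); independent Gaussian noise of standard deviation `sigma`
#' is added in quadrature to the real and imaginary part of every readout.
#' Background voxels (T1 = NA) are pure noise.
#'
#' @param true_t1 T1 array (seconds, `NA` outside the object).
#' @param b1 B1+ factor array, same shape.
#' @param params an [acq_params()] object.
#' @param sigma noise standard deviation (signal units).
#' @param seed integer seed.
#' @return List of K complex arrays.
#' @export
simulate_mp3rage <- function(true_t1, b1, params, sigma = 0.005, seed = 1L) {
  stopifnot(identical(dim(true_t1), dim(b1)))
  K <- length(params$inversion_times_s)
  n <- length(true_t1)
  inside <- which(is.finite(true_t1))
  ideal <- matrix(0, K, n)
  if (length(inside))
    ideal[, inside] <- mp2rage_signals(true_t1[inside], params,
                                       b1 = b1[inside])
  set.seed(substream_seed(seed, 17L))
  gres <- vector("list", K)
  for (k in seq_len(K)) {
    g <- complex(real = ideal[k, ] + stats::rnorm(n, 0, sigma),
                 imaginary = stats::rnorm(n, 0, sigma))
    dim(g) <- dim(true_t1)
    gres[[k]] <- g
  }
  gres
}

#' Simulate a selective inversion recovery acquisition
#'
#' Per voxel, the signed two-pool recovery is evaluated with `r1 = 1/T1` and
#' the tissue's `(psr, kmf, sf)`; additive Gaussian noise is applied.
#' Background voxels carry zero signal plus noise.
#'
#' @param true_t1 T1 array (`NA` in background).
#' @param labels tissue label array ([tissue_codes]).
#' @param spec a [phantom_spec()] supplying the per-tissue SIR parameters.
#' @param ti_s inversion times (default the 13 printed values).
#' @param td_s pre-delay (s).
#' @param sigma additive noise SD (signal units, m0f = 1).
#' @param sm macromolecular inversion coefficient used in simulation.
#' @return 4-D array `(x, y, z, ti)` of signed signals.
#' @export
simulate_sir <- function(true_t1, labels, spec, ti_s = default_sir_ti(),
                         td_s = 0.0025, sigma = 0, seed = 1L, sm = 0.83) {
  shp <- dim(true_t1)
  nti <- length(ti_s)
  out <- matrix(0, length(true_t1), nti)
  for (t in names(spec$tissue_sir)) {
    vox <- which(labels == tissue_codes[t] & is.finite(true_t1))
    if (!length(vox)) next
    ps <- spec$tissue_sir[[t]]
    out[vox, ] <- .sir_mf_grid(1 / true_t1[vox], ps$psr, ps$kmf, ps$sf, sm,
                               1, ti_s, td_s)
  }
  if (sigma > 0) {
    set.seed(substream_seed(seed, 23L))
    out <- out + stats::rnorm(length(out), 0, sigma)
  }
  array(out, c(shp, nti))
}

#' Inject the tissue-dependent MP2RAGE-vs-IR bias
#'
#' Multiplies T1 in each brain tissue by its configured bias factor and by
#' `1 + f(x, y)` where `f` is a smooth low-order polynomial, zero-mean within
#' each tissue class, with the configured amplitude (default 2 percent). CSF
#' and background voxels pass through unchanged. Emulates the systematic,
#' spatially structured underestimation that the calibrator must undo.
#'
#' @param t1 T1 array, or a `t1_map` object (returned in kind).
#' @param labels tissue label array.
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the (deterministic) field orientation.
#' @return Same type as `t1`.
#' @export
inject_tissue_bias <- function(t1, labels, spec, seed = spec$seed) {
  is_map <- inherits(t1, "t1_map")
  vol <- if (is_map) t1$t1_s else t1
  shp <- dim(vol)
  set.seed(substream_seed(seed, 29L))
  cf <- stats::rnorm(3)
  co <- .plane_coords(shp)
  raw <- cf[1] * co$x + cf[2] * co$y + cf[3] * co$x * co$y
  raw <- raw / max(abs(raw), 1e-12)
  field <- array(rep(raw, shp[3]), shp) * spec$bias_field_amplitude
  out <- vol
  for (t in names(spec$bias_factors)) {
    vox <- which(labels == tissue_codes[t])
    if (!length(vox)) next
    f <- field[vox]
    f <- f - mean(f)   # zero-mean within tissue: keeps the configured
    # relative value exact by construction
    out[vox] <- vol[vox] * spec$bias_factors[[t]] * (1 + f)
  }
  if (is_map) {
    t1$t1_s <- out
    t1
  } else out
}

#' Generate a cohort of paired synthetic subjects
#'
#' Per subject: labels, ground-truth T1, B1+ field, simulated MP3RAGE GREs,
#' optional SIR volumes, the IR-reference T1 map, and the biased MP2RAGE-side
#' T1 map the calibrator trains on. The MP2RAGE-side map is either the truth
#' itself (`map_cfg = NULL`, fast) or a MAP estimate computed from the
#' simulated GREs; tissue bias is injected in both cases.
#'
#' @param spec a [phantom_spec()].
#' @param n number of subjects (default `spec$n_subjects`).
#' @param params acquisition protocol for GRE simulation.
#' @param map_cfg optional [mc_config()]; when given, `mp2rage_t1` is the MAP
#'   pair-mode estimate (tables shared across subjects via `tables`).
#' @param include_sir simulate SIR volumes per subject.
#' @param sir_sigma noise SD for the SIR volumes.
#' @return List of `n` subject lists (fields `subject`, `labels`, `true_t1`,
#'   `b1`, `gres`, `sir`, `ir_t1`, `mp2rage_t1`, `mp2rage_biased`, `sigma_t1`).
#' @export
synth_subjects <- function(spec, n = spec$n_subjects,
                           params = default_protocol(), map_cfg = NULL,
                           include_sir = FALSE, sir_sigma = 0) {
  stopifnot(n >= 1)
  tables <- list()
  out <- vector("list", n)
  for (s in seq_len(n)) {
    ph <- make_phantom(spec, s)
    gres <- simulate_mp3rage(ph$true_t1, ph$b1, params, spec$noise_sigma,
                             seed = substream_seed(spec$seed, 31L, s))
    sirv <- NULL
    if (include_sir)
      sirv <- simulate_sir(ph$true_t1, ph$labels, spec, sigma = sir_sigma,
                           seed = substream_seed(spec$seed, 37L, s))
    sigma_t1 <- NULL
    if (is.null(map_cfg)) {
      brain <- ph$labels > 0
      mp <- new_t1_map(ph$true_t1, brain, "point_mp2rage")
    } else {
      mp <- map_t1_volume(gres, ph$b1, params, map_cfg, "pair",
                          tables = tables)
      tables <- attr(mp, "tables")
      sigma_t1 <- mp$sigma_t1_s
    }
    biased <- inject_tissue_bias(mp, ph$labels, spec,
                                 seed = substream_seed(spec$seed, 41L, s))
    out[[s]] <- list(subject = s, labels = ph$labels, true_t1 = ph$true_t1,
                     b1 = ph$b1, gres = gres, sir = sirv,
                     ir_t1 = ph$true_t1, mp2rage_t1 = mp$t1_s,
                     mp2rage_biased = biased$t1_s, sigma_t1 = sigma_t1,
                     valid = biased$valid_mask)
  }
  out
}
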