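# Monte-Carlo posterior construction and MAP T1 estimation.
#
# For each T1 grid point the ideal GRE signals are computed from the forward
# model, independent Gaussian noise of standard deviation sigma is added to
# the real and imaginary part of every readout, the uniform image value(s)
# are formed, and their counts are histogrammed over signal bins. Row
# normalization gives the likelihood P(S-bin | T1); with the uniform T1 prior,
# column normalization gives the posterior P(T1 | S-bin) by Bayes' theorem.

#' Monte-Carlo configuration for MAP T1 estimation
#'
#' @param n_trials total simulated draws, split evenly (stratified) across the
#'   T1 grid. Default 1e7; 1e6 is the reduced sweep mode.
#' @param noise_sigma Gaussian standard deviation added to the real and
#'   imaginary part of each GRE, in (unitless) signal units. Default 0.005.
#' @param t1_grid T1 prior support; default 100 linearly spaced points over
#'   (0, 5] s, matching the resolution of the 100-bin signal histogram.
#' @param signal_bins number of histogram bins over `[-0.5, 0.5]` (default 100).
#' @param b1_grid linearly spaced B1+ factors for which posterior tables are
#'   built (default 41 points over `[0, 2]`).
#' @param seed base seed; expanded into per-(B1, T1-grid-point) substreams so
#'   results do not depend on the order in which tables are built.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(n_trials = 1e7, noise_sigma = 0.005,
                      t1_grid = seq(0.05, 5, length.out = 100),
                      signal_bins = 100L,
                      b1_grid = seq(0, 2, length.out = 41),
                      seed = 1L) {
  stopifnot(n_trials >= length(t1_grid), noise_sigma > 0, signal_bins >= 2,
            all(t1_grid > 0), all(b1_grid >= 0 & b1_grid <= 2))
  structure(list(n_trials = n_trials, noise_sigma = noise_sigma,
                 t1_grid = as.numeric(t1_grid),
                 signal_bins = as.integer(signal_bins),
                 b1_grid = as.numeric(b1_grid), seed = as.integer(seed)),
            class = "mc_config")
}

# Bin index over [-0.5, 0.5]; S = 0.5 falls in the last bin. Values are
# bounded by construction of the uniform image, so no draw is ever dropped.
.s_bin <- function(s, nbins) {
  pmin.int(pmax.int(as.integer(floor((s + 0.5) * nbins)) + 1L, 1L), nbins)
}

#' Run the Monte-Carlo simulation for one B1 factor
#'
#' Builds the likelihood/posterior histogram for either the single uniform
#' image S1,2 (`mode = "pair"`) or the joint 2-D histogram over (S1,2, S1,3)
#' (`mode = "joint"`, requires a 3-readout protocol). Sampling is stratified:
#' `n_trials / length(t1_grid)` draws per T1 grid point (any remainder spread
#' over the first points), which realizes the uniform T1 prior with exact
#' per-T1 normalization counts.
#'
#' @param params an [acq_params()] object.
#' @param b1 B1+ correction factor the table is built for.
#' @param cfg an [mc_config()].
#' @param mode `"pair"` or `"joint"`.
#' @return Object of class `posterior_grid` holding the integer count matrix
#'   (T1 grid x flattened signal bins) and per-bin MAP summaries (`map_t1`,
#'   `map_sigma`, `valid_bin`).
#' @export
run_monte_carlo <- function(params, b1, cfg, mode = c("pair", "joint")) {
  mode <- match.arg(mode)
  K <- length(params$inversion_times_s)
  if (mode == "joint" && K < 3L)
    stop_mapt1("joint mode requires a 3-readout protocol")
  nT <- length(cfg$t1_grid)
  nb <- cfg$signal_bins
  nbins_total <- if (mode == "pair") nb else nb * nb
  per <- rep(cfg$n_trials %/% nT, nT)
  rem <- cfg$n_trials %% nT
  if (rem > 0) per[seq_len(rem)] <- per[seq_len(rem)] + 1L

  ideal <- mp2rage_signals(cfg$t1_grid, params, b1 = b1)  # K x nT
  if (!is.matrix(ideal)) ideal <- matrix(ideal, nrow = K)
  counts <- matrix(0L, nT, nbins_total)
  b1_key <- as.integer(round(b1 * 1e6)) %% 1000003L
  for (i in seq_len(nT)) {
    set.seed(substream_seed(cfg$seed, b1_key, i))
    m <- per[i]
    re1 <- ideal[1, i] + stats::rnorm(m, 0, cfg$noise_sigma)
    im1 <- stats::rnorm(m, 0, cfg$noise_sigma)
    re2 <- ideal[2, i] + stats::rnorm(m, 0, cfg$noise_sigma)
    im2 <- stats::rnorm(m, 0, cfg$noise_sigma)
    s12 <- (re1 * re2 + im1 * im2) / (re1^2 + im1^2 + re2^2 + im2^2)
    bin <- .s_bin(s12, nb)
    if (mode == "joint") {
      re3 <- ideal[3, i] + stats::rnorm(m, 0, cfg$noise_sigma)
      im3 <- stats::rnorm(m, 0, cfg$noise_sigma)
      s13 <- (re1 * re3 + im1 * im3) / (re1^2 + im1^2 + re3^2 + im3^2)
      bin <- bin + nb * (.s_bin(s13, nb) - 1L)
    }
    counts[i, ] <- tabulate(bin, nbins_total)
  }

  colsum <- .colSums(counts, nT, nbins_total)
  # Per-bin posterior summaries; argmax ties break toward the smaller T1
  # (which.max returns the first maximum on the ascending grid).
  map_idx <- integer(nbins_total)
  occupied <- which(colsum > 0)
  for (j in occupied) map_idx[j] <- which.max(counts[, j])
  t1 <- cfg$t1_grid
  m1 <- as.numeric(crossprod(counts, t1))        # sum counts * t1 per bin
  m2 <- as.numeric(crossprod(counts, t1^2))
  mu <- ifelse(colsum > 0, m1 / colsum, NA_real_)
  sig <- ifelse(colsum > 0, sqrt(pmax(m2 / colsum - mu^2, 0)), NA_real_)

  structure(list(
    t1_grid = t1, signal_bins = nb, mode = mode, b1 = b1,
    noise_sigma = cfg$noise_sigma, n_trials = cfg$n_trials, seed = cfg$seed,
    counts = counts, bin_colsum = colsum,
    map_t1 = ifelse(map_idx > 0, t1[pmax(map_idx, 1L)], NA_real_),
    map_sigma = sig, post_mean = mu,
    valid_bin = colsum > 0,
    bin_breaks = seq(-0.5, 0.5, length.out = nb + 1L)
  ), class = "posterior_grid")
}

#' Likelihood matrix P(S-bin | T1)
#'
#' Row-normalized histogram counts; every row sums to 1 because stratified
#' sampling guarantees a fixed number of draws per T1 grid point.
#' @param pg a `posterior_grid`.
#' @return Matrix (T1 grid x signal bins).
#' @export
posterior_likelihood <- function(pg) {
  pg$counts / rowSums(pg$counts)
}

#' Posterior matrix P(T1 | S-bin)
#'
#' Column-normalized counts (Bayes' theorem with the uniform T1 prior).
#' Columns of empty bins are all-`NA`.
#' @param pg a `posterior_grid`.
#' @return Matrix (T1 grid x signal bins).
#' @export
posterior_distribution <- function(pg) {
  cs <- pg$bin_colsum
  cs[cs == 0] <- NA_real_
  sweep(pg$counts, 2, cs, "/")
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat(sprintf("Posterior grid (%s mode): %d T1 points, %d bins, b1 = %g, sigma = %g, %g trials\n",
              x$mode, length(x$t1_grid), x$signal_bins, x$b1, x$noise_sigma,
              x$n_trials))
  invisible(x)
}

#' MAP estimate and posterior standard deviation for observed signal values
#'
#' Locates the signal bin of each observation and returns the precomputed MAP
#' T1 (posterior argmax over the T1 grid, ties toward smaller T1) and the
#' standard deviation of the discrete posterior. Observations outside
#' `[-0.5, 0.5]`, or falling in a bin that received no Monte-Carlo counts,
#' are flagged invalid.
#'
#' @param pg a `posterior_grid`.
#' @param s_values numeric vector of S1,2 values (pair mode) or a 2-column
#'   matrix of (S1,2, S1,3) values (joint mode).
#' @return List with `t1`, `sigma`, `valid`.
#' @export
map_estimate <- function(pg, s_values) {
  nb <- pg$signal_bins
  if (pg$mode == "joint") {
    s_values <- as.matrix(s_values)
    if (ncol(s_values) != 2L)
      stop_mapt1("joint mode expects a 2-column matrix of (S12, S13) values")
    inr <- abs(s_values[, 1]) <= 0.5 & abs(s_values[, 2]) <= 0.5
    idx <- .s_bin(s_values[, 1], nb) + nb * (.s_bin(s_values[, 2], nb) - 1L)
  } else {
    s_values <- as.numeric(s_values)
    inr <- abs(s_values) <= 0.5
    idx <- .s_bin(s_values, nb)
  }
  valid <- inr & pg$valid_bin[idx]
  list(t1 = ifelse(valid, pg$map_t1[idx], NA_real_),
       sigma = ifelse(valid, pg$map_sigma[idx], NA_real_),
       valid = valid)
}

#' Precompute posterior tables for a set of B1 factors
#'
#' @param params an [acq_params()] object.
#' @param cfg an [mc_config()].
#' @param mode `"pair"` or `"joint"`.
#' @param b1_indices indices into `cfg$b1_grid` to build (default all).
#' @return Named list of `posterior_grid` objects, keyed by index.
#' @export
build_posterior_tables <- function(params, cfg, mode = "pair",
                                   b1_indices = seq_along(cfg$b1_grid)) {
  tabs <- list()
  for (i in b1_indices)
    tabs[[as.character(i)]] <- run_monte_carlo(params, cfg$b1_grid[i], cfg, mode)
  tabs
}

#' Voxelwise MAP T1 mapping from complex GRE volumes
#'
#' Forms the uniform image(s) from the acquired GREs, selects for every voxel
#' the posterior table of the nearest `b1_grid` factor, and applies
#' [map_estimate()]. Voxels with zero total GRE magnitude, out-of-range S, or
#' empty posterior bins are masked invalid.
#'
#' @param gres list of K complex arrays (one per inversion time).
#' @param b1map B1+ factor array, same shape.
#' @param params an [acq_params()] object.
#' @param cfg an [mc_config()].
#' @param mode `"pair"` (uses GREs 1, 2) or `"joint"` (also uses GRE 3).
#' @param tables optional precomputed [build_posterior_tables()] result;
#'   missing tables are built (and returned invisibly via attribute `tables`).
#' @return A `t1_map` with `sigma_t1_s` filled (method `map_mp2rage` or
#'   `map_mp3rage`).
#' @export
map_t1_volume <- function(gres, b1map, params, cfg, mode = c("pair", "joint"),
                          tables = NULL) {
  mode <- match.arg(mode)
  s12 <- uniform_signal(gres[[1]], gres[[2]])
  s13 <- if (mode == "joint") uniform_signal(gres[[1]], gres[[3]]) else NULL
  mag2 <- Reduce(`+`, lapply(gres, function(g) Mod(as.complex(g))^2))
  nonzero <- mag2 > 0
  b1v <- clamp(as.numeric(b1map), 0, 2)
  # nearest b1 grid index
  mids <- (utils::head(cfg$b1_grid, -1) + utils::tail(cfg$b1_grid, -1)) / 2
  idx <- findInterval(b1v, mids) + 1L

  n <- length(s12)
  t1 <- rep(NA_real_, n); sg <- rep(NA_real_, n); ok <- rep(FALSE, n)
  if (is.null(tables)) tables <- list()
  for (i in sort(unique(idx[nonzero]))) {
    key <- as.character(i)
    if (is.null(tables[[key]]))
      tables[[key]] <- run_monte_carlo(params, cfg$b1_grid[i], cfg, mode)
    vox <- which(idx == i & nonzero)
    sv <- if (mode == "joint") cbind(s12[vox], s13[vox]) else s12[vox]
    est <- map_estimate(tables[[key]], sv)
    t1[vox] <- est$t1; sg[vox] <- est$sigma; ok[vox] <- est$valid
  }
  shp <- dim(s12) %||% length(s12)
  dim(t1) <- dim(s12); dim(sg) <- dim(s12); dim(ok) <- dim(s12)
  out <- new_t1_map(t1, ok, if (mode == "pair") "map_mp2rage" else "map_mp3rage",
                    sigma = sg)
  attr(out, "tables") <- tables
  out
}

#' Estimate the noise level from a homogeneous region of interest
#'
#' Computes the standard deviation of the real and imaginary part of every
#' GRE over the ROI and takes the largest. When `params` and `brain_mask` are
#' supplied, the raw SD is rescaled by the ratio of the modeled ideal-signal
#' range (over T1 in `t1_range`) to the acquired GRE magnitude range within
#' the brain mask, holding the contrast-to-noise ratio approximately constant
#' between acquired and simulated signal scales.
#'
#' @param gres list of complex GRE arrays.
#' @param roi_mask logical array with at least 20 `TRUE` voxels.
#' @param params optional [acq_params()] enabling the CNR rescaling.
#' @param brain_mask logical array over which the acquired signal range is
#'   measured (required with `params`).
#' @param t1_range T1 range (s) spanned when computing the modeled range.
#' @return List with `sigma`, `roi_voxel_count`, `per_channel_sds` (2 x K
#'   matrix), `scale_factor`.
#' @export
estimate_noise_roi <- function(gres, roi_mask, params = NULL,
                               brain_mask = NULL, t1_range = c(0.5, 5)) {
  roi <- which(as.logical(roi_mask))
  if (length(roi) < 20L)
    stop_mapt1("ROI too small for noise estimation (%d voxels, need >= 20)",
               length(roi))
  sds <- vapply(gres, function(g) {
    g <- as.complex(g)[roi]
    c(stats::sd(Re(g)), stats::sd(Im(g)))
  }, numeric(2))
  rownames(sds) <- c("real", "imag")
  if (any(sds < .Machine$double.eps))
    stop_mapt1("degenerate ROI: a GRE channel has zero variance in the ROI")
  sigma_raw <- max(sds)
  scale <- 1
  if (!is.null(params)) {
    if (is.null(brain_mask))
      stop_mapt1("brain_mask is required for contrast-to-noise rescaling")
    grid <- seq(t1_range[1], t1_range[2], length.out = 200)
    model_range <- diff(range(mp2rage_signals(grid, params)))
    bm <- which(as.logical(brain_mask))
    acq <- unlist(lapply(gres, function(g) Mod(as.complex(g)[bm])))
    acq_range <- diff(range(acq))
    if (acq_range <= 0)
      stop_mapt1("degenerate brain mask: acquired GRE magnitude range is zero")
    scale <- model_range / acq_range
  }
  list(sigma = sigma_raw * scale, roi_voxel_count = length(roi),
       per_channel_sds = sds, scale_factor = scale)
}

#' Cache a posterior table on disk
#'
#' Monte-Carlo tables are expensive; these helpers round-trip a
#' `posterior_grid` through a single file together with the configuration
#' fingerprint so stale caches are rejected on load.
#'
#' @param pg a `posterior_grid`.
#' @param path file path.
#' @export
write_posterior <- function(pg, path) {
  pg$fingerprint <- .pg_fingerprint(pg)
  saveRDS(pg, path)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  pg <- readRDS(path)
  if (!inherits(pg, "posterior_grid"))
    stop_mapt1("file does not contain a posterior table")
  fp <- pg$fingerprint; pg$fingerprint <- NULL
  if (!identical(fp, .pg_fingerprint(pg)))
    stop_mapt1("posterior table fingerprint mismatch (stale or corrupt cache)")
  pg
}

.pg_fingerprint <- function(pg) {
  c(length(pg$t1_grid), pg$signal_bins, pg$b1, pg$noise_sigma, pg$n_trials,
    pg$seed, sum(pg$counts), sum(pg$counts * seq_len(nrow(pg$counts))) %% 1e9)
}
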