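# MP2RAGE/MP3RAGE steady-state forward model.
#
# Longitudinal magnetization (M0 normalized to 1) is propagated through the
# inversion cycle as a composition of affine maps Mz -> A*Mz + B:
#   inversion          Mz -> -eff * Mz
#   free recovery (t)  Mz -> Mz * e + (1 - e),              e = exp(-t/T1)
#   one excitation     Mz -> Mz * cos(b1*alpha) * E1 + (1 - E1),
#                                                    E1 = exp(-TR_exc/T1)
# A run of m excitation periods composes in closed form (geometric series),
# so the whole cycle is a single affine map whose fixed point B/(1 - A) is the
# steady state. Signals are read at the block center, (n/2) periods into each
# block, as sin(b1*alpha) times the longitudinal magnetization there.

# Compose m identical excitation periods: returns the affine (A, B) of the run.
# a = cos(theta)*E1 per voxel/block; fractional m requires a > 0.
.block_affine <- function(a, E1, m) {
  if (m %% 1 != 0 && any(a <= 0))
    stop_mapt1("fractional block-center exponent requires cos(b1*alpha) > 0")
  Am <- a^m
  denom <- 1 - a
  B <- ifelse(abs(denom) < 1e-12, m * (1 - E1), (1 - E1) * (1 - Am) / denom)
  list(A = Am, B = B)
}

#' Steady-state longitudinal magnetization of the inversion cycle
#'
#' Returns the fixed point of the full-cycle affine map, i.e. the normalized
#' longitudinal magnetization immediately before each inversion pulse once
#' the sequence has reached its periodic steady state. Mainly useful for
#' validating the closed-form propagation against explicit cycle iteration.
#'
#' @inheritParams mp2rage_signals
#' @return Numeric vector of steady-state Mz values, one per T1.
#' @export
mp2rage_steady_state <- function(t1_s, params, b1 = 1) {
  .mp2rage_cycle(t1_s, params, b1)$Mss
}

# Shared engine: composes the full-cycle affine map and returns its fixed
# point together with the per-voxel excitation-period coefficients.
.mp2rage_cycle <- function(t1_s, params, b1) {
  if (!is.numeric(t1_s) || any(!is.finite(t1_s)) || any(t1_s <= 0))
    stop_mapt1("t1_s must be finite and > 0")
  if (any(!is.finite(b1)) || any(b1 < 0))
    stop_mapt1("b1 must be finite and >= 0")
  N <- max(length(t1_s), length(b1))
  t1 <- rep_len(as.numeric(t1_s), N)
  b1 <- rep_len(as.numeric(b1), N)
  timing <- derive_block_timing(params)
  K <- length(params$inversion_times_s)
  n <- params$n_excitations
  eff <- params$inversion_efficiency
  E1 <- exp(-params$excitation_tr_s / t1)
  theta <- outer(params$flip_deg * pi / 180, b1)
  a <- cos(theta) * rep(E1, each = K)
  A <- rep(-eff, N); B <- rep(0, N)
  step <- function(A, B, a_seg, b_seg) list(A = a_seg * A, B = a_seg * B + b_seg)
  e <- exp(-timing$pre_first_block_s / t1)
  st <- step(A, B, e, 1 - e); A <- st$A; B <- st$B
  for (k in seq_len(K)) {
    blk <- .block_affine(a[k, ], E1, n)
    st <- step(A, B, blk$A, blk$B); A <- st$A; B <- st$B
    tgap <- if (k < K) timing$inter_block_gaps_s[k] else timing$post_last_block_s
    e <- exp(-tgap / t1)
    st <- step(A, B, e, 1 - e); A <- st$A; B <- st$B
  }
  if (any(abs(1 - A) < 1e-14))
    stop_mapt1("degenerate cycle: affine map has no unique fixed point")
  list(Mss = B / (1 - A), t1 = t1, E1 = E1, theta = theta, a = a,
       timing = timing, N = N, K = K)
}

#' Ideal MP2RAGE/MP3RAGE gradient-echo signals
#'
#' Evaluates the steady-state forward model for one or more T1 values and B1+
#' correction factors, returning the ideal (noiseless, real-valued) GRE signal
#' at the center of each readout block. M0 is normalized to 1, so signals are
#' unitless; the B1 factor scales all nominal flip angles.
#'
#' @param t1_s positive T1 value(s) in seconds.
#' @param params an [acq_params()] object.
#' @param b1 non-negative B1+ correction factor(s); recycled against `t1_s`.
#' @return A `K x N` matrix of signals (one row per readout block); a plain
#'   vector of length K when a single T1 is supplied.
#' @examples
#' s <- mp2rage_signals(1.5, default_protocol())
#' @export
mp2rage_signals <- function(t1_s, params, b1 = 1) {
  cy <- .mp2rage_cycle(t1_s, params, b1)
  eff <- params$inversion_efficiency
  # Propagate the steady state to each block center and read the signal.
  M <- -eff * cy$Mss
  e <- exp(-cy$timing$pre_first_block_s / cy$t1)
  M <- M * e + (1 - e)
  S <- matrix(0, cy$K, cy$N)
  half <- params$n_excitations / 2
  for (k in seq_len(cy$K)) {
    hb <- .block_affine(cy$a[k, ], cy$E1, half)
    M <- hb$A * M + hb$B
    S[k, ] <- sin(cy$theta[k, ]) * M
    M <- hb$A * M + hb$B
    if (k < cy$K) {
      e <- exp(-cy$timing$inter_block_gaps_s[k] / cy$t1)
      M <- M * e + (1 - e)
    }
  }
  if (cy$N == 1L) drop(S) else S
}

#' Combine two complex GREs into a uniform T1-weighted image
#'
#' The classical MP2RAGE combination
#' `Re(conj(gre_i) * gre_j) / (|gre_i|^2 + |gre_j|^2)`, which cancels proton
#' density, T2* and receive-field modulation and is bounded in `[-0.5, 0.5]`.
#' The indeterminate 0/0 case is defined as 0.
#'
#' @param gre_i,gre_j complex (or real) arrays of identical shape.
#' @return Real array of the same shape with values in `[-0.5, 0.5]`.
#' @export
uniform_signal <- function(gre_i, gre_j) {
  if (!identical(dim(gre_i) %||% length(gre_i), dim(gre_j) %||% length(gre_j)))
    stop_mapt1("GRE volumes must have identical shape")
  gi <- as.complex(gre_i); gj <- as.complex(gre_j)
  num <- Re(Conj(gi) * gj)
  den <- Mod(gi)^2 + Mod(gj)^2
  out <- ifelse(den == 0, 0, num / den)
  if (!is.null(dim(gre_i))) dim(out) <- dim(gre_i)
  out
}

#' Background-robust uniform image
#'
#' Adds a constant `beta` to the denominator of [uniform_signal()] to suppress
#' the noise amplification where both GRE magnitudes are near zero, with
#' `beta = beta_fraction * mean(|gre_i|^2 + |gre_j|^2)` over the volume.
#' Intended only as registration/segmentation support imagery; never used for
#' T1 fitting because it breaks the lookup relation.
#'
#' @inheritParams uniform_signal
#' @param beta_fraction non-negative multiplier on the volume-mean sum of
#'   squared magnitudes (default 0.25).
#' @param beta optional explicit beta overriding `beta_fraction`.
#' @return Real array of the same shape.
#' @export
robust_uniform_signal <- function(gre_i, gre_j, beta_fraction = 0.25,
                                  beta = NULL) {
  if (!identical(dim(gre_i) %||% length(gre_i), dim(gre_j) %||% length(gre_j)))
    stop_mapt1("GRE volumes must have identical shape")
  if (is.null(beta)) {
    stopifnot(beta_fraction >= 0)
    beta <- beta_fraction * mean(Mod(as.complex(gre_i))^2 +
                                   Mod(as.complex(gre_j))^2)
  }
  gi <- as.complex(gre_i); gj <- as.complex(gre_j)
  num <- Re(Conj(gi) * gj)
  den <- Mod(gi)^2 + Mod(gj)^2 + beta
  out <- ifelse(den == 0, 0, num / den)
  if (!is.null(dim(gre_i))) dim(out) <- dim(gre_i)
  out
}
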