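#' MP2RAGE/MP3RAGE acquisition parameters
#'
#' Container for the sequence timing and flip angles of a
#' magnetization-prepared rapid gradient-echo acquisition with K gradient-echo
#' readout (GRE) blocks per inversion cycle (K = 2 for MP2RAGE, K = 3 for
#' MP3RAGE). Inversion times are measured from the inversion pulse to the
#' center of each GRE block (k-space-center convention).
#'
#' @param inversion_times_s numeric vector of K inversion times (seconds),
#'   strictly increasing.
#' @param excitation_tr_s repetition time between excitation pulses within a
#'   GRE block (seconds).
#' @param cycle_tr_s repetition time between inversion pulses, i.e. the full
#'   MP2RAGE TR (seconds).
#' @param n_excitations number of excitation pulses per GRE block.
#' @param flip_deg nominal flip angles in degrees, one per block (recycled if
#'   a single value is given).
#' @param inversion_efficiency fraction of longitudinal magnetization inverted
#'   by the adiabatic pulse, in `[0, 1]`.
#' @return An object of class `acq_params`.
#' @examples
#' p <- acq_params(c(1.010, 3.683, 6.355), 0.006, 8.25, 225, 4, 0.84)
#' derive_block_timing(p)
#' @export
acq_params <- function(inversion_times_s, excitation_tr_s, cycle_tr_s,
                       n_excitations, flip_deg, inversion_efficiency = 0.84) {
  K <- length(inversion_times_s)
  if (length(flip_deg) == 1L) flip_deg <- rep(flip_deg, K)
  if (length(flip_deg) != K)
    stop_mapt1("flip_deg must have one angle per inversion time (got %d for K = %d)",
               length(flip_deg), K)
  if (K < 2L || K > 3L)
    stop_mapt1("expected 2 or 3 inversion times, got %d", K)
  if (is.unsorted(inversion_times_s, strictly = TRUE))
    stop_mapt1("inversion times must be strictly increasing")
  stopifnot(is_scalar_number(excitation_tr_s), excitation_tr_s > 0,
            is_scalar_number(cycle_tr_s), cycle_tr_s > 0,
            is_scalar_number(n_excitations), n_excitations > 0,
            is_scalar_number(inversion_efficiency),
            inversion_efficiency >= 0, inversion_efficiency <= 1)
  p <- structure(list(
    inversion_times_s = as.numeric(inversion_times_s),
    excitation_tr_s = excitation_tr_s,
    cycle_tr_s = cycle_tr_s,
    n_excitations = n_excitations,
    flip_deg = as.numeric(flip_deg),
    inversion_efficiency = inversion_efficiency
  ), class = "acq_params")
  derive_block_timing(p)  # validates that all free-recovery gaps are >= 0
  p
}

#' The published MP3RAGE protocol used throughout examples and tests
#'
#' TI 1010/3683/6355 ms, excitation TR 6 ms, cycle TR 8.25 s, 225 excitations
#' per block, 4 degree flip angles, inversion efficiency 0.84.
#'
#' @param K use the first `K` readouts (2 gives the plain MP2RAGE subset).
#' @return An `acq_params` object.
#' @export
default_protocol <- function(K = 3) {
  acq_params(c(1.010, 3.683, 6.355)[seq_len(K)], 0.006, 8.25, 225,
             rep(4, K), 0.84)
}

#' Decompose an inversion cycle into free-recovery delays and GRE blocks
#'
#' Converts block-center inversion times into the explicit timing needed to
#' propagate longitudinal magnetization: the delay TA between inversion and
#' the first block, the gaps between consecutive blocks, and the tail delay TD
#' after the last block. The readout is taken at `(n/2) * TR_exc` after the
#' block start; fractional half-blocks are permitted.
#'
#' @param params an [acq_params()] object.
#' @return List with `pre_first_block_s` (TA), `inter_block_gaps_s`,
#'   `post_last_block_s` (TD) and `block_duration_s`; the components always
#'   sum to `cycle_tr_s`.
#' @export
derive_block_timing <- function(params) {
  ti <- params$inversion_times_s
  K <- length(ti)
  block <- params$n_excitations * params$excitation_tr_s
  half <- block / 2
  ta <- ti[1] - half
  td <- params$cycle_tr_s - ti[K] - half
  gaps <- if (K > 1) diff(ti) - block else numeric(0)
  if (ta < 0)
    stop_mapt1("invalid protocol: pre-first-block delay TA = %.4f s < 0", ta)
  if (td < 0)
    stop_mapt1("invalid protocol: post-last-block delay TD = %.4f s < 0", td)
  bad <- which(gaps < 0)
  if (length(bad))
    stop_mapt1("invalid protocol: inter-block gap %d = %.4f s < 0",
               bad[1], gaps[bad[1]])
  list(pre_first_block_s = ta, inter_block_gaps_s = gaps,
       post_last_block_s = td, block_duration_s = block)
}

#' Read acquisition parameters from a YAML configuration
#'
#' Times in the file are given in milliseconds (`inversion_times_ms`,
#' `excitation_tr_ms`, `cycle_tr_ms`) as usually printed in protocol sheets
#' and are converted to seconds on ingest.
#'
#' @param path path to a YAML file.
#' @return An [acq_params()] object.
#' @export
read_acq_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("inversion_times_ms", "excitation_tr_ms", "cycle_tr_ms",
            "n_excitations", "flip_deg")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop_mapt1("acquisition config is missing keys: %s",
               paste(missing, collapse = ", "))
  acq_params(cfg$inversion_times_ms / 1000, cfg$excitation_tr_ms / 1000,
             cfg$cycle_tr_ms / 1000, cfg$n_excitations, cfg$flip_deg,
             cfg$inversion_efficiency %||% 0.84)
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("MP%dRAGE protocol: TI = %s ms, TR_exc = %g ms, cycle TR = %g s\n",
              length(x$inversion_times_s),
              paste(round(x$inversion_times_s * 1000), collapse = "/"),
              x$excitation_tr_s * 1000, x$cycle_tr_s))
  cat(sprintf("  %g excitations/block, flip %s deg, inversion efficiency %g\n",
              x$n_excitations, paste(x$flip_deg, collapse = "/"),
              x$inversion_efficiency))
  invisible(x)
}
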