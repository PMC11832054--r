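# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tissue label codes used throughout the package
#'
#' Integer codes for the tissue label maps consumed and produced by the
#' phantom, calibration and evaluation functions.
#'
#' @format Named integer vector: background 0, CSF 1, WM 2, SGM 3, CGM 4.
#' @export
tissue_codes <- c(background = 0L, CSF = 1L, WM = 2L, SGM = 3L, CGM = 4L)

# Tissues entering quantitative comparisons (CSF and background excluded).
brain_tissues <- c("WM", "SGM", "CGM")

#' Derive a reproducible substream seed
#'
#' Expands a single user seed into per-(table, grid-point) substream seeds so
#' that Monte-Carlo histograms are bit-reproducible regardless of the order in
#' which B1 tables are built. Kept below 2^31 - 1.
#'
#' @param seed integer base seed.
#' @param ... further non-negative integer counters (table index, grid index).
#' @return A single integer seed.
#' @keywords internal
substream_seed <- function(seed, ...) {
  counters <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in counters) {
    # LCG-style mixing; doubles hold the intermediate exactly (< 2^53)
    s <- (s * 69069 + as.double(k) * 104729 + 12345) %% 2147483647
  }
  as.integer(s)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_mapt1 <- function(fmt, ..., class = "mapt1_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Population variance (denominator n), used so RMSE^2 = bias^2 + variance is
# exact in the agreement metrics.
pop_var <- function(x) mean((x - mean(x))^2)
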