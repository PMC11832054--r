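# Classical lookup-table (point-estimate) T1 mapping.

# Largest contiguous strictly-monotone run of `s` containing the grid index
# nearest `anchor` (in T1). Returns c(from, to) grid indices or NULL.
.monotone_run <- function(s, t1, anchor = 1.5, min_len = 10L) {
  d <- diff(s)
  sgn <- sign(d)
  if (!length(d) || all(sgn == 0)) return(NULL)
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i0 <- which.min(abs(t1 - anchor))
  best <- NULL
  for (j in seq_along(r$values)) {
    if (r$values[j] == 0) next
    from <- starts[j]; to <- ends[j] + 1L  # diff run i..j covers points i..j+1
    if (i0 < from || i0 > to) next
    if (is.null(best) || (to - from) > (best[2] - best[1])) best <- c(from, to)
  }
  if (is.null(best) || best[2] - best[1] + 1L < min_len) return(NULL)
  best
}

#' Build a monotone S(T1) lookup table
#'
#' Evaluates the uniform-image value S1,2 from the forward model on a T1 grid
#' at a fixed B1+ factor and restricts it to the largest contiguous strictly
#' monotone sub-grid containing T1 = 1.5 s, on which the relation can be
#' inverted. Values outside the recorded S range are out of the invertible
#' branch and must be masked, not clipped.
#'
#' @param params an [acq_params()] object.
#' @param b1 B1+ correction factor (scalar).
#' @param t1_grid T1 grid in seconds; default 500 points over (0, 5].
#' @param pair indices of the two GRE blocks combined (default 1 and 2).
#' @return Object of class `t1_lookup`: `t1`, `s` (monotone branch),
#'   `s_range`, `direction` (+1/-1), plus the full grid/curve.
#' @export
build_lookup <- function(params, b1 = 1,
                         t1_grid = seq(5 / 500, 5, length.out = 500),
                         pair = c(1L, 2L)) {
  sig <- mp2rage_signals(t1_grid, params, b1 = b1)
  if (!is.matrix(sig)) sig <- matrix(sig, ncol = 1)
  s_full <- uniform_signal(complex(real = sig[pair[1], ]),
                           complex(real = sig[pair[2], ]))
  run <- .monotone_run(s_full, t1_grid)
  if (is.null(run))
    stop_mapt1("no strictly monotone S(T1) segment of length >= 10 containing T1 = 1.5 s (b1 = %g)", b1)
  idx <- run[1]:run[2]
  structure(list(
    t1 = t1_grid[idx], s = s_full[idx],
    s_range = range(s_full[idx]),
    direction = sign(s_full[idx[length(idx)]] - s_full[idx[1]]),
    b1 = b1, pair = pair, full_t1 = t1_grid, full_s = s_full
  ), class = "t1_lookup")
}

#' Invert a lookup table
#'
#' Monotone linear interpolation of T1 from uniform-image values. Values
#' outside the table's S range return `NA` (masked invalid, never clipped).
#'
#' @param lookup a [build_lookup()] result.
#' @param s uniform-image values.
#' @return Numeric vector of T1 (seconds), `NA` where `s` is out of range.
#' @export
lookup_t1 <- function(lookup, s) {
  x <- lookup$s; y <- lookup$t1
  if (lookup$direction < 0) { x <- rev(x); y <- rev(y) }
  stats::approx(x, y, xout = s, rule = 1, ties = "ordered")$y
}

# Minimal container for voxelwise T1 results shared by all estimators.
new_t1_map <- function(t1, valid, method, sigma = NULL) {
  t1[!valid] <- NA_real_
  if (!is.null(sigma)) sigma[!valid] <- NA_real_
  structure(list(t1_s = t1, sigma_t1_s = sigma, valid_mask = valid,
                 method = method), class = "t1_map")
}

#' @export
print.t1_map <- function(x, ...) {
  cat(sprintf("T1 map (%s): %d/%d valid voxels, median T1 = %.3f s\n",
              x$method, sum(x$valid_mask), length(x$valid_mask),
              stats::median(x$t1_s[x$valid_mask])))
  invisible(x)
}

#' Point-estimate T1 mapping from a uniform image
#'
#' The classical inversion of the MP2RAGE model: per voxel, the S(T1) lookup
#' curve is linearly interpolated between the two tables bracketing the
#' voxel's B1+ factor (tables precomputed on `b1_grid`), and T1 is obtained by
#' monotone inverse interpolation. Voxels whose S value falls outside the
#' invertible branch, or whose B1 admits no monotone branch, are masked.
#'
#' @param uniform real array of uniform-image values in `[-0.5, 0.5]`.
#' @param b1map array of B1+ correction factors, same shape (values clipped
#'   to `[0, 2]` with a warning).
#' @param params an [acq_params()] object.
#' @param t1_grid T1 grid for the lookup curves.
#' @param b1_grid grid of B1 factors at which curves are tabulated.
#' @param pair GRE pair forming the uniform image.
#' @return A `t1_map` object (method `point_mp2rage`), without uncertainty.
#' @export
point_estimate_t1 <- function(uniform, b1map, params,
                              t1_grid = seq(5 / 500, 5, length.out = 500),
                              b1_grid = seq(0, 2, length.out = 41),
                              pair = c(1L, 2L)) {
  if (!identical(dim(uniform) %||% length(uniform),
                 dim(b1map) %||% length(b1map)))
    stop_mapt1("uniform image and B1 map must be co-registered (same shape)")
  b1v <- as.numeric(b1map)
  if (any(b1v < 0 | b1v > 2, na.rm = TRUE)) {
    warning("B1 factors outside [0, 2] clipped on ingest")
    b1v <- clamp(b1v, 0, 2)
  }
  nb <- length(b1_grid)
  # S1,2 curve per B1 grid value (full grid; monotone branch found per pair)
  curves <- vapply(b1_grid, function(b) {
    sig <- mp2rage_signals(t1_grid, params, b1 = b)
    uniform_signal(complex(real = sig[pair[1], ]), complex(real = sig[pair[2], ]))
  }, numeric(length(t1_grid)))
  # Invertible index range per bracketing pair: a convex blend of two curves
  # monotone in the same direction on a common range is monotone there.
  pair_range <- vector("list", nb - 1L)
  for (i in seq_len(nb - 1L)) {
    r1 <- .monotone_run(curves[, i], t1_grid)
    r2 <- .monotone_run(curves[, i + 1L], t1_grid)
    if (is.null(r1) || is.null(r2)) next
    d1 <- sign(curves[r1[2], i] - curves[r1[1], i])
    d2 <- sign(curves[r2[2], i + 1L] - curves[r2[1], i + 1L])
    if (d1 != d2) next
    from <- max(r1[1], r2[1]); to <- min(r1[2], r2[2])
    if (to - from + 1L >= 10L) pair_range[[i]] <- c(from, to)
  }
  sv <- as.numeric(uniform)
  t1_out <- rep(NA_real_, length(sv))
  lo <- findInterval(b1v, b1_grid, all.inside = TRUE)  # bracketing lower index
  w <- (b1v - b1_grid[lo]) / diff(b1_grid)[lo]
  for (i in unique(lo)) {
    rng <- pair_range[[i]]
    if (is.null(rng)) next
    vox <- which(lo == i)
    idx <- rng[1]:rng[2]
    t1_sub <- t1_grid[idx]
    c_lo <- curves[idx, i]; c_hi <- curves[idx, i + 1L]
    descending <- c_lo[length(c_lo)] < c_lo[1]
    for (v in vox) {
      s_curve <- (1 - w[v]) * c_lo + w[v] * c_hi
      t1v <- if (descending) {
        stats::approx(rev(s_curve), rev(t1_sub), xout = sv[v], rule = 1, ties = "ordered")$y
      } else {
        stats::approx(s_curve, t1_sub, xout = sv[v], rule = 1, ties = "ordered")$y
      }
      t1_out[v] <- t1v
    }
  }
  valid <- is.finite(t1_out)
  dim(t1_out) <- dim(uniform); dim(valid) <- dim(uniform)
  new_t1_map(t1_out, valid, "point_mp2rage")
}
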