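# Agreement metrics between co-registered T1 maps, label morphology, and the
# paired test used to compare fold-level errors.

# Coerce a t1_map or plain array to (values, validity) for metric functions.
.as_vol <- function(x) {
  if (inherits(x, "t1_map")) list(v = x$t1_s, ok = x$valid_mask)
  else list(v = x, ok = is.finite(x))
}

# Voxel indices entering a per-tissue comparison: label match and both maps
# valid (intersection of validity masks).
.tissue_voxels <- function(a, b, labels, tissue) {
  which(labels == tissue_codes[tissue] & a$ok & b$ok)
}

#' Erode one tissue label with a cubic structuring element
#'
#' Binary erosion of the named tissue's mask by a cube of odd side length;
#' eroded-away voxels become background so they drop out of the metrics
#' (partial-volume mitigation at tissue boundaries). Other labels are left
#' untouched.
#'
#' @param labels integer label array ([tissue_codes]).
#' @param tissue tissue name (default `"CGM"`, the class bordering CSF).
#' @param cube_side odd cube side in voxels (1 = identity; default 3).
#' @return The modified label array.
#' @export
erode_labels <- function(labels, tissue = "CGM", cube_side = 3L) {
  stopifnot(cube_side >= 1L, cube_side %% 2L == 1L)
  code <- tissue_codes[tissue]
  mask <- labels == code
  if (!any(mask)) {
    warning(sprintf("tissue %s absent; erosion is the identity", tissue))
    return(labels)
  }
  if (cube_side == 1L) return(labels)
  r <- (cube_side - 1L) %/% 2L
  d <- dim(mask)
  core <- mask
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    if (dx == 0 && dy == 0 && dz == 0) next
    shifted <- array(FALSE, d)
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    shifted[xs, ys, zs] <- mask[xs - dx, ys - dy, zs - dz]
    core <- core & shifted
  }
  labels[mask & !core] <- tissue_codes["background"]
  labels
}

#' Per-tissue root mean square error between two T1 maps
#'
#' @param map_a,ref `t1_map` objects or plain arrays (seconds).
#' @param labels tissue label array.
#' @param tissues tissue names to report.
#' @return Named numeric vector of RMSE (s); `NA` where no voxels overlap.
#' @export
rmse_by_tissue <- function(map_a, ref, labels, tissues = brain_tissues) {
  a <- .as_vol(map_a); b <- .as_vol(ref)
  vapply(tissues, function(t) {
    vox <- .tissue_voxels(a, b, labels, t)
    if (!length(vox)) return(NA_real_)
    sqrt(mean((a$v[vox] - b$v[vox])^2))
  }, numeric(1))
}

#' Per-tissue relative value (percent)
#'
#' `100 * mean(a) / mean(ref)` over each tissue's voxels. Multi-subject
#' summaries should average these per-subject percentages.
#'
#' @inheritParams rmse_by_tissue
#' @param voxelwise if `TRUE`, average the voxelwise ratio instead of taking
#'   the ratio of tissue means (alternative aggregation, off by default).
#' @return Named numeric vector of percentages.
#' @export
relative_value_by_tissue <- function(map_a, ref, labels,
                                     tissues = brain_tissues,
                                     voxelwise = FALSE) {
  a <- .as_vol(map_a); b <- .as_vol(ref)
  vapply(tissues, function(t) {
    vox <- .tissue_voxels(a, b, labels, t)
    if (!length(vox)) return(NA_real_)
    if (voxelwise) 100 * mean(a$v[vox] / b$v[vox])
    else {
      m <- mean(b$v[vox])
      if (m == 0) return(NA_real_)
      100 * mean(a$v[vox]) / m
    }
  }, numeric(1))
}

#' Bland-Altman-style bias/variance decomposition per tissue
#'
#' For each tissue reports the mean voxelwise error (bias), the population SD
#' of the error, limits of agreement `bias +/- 1.96 * SD`, the error variance
#' and the RMSE. The population-variance convention makes
#' `rmse^2 = bias^2 + variance` an exact identity.
#'
#' @inheritParams rmse_by_tissue
#' @return Data frame with one row per tissue: `tissue`, `n_voxels`,
#'   `bias_s`, `sd_s`, `loa_low_s`, `loa_high_s`, `error_variance_s2`,
#'   `rmse_s`.
#' @export
bland_altman <- function(map_a, ref, labels, tissues = brain_tissues) {
  a <- .as_vol(map_a); b <- .as_vol(ref)
  rows <- lapply(tissues, function(t) {
    vox <- .tissue_voxels(a, b, labels, t)
    if (!length(vox))
      return(data.frame(tissue = t, n_voxels = 0L, bias_s = NA_real_,
                        sd_s = NA_real_, loa_low_s = NA_real_,
                        loa_high_s = NA_real_, error_variance_s2 = NA_real_,
                        rmse_s = NA_real_))
    err <- a$v[vox] - b$v[vox]
    bias <- mean(err)
    v <- pop_var(err)
    s <- sqrt(v)
    data.frame(tissue = t, n_voxels = length(vox), bias_s = bias, sd_s = s,
               loa_low_s = bias - 1.96 * s, loa_high_s = bias + 1.96 * s,
               error_variance_s2 = v, rmse_s = sqrt(bias^2 + v))
  })
  do.call(rbind, rows)
}

#' Paired t-test between two metric vectors
#'
#' Classical paired two-sided t-test (e.g. fold-level RMSE before vs after
#' calibration) with a significance flag at alpha = 0.05. Zero-variance
#' differences are reported as degenerate rather than raising an error.
#'
#' @param values_a,values_b paired numeric vectors (length >= 2).
#' @return List: `t_statistic`, `p_value`, `significant_at_0p05`, `n_pairs`,
#'   `degenerate`.
#' @export
paired_t <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  if (stats::sd(d) == 0)
    return(list(t_statistic = NA_real_, p_value = NA_real_,
                significant_at_0p05 = FALSE, n_pairs = length(d),
                degenerate = TRUE))
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       significant_at_0p05 = ht$p.value < 0.05, n_pairs = length(d),
       degenerate = FALSE)
}
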