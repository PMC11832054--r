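# Patch-based residual-CNN calibration of MP2RAGE T1 maps to multi-TI IR
# T1 values: patch extraction, model construction/training with early
# stopping, whole-volume application, leave-one-out cross-validation, and
# the patch-size / noise-level sensitivity sweeps.

#' Calibration configuration
#'
#' Defaults follow the training recipe: 5x5 in-plane patches, batches of 256,
#' learning rate 1e-5, up to 10,000 steps with validation every 50 steps and
#' early stopping after 1000 steps (20 evaluations) without a new best
#' validation loss. `width_base = 64` gives the stock 18-layer residual
#' topology (widths 64/128/256/512); smaller bases shrink every stage
#' proportionally for reduced-scale benchmarks.
#'
#' @param patch_size odd in-plane patch side, one of 1, 5, 9, 13.
#' @param in_channels 1 (T1 only) or 2 (T1 plus posterior-SD channel).
#' @param learning_rate Adam step size.
#' @param batch_size patches per gradient step.
#' @param max_steps maximum gradient steps.
#' @param val_every validation cadence in steps.
#' @param patience_steps early-stopping horizon (multiple of `val_every`).
#' @param width_base channel width of the first stage.
#' @param seed seed for initialization and batch shuffling.
#' @return Object of class `calib_config`.
#' @export
calib_config <- function(patch_size = 5L, in_channels = 1L,
                         learning_rate = 1e-5, batch_size = 256L,
                         max_steps = 10000L, val_every = 50L,
                         patience_steps = 1000L, width_base = 64L,
                         seed = 1L) {
  stopifnot(patch_size %in% c(1L, 5L, 9L, 13L), in_channels %in% 1:2,
            learning_rate > 0, batch_size >= 1, max_steps >= 1,
            val_every >= 1, patience_steps %% val_every == 0,
            width_base >= 1)
  structure(list(patch_size = as.integer(patch_size),
                 in_channels = as.integer(in_channels),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps),
                 val_every = as.integer(val_every),
                 patience_steps = as.integer(patience_steps),
                 width_base = as.integer(width_base),
                 seed = as.integer(seed)),
            class = "calib_config")
}

#' Reduced-scale calibration configuration
#'
#' The settings used for the package's synthetic benchmark on a single CPU:
#' the same topology at width base 4, batch 64, learning rate 1e-3, and a
#' 2000-step cap (the learning rate is raised to compensate for the shorter
#' schedule; see the methods vignette).
#'
#' @param ... overrides passed to [calib_config()].
#' @export
calib_config_reduced <- function(...) {
  args <- list(...)
  defaults <- list(width_base = 4L, batch_size = 64L, learning_rate = 1e-3,
                   max_steps = 2000L)
  do.call(calib_config, utils::modifyList(defaults, args))
}

# Reflect-padding index vector for one axis: padded position -> original.
.reflect_idx <- function(n, r) {
  if (r == 0L) return(seq_len(n))
  c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
}

#' Extract training patches from a T1 map
#'
#' One sample per WM/SGM/CGM voxel with a valid (finite) center value, on
#' each axial slice. Patches are 2-D in-plane windows; in-plane edges use
#' reflect padding and invalid neighbors are replaced by the center value.
#' Ordering is deterministic by (slice, row, column).
#'
#' @param t1 input T1 volume (`t1_map` or array, seconds).
#' @param labels tissue label array.
#' @param cfg a [calib_config()] (patch size and channel count).
#' @param sigma optional posterior-SD volume for the second channel.
#' @param target optional reference T1 volume providing the regression
#'   target at the center voxel.
#' @param subject_id optional identifier recorded per sample.
#' @return List: `x` (`(P^2 * n) x C` matrix, pixel-major row order), `y`
#'   (targets or `NULL`), `n`, `meta` (data frame: slice, row, col, tissue,
#'   subject, voxel).
#' @export
extract_patches <- function(t1, labels, cfg, sigma = NULL, target = NULL,
                            subject_id = NA_integer_) {
  a <- .as_vol(t1)
  if (cfg$in_channels == 2L && is.null(sigma))
    stop_mapt1("cfg requests 2 channels but no sigma volume was supplied")
  if (cfg$in_channels == 1L && !is.null(sigma))
    stop_mapt1("sigma channel supplied but cfg$in_channels is 1")
  tgt <- if (!is.null(target)) .as_vol(target) else NULL
  shp <- dim(a$v)
  P <- cfg$patch_size
  r <- (P - 1L) %/% 2L
  brain <- array(labels %in% tissue_codes[brain_tissues], dim(labels))
  off <- as.matrix(expand.grid(a = -r:r, b = -r:r))  # a (row) fastest
  xs_list <- list(); y_list <- list(); meta <- list()
  for (z in seq_len(shp[3])) {
    sl_v <- a$v[, , z]; sl_ok <- a$ok[, , z] & is.finite(sl_v)
    cen <- which(brain[, , z] & sl_ok, arr.ind = TRUE)
    if (!is.null(tgt)) {
      keep <- tgt$ok[, , z][cen] & is.finite(tgt$v[, , z][cen])
      cen <- cen[keep, , drop = FALSE]
    }
    if (!nrow(cen)) next
    cen <- cen[order(cen[, 1], cen[, 2]), , drop = FALSE]
    ri <- .reflect_idx(shp[1], r); ci <- .reflect_idx(shp[2], r)
    grab <- function(slice, okslice, centers) {
      sp <- slice[ri, ci, drop = FALSE]
      op <- okslice[ri, ci, drop = FALSE]
      Hp <- nrow(sp)
      cvals <- slice[centers]
      out <- matrix(0, nrow(centers), P * P)
      for (o in seq_len(nrow(off))) {
        lin <- (centers[, 1] + r + off[o, 1]) +
          (centers[, 2] + r + off[o, 2] - 1L) * Hp
        v <- sp[lin]
        out[, o] <- ifelse(op[lin] & is.finite(v), v, cvals)
      }
      out
    }
    px <- grab(sl_v, sl_ok, cen)
    chans <- list(px)
    if (cfg$in_channels == 2L) {
      sg <- sigma[, , z]
      chans[[2]] <- grab(sg, sl_ok & is.finite(sg), cen)
    }
    xs_list[[length(xs_list) + 1L]] <- chans
    if (!is.null(tgt)) y_list[[length(y_list) + 1L]] <- tgt$v[, , z][cen]
    meta[[length(meta) + 1L]] <- data.frame(
      slice = z, row = cen[, 1], col = cen[, 2],
      tissue = names(tissue_codes)[match(labels[, , z][cen], tissue_codes)],
      subject = subject_id,
      voxel = cen[, 1] + (cen[, 2] - 1L) * shp[1] + (z - 1L) * shp[1] * shp[2])
  }
  if (!length(xs_list)) stop_mapt1("no eligible patch centers found")
  n <- sum(vapply(xs_list, function(ch) nrow(ch[[1]]), numeric(1)))
  # channels-first layout: columns are pixel-major per sample
  X <- matrix(0, cfg$in_channels, P * P * n)
  for (ch in seq_len(cfg$in_channels)) {
    X[ch, ] <- unlist(lapply(xs_list, function(b) as.vector(t(b[[ch]]))),
                      use.names = FALSE)
  }
  list(x = X, y = if (length(y_list)) unlist(y_list) else NULL, n = n,
       meta = do.call(rbind, meta), patch = P, channels = cfg$in_channels)
}

# Concatenate patch sets (e.g. training subjects).
.bind_patches <- function(sets) {
  list(x = do.call(cbind, lapply(sets, `[[`, "x")),
       y = unlist(lapply(sets, `[[`, "y")),
       n = sum(vapply(sets, `[[`, numeric(1), "n")),
       meta = do.call(rbind, lapply(sets, `[[`, "meta")),
       patch = sets[[1]]$patch, channels = sets[[1]]$channels)
}

#' Build the patch-regression network
#'
#' Residual CNN regressing a single T1 value from a patch: 3x3 stride-1 stem,
#' four stages of two basic residual blocks (widths `width_base * (1,2,4,8)`,
#' 18 weight layers at the stock width 64), with stage downsampling dropped
#' whenever the running spatial extent is below 4 so that tiny patches do not
#' collapse, global average pooling, and a scalar affine head.
#' Initialization is fully determined by `cfg$seed`.
#'
#' @param cfg a [calib_config()].
#' @return Model object (opaque environment) of class `calib_model`.
#' @export
build_regressor <- function(cfg) {
  m <- nn_build(cfg$patch_size, cfg$in_channels, cfg$width_base, cfg$seed)
  m$cfg <- cfg
  class(m) <- c("calib_model", "environment")
  m
}

#' @export
print.calib_model <- function(x, ...) {
  np <- sum(vapply(x$par, length, numeric(1)))
  cat(sprintf("Patch regression CNN: %dx%d x %d input, width base %d, %d parameters\n",
              x$patch, x$patch, x$in_channels, x$width_base, np))
  invisible(x)
}

# Columns of the (channels x pixels) dataset matrix for sample indices.
.patch_cols <- function(samples, P2) {
  rep((samples - 1L) * P2, each = P2) + seq_len(P2)
}

#' Train the calibration network
#'
#' Adam on the mean-square error between the network output and the
#' reference T1 at the patch center, with seeded batch shuffling, validation
#' MSE every `val_every` steps, and early stopping when the best validation
#' loss has not improved within `patience_steps`. The returned model carries
#' the best-validation checkpoint.
#'
#' @param train,val patch sets from [extract_patches()] (with targets).
#' @param cfg a [calib_config()].
#' @param model optional pre-built [build_regressor()] model to continue.
#' @param val_max cap on validation samples used per evaluation (seeded
#'   subsample; `Inf` evaluates the full set).
#' @return List: `model`, `history` (data frame of step/val MSE), `best_step`,
#'   `best_val`, `steps_run`.
#' @export
train_calibrator <- function(train, val, cfg, model = NULL, val_max = Inf) {
  if (is.null(train$y) || is.null(val$y))
    stop_mapt1("training and validation patch sets need targets")
  if (train$n < 1 || val$n < 1) stop_mapt1("empty train or validation set")
  if (is.null(model)) model <- build_regressor(cfg)
  P2 <- cfg$patch_size^2
  opt <- new.env(parent = emptyenv()); opt$t <- 0L
  opt$m <- list(); opt$v <- list()
  set.seed(substream_seed(cfg$seed, 53L))
  vidx <- seq_len(val$n)
  if (is.finite(val_max) && val$n > val_max)
    vidx <- sort(sample.int(val$n, val_max))
  vX <- val$x[, .patch_cols(vidx, P2), drop = FALSE]
  vy <- val$y[vidx]
  eval_val <- function() {
    pr <- nn_predict(model, vX, length(vidx))
    mean((pr - vy)^2)
  }
  pool <- sample.int(train$n)
  pos <- 1L
  best <- NULL; best_step <- 0L; evals_bad <- 0L
  hist_step <- integer(0); hist_val <- numeric(0)
  max_bad <- cfg$patience_steps %/% cfg$val_every
  step <- 0L
  while (step < cfg$max_steps) {
    step <- step + 1L
    if (pos + cfg$batch_size - 1L > train$n) {
      pool <- sample.int(train$n); pos <- 1L
    }
    bidx <- pool[pos:(pos + cfg$batch_size - 1L)]
    pos <- pos + cfg$batch_size
    bX <- train$x[, .patch_cols(bidx, P2), drop = FALSE]
    by <- train$y[bidx]
    fw <- nn_forward(model, bX, cfg$batch_size, train = TRUE, keep = TRUE)
    loss <- mean((fw$pred - by)^2)
    if (!is.finite(loss))
      stop_mapt1("training diverged (non-finite loss at step %d)", step)
    gr <- nn_backward(model, fw$caches, 2 * (fw$pred - by) / cfg$batch_size,
                      cfg$batch_size)
    nn_adam_step(model, gr, opt, cfg$learning_rate)
    if (step %% cfg$val_every == 0L) {
      v <- eval_val()
      hist_step <- c(hist_step, step); hist_val <- c(hist_val, v)
      if (is.null(best) || v < best$val) {
        best <- list(val = v, snap = nn_snapshot(model))
        best_step <- step
        evals_bad <- 0L
      } else {
        evals_bad <- evals_bad + 1L
        if (evals_bad >= max_bad) break
      }
    }
  }
  if (!is.null(best)) nn_restore(model, best$snap)
  list(model = model, history = data.frame(step = hist_step, val_mse = hist_val),
       best_step = best_step, best_val = if (is.null(best)) NA_real_ else best$val,
       steps_run = step)
}

#' Apply a trained calibrator to a T1 map
#'
#' Predicts a calibrated T1 for every WM/SGM/CGM voxel with a valid input
#' value; all other voxels are invalid in the output mask.
#'
#' @param model a trained [build_regressor()] model.
#' @param t1 input T1 volume (`t1_map` or array).
#' @param labels tissue label array.
#' @param cfg the [calib_config()] the model was trained with.
#' @param sigma optional posterior-SD volume (required iff 2-channel).
#' @return A `t1_map` (method `calibrated`).
#' @export
apply_calibrator <- function(model, t1, labels, cfg, sigma = NULL) {
  if (model$patch != cfg$patch_size || model$in_channels != cfg$in_channels)
    stop_mapt1("model was built for patch %d x %d channels, got config %d x %d",
               model$patch, model$in_channels, cfg$patch_size, cfg$in_channels)
  ps <- extract_patches(t1, labels, cfg, sigma = sigma)
  pred <- nn_predict(model, ps$x, ps$n)
  shp <- dim(.as_vol(t1)$v)
  out <- array(NA_real_, shp); ok <- array(FALSE, shp)
  out[ps$meta$voxel] <- pred
  ok[ps$meta$voxel] <- TRUE
  new_t1_map(out, ok, "calibrated")
}

#' Leave-one-out cross-validated calibration
#'
#' Rotates the test subject across folds (n folds for n subjects, 4 in the
#' benchmark design), with one validation subject and the rest for training;
#' subject identities are disjoint by construction and asserted. Per fold,
#' reports per-tissue RMSE and relative value of the input (uncalibrated) and
#' calibrated map against the reference on the held-out subject, and a paired
#' t-test on the fold-level before/after RMSE.
#'
#' @param subjects list of subject lists as produced by [synth_subjects()]
#'   (fields `mp2rage_biased`, `ir_t1`, `labels`, plus `sigma_t1` when
#'   2-channel).
#' @param cfg a [calib_config()].
#' @param val_max validation-sample cap per evaluation (see
#'   [train_calibrator()]).
#' @return List: `folds` (data frame, one row per fold x tissue), `summary`
#'   (mean/SD across folds), `ttest` (paired test on fold mean RMSE),
#'   `models`.
#' @export
loo_cv <- function(subjects, cfg, val_max = Inf) {
  n <- length(subjects)
  if (n < 4L) stop_mapt1("leave-one-out calibration needs >= 4 subjects")
  two_ch <- cfg$in_channels == 2L
  patches <- lapply(seq_len(n), function(s) {
    sub <- subjects[[s]]
    extract_patches(sub$mp2rage_biased, sub$labels, cfg,
                    sigma = if (two_ch) sub$sigma_t1 else NULL,
                    target = sub$ir_t1, subject_id = s)
  })
  rows <- list(); models <- list(); fold_rmse <- matrix(NA_real_, n, 2)
  for (fold in seq_len(n)) {
    test_s <- fold
    val_s <- fold %% n + 1L
    train_s <- setdiff(seq_len(n), c(test_s, val_s))
    stopifnot(length(intersect(train_s, c(val_s, test_s))) == 0L,
              val_s != test_s)
    cfg_fold <- cfg; cfg_fold$seed <- substream_seed(cfg$seed, 59L, fold)
    tr <- train_calibrator(.bind_patches(patches[train_s]), patches[[val_s]],
                           cfg_fold, val_max = val_max)
    models[[fold]] <- tr$model
    sub <- subjects[[test_s]]
    calib <- apply_calibrator(tr$model, sub$mp2rage_biased, sub$labels,
                              cfg_fold, sigma = if (two_ch) sub$sigma_t1)
    before <- rmse_by_tissue(sub$mp2rage_biased, sub$ir_t1, sub$labels)
    after <- rmse_by_tissue(calib, sub$ir_t1, sub$labels)
    rel_b <- relative_value_by_tissue(sub$mp2rage_biased, sub$ir_t1, sub$labels)
    rel_a <- relative_value_by_tissue(calib, sub$ir_t1, sub$labels)
    rows[[fold]] <- data.frame(
      fold = fold, test_subject = test_s, tissue = brain_tissues,
      rmse_uncalibrated_s = unname(before), rmse_calibrated_s = unname(after),
      relative_uncalibrated_pct = unname(rel_b),
      relative_calibrated_pct = unname(rel_a),
      best_step = tr$best_step, steps_run = tr$steps_run)
    fold_rmse[fold, ] <- c(mean(before), mean(after))
  }
  folds <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(rmse_uncalibrated_s, rmse_calibrated_s,
                                relative_uncalibrated_pct,
                                relative_calibrated_pct) ~ tissue,
                          folds, function(x) c(mean = mean(x), sd = stats::sd(x)))
  list(folds = folds, summary = agg,
       ttest = paired_t(fold_rmse[, 1], fold_rmse[, 2]),
       models = models)
}

#' Patch-size and noise-level sensitivity sweeps
#'
#' Re-generates the MP2RAGE-side maps at each Monte-Carlo noise level
#' (reduced 1e6-trial mode by default) and/or re-trains the calibrator at
#' each patch size, reporting calibrated and uncalibrated per-tissue RMSE for
#' every setting. Training uses a single fold (train on subjects 3..n,
#' validate on 2, test on 1) to keep the grid affordable; set `train = FALSE`
#' for the uncalibrated-only noise sweep.
#'
#' @param spec a [phantom_spec()].
#' @param cfg a [calib_config()].
#' @param params acquisition protocol.
#' @param patch_sizes patch sides to sweep (`NULL` skips the patch sweep).
#' @param noise_sigmas Monte-Carlo noise levels to sweep.
#' @param n_trials Monte-Carlo trials per noise level.
#' @param train fit the calibrator per setting (else uncalibrated only).
#' @param val_max validation cap (see [train_calibrator()]).
#' @return Data frame: sweep, setting, tissue, uncalibrated/calibrated RMSE.
#' @export
sensitivity_sweeps <- function(spec, cfg, params = default_protocol(),
                               patch_sizes = c(1L, 5L, 9L, 13L),
                               noise_sigmas = c(0.001, 0.005, 0.01, 0.015,
                                                0.02),
                               n_trials = 1e6, train = TRUE, val_max = Inf) {
  out <- list()
  run_setting <- function(subjects, cfg_s, sweep, setting) {
    sub1 <- subjects[[1]]
    before <- rmse_by_tissue(sub1$mp2rage_biased, sub1$ir_t1, sub1$labels)
    after <- rep(NA_real_, length(before))
    if (train) {
      n <- length(subjects)
      patches <- lapply(seq_len(n), function(s)
        extract_patches(subjects[[s]]$mp2rage_biased, subjects[[s]]$labels,
                        cfg_s, target = subjects[[s]]$ir_t1, subject_id = s))
      tr <- train_calibrator(.bind_patches(patches[seq(3, n)]), patches[[2]],
                             cfg_s, val_max = val_max)
      calib <- apply_calibrator(tr$model, sub1$mp2rage_biased, sub1$labels,
                                cfg_s)
      after <- rmse_by_tissue(calib, sub1$ir_t1, sub1$labels)
    }
    data.frame(sweep = sweep, setting = setting, tissue = brain_tissues,
               rmse_uncalibrated_s = unname(before),
               rmse_calibrated_s = unname(after))
  }
  if (!is.null(noise_sigmas)) {
    for (sg in noise_sigmas) {
      mc <- mc_config(n_trials = n_trials, noise_sigma = sg, seed = spec$seed)
      subs <- synth_subjects(spec, params = params, map_cfg = mc)
      out[[length(out) + 1L]] <- run_setting(subs, cfg, "noise_sigma", sg)
    }
  }
  if (!is.null(patch_sizes)) {
    mc <- mc_config(n_trials = n_trials, noise_sigma = spec$noise_sigma,
                    seed = spec$seed)
    subs <- synth_subjects(spec, params = params, map_cfg = mc)
    for (P in patch_sizes) {
      cfg_p <- cfg; cfg_p$patch_size <- as.integer(P)
      out[[length(out) + 1L]] <- run_setting(subs, cfg_p, "patch_size", P)
    }
  }
  do.call(rbind, out)
}
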