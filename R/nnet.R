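# Minimal convolutional-network engine used by the patch calibration model.
#
# Everything is dense linear algebra: convolutions are im2col gathers
# followed by a single matrix multiply (BLAS), batch normalization and the
# residual adds are vectorized, and optimization is Adam. Activations are
# stored channels-first as C x (H*W*N) matrices — columns ordered (h fastest,
# then w, then sample) — so spatial gathers are contiguous column copies and
# per-channel broadcasts are plain R recycling. The model lives in an
# environment so parameter updates and batch-norm running statistics mutate
# in place. All randomness is seeded.

# --- geometry -------------------------------------------------------------

# im2col index sets for a (k x k, stride, pad) convolution on H x W inputs
# with batch size N. Cached per model because they depend only on shapes.
.nn_geom <- function(H, W, k, stride, pad, N) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  HW <- H * W; HpWp <- Hp * Wp; HoWo <- Ho * Wo
  noff <- (0:(N - 1L)) * HpWp
  inner <- NULL
  if (pad > 0L) {
    h <- rep(seq_len(H), times = W)
    w <- rep(seq_len(W), each = H)
    base <- (h + pad) + (w + pad - 1L) * Hp
    inner <- rep(base, times = N) + rep(noff, each = HW)
  }
  off <- vector("list", k * k)
  ho <- rep(seq_len(Ho), times = Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  o <- 0L
  for (b in seq_len(k)) for (a in seq_len(k)) {
    o <- o + 1L
    base <- ((ho - 1L) * stride + a) + ((wo - 1L) * stride + b - 1L) * Hp
    off[[o]] <- rep(base, times = N) + rep(noff, each = HoWo)
  }
  list(H = H, W = W, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, k = k,
       stride = stride, pad = pad, N = N, inner = inner, off = off,
       off_all = unlist(off),
       identity = (k == 1L && stride == 1L && pad == 0L))
}

.nn_geom_cached <- function(model, H, W, k, stride, pad, N) {
  key <- paste(H, W, k, stride, pad, N, sep = "_")
  g <- model$geom[[key]]
  if (is.null(g)) {
    g <- .nn_geom(H, W, k, stride, pad, N)
    model$geom[[key]] <- g
  }
  g
}

# --- primitive layers -----------------------------------------------------

# Weights: (k^2 * Cin) x Cout, rows offset-major with channel fastest.
.conv_fwd <- function(Wmat, X, g, Cin) {
  if (g$identity)
    return(list(Y = crossprod(Wmat, X), cols = X))
  if (g$pad > 0L) {
    Xp <- matrix(0, Cin, g$Hp * g$Wp * g$N)
    Xp[, g$inner] <- X
  } else Xp <- X
  k2 <- g$k * g$k
  M <- g$Ho * g$Wo * g$N
  if (k2 == 1L) {
    cols <- Xp[, g$off[[1L]], drop = FALSE]
  } else {
    big <- Xp[, g$off_all, drop = FALSE]        # Cin x (k2 * M)
    dim(big) <- c(Cin, M, k2)
    cols <- aperm(big, c(1L, 3L, 2L))           # (Cin, k2, M)
    dim(cols) <- c(Cin * k2, M)
  }
  list(Y = crossprod(Wmat, cols), cols = cols)
}

.conv_bwd <- function(Wmat, dY, cols, g, Cin, model = NULL) {
  dW <- tcrossprod(cols, dY)
  if (g$identity)
    return(list(dX = Wmat %*% dY, dW = dW))
  k2 <- g$k * g$k
  if (g$stride == 1L && g$k == 3L && g$pad == 1L && !is.null(model)) {
    # stride-1 conv: the input gradient is the convolution of dY with the
    # 180-degree-rotated kernel — a gather + GEMM instead of scatter-adds
    Cout <- ncol(Wmat)
    Wa <- Wmat
    dim(Wa) <- c(Cin, k2, Cout)
    Wt <- aperm(Wa[, k2:1, , drop = FALSE], c(3, 2, 1))
    dim(Wt) <- c(k2 * Cout, Cin)
    gb <- .nn_geom_cached(model, g$Ho, g$Wo, 3L, 1L, 1L, g$N)
    back <- .conv_fwd(Wt, dY, gb, Cout)
    return(list(dX = back$Y, dW = dW))
  }
  dcols <- Wmat %*% dY                           # (k2 * Cin) x M
  dXp <- matrix(0, Cin, g$Hp * g$Wp * g$N)
  rows <- seq_len(Cin)
  for (o in seq_len(k2)) {
    idx <- g$off[[o]]
    dXp[, idx] <- dXp[, idx, drop = FALSE] +
      dcols[(o - 1L) * Cin + rows, , drop = FALSE]
  }
  dX <- if (g$pad > 0L) dXp[, g$inner, drop = FALSE] else dXp
  list(dX = dX, dW = dW)
}

# Batch norm over columns, per channel row; population variance so the
# backward pass is exact. Broadcasts are column-major recycling.
.bn_fwd <- function(model, key, X, train) {
  g <- model$par[[paste0(key, ".g")]]
  b <- model$par[[paste0(key, ".b")]]
  eps <- 1e-5
  if (train) {
    mu <- rowMeans(X)
    xc <- X - mu
    v <- rowMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * inv
    st <- model$bn[[key]]
    mom <- 0.1
    model$bn[[key]] <- list(rm = (1 - mom) * st$rm + mom * mu,
                            rv = (1 - mom) * st$rv + mom * v)
    list(Y = xhat * g + b, xhat = xhat, inv = inv)
  } else {
    st <- model$bn[[key]]
    inv <- 1 / sqrt(st$rv + eps)
    xhat <- (X - st$rm) * inv
    list(Y = xhat * g + b)
  }
}

.bn_bwd <- function(model, key, dY, cache) {
  g <- model$par[[paste0(key, ".g")]]
  m <- ncol(dY)
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  dX <- (g * cache$inv) *
    (dY - dbeta / m - cache$xhat * (dgamma / m))
  list(dX = dX, dg = dgamma, db = dbeta)
}

# --- model construction ---------------------------------------------------

# Residual regression network: 3x3 stride-1 stem (no max-pool), four stages
# of two basic blocks with widths width_base * (1, 2, 4, 8); a stage's
# opening stride is 2 only while the incoming spatial extent is >= 4 (tiny
# inputs would otherwise collapse), global average pooling, affine head to a
# single scalar. width_base = 64 gives the stock 18-layer configuration.
nn_build <- function(patch, in_channels, width_base, seed) {
  model <- new.env(parent = emptyenv())
  model$par <- list(); model$bn <- list(); model$geom <- list()
  model$patch <- patch; model$in_channels <- in_channels
  model$width_base <- width_base; model$seed <- seed
  set.seed(seed)
  add_conv <- function(key, k, Cin, Cout) {
    model$par[[key]] <- matrix(
      stats::rnorm(k * k * Cin * Cout, 0, sqrt(2 / (k * k * Cin))),
      k * k * Cin, Cout)
  }
  add_bn <- function(key, C) {
    model$par[[paste0(key, ".g")]] <- rep(1, C)
    model$par[[paste0(key, ".b")]] <- rep(0, C)
    model$bn[[key]] <- list(rm = rep(0, C), rv = rep(1, C))
  }
  widths <- width_base * c(1L, 2L, 4L, 8L)
  H <- patch
  add_conv("stem.conv", 3L, in_channels, widths[1])
  add_bn("stem.bn", widths[1])
  stages <- list()
  Cin <- widths[1]
  for (s in 1:4) {
    Cout <- widths[s]
    blocks <- list()
    for (j in 1:2) {
      stride <- if (s > 1 && j == 1 && H >= 4) 2L else 1L
      Hout <- (H + 2L - 3L) %/% stride + 1L
      key <- sprintf("s%db%d", s, j)
      add_conv(paste0(key, ".conv1"), 3L, Cin, Cout)
      add_bn(paste0(key, ".bn1"), Cout)
      add_conv(paste0(key, ".conv2"), 3L, Cout, Cout)
      add_bn(paste0(key, ".bn2"), Cout)
      proj <- stride != 1L || Cin != Cout
      if (proj) {
        add_conv(paste0(key, ".proj"), 1L, Cin, Cout)
        add_bn(paste0(key, ".bnp"), Cout)
      }
      blocks[[j]] <- list(key = key, Cin = Cin, Cout = Cout, stride = stride,
                          Hin = H, Hout = Hout, proj = proj)
      Cin <- Cout; H <- Hout
    }
    stages[[s]] <- blocks
  }
  model$arch <- stages
  model$head_dim <- widths[4]
  model$par[["fc.W"]] <- matrix(stats::rnorm(widths[4], 0, 0.01), widths[4], 1)
  model$par[["fc.b"]] <- 0
  model
}

# Forward pass. X: in_channels x (patch^2 * N) matrix. Returns predictions
# (length N) and, when `keep = TRUE`, the caches needed for backprop.
nn_forward <- function(model, X, N, train = FALSE, keep = FALSE) {
  caches <- if (keep) list() else NULL
  g <- .nn_geom_cached(model, model$patch, model$patch, 3L, 1L, 1L, N)
  cv <- .conv_fwd(model$par[["stem.conv"]], X, g, model$in_channels)
  bn <- .bn_fwd(model, "stem.bn", cv$Y, train)
  A <- bn$Y * (bn$Y > 0)
  if (keep) caches$stem <- list(cols = cv$cols, bn = bn, g = g)
  for (s in 1:4) for (j in 1:2) {
    blk <- model$arch[[s]][[j]]
    key <- blk$key
    g1 <- .nn_geom_cached(model, blk$Hin, blk$Hin, 3L, blk$stride, 1L, N)
    c1 <- .conv_fwd(model$par[[paste0(key, ".conv1")]], A, g1, blk$Cin)
    b1 <- .bn_fwd(model, paste0(key, ".bn1"), c1$Y, train)
    r1 <- b1$Y * (b1$Y > 0)
    g2 <- .nn_geom_cached(model, blk$Hout, blk$Hout, 3L, 1L, 1L, N)
    c2 <- .conv_fwd(model$par[[paste0(key, ".conv2")]], r1, g2, blk$Cout)
    b2 <- .bn_fwd(model, paste0(key, ".bn2"), c2$Y, train)
    if (blk$proj) {
      gp <- .nn_geom_cached(model, blk$Hin, blk$Hin, 1L, blk$stride, 0L, N)
      cp <- .conv_fwd(model$par[[paste0(key, ".proj")]], A, gp, blk$Cin)
      bp <- .bn_fwd(model, paste0(key, ".bnp"), cp$Y, train)
      sc <- bp$Y
    } else {
      gp <- cp <- bp <- NULL
      sc <- A
    }
    pre <- b2$Y + sc
    out <- pre * (pre > 0)
    if (keep)
      caches[[key]] <- list(A = A, c1 = c1, b1 = b1, pre1 = b1$Y, r1 = r1,
                            c2 = c2, b2 = b2, cp = cp, bp = bp,
                            g1 = g1, g2 = g2, gp = gp)
    A <- out
  }
  HW <- model$arch[[4]][[2]]$Hout^2
  C <- model$head_dim
  B <- A
  dim(B) <- c(C, HW, N)
  pooled <- colSums(aperm(B, c(2L, 1L, 3L))) / HW   # C x N
  dim(pooled) <- c(C, N)
  pred <- drop(crossprod(pooled, model$par[["fc.W"]])) + model$par[["fc.b"]]
  if (keep) {
    caches$pooled <- pooled; caches$HW <- HW
    caches$lastA <- A
    list(pred = pred, caches = caches)
  } else pred
}

# Backward pass: returns the flat gradient list keyed like model$par.
nn_backward <- function(model, caches, dpred, N) {
  gr <- list()
  dpred <- matrix(dpred, N, 1)
  gr[["fc.W"]] <- caches$pooled %*% dpred
  gr[["fc.b"]] <- sum(dpred)
  dpool <- tcrossprod(model$par[["fc.W"]], dpred)          # C x N
  HW <- caches$HW
  dA <- dpool[, rep(seq_len(N), each = HW), drop = FALSE] / HW
  dA <- dA * (caches$lastA > 0)
  for (s in 4:1) for (j in 2:1) {
    blk <- model$arch[[s]][[j]]
    key <- blk$key
    cc <- caches[[key]]
    dpre <- dA                                   # gradient at pre-ReLU sum
    bb2 <- .bn_bwd(model, paste0(key, ".bn2"), dpre, cc$b2)
    gr[[paste0(key, ".bn2.g")]] <- bb2$dg
    gr[[paste0(key, ".bn2.b")]] <- bb2$db
    cb2 <- .conv_bwd(model$par[[paste0(key, ".conv2")]], bb2$dX, cc$c2$cols,
                     cc$g2, blk$Cout, model)
    gr[[paste0(key, ".conv2")]] <- cb2$dW
    dr1 <- cb2$dX * (cc$pre1 > 0)
    bb1 <- .bn_bwd(model, paste0(key, ".bn1"), dr1, cc$b1)
    gr[[paste0(key, ".bn1.g")]] <- bb1$dg
    gr[[paste0(key, ".bn1.b")]] <- bb1$db
    cb1 <- .conv_bwd(model$par[[paste0(key, ".conv1")]], bb1$dX, cc$c1$cols,
                     cc$g1, blk$Cin, model)
    gr[[paste0(key, ".conv1")]] <- cb1$dW
    dX <- cb1$dX
    if (blk$proj) {
      bbp <- .bn_bwd(model, paste0(key, ".bnp"), dpre, cc$bp)
      gr[[paste0(key, ".bnp.g")]] <- bbp$dg
      gr[[paste0(key, ".bnp.b")]] <- bbp$db
      cbp <- .conv_bwd(model$par[[paste0(key, ".proj")]], bbp$dX,
                       cc$cp$cols, cc$gp, blk$Cin, model)
      gr[[paste0(key, ".proj")]] <- cbp$dW
      dX <- dX + cbp$dX
    } else {
      dX <- dX + dpre
    }
    # gate through the previous layer's ReLU: its post-ReLU output (this
    # block's cached input) is positive exactly where its pre-activation is
    dA <- dX * (cc$A > 0)
    if (s == 1 && j == 1) {
      stc <- caches$stem
      bbs <- .bn_bwd(model, "stem.bn", dA, stc$bn)
      gr[["stem.bn.g"]] <- bbs$dg
      gr[["stem.bn.b"]] <- bbs$db
      cbs <- .conv_bwd(model$par[["stem.conv"]], bbs$dX, stc$cols, stc$g,
                       model$in_channels, model)
      gr[["stem.conv"]] <- cbs$dW
    }
  }
  gr
}

# One Adam update over the flat parameter list; state lives in `opt` (env).
nn_adam_step <- function(model, gr, opt, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (k in names(gr)) {
    gk <- gr[[k]]
    if (is.null(opt$m[[k]])) {
      opt$m[[k]] <- gk * 0
      opt$v[[k]] <- gk * 0
    }
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * gk
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * gk * gk
    model$par[[k]] <- model$par[[k]] -
      lr * (opt$m[[k]] / c1) / (sqrt(opt$v[[k]] / c2) + eps)
  }
  invisible(NULL)
}

# Deep snapshot/restore of the learnable state (parameters + BN statistics).
nn_snapshot <- function(model) list(par = model$par, bn = model$bn)
nn_restore <- function(model, snap) {
  model$par <- snap$par
  model$bn <- snap$bn
  invisible(NULL)
}

# Chunked eval-mode prediction on a full dataset matrix (channels x columns).
nn_predict <- function(model, X, n, chunk = 1024L) {
  P2 <- model$patch^2
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    jj <- i:min(n, i + chunk - 1L)
    colsel <- rep((jj - 1L) * P2, each = P2) + seq_len(P2)
    out[jj] <- nn_forward(model, X[, colsel, drop = FALSE], length(jj))
  i <- i + chunk
  }
  out
}
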