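# Minimal reverse-mode automatic differentiation for the network modules.
#
# Feature maps are dense R arrays in (H, W, C, N) layout (rows, columns,
# channels, batch). The graph records nodes in creation order, which is a
# topological order, so the backward sweep is a single reverse pass.
# Convolutions are realised as im2col gathers followed by BLAS matrix
# multiplies; their adjoints reuse the cached patch matrices.

ad_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- vector("list", 256L)
  g$n <- 0L
  g$leaves <- list()   # named: parameter name -> leaf node
  g
}

ad_node <- function(g, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  g$n <- g$n + 1L
  if (g$n > length(g$nodes)) g$nodes <- c(g$nodes, vector("list", length(g$nodes)))
  g$nodes[[g$n]] <- nd
  nd
}

ad_accum <- function(nd, grad) {
  if (is.null(nd$grad)) nd$grad <- grad else nd$grad <- nd$grad + grad
}

# Backpropagate from a scalar loss node through the whole graph.
ad_backward <- function(g, loss) {
  loss$grad <- 1
  for (i in seq.int(g$n, 1L)) {
    nd <- g$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

op_const <- function(g, value) ad_node(g, value)

# Leaf node bound to a named parameter array; cached so each parameter
# appears once per graph and accumulates its full gradient.
op_param <- function(g, params, name) {
  nd <- g$leaves[[name]]
  if (is.null(nd)) {
    if (is.null(params[[name]])) stopf("unknown parameter '%s'", name)
    nd <- ad_node(g, params[[name]])
    g$leaves[[name]] <- nd
  }
  nd
}

op_add <- function(g, a, b) {
  ad_node(g, a$value + b$value, list(a, b), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad)
    ad_accum(nd$parents[[2]], nd$grad)
  })
}

op_relu <- function(g, x) {
  ad_node(g, pmax(x$value, 0), list(x), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad * (nd$value > 0))
  })
}

op_sigmoid <- function(g, x) {
  ad_node(g, 1 / (1 + exp(-x$value)), list(x), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad * nd$value * (1 - nd$value))
  })
}

# softplus(x) + floor, used for latent standard deviations.
op_softplus <- function(g, x, floor = 1e-5) {
  v <- ifelse(x$value > 30, x$value, log1p(exp(pmin(x$value, 30)))) + floor
  ad_node(g, v, list(x), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad / (1 + exp(-nd$parents[[1]]$value)))
  })
}

# Elementwise product with a constant array (e.g. reparameterisation noise).
op_cmul <- function(g, x, const) {
  ad_node(g, x$value * const, list(x), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad * const)
  })
}

# Concatenate along the channel dimension.
op_concat <- function(g, xs) {
  vals <- lapply(xs, function(x) x$value)
  d <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[3], numeric(1))
  out <- array(0, c(d[1], d[2], sum(chans), d[4]))
  at <- 0L
  for (v in vals) {
    cc <- dim(v)[3]
    out[, , at + seq_len(cc), ] <- v
    at <- at + cc
  }
  ad_node(g, out, xs, function(nd) {
    at <- 0L
    for (p in nd$parents) {
      cc <- dim(p$value)[3]
      ad_accum(p, nd$grad[, , at + seq_len(cc), , drop = FALSE])
      at <- at + cc
    }
  })
}

# Nearest-neighbour x2 upsampling.
op_upsample2 <- function(g, x) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = 2)
  rj <- rep(seq_len(d[2]), each = 2)
  ad_node(g, x$value[ri, rj, , , drop = FALSE], list(x), function(nd) {
    gg <- nd$grad
    i1 <- seq(1, 2 * d[1], by = 2)
    j1 <- seq(1, 2 * d[2], by = 2)
    dx <- gg[i1, j1, , , drop = FALSE] + gg[i1 + 1, j1, , , drop = FALSE] +
      gg[i1, j1 + 1, , , drop = FALSE] + gg[i1 + 1, j1 + 1, , , drop = FALSE]
    ad_accum(nd$parents[[1]], dx)
  })
}

# Average-pool an s x s map down to gout x gout (s a multiple of gout).
op_avgpool_to <- function(g, x, gout) {
  d <- dim(x$value)
  f <- d[1] %/% gout
  stopifnot(f * gout == d[1], d[1] == d[2])
  xa <- array(x$value, c(f, gout, f, gout, d[3], d[4]))
  out <- apply(xa, c(2, 4, 5, 6), mean)
  dim(out) <- c(gout, gout, d[3], d[4])
  ad_node(g, out, list(x), function(nd) {
    gg <- nd$grad / (f * f)
    ri <- rep(seq_len(gout), each = f)
    dx <- gg[ri, ri, , , drop = FALSE]
    ad_accum(nd$parents[[1]], dx)
  })
}

# Multiply a C-channel map by a 1-channel gate, broadcasting over channels.
op_gate_mul <- function(g, x, alpha) {
  C <- dim(x$value)[3]
  a <- alpha$value[, , rep(1L, C), , drop = FALSE]
  ad_node(g, x$value * a, list(x, alpha), function(nd) {
    xn <- nd$parents[[1]]; an <- nd$parents[[2]]
    ad_accum(xn, nd$grad * a)
    da <- nd$grad * xn$value
    d <- dim(da)
    m <- array(da, c(d[1] * d[2], d[3], d[4]))
    s <- array(0, c(d[1] * d[2], 1, d[4]))
    for (n in seq_len(d[4])) {
      s[, 1, n] <- rowSums(matrix(m[, , n], d[1] * d[2], d[3]))
    }
    dim(s) <- c(d[1], d[2], 1, d[4])
    ad_accum(an, s)
  })
}

# ---- convolution -----------------------------------------------------------

.conv_cache <- new.env(parent = emptyenv())

conv_index <- function(H, W, k, stride, pad) {
  key <- paste(H, W, k, stride, pad, sep = "_")
  got <- .conv_cache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  idx <- matrix(0L, Ho * Wo, k * k)
  cnt <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    cnt <- cnt + 1L
    ii <- (oi - 1L) * stride + 1L + di
    jj <- (oj - 1L) * stride + 1L + dj
    idx[, cnt] <- ii + (jj - 1L) * Hp
  }
  inner <- as.vector(outer(pad + seq_len(H), (pad + seq_len(W) - 1L) * Hp, `+`))
  info <- list(idx = idx, inner = inner, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  assign(key, info, envir = .conv_cache)
  info
}

# 2D convolution; weight is a (k*k*Cin, Cout) matrix with rows ordered
# kernel-offset fastest, then input channel; bias has length Cout.
op_conv <- function(g, x, wn, bn, stride = 1L, pad = 1L) {
  xv <- x$value
  d <- dim(xv)
  H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  Wm <- wn$value
  k <- as.integer(round(sqrt(nrow(Wm) / Cin)))
  if (k * k * Cin != nrow(Wm)) stopf("conv weight shape mismatch")
  Cout <- ncol(Wm)
  ci <- conv_index(H, W, k, as.integer(stride), as.integer(pad))
  Ho <- ci$Ho; Wo <- ci$Wo
  npos <- Ho * Wo
  P <- matrix(0, N * npos, k * k * Cin)
  flat <- as.vector(ci$idx)
  for (n in seq_len(N)) {
    xp <- matrix(0, ci$Hp * ci$Wp, Cin)
    xp[ci$inner, ] <- matrix(xv[, , , n], H * W, Cin)
    pn <- xp[flat, , drop = FALSE]          # (npos*k2, Cin)
    dim(pn) <- c(npos, k * k * Cin)
    P[(n - 1L) * npos + seq_len(npos), ] <- pn
  }
  Y <- P %*% Wm
  Y <- sweep(Y, 2, bn$value, `+`)
  # rows are (position within sample, sample): reshape to (H,W,C,N)
  out <- aperm(array(Y, c(npos, N, Cout)), c(1, 3, 2))
  dim(out) <- c(Ho, Wo, Cout, N)
  ad_node(g, out, list(x, wn, bn), function(nd) {
    gv <- nd$grad
    dY <- aperm(array(gv, c(npos, Cout, N)), c(1, 3, 2))
    dim(dY) <- c(npos * N, Cout)
    ad_accum(nd$parents[[2]], crossprod(P, dY))
    ad_accum(nd$parents[[3]], colSums(dY))
    xn <- nd$parents[[1]]
    dP <- dY %*% t(Wm)
    dx <- array(0, d)
    for (n in seq_len(N)) {
      pn <- dP[(n - 1L) * npos + seq_len(npos), , drop = FALSE]
      dim(pn) <- c(npos, k * k, Cin)
      gxp <- matrix(0, ci$Hp * ci$Wp, Cin)
      for (off in seq_len(k * k)) {
        rows <- ci$idx[, off]
        gxp[rows, ] <- gxp[rows, ] + pn[, off, ]
      }
      dx[, , , n] <- array(gxp[ci$inner, ], c(H, W, Cin))
    }
    ad_accum(xn, dx)
  })
}

# ---- loss heads ------------------------------------------------------------

# Soft IoU loss, averaged over the batch; pred in [0,1], target binary.
op_loss_iou <- function(g, pred, target, eps = 1e-6) {
  pv <- pred$value
  d <- dim(pv)
  N <- d[4]
  I <- U <- numeric(N)
  for (n in seq_len(N)) {
    p <- pv[, , 1, n]; y <- target[, , n]
    I[n] <- sum(p * y)
    U[n] <- sum(p) + sum(y) - I[n]
  }
  val <- mean(1 - (I + eps) / (U + eps))
  ad_node(g, val, list(pred), function(nd) {
    dp <- array(0, d)
    for (n in seq_len(N)) {
      y <- target[, , n]
      dp[, , 1, n] <- -(y * (U[n] + eps) - (I[n] + eps) * (1 - y)) /
        (U[n] + eps)^2 / N
    }
    ad_accum(nd$parents[[1]], nd$grad * dp)
  })
}

# Per-pixel binary cross-entropy, averaged over pixels and batch.
op_loss_bce <- function(g, pred, target, eps = 1e-7) {
  pv <- clamp(pred$value, eps, 1 - eps)
  d <- dim(pv)
  ta <- array(target, d)
  val <- -mean(ta * log(pv) + (1 - ta) * log(1 - pv))
  ad_node(g, val, list(pred), function(nd) {
    dp <- (pv - ta) / (pv * (1 - pv)) / length(pv)
    ad_accum(nd$parents[[1]], nd$grad * dp)
  })
}

# Differentiable longest diameter (soft Feret): for each of n_dir caliper
# directions take the mask-weighted softmax / softmin expectation of pixel
# projections; the widest direction plus one pixel extent, scaled to mm.
# Returns a length-N vector node (mm).
op_soft_feret <- function(g, pred, spacing, temp = 4, n_dir = 16L, eps = 1e-8) {
  pv <- pred$value
  d <- dim(pv)
  H <- d[1]; W <- d[2]; N <- d[4]
  ii <- rep(seq_len(H) - 1, times = W)
  jj <- rep(seq_len(W) - 1, each = H)
  thetas <- (seq_len(n_dir) - 1) * pi / n_dir
  proj <- vapply(thetas, function(th) ii * cos(th) + jj * sin(th),
                 numeric(H * W))              # (H*W, n_dir)
  spacing <- rep(spacing, length.out = N)
  val <- numeric(N)
  # cache per-sample info for the backward pass; restrict to the mask
  # support so the log-sum-exp stabilisation point lies on the mask
  cache <- vector("list", N)
  for (n in seq_len(N)) {
    p <- as.vector(pv[, , 1, n])
    sel <- which(p > eps)
    if (!length(sel)) { val[n] <- 0; next }
    ps <- p[sel]
    best <- -Inf; binfo <- NULL
    for (t in seq_len(n_dir)) {
      cc <- proj[sel, t]
      umax <- exp(temp * (cc - max(cc)))
      umin <- exp(-temp * (cc - min(cc)))
      Smax <- sum(ps * umax)
      Smin <- sum(ps * umin)
      smax <- sum(ps * umax * cc) / Smax
      smin <- sum(ps * umin * cc) / Smin
      ext <- smax - smin
      if (ext > best) {
        best <- ext
        binfo <- list(t = t, umax = umax, umin = umin, Smax = Smax,
                      Smin = Smin, smax = smax, smin = smin)
      }
    }
    val[n] <- (max(best, 0) + 1) * spacing[n]
    cache[[n]] <- binfo
  }
  ad_node(g, val, list(pred), function(nd) {
    dp <- array(0, d)
    for (n in seq_len(N)) {
      b <- cache[[n]]
      if (is.null(b)) next
      p <- as.vector(pv[, , 1, n])
      sel <- which(p > eps)
      cc <- proj[sel, b$t]
      gsm <- b$umax * (cc - b$smax) / b$Smax
      gsn <- b$umin * (cc - b$smin) / b$Smin
      dpn <- numeric(H * W)
      dpn[sel] <- (gsm - gsn) * spacing[n] * nd$grad[n]
      dp[, , 1, n] <- matrix(dpn, H, W)
    }
    ad_accum(nd$parents[[1]], dp)
  })
}

# Mean absolute error between a vector node and a constant target vector.
op_l1_vec <- function(g, x, target) {
  val <- mean(abs(x$value - target))
  ad_node(g, val, list(x), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad * sign(x$value - target) / length(target))
  })
}

# Closed-form KL between diagonal Gaussians q=(muq,sq) and p=(mup,sp),
# summed over all cells and scaled (scale = 1/batch for a batch mean).
op_kl_gauss <- function(g, muq, sq, mup, sp, scale = 1) {
  mq <- muq$value; s1 <- sq$value; mp <- mup$value; s2 <- sp$value
  val <- scale * sum(log(s2 / s1) + (s1^2 + (mq - mp)^2) / (2 * s2^2) - 0.5)
  ad_node(g, val, list(muq, sq, mup, sp), function(nd) {
    gsc <- nd$grad * scale
    ad_accum(nd$parents[[1]], gsc * (mq - mp) / s2^2)
    ad_accum(nd$parents[[2]], gsc * (-1 / s1 + s1 / s2^2))
    ad_accum(nd$parents[[3]], gsc * (mp - mq) / s2^2)
    ad_accum(nd$parents[[4]], gsc * (1 / s2 - (s1^2 + (mq - mp)^2) / s2^3))
  })
}

# Weighted sum of scalar nodes.
op_wsum <- function(g, xs, w) {
  val <- sum(vapply(seq_along(xs), function(i) w[i] * xs[[i]]$value, numeric(1)))
  ad_node(g, val, xs, function(nd) {
    for (i in seq_along(nd$parents)) ad_accum(nd$parents[[i]], nd$grad * w[i])
  })
}
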