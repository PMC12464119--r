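# Differentiable operations used by the network. Values are dense double
# arrays; grids are channel-first (C, X, Y, Z), token matrices are
# (tokens x channels).

ag_add <- function(a, b) {
  ag_op(ag_value(a) + ag_value(b), list(a, b), function(nd) {
    add_grad(nd$parents[[1]], nd$grad)
    add_grad(nd$parents[[2]], nd$grad)
  })
}

ag_scale <- function(a, s) {
  ag_op(ag_value(a) * s, list(a), function(nd) {
    add_grad(nd$parents[[1]], nd$grad * s)
  })
}

# y = x + b per channel; x (C, ...) with channel first, b length C
ag_bias_add <- function(x, b) {
  xv <- ag_value(x)
  ag_op(xv + as.vector(ag_value(b)), list(x, b), function(nd) {
    add_grad(nd$parents[[1]], nd$grad)
    add_grad(nd$parents[[2]], rowSums(matrix(nd$grad, dim(ag_value(nd$parents[[1]]))[1])))
  })
}

# token matrix (N, C) + row vector b (C)
ag_rowvec_add <- function(x, b) {
  xv <- ag_value(x)
  y <- xv + rep(as.vector(ag_value(b)), each = nrow(xv))
  ag_op(y, list(x, b), function(nd) {
    add_grad(nd$parents[[1]], nd$grad)
    add_grad(nd$parents[[2]], colSums(nd$grad))
  })
}

ag_matmul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av %*% bv, list(a, b), function(nd) {
    add_grad(nd$parents[[1]], nd$grad %*% t(ag_value(nd$parents[[2]])))
    add_grad(nd$parents[[2]], crossprod(ag_value(nd$parents[[1]]), nd$grad))
  })
}

ag_leaky_relu <- function(x, slope = 0.01) {
  xv <- ag_value(x)
  neg <- xv < 0
  y <- xv
  y[neg] <- slope * y[neg]
  ag_op(y, list(x), function(nd) {
    g <- nd$grad
    g[neg] <- slope * g[neg]
    add_grad(nd$parents[[1]], g)
  })
}

ag_gelu <- function(x) {
  xv <- ag_value(x)
  ph <- stats::pnorm(xv)
  ag_op(xv * ph, list(x), function(nd) {
    add_grad(nd$parents[[1]], nd$grad * (ph + xv * stats::dnorm(xv)))
  })
}

ag_softplus <- function(x) {
  xv <- ag_value(x)
  v <- ifelse(xv > 30, xv, log1p(exp(pmin(xv, 30))))
  ag_op(v, list(x), function(nd) {
    add_grad(nd$parents[[1]], nd$grad * stats::plogis(xv))
  })
}

ag_sigmoid <- function(x) {
  v <- stats::plogis(ag_value(x))
  ag_op(v, list(x), function(nd) {
    add_grad(nd$parents[[1]], nd$grad * v * (1 - v))
  })
}

# layer norm over columns of a token matrix (N, C), affine gamma/beta (C)
ag_layer_norm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ag_value(x)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xh <- xc * inv
  gv <- as.vector(ag_value(gamma))
  y <- sweep(xh, 2L, gv, "*")
  y <- sweep(y, 2L, as.vector(ag_value(beta)), "+")
  ag_op(y, list(x, gamma, beta), function(nd) {
    g <- nd$grad
    C <- ncol(g)
    add_grad(nd$parents[[3]], colSums(g))
    add_grad(nd$parents[[2]], colSums(g * xh))
    gxh <- sweep(g, 2L, gv, "*")
    gx <- inv * (gxh - rowMeans(gxh) - xh * rowMeans(gxh * xh))
    add_grad(nd$parents[[1]], gx)
  })
}

# instance norm over spatial dims of a grid (C, X, Y, Z). Channels whose
# variance sits at the rounding floor are treated as exactly constant
# (output = beta): without this, the eps floor turns normalization into a
# x300 amplifier of float noise, and a constant input stops propagating
# as constant through deep stages.
ag_instance_norm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ag_value(x)
  d <- dim(xv)
  C <- d[1]
  xm <- matrix(xv, C)
  mu <- rowMeans(xm)
  xc <- xm - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  inv[va < 1e-12 * (mu * mu + 1)] <- 0
  xh <- xc * inv
  gv <- as.vector(ag_value(gamma))
  y <- xh * gv + as.vector(ag_value(beta))
  dim(y) <- d
  ag_op(y, list(x, gamma, beta), function(nd) {
    g <- matrix(nd$grad, C)
    add_grad(nd$parents[[3]], rowSums(g))
    add_grad(nd$parents[[2]], rowSums(g * xh))
    gxh <- g * gv
    gx <- inv * (gxh - rowMeans(gxh) - xh * rowMeans(gxh * xh))
    dim(gx) <- d
    add_grad(nd$parents[[1]], gx)
  })
}

# 3D convolution, kernel k, stride s, zero padding p.
# x: (Cin, X, Y, Z); W: (Cout, Cin*k^3); b: (Cout)
ag_conv3d <- function(x, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  xv <- ag_value(x)
  d <- dim(xv)
  if (k == 1L && stride == 1L) {
    # pointwise convolution: a plain channel mixing, no patch extraction
    y <- ag_value(W) %*% `dim<-`(xv, c(d[1], prod(d[-1]))) +
      as.vector(ag_value(b))
    dout <- c(nrow(y), d[-1])
    dim(y) <- dout
    return(ag_op(y, list(x, W, b), function(nd) {
      g <- nd$grad
      dim(g) <- c(dout[1], prod(dout[-1]))
      xm <- ag_value(nd$parents[[1]])
      dim(xm) <- c(d[1], prod(d[-1]))
      add_grad(nd$parents[[3]], rowSums(g))
      add_grad(nd$parents[[2]], tcrossprod(g, xm))
      gx <- crossprod(ag_value(nd$parents[[2]]), g)
      dim(gx) <- d
      add_grad(nd$parents[[1]], gx)
    }))
  }
  dout <- c(nrow(ag_value(W)), (d[2] + 2 * pad - k) %/% stride + 1L,
            (d[3] + 2 * pad - k) %/% stride + 1L,
            (d[4] + 2 * pad - k) %/% stride + 1L)
  # large grids: process output z-slabs over a pre-padded input so the
  # patch matrix never exceeds ~200 MB
  if (prod(d[1] * k^3) * prod(dout[2:4]) > 3e7) {
    return(conv3d_chunked(x, W, b, k, stride, pad, d, dout))
  }
  cols <- cpp_im2col3(as.double(xv), as.integer(d), k, stride, pad)
  y <- ag_value(W) %*% cols + as.vector(ag_value(b))
  dim(y) <- dout
  if (.ag$no_grad) {
    cols <- NULL  # free before building the (inert) node
    return(ag_op(y, list(x, W, b), NULL))
  }
  node <- ag_op(y, list(x, W, b), function(nd) {
    g <- nd$grad
    dim(g) <- c(dout[1], prod(dout[-1]))
    add_grad(nd$parents[[3]], rowSums(g))
    add_grad(nd$parents[[2]], tcrossprod(g, cols))
    gcols <- crossprod(ag_value(nd$parents[[2]]), g)
    add_grad(nd$parents[[1]],
             cpp_col2im3(gcols, as.integer(d), k, stride, pad))
  })
  node
}

conv3d_chunked <- function(x, W, b, k, stride, pad, d, dout) {
  xv <- ag_value(x)
  Wv <- ag_value(W)
  bv <- as.vector(ag_value(b))
  # pad once; slabs then use pad = 0
  dp <- d + c(0L, 2L * pad, 2L * pad, 2L * pad)
  xp <- array(0, dp)
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), pad + seq_len(d[4])] <- xv
  slab <- max(1L, as.integer(3e7 / (d[1] * k^3 * prod(dout[2:3]))))
  y <- array(0, dout)
  oz <- 1L
  while (oz <= dout[4]) {
    oe <- min(oz + slab - 1L, dout[4])
    z0 <- (oz - 1L) * stride + 1L
    z1 <- (oe - 1L) * stride + k
    xin <- xp[, , , z0:z1, drop = FALSE]
    cols <- cpp_im2col3(as.double(xin), as.integer(dim(xin)), k, stride, 0L)
    ys <- Wv %*% cols + bv
    dim(ys) <- c(dout[1], dout[2], dout[3], oe - oz + 1L)
    y[, , , oz:oe] <- ys
    oz <- oe + 1L
  }
  ag_op(y, list(x, W, b), function(nd) {
    g <- nd$grad
    Wv2 <- ag_value(nd$parents[[2]])
    gW <- array(0, dim(Wv2))
    gxp <- array(0, dp)
    oz <- 1L
    while (oz <= dout[4]) {
      oe <- min(oz + slab - 1L, dout[4])
      z0 <- (oz - 1L) * stride + 1L
      z1 <- (oe - 1L) * stride + k
      xin <- xp[, , , z0:z1, drop = FALSE]
      cols <- cpp_im2col3(as.double(xin), as.integer(dim(xin)), k, stride, 0L)
      gs <- g[, , , oz:oe, drop = FALSE]
      dim(gs) <- c(dout[1], prod(dout[2:3]) * (oe - oz + 1L))
      gW <- gW + tcrossprod(gs, cols)
      gcols <- crossprod(Wv2, gs)
      gxs <- cpp_col2im3(gcols, as.integer(dim(xin)), k, stride, 0L)
      gxp[, , , z0:z1] <- gxp[, , , z0:z1] + gxs
      oz <- oe + 1L
    }
    add_grad(nd$parents[[3]], rowSums(matrix(nd$grad, dout[1])))
    add_grad(nd$parents[[2]], gW)
    add_grad(nd$parents[[1]],
             gxp[, pad + seq_len(d[2]), pad + seq_len(d[3]),
                 pad + seq_len(d[4]), drop = FALSE])
  })
}

# nearest-neighbour spatial upsampling by 2 of a grid (C, X, Y, Z)
ag_upsample2 <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  ix <- rep(seq_len(d[2]), each = 2L)
  iy <- rep(seq_len(d[3]), each = 2L)
  iz <- rep(seq_len(d[4]), each = 2L)
  y <- xv[, ix, iy, iz, drop = FALSE]
  ag_op(y, list(x), function(nd) {
    g <- nd$grad
    dg <- dim(g)
    # sum each 2x2x2 block back onto the source voxel
    g <- g[, seq.int(1L, dg[2], 2L), , , drop = FALSE] +
      g[, seq.int(2L, dg[2], 2L), , , drop = FALSE]
    g <- g[, , seq.int(1L, dg[3], 2L), , drop = FALSE] +
      g[, , seq.int(2L, dg[3], 2L), , drop = FALSE]
    g <- g[, , , seq.int(1L, dg[4], 2L), drop = FALSE] +
      g[, , , seq.int(2L, dg[4], 2L), drop = FALSE]
    add_grad(nd$parents[[1]], g)
  })
}

ag_concat_channels <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(identical(da[-1], db[-1]))
  y <- array(0, c(da[1] + db[1], da[-1]))
  y[seq_len(da[1]), , , ] <- av
  y[da[1] + seq_len(db[1]), , , ] <- bv
  ag_op(y, list(a, b), function(nd) {
    g <- nd$grad
    add_grad(nd$parents[[1]], g[seq_len(da[1]), , , , drop = FALSE])
    add_grad(nd$parents[[2]], g[da[1] + seq_len(db[1]), , , , drop = FALSE])
  })
}

# grid (C, X, Y, Z) <-> token matrix (S, C) in plain raster order
ag_grid_to_tokens <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  ag_op(t(matrix(xv, d[1])), list(x), function(nd) {
    g <- t(nd$grad)
    dim(g) <- d
    add_grad(nd$parents[[1]], g)
  })
}

ag_tokens_to_grid <- function(x, d) {
  xv <- ag_value(x)
  y <- t(xv)
  dim(y) <- d
  ag_op(y, list(x), function(nd) {
    add_grad(nd$parents[[1]], t(matrix(nd$grad, d[1])))
  })
}

# gather rows of a token matrix by index; rows with idx == 0 become zero.
# Used for (shifted) window partition; each source row appears at most once.
ag_gather_rows <- function(x, idx, nrow_out) {
  xv <- ag_value(x)
  C <- ncol(xv)
  y <- matrix(0, nrow_out, C)
  valid <- idx > 0L
  y[valid, ] <- xv[idx[valid], ]
  ag_op(y, list(x), function(nd) {
    g <- matrix(0, nrow(xv), C)
    g[idx[valid], ] <- nd$grad[valid, , drop = FALSE]
    add_grad(nd$parents[[1]], g)
  })
}

# fused windowed multi-head attention over already-partitioned tokens
ag_window_attention <- function(qkv, rpb, rpb_idx, masks, maskid, T, H, hd) {
  qv <- ag_value(qkv)
  y <- cpp_winattn_fwd(qv, ag_value(rpb), rpb_idx, masks, maskid, T, H, hd)
  ag_op(y, list(qkv, rpb), function(nd) {
    bk <- cpp_winattn_bwd(ag_value(nd$parents[[1]]),
                          ag_value(nd$parents[[2]]),
                          rpb_idx, masks, maskid, nd$grad, T, H, hd)
    add_grad(nd$parents[[1]], bk$gqkv)
    add_grad(nd$parents[[2]], bk$grpb)
  })
}

# fused selective scan along the second dimension of (C, L, M) inputs
ag_sscan <- function(u, delta, B, Cc, Alog, D) {
  uv <- ag_value(u)
  d <- dim(uv)
  N <- nrow(ag_value(B))
  want <- !.ag$no_grad
  res <- cpp_sscan_fwd(uv, ag_value(delta), ag_value(B), ag_value(Cc),
                       ag_value(Alog), ag_value(D),
                       d[1], d[2], d[3], N, want)
  ag_op(res$y, list(u, delta, B, Cc, Alog, D), function(nd) {
    p <- nd$parents
    bk <- cpp_sscan_bwd(ag_value(p[[1]]), ag_value(p[[2]]), ag_value(p[[3]]),
                        ag_value(p[[4]]), ag_value(p[[5]]), ag_value(p[[6]]),
                        res$h, nd$grad, d[1], d[2], d[3], N)
    add_grad(p[[1]], bk$gu)
    add_grad(p[[2]], bk$gdelta)
    add_grad(p[[3]], bk$gB)
    add_grad(p[[4]], bk$gC)
    add_grad(p[[5]], bk$gAlog)
    add_grad(p[[6]], bk$gD)
  })
}

# permute grid axes (channel stays first); perm is a permutation of 1:3
ag_permute_grid <- function(x, perm) {
  xv <- ag_value(x)
  p4 <- c(1L, perm + 1L)
  y <- aperm(xv, p4)
  ag_op(y, list(x), function(nd) {
    add_grad(nd$parents[[1]], aperm(nd$grad, order(p4)))
  })
}

# reshape grid (C, X, Y, Z) to sequences (C, L=X, M=Y*Z) — scan along x
ag_grid_to_seq <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- xv
  dim(y) <- c(d[1], d[2], d[3] * d[4])
  ag_op(y, list(x), function(nd) {
    g <- nd$grad
    dim(g) <- d
    add_grad(nd$parents[[1]], g)
  })
}

ag_seq_to_grid <- function(x, d) {
  y <- ag_value(x)
  dim(y) <- d
  ag_op(y, list(x), function(nd) {
    g <- nd$grad
    dim(g) <- dim(ag_value(nd$parents[[1]]))
    add_grad(nd$parents[[1]], g)
  })
}

# composite DiceCE loss on logits (K, X, Y, Z) against integer labels
# (values 0..K-1). Softmax over channels; loss =
#   w_dice * (1 - mean_k softdice_k) + w_ce * mean_vox(-log p[target])
# with smooth = 1e-5 in both numerator and denominator of the soft Dice.
col_max <- function(m) {
  mx <- m[1L, ]
  for (k in seq_len(nrow(m))[-1L]) mx <- pmax(mx, m[k, ])
  mx
}

ag_dice_ce <- function(logits, target, w_dice = 1, w_ce = 1, smooth = 1e-5) {
  lv <- ag_value(logits)
  d <- dim(lv)
  K <- d[1]
  S <- prod(d[-1])
  lm <- lv
  dim(lm) <- c(K, S)
  em <- exp(lm - rep(col_max(lm), each = K))
  p <- em / rep(colSums(em), each = K)
  tgt <- as.integer(target)
  ti <- tgt + 1L
  lin <- ti + K * (seq_len(S) - 1L)
  ce <- -mean(log(pmax(p[lin], 1e-300)))
  tcount <- tabulate(ti, nbins = K)        # |T_k|
  psum <- rowSums(p)
  inter <- vapply(seq_len(K), function(k) sum(p[k, ti == k]), numeric(1))
  dice_k <- (2 * inter + smooth) / (psum + tcount + smooth)
  loss <- w_dice * (1 - mean(dice_k)) + w_ce * ce
  ag_op(loss, list(logits), function(nd) {
    g <- nd$grad
    # d(ce)/dp and d(dice)/dp
    gp <- matrix(0, K, S)
    gp[lin] <- gp[lin] - g * w_ce / (S * pmax(p[lin], 1e-300))
    denom <- (psum + tcount + smooth)
    for (k in seq_len(K)) {
      is_k <- ti == k
      base <- -g * w_dice / K
      # d dice_k / d p[k, s] = (2*[s in T_k]*denom - (2 inter + smooth)) / denom^2
      gp[k, ] <- gp[k, ] + base *
        ((2 * is_k) * denom[k] - (2 * inter[k] + smooth)) / denom[k]^2
    }
    # back through softmax
    dots <- colSums(p * gp)
    gl <- p * (gp - rep(dots, each = K))
    dim(gl) <- d
    add_grad(nd$parents[[1]], gl)
  })
}
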