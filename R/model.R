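#' Network configuration
#'
#' Architectural hyperparameters of the hybrid encoder-decoder. The
#' encoder has four stages; each stage fuses a volumetric shifted-window
#' self-attention branch with a spatial state-space branch, then halves
#' the resolution. Channel widths double per stage starting from
#' `embed_size` (48/96/192/384 at the default). `feature_dim` is the
#' per-head attention dimension (8), so stage `s` runs
#' `embed_size * 2^(s-1) / feature_dim` heads. The decoder mirrors the
#' encoder with nearest-neighbour x2 upsampling, skip concatenation and
#' residual convolution blocks, ending in a 1x1x1 convolution head over
#' `num_classes` channels.
#'
#' @param in_channels Input channels (CBCT is single-modality: 1).
#' @param num_classes Output channels: 36 foreground structures plus
#'   background = 37.
#' @param stages Encoder stages (4).
#' @param patch_embed Patch-embedding kernel/stride (2).
#' @param feature_dim Attention head dimension (8).
#' @param embed_size Stage-1 channel width (48).
#' @param attention_window Length-3 attention window (default 7^3,
#'   clipped per stage to the grid when larger).
#' @param smamba_state_dim State dimension of the selective scan (16).
#' @param decoder_residual_blocks Residual blocks per decoder stage.
#' @param ablation `"full"`, `"swin_only"` or `"smamba_only"`.
#' @param head `"softmax"` (default: mutually exclusive classes) or
#'   `"sigmoid"` (literal per-channel head).
#' @param fusion `"concat"` (concatenate the two branch outputs and
#'   project back to the stage width) or `"sum"`.
#' @param mlp_ratio Hidden widening of the attention MLP.
#' @return An object of class `model_config`.
#' @export
model_config <- function(in_channels = 1L, num_classes = 37L, stages = 4L,
                         patch_embed = 2L, feature_dim = 8L, embed_size = 48L,
                         attention_window = c(7L, 7L, 7L),
                         smamba_state_dim = 16L,
                         decoder_residual_blocks = 1L,
                         ablation = c("full", "swin_only", "smamba_only"),
                         head = c("softmax", "sigmoid"),
                         fusion = c("concat", "sum"),
                         mlp_ratio = 2) {
  ablation <- match.arg(ablation)
  head <- match.arg(head)
  fusion <- match.arg(fusion)
  stopifnot(stages == 4L, num_classes >= 2L, embed_size %% feature_dim == 0,
            patch_embed >= 1L, length(attention_window) == 3L,
            all(attention_window >= 2L), smamba_state_dim >= 1L,
            decoder_residual_blocks >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 stages = as.integer(stages),
                 patch_embed = as.integer(patch_embed),
                 feature_dim = as.integer(feature_dim),
                 embed_size = as.integer(embed_size),
                 attention_window = as.integer(attention_window),
                 smamba_state_dim = as.integer(smamba_state_dim),
                 decoder_residual_blocks = as.integer(decoder_residual_blocks),
                 ablation = ablation, head = head, fusion = fusion,
                 mlp_ratio = mlp_ratio),
            class = "model_config")
}

# ---- window partition bookkeeping ------------------------------------------

.win_cache <- new.env(parent = emptyenv())

# relative-position index table for a window of dims w (length 3)
rpb_index <- function(w) {
  T <- prod(w)
  cx <- (seq_len(T) - 1L) %% w[1]
  cy <- ((seq_len(T) - 1L) %/% w[1]) %% w[2]
  cz <- (seq_len(T) - 1L) %/% (w[1] * w[2])
  dx <- outer(cx, cx, "-") + w[1] - 1L
  dy <- outer(cy, cy, "-") + w[2] - 1L
  dz <- outer(cz, cz, "-") + w[3] - 1L
  idx <- 1L + dx + (2L * w[1] - 1L) * (dy + (2L * w[2] - 1L) * dz)
  storage.mode(idx) <- "integer"
  idx
}

n_rel <- function(w) prod(2L * w - 1L)

# gather/scatter indices, attention masks and region bookkeeping for a
# (possibly shifted) window partition of a grid
win_partition <- function(g, w, shift) {
  key <- paste(c(g, w, shift), collapse = "_")
  if (!is.null(.win_cache[[key]])) return(.win_cache[[key]])
  P <- as.integer(ceiling(g / w) * w)
  nw <- P %/% w
  T <- prod(w)
  nwin <- prod(nw)
  # per-axis source coordinate (0-based, on the padded grid) and region band
  ax <- lapply(1:3, function(a) {
    i <- 0:(P[a] - 1L)
    src <- (i + shift[a]) %% P[a]
    band <- integer(P[a])
    if (shift[a] > 0L) {
      band[src >= (P[a] - w[a])] <- 1L
      band[src >= (P[a] - shift[a])] <- 2L
    }
    list(src = src, band = band)
  })
  # enumerate tokens window-by-window (windows and intra-window voxels in
  # raster order); compute the source grid-token row or 0 for padding
  wi <- (0:(nwin - 1L))
  wx <- wi %% nw[1]; wy <- (wi %/% nw[1]) %% nw[2]; wz <- wi %/% (nw[1] * nw[2])
  ti <- (0:(T - 1L))
  tx <- ti %% w[1]; ty <- (ti %/% w[1]) %% w[2]; tz <- ti %/% (w[1] * w[2])
  px <- outer(tx, wx * w[1], "+")  # (T, nwin) padded x coordinate
  py <- outer(ty, wy * w[2], "+")
  pz <- outer(tz, wz * w[3], "+")
  sx <- matrix(ax[[1]]$src[px + 1L], T); bx <- matrix(ax[[1]]$band[px + 1L], T)
  sy <- matrix(ax[[2]]$src[py + 1L], T); by <- matrix(ax[[2]]$band[py + 1L], T)
  sz <- matrix(ax[[3]]$src[pz + 1L], T); bz <- matrix(ax[[3]]$band[pz + 1L], T)
  valid <- sx < g[1] & sy < g[2] & sz < g[3]
  idx <- ifelse(valid, 1L + sx + g[1] * (sy + g[2] * sz), 0L)
  rid <- ifelse(valid, bx * 9L + by * 3L + bz, -1L)
  # attention masks: one column per distinct region pattern
  maskid <- integer(nwin)
  masks <- list()
  keys <- character(0)
  for (wn in seq_len(nwin)) {
    r <- rid[, wn]
    if (length(unique(r)) == 1L && r[1] >= 0L) {
      maskid[wn] <- 0L
      next
    }
    k <- paste(r, collapse = ",")
    hit <- match(k, keys)
    if (is.na(hit)) {
      m <- ifelse(outer(r, r, "=="), 0, -1e9)
      masks[[length(masks) + 1L]] <- as.vector(m)
      keys <- c(keys, k)
      hit <- length(masks)
    }
    maskid[wn] <- hit
  }
  masks_mat <- if (length(masks)) matrix(unlist(masks), ncol = length(masks))
               else matrix(0, T * T, 1L)
  out <- list(idx = as.integer(idx), maskid = as.integer(maskid),
              masks = masks_mat, nwin = nwin, T = T,
              rpb_idx = rpb_index(w), ntok = nwin * T)
  .win_cache[[key]] <- out
  out
}

# scatter window tokens back onto the grid-token matrix (inverse gather)
ag_scatter_rows <- function(x, idx, nrow_out) {
  xv <- ag_value(x)
  valid <- idx > 0L
  y <- matrix(0, nrow_out, ncol(xv))
  y[idx[valid], ] <- xv[valid, , drop = FALSE]
  ag_op(y, list(x), function(nd) {
    g <- matrix(0, nrow(xv), ncol(xv))
    g[valid, ] <- nd$grad[idx[valid], , drop = FALSE]
    add_grad(nd$parents[[1]], g)
  })
}

# ---- parameter creation -----------------------------------------------------

new_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e
}

mk_param <- function(reg, name, value, decay = TRUE) {
  p <- ag_param(value, decay = decay)
  reg$params[[name]] <- p
  p
}

tn <- function(n, sd = 0.02) {
  # truncated-normal-ish init
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

mk_linear <- function(reg, name, cin, cout, sd = 0.02) {
  list(W = mk_param(reg, paste0(name, ".W"), matrix(tn(cin * cout, sd), cin)),
       b = mk_param(reg, paste0(name, ".b"), numeric(cout), decay = FALSE))
}

mk_conv <- function(reg, name, cin, cout, k, init_scale = 1) {
  fan <- cin * k^3
  W <- matrix(stats::rnorm(cout * fan, 0, init_scale * sqrt(2 / fan)), cout)
  list(W = mk_param(reg, paste0(name, ".W"), W),
       b = mk_param(reg, paste0(name, ".b"), numeric(cout), decay = FALSE),
       k = k)
}

mk_norm <- function(reg, name, C) {
  list(g = mk_param(reg, paste0(name, ".g"), rep(1, C), decay = FALSE),
       b = mk_param(reg, paste0(name, ".b"), numeric(C), decay = FALSE))
}

apply_linear <- function(x, lin) ag_rowvec_add(ag_matmul(x, lin$W), lin$b)
apply_conv <- function(x, cv, stride = 1L, pad = (cv$k - 1L) %/% 2L) {
  ag_conv3d(x, cv$W, cv$b, cv$k, stride, pad)
}
apply_in <- function(x, nm) ag_instance_norm(x, nm$g, nm$b)
apply_ln <- function(x, nm) ag_layer_norm(x, nm$g, nm$b)

mk_swin_block <- function(reg, name, C, heads, win, mlp_ratio) {
  list(
    ln1 = mk_norm(reg, paste0(name, ".ln1"), C),
    qkv = mk_linear(reg, paste0(name, ".qkv"), C, 3L * C),
    rpb = mk_param(reg, paste0(name, ".rpb"),
                   matrix(tn(n_rel(win) * heads), n_rel(win)), decay = FALSE),
    proj = mk_linear(reg, paste0(name, ".proj"), C, C),
    ln2 = mk_norm(reg, paste0(name, ".ln2"), C),
    mlp1 = mk_linear(reg, paste0(name, ".mlp1"), C, as.integer(mlp_ratio * C)),
    mlp2 = mk_linear(reg, paste0(name, ".mlp2"), as.integer(mlp_ratio * C), C),
    heads = heads, win = win, C = C
  )
}

apply_swin_block <- function(blk, x, shifted, hd) {
  d <- dim(ag_value(x))
  g <- d[2:4]
  win <- pmin(blk$win, g)
  shift <- if (shifted && any(win < g)) win %/% 2L else c(0L, 0L, 0L)
  wp <- win_partition(g, win, shift)
  S <- prod(g)
  tokens <- ag_grid_to_tokens(x)
  t1 <- apply_ln(tokens, blk$ln1)
  part <- ag_gather_rows(t1, wp$idx, wp$ntok)
  qkv <- apply_linear(part, blk$qkv)
  att <- ag_window_attention(qkv, blk$rpb, wp$rpb_idx, wp$masks, wp$maskid,
                             wp$T, blk$heads, hd)
  proj <- apply_linear(att, blk$proj)
  back <- ag_scatter_rows(proj, wp$idx, S)
  x <- ag_add(x, ag_tokens_to_grid(back, d))
  t2 <- apply_ln(ag_grid_to_tokens(x), blk$ln2)
  h <- ag_gelu(apply_linear(t2, blk$mlp1))
  o <- apply_linear(h, blk$mlp2)
  ag_add(x, ag_tokens_to_grid(o, d))
}

mk_smamba_block <- function(reg, name, C, N) {
  list(
    conv1 = mk_conv(reg, paste0(name, ".conv1"), C, C, 1L),
    conv3 = mk_conv(reg, paste0(name, ".conv3"), C, C, 3L),
    in1 = mk_norm(reg, paste0(name, ".in1"), C),
    in3 = mk_norm(reg, paste0(name, ".in3"), C),
    delta = mk_conv(reg, paste0(name, ".delta"), C, C, 1L),
    Bproj = mk_conv(reg, paste0(name, ".Bproj"), C, N, 1L),
    Cproj = mk_conv(reg, paste0(name, ".Cproj"), C, N, 1L),
    Alog = mk_param(reg, paste0(name, ".Alog"),
                    matrix(log(seq_len(N)), C, N, byrow = TRUE),
                    decay = FALSE),
    Dskip = mk_param(reg, paste0(name, ".D"), rep(1, C), decay = FALSE),
    proj = mk_conv(reg, paste0(name, ".proj"), C, C, 1L),
    C = C, N = N
  )
}

# delta bias initialised so softplus starts near 0.05
smamba_post_init <- function(blk) {
  blk$delta$b$v[] <- log(expm1(0.05))
  blk
}

apply_smamba_block <- function(blk, x) {
  h <- ag_leaky_relu(ag_add(apply_in(apply_conv(x, blk$conv1), blk$in1),
                            apply_in(apply_conv(x, blk$conv3), blk$in3)))
  delta <- ag_softplus(apply_conv(h, blk$delta))
  Bm <- apply_conv(h, blk$Bproj)
  Cm <- apply_conv(h, blk$Cproj)
  d <- dim(ag_value(h))
  perms <- list(c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  ssum <- NULL
  for (perm in perms) {
    hp <- ag_permute_grid(h, perm)
    dp <- dim(ag_value(hp))
    y <- ag_sscan(ag_grid_to_seq(hp), ag_grid_to_seq(ag_permute_grid(delta, perm)),
                  ag_grid_to_seq(ag_permute_grid(Bm, perm)),
                  ag_grid_to_seq(ag_permute_grid(Cm, perm)),
                  blk$Alog, blk$Dskip)
    yg <- ag_permute_grid(ag_seq_to_grid(y, dp), order(perm))
    ssum <- if (is.null(ssum)) yg else ag_add(ssum, yg)
  }
  ag_add(h, apply_conv(ssum, blk$proj))
}

mk_res_block <- function(reg, name, cin, cout) {
  list(
    c1 = mk_conv(reg, paste0(name, ".c1"), cin, cout, 3L),
    n1 = mk_norm(reg, paste0(name, ".n1"), cout),
    c2 = mk_conv(reg, paste0(name, ".c2"), cout, cout, 3L),
    n2 = mk_norm(reg, paste0(name, ".n2"), cout),
    sc = if (cin != cout) mk_conv(reg, paste0(name, ".sc"), cin, cout, 1L)
         else NULL
  )
}

apply_res_block <- function(blk, x) {
  y <- ag_leaky_relu(apply_in(apply_conv(x, blk$c1), blk$n1))
  y <- apply_in(apply_conv(y, blk$c2), blk$n2)
  sc <- if (is.null(blk$sc)) x else apply_conv(x, blk$sc)
  ag_leaky_relu(ag_add(y, sc))
}

# ---- model assembly ---------------------------------------------------------

#' Build the segmentation network
#'
#' Constructs all parameters (deterministically from `init_seed`) and
#' returns a model object whose forward pass maps a normalized 3D volume
#' to a per-class probability map. Input spatial dims must be divisible
#' by `patch_embed * 2^stages` (64^3 is valid at defaults).
#'
#' @param cfg A [model_config()].
#' @param init_seed Integer initialization seed.
#' @return An object of class `oralseg_model` with elements `cfg`,
#'   `params` (named list), `n_parameters`.
#' @export
build_model <- function(cfg = model_config(), init_seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  run_seeded(init_seed, {
    reg <- new_registry()
    C1 <- cfg$embed_size
    widths <- C1 * 2L^(0:(cfg$stages - 1L))
    hd <- cfg$feature_dim
    m <- list(cfg = cfg, widths = widths, init_seed = as.integer(init_seed))
    m$embed <- mk_conv(reg, "embed", cfg$in_channels, C1, cfg$patch_embed)
    m$enc <- list()
    for (s in seq_len(cfg$stages)) {
      C <- widths[s]
      st <- list()
      if (cfg$ablation != "smamba_only") {
        st$swin1 <- mk_swin_block(reg, sprintf("enc%d.swin1", s), C, C %/% hd,
                                  cfg$attention_window, cfg$mlp_ratio)
        st$swin2 <- mk_swin_block(reg, sprintf("enc%d.swin2", s), C, C %/% hd,
                                  cfg$attention_window, cfg$mlp_ratio)
      }
      if (cfg$ablation != "swin_only") {
        st$smamba <- smamba_post_init(
          mk_smamba_block(reg, sprintf("enc%d.smamba", s), C,
                          cfg$smamba_state_dim))
      }
      fin <- if (cfg$ablation == "full" && cfg$fusion == "concat") 2L * C else C
      st$fuse <- mk_conv(reg, sprintf("enc%d.fuse", s), fin, C, 1L)
      st$fuse_n <- mk_norm(reg, sprintf("enc%d.fuse_n", s), C)
      if (s < cfg$stages) {
        st$down <- mk_conv(reg, sprintf("enc%d.down", s), C, 2L * C, 2L)
        st$down_n <- mk_norm(reg, sprintf("enc%d.down_n", s), 2L * C)
      }
      m$enc[[s]] <- st
    }
    m$dec <- list()
    for (s in (cfg$stages - 1L):1L) {
      C <- widths[s]
      dc <- list(
        up = mk_conv(reg, sprintf("dec%d.up", s), 2L * C, C, 1L),
        up_n = mk_norm(reg, sprintf("dec%d.up_n", s), C),
        res = lapply(seq_len(cfg$decoder_residual_blocks), function(r) {
          mk_res_block(reg, sprintf("dec%d.res%d", s, r),
                       if (r == 1L) 2L * C else C, C)
        })
      )
      m$dec[[s]] <- dc
    }
    # full-resolution stem skip + residual block: small structures (canals,
    # root apices) need voxel-scale convolution, not just an upsampled map
    sw <- max(8L, C1 %/% 2L)
    m$stem <- mk_conv(reg, "stem.conv", cfg$in_channels, sw, 3L)
    m$stem_n <- mk_norm(reg, "stem.n", sw)
    m$final_up <- mk_conv(reg, "final.up", C1, sw, 1L)
    m$final_n <- mk_norm(reg, "final.n", sw)
    m$final_res <- mk_res_block(reg, "final.res", 2L * sw, sw)
    # near-uniform initial class scores: a hot random head biases early
    # training against rare classes, which can collapse and never recover
    m$head <- mk_conv(reg, "head", sw, cfg$num_classes, 1L,
                      init_scale = 0.05)
    m$params <- reg$params
    m$n_parameters <- sum(vapply(reg$params, function(p) length(p$v),
                                 numeric(1)))
    class(m) <- "oralseg_model"
    m
  })
}

#' @export
print.oralseg_model <- function(x, ...) {
  cat(sprintf(
    "<oralseg model> %s, embed %d, window %s, %d classes, %s head, %d parameters\n",
    x$cfg$ablation, x$cfg$embed_size,
    paste(x$cfg$attention_window, collapse = "x"), x$cfg$num_classes,
    x$cfg$head, x$n_parameters))
  invisible(x)
}

check_divisible <- function(g, cfg) {
  need <- cfg$patch_embed * 2L^cfg$stages
  bad <- which(g %% need != 0L)
  if (length(bad)) {
    stop("input spatial dim ", paste(g[bad], collapse = ","), " (axis ",
         paste(bad, collapse = ","), ") not divisible by ", need)
  }
}

# encoder: returns list(skips = list of stage-fused feature nodes)
encode_nodes <- function(model, xnode) {
  cfg <- model$cfg
  x <- apply_conv(xnode, model$embed, stride = cfg$patch_embed, pad = 0L)
  skips <- vector("list", cfg$stages)
  for (s in seq_len(cfg$stages)) {
    st <- model$enc[[s]]
    branches <- list()
    if (!is.null(st$swin1)) {
      sw <- apply_swin_block(st$swin1, x, shifted = FALSE, hd = cfg$feature_dim)
      sw <- apply_swin_block(st$swin2, sw, shifted = TRUE, hd = cfg$feature_dim)
      branches$swin <- sw
    }
    if (!is.null(st$smamba)) branches$smamba <- apply_smamba_block(st$smamba, x)
    fin <- if (length(branches) == 2L) {
      if (cfg$fusion == "concat") ag_concat_channels(branches$swin, branches$smamba)
      else ag_add(branches$swin, branches$smamba)
    } else branches[[1]]
    fused <- ag_leaky_relu(apply_in(apply_conv(fin, st$fuse), st$fuse_n))
    skips[[s]] <- fused
    if (s < cfg$stages) {
      x <- ag_leaky_relu(apply_in(apply_conv(fused, st$down, stride = 2L,
                                             pad = 0L), st$down_n))
    }
  }
  skips
}

forward_logits <- function(model, x_array) {
  cfg <- model$cfg
  d <- dim(x_array)
  check_divisible(d, cfg)
  xnode <- ag_const(array(x_array, c(1L, d)))
  skips <- encode_nodes(model, xnode)
  dnode <- skips[[cfg$stages]]
  for (s in (cfg$stages - 1L):1L) {
    dc <- model$dec[[s]]
    up <- ag_leaky_relu(apply_in(apply_conv(ag_upsample2(dnode), dc$up),
                                 dc$up_n))
    skip <- skips[[s]]
    stopifnot(identical(dim(ag_value(up))[-1], dim(ag_value(skip))[-1]))
    dnode <- ag_concat_channels(up, skip)
    for (r in seq_along(dc$res)) dnode <- apply_res_block(dc$res[[r]], dnode)
  }
  stem <- ag_leaky_relu(apply_in(apply_conv(xnode, model$stem), model$stem_n))
  up0 <- ag_leaky_relu(apply_in(apply_conv(ag_upsample2(dnode),
                                           model$final_up), model$final_n))
  fin <- apply_res_block(model$final_res, ag_concat_channels(up0, stem))
  apply_conv(fin, model$head)
}

softmax_channels <- function(a) {
  d <- dim(a)
  K <- d[1]
  m <- a
  dim(m) <- c(K, prod(d[-1]))
  e <- exp(m - rep(col_max(m), each = K))
  p <- e / rep(colSums(e), each = K)
  dim(p) <- d
  p
}

#' Run the encoder and return the feature pyramid
#'
#' Stage `s` of the pyramid has spatial shape
#' `input / (2^(s-1) * patch_embed)` — the resolution halves exactly per
#' stage — with the declared channel width.
#'
#' @param model An [build_model()] object.
#' @param x 3D numeric array (normalized input), dims divisible per the
#'   config.
#' @return List of 4 feature arrays `(C_s, X_s, Y_s, Z_s)`.
#' @export
swin_encode <- function(model, x) {
  stopifnot(inherits(model, "oralseg_model"), length(dim(x)) == 3L)
  check_divisible(dim(x), model$cfg)
  no_grad({
    xnode <- ag_const(array(x, c(1L, dim(x))))
    lapply(encode_nodes(model, xnode), ag_value)
  })
}

#' Apply one spatial state-space block
#'
#' Exposes the stage-`stage` SMamba block of a model: two fused
#' convolution paths (1^3 and 3^3 kernels) followed by selective scans
#' along each of the three axes (parameters tied across axes), summed and
#' projected back onto the convolution path. Output shape equals input
#' shape.
#'
#' @param model A model built with an ablation that includes SMamba.
#' @param x Feature array `(C_stage, X, Y, Z)`.
#' @param stage Encoder stage whose block to apply (default 1).
#' @return Array of the same shape.
#' @export
smamba_block <- function(model, x, stage = 1L) {
  blk <- model$enc[[stage]]$smamba
  if (is.null(blk)) stop("model ablation '", model$cfg$ablation,
                         "' has no SMamba block")
  stopifnot(dim(x)[1] == blk$C)
  no_grad(ag_value(apply_smamba_block(blk, ag_const(x))))
}

#' Whole-patch forward pass
#'
#' @param model An [build_model()] object.
#' @param x 3D array `(X, Y, Z)` of normalized intensities, or a 5D array
#'   `(1, 1, X, Y, Z)`.
#' @return Per-class probability array `(1, num_classes, X, Y, Z)`,
#'   values in `[0, 1]` (softmax across channels by default; independent
#'   sigmoids if configured).
#' @export
model_forward <- function(model, x) {
  if (length(dim(x)) == 5L) {
    stopifnot(dim(x)[1] == 1L, dim(x)[2] == 1L)
    x <- array(x, dim(x)[3:5])
  }
  stopifnot(length(dim(x)) == 3L)
  logits <- no_grad(ag_value(forward_logits(model, x)))
  p <- if (model$cfg$head == "softmax") softmax_channels(logits)
       else stats::plogis(logits)
  array(p, c(1L, dim(p)))
}

#' Per-component parameter census
#'
#' @param model An [build_model()] object.
#' @return Data frame with `group` (top-level component name) and
#'   `parameters`; total equals `model$n_parameters`.
#' @export
parameter_census <- function(model) {
  sizes <- vapply(model$params, function(p) length(p$v), numeric(1))
  group <- sub("^([^.]+\\.[^.]+)\\..*$", "\\1", names(sizes))
  agg <- tapply(sizes, group, sum)
  data.frame(group = names(agg), parameters = as.numeric(agg),
             row.names = NULL)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores parameter values, the model config, the label
#' scheme, optimizer state and RNG state, plus a JSON sidecar carrying
#' the config and scheme so a checkpoint is self-describing.
#'
#' @param model An [build_model()] object.
#' @param path Checkpoint file path (`.rds`; the sidecar adds `.json`).
#' @param extra Optional list stored alongside (optimizer/RNG state).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  obj <- list(cfg = unclass(model$cfg),
              init_seed = model$init_seed,
              values = lapply(model$params, function(p) p$v),
              extra = extra)
  saveRDS(obj, path)
  side <- list(config = unclass(model$cfg),
               scheme = as.data.frame(default_scheme()),
               n_parameters = model$n_parameters)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns a rebuilt `oralseg_model` with the
#'   stored weights; the `extra` list is attached as attribute `"extra"`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(model_config, obj$cfg[setdiff(names(obj$cfg), NULL)])
  model <- build_model(cfg, obj$init_seed)
  stopifnot(identical(sort(names(model$params)), sort(names(obj$values))))
  for (nm in names(obj$values)) model$params[[nm]]$v <- obj$values[[nm]]
  attr(model, "extra") <- obj$extra
  model
}
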