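#' Inference configuration
#'
#' @param roi Optional axis-aligned box in 1-based voxel coordinates,
#'   `c(x0, y0, z0, x1, y1, z1)` inclusive; computation is restricted to
#'   it and the result embedded in a background-filled full-size grid.
#' @param window Patch shape fed to the model (default 64^3).
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.5).
#' @param blend `"gaussian"` (sigma = window/8, the default; suppresses
#'   seam artifacts) or `"constant"`.
#' @param target_spacing Spacing (mm) the model was trained at (default
#'   0.3); inputs whose spacing differs by more than `spacing_tol`
#'   (relative) are resampled in, and the labels resampled back out, so
#'   the output grid always equals the input grid.
#' @param spacing_tol Relative spacing tolerance (default 0.01).
#' @param output_mode `"instance"` (37-class) or `"semantic"` (merged
#'   tissue classes via [merge_to_semantic()]).
#' @param keep_largest_component Optional cleanup: keep only the largest
#'   connected component per class (off by default).
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(roi = NULL, window = c(64L, 64L, 64L),
                             overlap = 0.5,
                             blend = c("gaussian", "constant"),
                             target_spacing = 0.3, spacing_tol = 0.01,
                             output_mode = c("instance", "semantic"),
                             keep_largest_component = FALSE) {
  blend <- match.arg(blend)
  output_mode <- match.arg(output_mode)
  stopifnot(overlap >= 0, overlap < 1, length(window) == 3L)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  structure(list(roi = roi, window = as.integer(window), overlap = overlap,
                 blend = blend, target_spacing = target_spacing,
                 spacing_tol = spacing_tol, output_mode = output_mode,
                 keep_largest_component = keep_largest_component),
            class = "inference_config")
}

#' Decode per-class scores to labels
#'
#' Voxelwise argmax over the class channel; ties break toward the lower
#' class index; channel 1 is background (class 0).
#'
#' @param scores Array `(K, X, Y, Z)` or `(1, K, X, Y, Z)`.
#' @param spacing,origin,orientation Grid metadata for the result.
#' @return A [label_volume()].
#' @export
decode_labels <- function(scores, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          orientation = "RAS") {
  if (length(dim(scores)) == 5L) scores <- array(scores, dim(scores)[-1])
  d <- dim(scores)
  m <- matrix(scores, d[1])
  lab <- max.col(t(m), ties.method = "first") - 1L
  dim(lab) <- d[-1]
  label_volume(lab, spacing = spacing, origin = origin,
               orientation = orientation)
}

# per-axis window start offsets (0-based) covering [0, n)
window_starts <- function(n, win, overlap) {
  if (n <= win) return(0L)
  step <- max(1L, as.integer(round(win * (1 - overlap))))
  st <- seq.int(0L, n - win, by = step)
  if (st[length(st)] != n - win) st <- c(st, n - win)
  as.integer(st)
}

blend_weights <- function(win, blend) {
  if (blend == "constant") return(array(1, win))
  sig <- win / 8
  wv <- lapply(1:3, function(a) {
    c0 <- (win[a] - 1) / 2
    exp(-((seq_len(win[a]) - 1 - c0)^2) / (2 * sig[a]^2))
  })
  outer(outer(wv[[1]], wv[[2]]), wv[[3]])
}

# nearest-neighbour resample of an integer label array onto a target grid
# (voxel-centre alignment), used to restore the caller's grid
resample_labels_to_grid <- function(lab, from_spacing, to_shape, to_spacing) {
  din <- dim(lab)
  nn <- lapply(1:3, function(a) {
    idx <- (seq_len(to_shape[a]) - 0.5) * to_spacing[a] / from_spacing[a] - 0.5
    pmin(pmax(as.integer(round_half_away(idx)), 0L), din[a] - 1L) + 1L
  })
  out <- lab[nn[[1]], nn[[2]], nn[[3]], drop = FALSE]
  dim(out) <- to_shape
  out
}

keep_largest_cc <- function(lab) {
  d <- dim(lab)
  for (k in sort(setdiff(unique(as.integer(lab)), 0L))) {
    mask <- lab == k
    comp <- label_components6(mask)
    tab <- tabulate(comp[comp > 0L])
    if (length(tab) > 1L) {
      keep <- which.max(tab)
      lab[mask & comp != keep] <- 0L
    }
  }
  lab
}

# 6-connected component labelling (two-pass union-find, plain R)
label_components6 <- function(mask) {
  d <- dim(mask)
  comp <- array(0L, d)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) {
    run <- which(mask[, y, z])
    for (x in run) {
      left <- if (x > 1L && mask[x - 1L, y, z]) comp[x - 1L, y, z] else 0L
      up <- if (y > 1L && mask[x, y - 1L, z]) comp[x, y - 1L, z] else 0L
      back <- if (z > 1L && mask[x, y, z - 1L]) comp[x, y, z - 1L] else 0L
      nb <- c(left, up, back)
      nb <- nb[nb > 0L]
      if (!length(nb)) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        comp[x, y, z] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        r <- min(roots)
        comp[x, y, z] <- r
        for (o in roots) parent[o] <- r
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    relab <- match(roots, unique(roots))
    w <- comp > 0L
    comp[w] <- relab[comp[w]]
  }
  comp
}

#' Whole-volume prediction by sliding-window inference
#'
#' Checks the input spacing against the model's training spacing
#' (resampling in and out if the relative difference exceeds the
#' tolerance), min-max normalizes, tiles the volume into overlapping
#' windows, blends the per-window class probabilities with the
#' configured weighting (the normalized blending weights form a
#' partition of unity at every voxel, including borders), decodes the
#' voxelwise argmax, and returns labels on exactly the input grid.
#' Volumes smaller than one window are zero-padded symmetrically and the
#' padding cropped from the output. Deterministic for a fixed model and
#' config.
#'
#' @param v A [volume()].
#' @param model An [build_model()] object.
#' @param cfg An [inference_config()].
#' @param return_probs Attach the blended probability array (on the
#'   internal grid) as attribute `"probs"`.
#' @param verbose Print tiling progress.
#' @return A [label_volume()] on the input grid (instance labels, or
#'   semantic labels if `cfg$output_mode == "semantic"`).
#' @export
predict_volume <- function(v, model, cfg = inference_config(),
                           return_probs = FALSE, verbose = FALSE) {
  stopifnot(inherits(v, "oralseg_volume"), inherits(model, "oralseg_model"))
  full_shape <- dim(v$data)
  work <- v
  roi <- cfg$roi
  if (!is.null(roi)) {
    roi <- as.integer(roi)
    if (length(roi) != 6L || any(roi[1:3] < 1L) ||
        any(roi[4:6] > full_shape) || any(roi[4:6] < roi[1:3])) {
      stop("ROI ", paste(roi, collapse = ","),
           " outside the volume ", paste(full_shape, collapse = "x"))
    }
    work <- volume(v$data[roi[1]:roi[4], roi[2]:roi[5], roi[3]:roi[6],
                          drop = FALSE],
                   v$spacing, v$origin, v$orientation)
  }
  in_shape <- dim(work$data)
  resampled <- any(abs(work$spacing - cfg$target_spacing) /
                     cfg$target_spacing > cfg$spacing_tol)
  if (resampled) {
    work <- resample_to_spacing(work, cfg$target_spacing, "continuous")
  }
  work <- normalize_intensity(work)
  arr <- work$data
  win <- cfg$window
  pad_lo <- pmax(win - dim(arr), 0L) %/% 2L
  padded <- pad_to_min(arr, win, 0)
  d <- dim(padded)
  K <- model$cfg$num_classes
  starts <- lapply(1:3, function(a) window_starts(d[a], win[a], cfg$overlap))
  wts <- blend_weights(win, cfg$blend)
  acc <- array(0, c(K, d))
  den <- array(0, d)
  nt <- prod(lengths(starts))
  done <- 0L
  for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
    ix <- sx + seq_len(win[1]); iy <- sy + seq_len(win[2])
    iz <- sz + seq_len(win[3])
    p <- model_forward(model, padded[ix, iy, iz, drop = FALSE])
    p <- array(p, dim(p)[-1])  # (K, win)
    if (cfg$blend == "constant" && nt == 1L) {
      acc[, ix, iy, iz] <- p
      den[ix, iy, iz] <- 1
    } else {
      wb <- aperm(array(wts, c(win, K)), c(4, 1, 2, 3))
      acc[, ix, iy, iz] <- acc[, ix, iy, iz] + p * wb
      den[ix, iy, iz] <- den[ix, iy, iz] + wts
    }
    done <- done + 1L
    if (verbose) message(sprintf("window %d/%d", done, nt))
  }
  probs <- acc / aperm(array(den, c(d, K)), c(4, 1, 2, 3))
  # crop padding
  probs <- probs[, pad_lo[1] + seq_len(dim(arr)[1]),
                 pad_lo[2] + seq_len(dim(arr)[2]),
                 pad_lo[3] + seq_len(dim(arr)[3]), drop = FALSE]
  lab <- decode_labels(probs, spacing = work$spacing)$labels
  if (resampled) {
    lab <- resample_labels_to_grid(lab, work$spacing, in_shape, v$spacing)
  }
  if (cfg$keep_largest_component) lab <- keep_largest_cc(lab)
  if (!is.null(roi)) {
    fulllab <- array(0L, full_shape)
    fulllab[roi[1]:roi[4], roi[2]:roi[5], roi[3]:roi[6]] <- lab
    lab <- fulllab
  }
  out <- label_volume(lab, spacing = v$spacing, origin = v$origin,
                      orientation = v$orientation)
  if (cfg$output_mode == "semantic") out <- merge_to_semantic(out)
  if (return_probs) attr(out, "probs") <- probs
  out
}
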