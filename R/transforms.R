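#' Augmentation configuration
#'
#' Spatial transforms (flips, axis-aligned 90-degree rotations) are
#' label-exact voxel permutations applied identically to the image and
#' its label map; intensity transforms (multiplicative scale, additive
#' shift) touch only the image. Default ranges (scale 0.9--1.1, shift
#' +/-0.1 after 0--1 normalization) are package defaults, configurable.
#' Free-angle rotation about the z axis (nearest-neighbour labels) is
#' available behind `free_rotate_deg`, off by default so augmentation
#' stays label-exact.
#'
#' @param flip_prob Length-3 per-axis flip probabilities.
#' @param rotate90_prob Length-3 probabilities for a single 90-degree
#'   rotation in the (x,y), (x,z) and (y,z) planes.
#' @param intensity_scale_range Length-2 multiplicative range (> 0).
#' @param intensity_shift_range Length-2 additive range.
#' @param free_rotate_deg Maximum free rotation about z in degrees
#'   (0 disables; uses trilinear image / nearest-label resampling).
#' @param seed Default seed used by [augment_pair()].
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(flip_prob = c(0.5, 0.5, 0.5),
                           rotate90_prob = c(0.5, 0, 0),
                           intensity_scale_range = c(0.9, 1.1),
                           intensity_shift_range = c(-0.1, 0.1),
                           free_rotate_deg = 0,
                           seed = 1L) {
  stopifnot(all(flip_prob >= 0 & flip_prob <= 1),
            all(rotate90_prob >= 0 & rotate90_prob <= 1),
            length(intensity_scale_range) == 2L,
            all(intensity_scale_range > 0),
            length(intensity_shift_range) == 2L,
            free_rotate_deg >= 0)
  structure(list(flip_prob = flip_prob, rotate90_prob = rotate90_prob,
                 intensity_scale_range = sort(intensity_scale_range),
                 intensity_shift_range = sort(intensity_shift_range),
                 free_rotate_deg = free_rotate_deg, seed = as.integer(seed)),
            class = "augment_config")
}

flip_axis <- function(a, axis) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

rot90_plane <- function(a, axes) {
  # 90-degree rotation in the plane of `axes` (a length-2 axis pair)
  perm <- 1:3
  perm[axes] <- axes[2:1]
  flip_axis(aperm(a, perm), axes[1])
}

rotate_z_free <- function(a, angle_rad, nearest) {
  d <- dim(a)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  co <- cos(-angle_rad); si <- sin(-angle_rad)  # inverse map
  gx <- matrix(seq_len(d[1]), d[1], d[2])
  gy <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  sx <- co * (gx - cx) - si * (gy - cy) + cx
  sy <- si * (gx - cx) + co * (gy - cy) + cy
  out <- array(if (nearest) 0L else 0, d)
  if (nearest) {
    ix <- pmin(pmax(round(sx), 1), d[1])
    iy <- pmin(pmax(round(sy), 1), d[2])
    for (z in seq_len(d[3])) {
      sl <- a[, , z]
      out[, , z] <- matrix(sl[cbind(as.vector(ix), as.vector(iy))], d[1])
    }
  } else {
    x0 <- pmin(pmax(floor(sx), 1), d[1]); x1 <- pmin(x0 + 1, d[1])
    y0 <- pmin(pmax(floor(sy), 1), d[2]); y1 <- pmin(y0 + 1, d[2])
    fx <- pmin(pmax(sx - x0, 0), 1); fy <- pmin(pmax(sy - y0, 0), 1)
    for (z in seq_len(d[3])) {
      sl <- a[, , z]
      v <- (1 - fx) * (1 - fy) * sl[cbind(c(x0), c(y0))] +
           fx * (1 - fy) * sl[cbind(c(x1), c(y0))] +
           (1 - fx) * fy * sl[cbind(c(x0), c(y1))] +
           fx * fy * sl[cbind(c(x1), c(y1))]
      out[, , z] <- matrix(v, d[1])
    }
  }
  out
}

#' Apply a seeded augmentation to an image/label pair
#'
#' Spatial draws are applied identically to both members; intensity
#' draws touch only the image, so the label value set is preserved.
#' The list of applied transforms is attached as attribute `"applied"`.
#'
#' @param v A [volume()].
#' @param lv The paired [label_volume()] (same grid).
#' @param cfg An [augment_config()].
#' @param seed Seed for this draw (defaults to `cfg$seed`).
#' @return List with elements `volume`, `labels`.
#' @export
augment_pair <- function(v, lv, cfg = augment_config(), seed = cfg$seed) {
  stopifnot(inherits(v, "oralseg_volume"), inherits(lv, "oralseg_labelvolume"))
  if (!identical(dim(v$data), dim(lv$labels))) {
    stop("image and label grids differ: ",
         paste(dim(v$data), collapse = "x"), " vs ",
         paste(dim(lv$labels), collapse = "x"))
  }
  run_seeded(seed, {
    img <- v$data; lab <- lv$labels
    applied <- character(0)
    for (axis in 1:3) {
      if (stats::runif(1) < cfg$flip_prob[axis]) {
        img <- flip_axis(img, axis); lab <- flip_axis(lab, axis)
        applied <- c(applied, paste0("flip", axis))
      }
    }
    planes <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    for (p in 1:3) {
      if (stats::runif(1) < cfg$rotate90_prob[p]) {
        ax <- planes[[p]]
        if (dim(img)[ax[1]] == dim(img)[ax[2]]) {
          img <- rot90_plane(img, ax); lab <- rot90_plane(lab, ax)
          applied <- c(applied, paste0("rot90_", ax[1], ax[2]))
        }
      }
    }
    if (cfg$free_rotate_deg > 0) {
      ang <- stats::runif(1, -cfg$free_rotate_deg, cfg$free_rotate_deg) *
        pi / 180
      img <- rotate_z_free(img, ang, nearest = FALSE)
      lab <- rotate_z_free(lab, ang, nearest = TRUE)
      applied <- c(applied, sprintf("rotz_%.2f", ang))
    }
    sc <- stats::runif(1, cfg$intensity_scale_range[1],
                       cfg$intensity_scale_range[2])
    sh <- stats::runif(1, cfg$intensity_shift_range[1],
                       cfg$intensity_shift_range[2])
    img <- img * sc + sh
    applied <- c(applied, sprintf("scale_%.4f", sc), sprintf("shift_%.4f", sh))
    out <- list(
      volume = volume(img, v$spacing, v$origin, v$orientation),
      labels = label_volume(lab, lv$spacing, lv$origin, lv$orientation,
                            lv$scheme_ref)
    )
    attr(out, "applied") <- applied
    out
  })
}

pad_to_min <- function(a, patch, fill) {
  d <- dim(a)
  need <- pmax(patch - d, 0L)
  if (all(need == 0L)) return(a)
  lo <- need %/% 2L
  out <- array(fill, pmax(d, patch))
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- a
  out
}

#' Sample an aligned random patch from an image/label pair
#'
#' Crop origin is uniform over all valid positions under the seed
#' (random 3D cropping). Inputs smaller than the patch are first padded
#' symmetrically with zeros (image) / background (labels). An optional
#' foreground-biased mode (off by default) retries until the patch
#' contains foreground, falling back to the last draw.
#'
#' @param v A [volume()].
#' @param lv The paired [label_volume()].
#' @param patch Integer length-3 patch shape (default `c(64, 64, 64)`).
#' @param seed Integer seed.
#' @param foreground_bias Class-balanced cropping: draw a foreground
#'   class uniformly from those present, then a voxel of that class
#'   uniformly, and centre the patch on it (clamped to the grid). May be
#'   logical or a probability in `[0, 1]` of using the balanced draw
#'   (otherwise a plain uniform crop), so training can mix
#'   structure-centred and arbitrary-offset views. Off by default —
#'   plain random 3D cropping is the default protocol; the balanced mode
#'   counteracts the extreme voxel imbalance between jaws and small
#'   structures.
#' @return List with elements `volume`, `labels`, `origin` (0-based crop
#'   origin in the padded grid).
#' @export
sample_patch <- function(v, lv, patch = c(64L, 64L, 64L), seed = 1L,
                         foreground_bias = FALSE) {
  stopifnot(identical(dim(v$data), dim(lv$labels)))
  patch <- as.integer(patch)
  img <- pad_to_min(v$data, patch, 0)
  lab <- pad_to_min(lv$labels, patch, 0L)
  d <- dim(img)
  bias_prob <- if (is.logical(foreground_bias)) as.numeric(foreground_bias)
               else foreground_bias
  stopifnot(bias_prob >= 0, bias_prob <= 1)
  run_seeded(seed, {
    use_bias <- bias_prob > 0 && stats::runif(1) < bias_prob
    org <- if (use_bias && any(lab != 0L)) {
      classes <- sort(unique(as.integer(lab)))
      classes <- classes[classes != 0L]
      k <- classes[sample.int(length(classes), 1L)]
      vox <- which(lab == k)
      ctr <- arrayInd(vox[sample.int(length(vox), 1L)], d)
      vapply(1:3, function(a) {
        min(max(ctr[a] - patch[a] %/% 2L, 1L), d[a] - patch[a] + 1L) - 1L
      }, integer(1))
    } else {
      vapply(1:3, function(a) {
        if (d[a] == patch[a]) 0L else sample.int(d[a] - patch[a] + 1L, 1L) - 1L
      }, integer(1))
    }
    list(volume = volume(img[org[1] + seq_len(patch[1]),
                             org[2] + seq_len(patch[2]),
                             org[3] + seq_len(patch[3]), drop = FALSE],
                         v$spacing, v$origin, v$orientation),
         labels = label_volume(lab[org[1] + seq_len(patch[1]),
                                   org[2] + seq_len(patch[2]),
                                   org[3] + seq_len(patch[3]), drop = FALSE],
                               lv$spacing, lv$origin, lv$orientation,
                               lv$scheme_ref),
         origin = org)
  })
}
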