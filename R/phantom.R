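#' @title Procedural dental CBCT phantom
#' @description Seeded generator of synthetic CBCT-like volumes with
#'   ground-truth instance labels following the 36-structure scheme:
#'   two dental arches of up to 32 teeth (ellipsoid crowns on an arch
#'   curve, tapered-cone roots penetrating the jaw slabs), maxilla and
#'   mandible slabs with a cortical/trabecular intensity split, two
#'   tubular mandibular canals, per-material intensities with additive
#'   Gaussian noise, and optional metal-streak / motion-blur artifacts.
#'   All geometry is parametric-analytic, so generation is a pure
#'   function of the spec and exactly reproducible from its seed.
#' @name phantom
NULL

run_seeded <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parametric description of a synthetic dental scene
#'
#' Defaults describe the desk-scale scene: a 128 x 128 x 96 grid at
#' 0.3 mm isotropic spacing (the clinical acquisition grid of
#' 440 x 440 x 344 at 0.3 mm remains a configuration choice), complete
#' dentition, and geometry scaled to the grid extent.
#'
#' @param grid_shape Integer length-3, each >= 32.
#' @param spacing_mm Voxel spacing in mm (scalar, isotropic).
#' @param teeth_present Named logical length-32 keyed by FDI code
#'   (`"11"`..`"48"`), or a logical scalar recycled to all 32.
#' @param arch_params List: `radius_frac` (arch half-width as a fraction
#'   of the x extent), `depth_frac` (arch depth as fraction of y extent),
#'   `span_deg` (angular half-span of the 8 tooth positions per side).
#' @param tooth_params List: `crown_radius_scale`, `crown_height_ratio`
#'   (height/radius), `root_length_ratio` (length/radius), and
#'   `type_scale` (length-4 factors for incisor/canine/premolar/molar).
#' @param jaw_params List: `slab_frac` (z thickness fraction per jaw),
#'   `gap_frac` (interocclusal gap fraction), `cortical_shell_frac`.
#' @param canal_params List: `radius_mm`, `z_frac` (canal depth within
#'   the mandible, 0 = top), `arc_frac` (radial position of the canal
#'   curve relative to the arch).
#' @param intensity_model List of mean intensities `background`,
#'   `trabecular`, `cortical`, `dentin`, `enamel`, `canal`, plus
#'   `noise_sd` (additive Gaussian, arbitrary CBCT-like units).
#' @param artifacts List: `metal_streak` (logical), `streak_fdi` (FDI
#'   code of the seeding crown), `motion_blur_sigma` (mm; 0 = off).
#' @param seed Integer seed; the whole phantom is a pure function of it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 96L),
                         spacing_mm = 0.3,
                         teeth_present = TRUE,
                         arch_params = list(),
                         tooth_params = list(),
                         jaw_params = list(),
                         canal_params = list(),
                         intensity_model = list(),
                         artifacts = list(),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 32L),
            length(spacing_mm) == 1L, spacing_mm > 0)
  fdi <- as.character(index_to_fdi(1:32))
  if (length(teeth_present) == 1L) {
    teeth_present <- stats::setNames(rep(as.logical(teeth_present), 32L), fdi)
  }
  if (is.null(names(teeth_present))) names(teeth_present) <- fdi
  teeth_present <- teeth_present[fdi]
  if (length(teeth_present) != 32L || any(is.na(teeth_present))) {
    stop("teeth_present must provide exactly 32 entries keyed by FDI code")
  }
  dflt <- function(user, def) utils::modifyList(def, user)
  spec <- structure(list(
    grid_shape = grid_shape,
    spacing_mm = spacing_mm,
    teeth_present = teeth_present,
    arch_params = dflt(arch_params, list(
      radius_frac = 0.33, depth_frac = 0.30, span_deg = 95,
      lower_scale = 0.94, center_y_frac = 0.06
    )),
    tooth_params = dflt(tooth_params, list(
      crown_radius_scale = 1.0, crown_height_ratio = 1.35,
      root_length_ratio = 2.4, type_scale = c(0.72, 0.80, 0.90, 1.0),
      # natural morphological variation: per-tooth seeded jitter of the
      # crown semi-axes/height (real dentitions are not clone sets)
      shape_jitter = 0.12
    )),
    jaw_params = dflt(jaw_params, list(
      slab_frac = 0.32, gap_frac = 0.20, cortical_shell_frac = 0.16
    )),
    canal_params = dflt(canal_params, list(
      radius_mm = max(0.6, 2 * spacing_mm), z_frac = 0.62, arc_frac = 0.82,
      # left/right canals are not mirror images in real mandibles: seeded
      # per-side jitter of calibre and depth
      side_jitter = 0.1
    )),
    intensity_model = dflt(intensity_model, list(
      background = 60, trabecular = 230, cortical = 340, dentin = 430,
      enamel = 520, canal = 120, noise_sd = 18,
      # per-tooth multiplicative brightness jitter (mineralization varies)
      per_tooth_jitter = 0.05
    )),
    artifacts = dflt(artifacts, list(
      metal_streak = FALSE, streak_fdi = 16L, motion_blur_sigma = 0
    )),
    seed = as.integer(seed)
  ), class = "phantom_spec")
  with(spec$tooth_params, stopifnot(crown_radius_scale > 0,
                                    crown_height_ratio > 0,
                                    root_length_ratio > 0,
                                    all(type_scale > 0)))
  stopifnot(spec$canal_params$radius_mm > 0)
  spec
}

# tooth archetype (1 incisor, 2 canine, 3 premolar, 4 molar) per FDI position
tooth_type_of_position <- function(pos) {
  c(1L, 1L, 2L, 3L, 3L, 4L, 4L, 4L)[pos]
}

# number of roots: incisor/canine 1, premolar 1 (2 for upper first),
# molar 2 lower / 3 upper
n_roots_of <- function(fdi) {
  pos <- fdi %% 10L
  upper <- fdi %/% 10L <= 2L
  ty <- tooth_type_of_position(pos)
  if (ty <= 2L) return(1L)
  if (ty == 3L) return(if (upper && pos == 4L) 2L else 1L)
  if (upper) 3L else 2L
}

# centres of the 16 tooth positions of one arch, anterior at +y.
# returns data.frame(fdi, x, y, type) ordered by FDI within the arch
arch_positions <- function(spec, upper) {
  ap <- spec$arch_params
  ext <- spec$grid_shape * spec$spacing_mm
  scale <- if (upper) 1 else ap$lower_scale
  rx <- ap$radius_frac * ext[1] * scale
  ry <- ap$depth_frac * ext[2] * scale
  yc <- ap$center_y_frac * ext[2]
  span <- ap$span_deg * pi / 180
  th <- (seq_len(8L) - 0.5) / 8 * span            # midline outwards
  q_right <- if (upper) 1L else 4L                # patient right: x < 0
  q_left <- if (upper) 2L else 3L
  pos <- rbind(
    data.frame(fdi = q_right * 10L + 1:8, theta = -th),
    data.frame(fdi = q_left * 10L + 1:8, theta = th)
  )
  pos$x <- rx * sin(pos$theta)
  pos$y <- ry * cos(pos$theta) + yc
  pos$type <- tooth_type_of_position(pos$fdi %% 10L)
  pos
}

paint_ball_box <- function(lab, mat, mask_fn, lo_mm, hi_mm, value, material,
                           coords) {
  idx <- lapply(1:3, function(a) {
    which(coords[[a]] >= lo_mm[a] & coords[[a]] <= hi_mm[a])
  })
  if (any(lengths(idx) == 0L)) return(list(lab = lab, mat = mat))
  sub <- mask_fn(coords[[1]][idx[[1]]], coords[[2]][idx[[2]]],
                 coords[[3]][idx[[3]]])
  if (any(sub)) {
    cur <- lab[idx[[1]], idx[[2]], idx[[3]]]
    curm <- mat[idx[[1]], idx[[2]], idx[[3]]]
    cur[sub] <- value
    curm[sub] <- material
    lab[idx[[1]], idx[[2]], idx[[3]]] <- cur
    mat[idx[[1]], idx[[2]], idx[[3]]] <- curm
  }
  list(lab = lab, mat = mat)
}

#' Generate one synthetic CBCT phantom
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (a [volume()]) and `labels`
#'   (a [label_volume()]), both on the spec grid. Every present tooth is
#'   one connected component; canals lie strictly inside the mandible
#'   slab region; bone/tooth intensities exceed background by
#'   construction (before artifact injection).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  run_seeded(spec$seed, {
    n <- spec$grid_shape
    s <- spec$spacing_mm
    ext <- n * s
    coords <- lapply(1:3, function(a) (seq_len(n[a]) - (n[a] + 1) / 2) * s)
    lab <- array(0L, n)
    mat <- array(0L, n)  # 0 bg, 1 trab, 2 cortical, 3 enamel, 4 dentin, 5 canal

    jp <- spec$jaw_params
    gap <- jp$gap_frac * ext[3] / 2
    slab <- jp$slab_frac * ext[3]
    mand_z <- c(-(gap + slab), -gap)
    max_z <- c(gap, gap + slab)

    # jaw slabs: elliptical cylinders with a cortical shell
    ax <- 0.44 * ext[1]; ay <- 0.42 * ext[2]; jyc <- 0.02 * ext[2]
    ell <- outer((coords[[1]] / ax)^2, ((coords[[2]] - jyc) / ay)^2, "+")
    shell_lo <- (1 - jp$cortical_shell_frac)^2
    for (jaw in c("mandible", "maxilla")) {
      zr <- if (jaw == "mandible") mand_z else max_z
      value <- if (jaw == "mandible") 34L else 33L
      inz <- which(coords[[3]] >= zr[1] & coords[[3]] <= zr[2])
      if (length(inz) == 0L) next
      core <- ell <= 1
      shell2d <- ell > shell_lo & ell <= 1
      zc <- coords[[3]][inz]
      near_face <- abs(zc - zr[1]) < 1.5 * s | abs(zc - zr[2]) < 1.5 * s
      for (k in seq_along(inz)) {
        sl_lab <- lab[, , inz[k]]
        sl_mat <- mat[, , inz[k]]
        sl_lab[core] <- value
        sl_mat[core] <- 1L
        cort <- shell2d | (core & near_face[k])
        sl_mat[cort & core] <- 2L
        lab[, , inz[k]] <- sl_lab
        mat[, , inz[k]] <- sl_mat
      }
    }

    # mandibular canals: tubes along a scaled arch curve inside the mandible
    cp <- spec$canal_params
    ap <- spec$arch_params
    rx <- ap$radius_frac * ext[1] * ap$lower_scale * cp$arc_frac
    ry <- ap$depth_frac * ext[2] * ap$lower_scale * cp$arc_frac
    yc <- ap$center_y_frac * ext[2]
    zcan <- mand_z[2] - cp$z_frac * (mand_z[2] - mand_z[1])
    span <- ap$span_deg * pi / 180 * 1.05
    # per-side signatures: calibre, depth, lumen brightness. The two
    # sides are jittered in opposite directions so no seed draws a
    # mirror-symmetric pair (real canal pairs are never identical)
    umag <- stats::runif(6L, 0.5, 1)
    side_jit <- rbind(1 - cp$side_jitter * umag[1:3],
                      1 + cp$side_jitter * umag[4:6])
    for (side in c(1, -1)) {  # +x = patient left (class 35), -x = right (36)
      value <- if (side > 0) 35L else 36L
      si <- if (side > 0) 1L else 2L
      rcan <- cp$radius_mm * side_jit[si, 1]
      zside <- zcan * side_jit[si, 2]
      ths <- seq(0.22 * span, span, length.out = 80L)
      for (th in ths) {
        cx <- side * rx * sin(th); cy <- ry * cos(th) + yc
        cz <- zside + 0.08 * (mand_z[2] - mand_z[1]) * (th / span)
        res <- paint_ball_box(lab, mat, function(x, y, z) {
          outer(outer((x - cx)^2, (y - cy)^2, "+"), (z - cz)^2, "+") <= rcan^2
        }, c(cx, cy, cz) - rcan, c(cx, cy, cz) + rcan, value, 5L, coords)
        lab <- res$lab; mat <- res$mat
      }
    }

    # teeth
    tp <- spec$tooth_params
    sj <- tp$shape_jitter
    # per-tooth morphology/brightness signatures, drawn for all 32 FDI
    # positions in fixed order so presence patterns do not shift them
    shape_jit <- matrix(stats::runif(32L * 3L, 1 - sj, 1 + sj), 32L)
    bright_jit <- stats::runif(32L, 1 - spec$intensity_model$per_tooth_jitter,
                               1 + spec$intensity_model$per_tooth_jitter)
    for (upper in c(TRUE, FALSE)) {
      pos <- arch_positions(spec, upper)
      present_i <- which(spec$teeth_present[as.character(pos$fdi)])
      if (length(present_i) == 0L) next
      # cap crown radii at a fraction of the distance to the nearest
      # *present* neighbour so instance labels never overlap
      dmin <- sapply(seq_len(nrow(pos)), function(i) {
        d <- sqrt((pos$x - pos$x[i])^2 + (pos$y - pos$y[i])^2)
        d <- d[setdiff(present_i, i)]
        if (length(d) == 0L) Inf else min(d)
      })
      base_r <- pmin(0.47 / (1 + sj) * dmin, 0.07 * ext[1]) *
        tp$type_scale[pos$type] * tp$crown_radius_scale
      for (i in seq_len(nrow(pos))) {
        fdi <- pos$fdi[i]
        if (!spec$teeth_present[[as.character(fdi)]]) next
        cls <- fdi_to_index(fdi)
        r <- base_r[i]
        if (r < 1.5 * s) {
          stop("tooth geometry cannot fit the grid: FDI ", fdi,
               " crown radius ", signif(r, 3), " mm < 1.5 voxels")
        }
        # crown height capped so opposing crowns never cross the
        # occlusal plane (gap = half the interocclusal distance)
        h <- min(tp$crown_height_ratio * r, gap / 1.7)
        rx <- r * shape_jit[cls, 1]
        ry <- r * shape_jit[cls, 2]
        hz <- h * shape_jit[cls, 3]
        zdir <- if (upper) 1 else -1
        zjaw <- if (upper) max_z[1] else mand_z[2]
        ccz <- zjaw - zdir * 0.55 * h
        # crown: ellipsoid with this tooth's signature axes
        res <- paint_ball_box(lab, mat, function(x, y, z) {
          outer(outer(((x - pos$x[i]) / rx)^2, ((y - pos$y[i]) / ry)^2, "+"),
                ((z - ccz) / hz)^2, "+") <= 1
        }, c(pos$x[i] - rx, pos$y[i] - ry, ccz - hz),
           c(pos$x[i] + rx, pos$y[i] + ry, ccz + hz), cls, 3L, coords)
        lab <- res$lab; mat <- res$mat
        # roots: tapered cones from inside the crown into the jaw slab
        nr <- n_roots_of(fdi)
        rootlen <- tp$root_length_ratio * r
        z0 <- ccz + zdir * 0.3 * h
        z1 <- ccz + zdir * (h + rootlen)
        offs <- switch(nr,
          list(c(0, 0)),
          list(c(-0.45 * r, 0), c(0.45 * r, 0)),
          list(c(-0.45 * r, -0.3 * r), c(0.45 * r, -0.3 * r), c(0, 0.45 * r))
        )
        rroot <- 0.5 * r / sqrt(nr)
        for (off in offs) {
          rcx <- pos$x[i] + off[1]; rcy <- pos$y[i] + off[2]
          res <- paint_ball_box(lab, mat, function(x, y, z) {
            tfrac <- (z - z0) / (z1 - z0)  # 0 at crown, 1 at apex
            rad <- pmax(rroot * (1 - 0.7 * tfrac), 0.8 * s)
            okz <- tfrac >= 0 & tfrac <= 1
            r2 <- outer((x - rcx)^2, (y - rcy)^2, "+")
            o <- outer(r2, rad^2, function(a, b) a <= b)
            o & rep(okz, each = length(r2))
          }, c(rcx - rroot, rcy - rroot, min(z0, z1)),
             c(rcx + rroot, rcy + rroot, max(z0, z1)), cls, 4L, coords)
          lab <- res$lab; mat <- res$mat
        }
      }
    }

    # voxelization can leave isolated surface voxels touching a tooth only
    # diagonally; keep each tooth's largest 6-connected component so every
    # instance is a single component
    for (k in sort(unique(as.integer(lab)))) {
      if (k < 1L || k > 32L) next
      w <- which(lab == k, arr.ind = TRUE)
      rng <- lapply(1:3, function(a) min(w[, a]):max(w[, a]))
      sub <- lab[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] == k
      comp <- label_components6(sub)
      tabs <- tabulate(comp[comp > 0L])
      if (length(tabs) > 1L) {
        drop <- sub & (comp != which.max(tabs))
        cur <- lab[rng[[1]], rng[[2]], rng[[3]]]
        cur[drop] <- 0L
        lab[rng[[1]], rng[[2]], rng[[3]]] <- cur
      }
    }

    # intensities from the material map + noise
    im <- spec$intensity_model
    lut <- c(im$background, im$trabecular, im$cortical, im$enamel,
             im$dentin, im$canal)
    img <- array(lut[mat + 1L], n)
    for (k in sort(unique(as.integer(lab)))) {
      if (k >= 1L && k <= 32L) {
        sel <- lab == k
        img[sel] <- img[sel] * bright_jit[k]
      } else if (k %in% c(35L, 36L)) {
        sel <- lab == k
        img[sel] <- img[sel] * side_jit[k - 34L, 3L]
      }
    }
    img <- img + array(stats::rnorm(prod(n), 0, im$noise_sd), n)

    # artifacts
    art <- spec$artifacts
    if (isTRUE(art$metal_streak)) {
      img <- add_metal_streak(img, lab, spec, coords,
                              fdi = as.integer(art$streak_fdi))
    }
    if (art$motion_blur_sigma > 0) {
      img <- gaussian_blur3(img, art$motion_blur_sigma / s)
    }

    list(volume = volume(img, spacing = rep(s, 3)),
         labels = label_volume(lab, spacing = rep(s, 3)))
  })
}

# radial high-intensity spokes through a chosen crown, in axial slices
add_metal_streak <- function(img, lab, spec, coords, fdi = 16L,
                             n_spokes = 10L, amplitude = 400) {
  cls <- fdi_to_index(fdi)
  w <- which(lab == cls, arr.ind = TRUE)
  if (nrow(w) == 0L) return(img)
  cx <- coords[[1]][round(mean(w[, 1]))]
  cy <- coords[[2]][round(mean(w[, 2]))]
  zidx <- sort(unique(w[, 3]))
  phi0 <- stats::runif(n_spokes, 0, 2 * pi)
  ang <- outer(atan2(rep(coords[[2]], each = length(coords[[1]])) - cy,
                     rep(coords[[1]], times = length(coords[[2]])) - cx), phi0, "-")
  dist <- sqrt(outer((coords[[1]] - cx)^2, (coords[[2]] - cy)^2, "+"))
  wrap <- abs(((ang + pi) %% (2 * pi)) - pi)
  spoke <- matrix(rowSums(exp(-(wrap / 0.04)^2)), length(coords[[1]]))
  bump <- amplitude * spoke * exp(-dist / (0.3 * max(dist)))
  for (z in zidx) img[, , z] <- img[, , z] + bump
  img
}

# separable gaussian blur, sigma in voxels
gaussian_blur3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  for (a in 1:3) {
    nk <- min(d[a], 2L * ceiling(3 * sigma) + 1L)
    half <- (nk - 1L) %/% 2L
    k <- stats::dnorm(-half:half, sd = sigma)
    k <- k / sum(k)
    km <- matrix(0, d[a], d[a])
    for (j in seq_len(d[a])) {
      ii <- pmin(pmax(j + (-half:half), 1L), d[a])
      for (t in seq_along(ii)) km[ii[t], j] <- km[ii[t], j] + k[t]
    }
    perm <- c(a, setdiff(1:3, a))
    x <- aperm(arr, perm)
    dims <- dim(x)
    x <- t(km) %*% matrix(x, dims[1])
    dim(x) <- dims
    arr <- aperm(x, order(perm))
  }
  arr
}

#' Generate a cohort of phantoms
#'
#' `n` independent phantoms; each tooth is absent independently with
#' probability `missing_rate` (the partially-edentulous case mix).
#' Per-phantom seeds are derived deterministically from the cohort seed.
#'
#' @param n Number of phantoms (>= 1).
#' @param missing_rate Per-tooth Bernoulli absence probability in `[0,1]`.
#' @param seed Cohort seed.
#' @param spec_fn Function `(seed, teeth_present) -> phantom_spec`,
#'   allowing grid/geometry overrides; defaults to [phantom_spec()].
#' @return List of `n` lists with elements `volume`, `labels`,
#'   `absent_fdi` (integer FDI codes of missing teeth).
#' @export
generate_cohort <- function(n, missing_rate = 0, seed = 1L,
                            spec_fn = phantom_spec) {
  stopifnot(n >= 1, missing_rate >= 0, missing_rate <= 1)
  run_seeded(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    absent <- lapply(seq_len(n), function(i) {
      stats::runif(32L) < missing_rate
    })
    lapply(seq_len(n), function(i) {
      present <- stats::setNames(!absent[[i]], as.character(index_to_fdi(1:32)))
      ph <- generate_phantom(spec_fn(seed = seeds[i], teeth_present = present))
      ph$absent_fdi <- index_to_fdi(which(absent[[i]]))
      ph
    })
  })
}

#' Simulate a second rater by flipping label-boundary voxels
#'
#' Voxels on a label boundary (any of the 6 face neighbours differs) are
#' reassigned, with probability `boundary_flip_prob`, to the label of a
#' randomly chosen differing neighbour. Interior voxels are untouched, so
#' per-label Dice against the original decreases monotonically in the
#' flip probability.
#'
#' @param lv A [label_volume()].
#' @param boundary_flip_prob Flip probability in `[0,1]`.
#' @param seed Integer seed.
#' @return A perturbed [label_volume()].
#' @export
perturb_annotation <- function(lv, boundary_flip_prob, seed = 1L) {
  stopifnot(inherits(lv, "oralseg_labelvolume"),
            boundary_flip_prob >= 0, boundary_flip_prob <= 1)
  if (boundary_flip_prob == 0) return(lv)
  run_seeded(seed, {
    lab <- lv$labels
    d <- dim(lab)
    shift <- function(a, axis, by) {
      src <- lapply(1:3, function(x) seq_len(d[x]))
      src[[axis]] <- pmin(pmax(src[[axis]] + by, 1L), d[axis])
      a[src[[1]], src[[2]], src[[3]]]
    }
    neigh <- list(shift(lab, 1, -1), shift(lab, 1, 1),
                  shift(lab, 2, -1), shift(lab, 2, 1),
                  shift(lab, 3, -1), shift(lab, 3, 1))
    differs <- lapply(neigh, function(nb) nb != lab)
    boundary <- Reduce(`|`, differs)
    flip <- boundary & array(stats::runif(length(lab)) < boundary_flip_prob, d)
    wf <- which(flip)
    if (length(wf)) {
      # random neighbour choice: random starting direction, first differing
      start <- sample.int(6L, length(wf), replace = TRUE)
      new <- lab[wf]
      undecided <- rep(TRUE, length(wf))
      for (step in 0:5) {
        dir <- ((start + step - 1L) %% 6L) + 1L
        for (dd in 1:6) {
          sel <- undecided & dir == dd
          if (!any(sel)) next
          cand <- differs[[dd]][wf[sel]]
          pick <- sel
          pick[sel] <- cand
          new[pick] <- neigh[[dd]][wf[pick]]
          undecided[pick] <- FALSE
        }
      }
      lab[wf] <- new
    }
    label_volume(lab, spacing = lv$spacing, origin = lv$origin,
                 orientation = lv$orientation, scheme_ref = lv$scheme_ref)
  })
}
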