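#' Construct a CBCT volume
#'
#' A `volume` is a 3D scalar grid with voxel spacing (mm), a world origin
#' (mm) and an axis-orientation tag. Internally every volume is held in
#' RAS voxel order (+x patient-left, +y anterior, +z superior); files
#' stored LPS are reoriented on read and restored on write, so voxel
#' operations never see mixed conventions.
#'
#' @param data 3D numeric array (each dimension >= 1).
#' @param spacing Numeric length-3, voxel spacing in mm, all > 0.
#' @param origin Numeric length-3, world position (mm) of voxel (1,1,1).
#' @param orientation `"RAS"` or `"LPS"` — the on-disk convention this
#'   volume came from / will be written in. Data is always RAS in memory.
#' @return An object of class `oralseg_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   orientation = "RAS") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("volume data must be a 3D array, got dimensionality ",
         if (is.array(data)) length(dim(data)) else 1L)
  }
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0),
            length(origin) == 3L, orientation %in% c("RAS", "LPS"))
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin), orientation = orientation),
            class = "oralseg_volume")
}

#' Construct a label volume
#'
#' Integer instance-label grid on the same voxel lattice as its paired
#' [volume()]. Values are 0 (background) .. K keys of the referenced
#' label scheme.
#'
#' @inheritParams volume
#' @param labels 3D integer array.
#' @param scheme_ref Identifier of the label scheme the values refer to.
#' @return An object of class `oralseg_labelvolume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = "RAS", scheme_ref = "oralseg-fdi-v1") {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("label data must be a 3D array, got dimensionality ",
         if (is.array(labels)) length(dim(labels)) else 1L)
  }
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0),
            length(origin) == 3L, orientation %in% c("RAS", "LPS"))
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin), orientation = orientation,
                 scheme_ref = scheme_ref),
            class = "oralseg_labelvolume")
}

#' @export
print.oralseg_volume <- function(x, ...) {
  cat(sprintf("<oralseg volume> %s voxels @ %s mm (%s), range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              x$orientation, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.oralseg_labelvolume <- function(x, ...) {
  vals <- sort(unique(as.integer(x$labels)))
  cat(sprintf("<oralseg labels> %s voxels @ %s mm (%s), %d labels [%s]\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              x$orientation, sum(vals != 0L),
              paste(utils::head(vals, 12), collapse = ",")))
  invisible(x)
}

grid_of <- function(x) if (inherits(x, "oralseg_labelvolume")) x$labels else x$data

file_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.(seg\\.)?nrrd$", lp)) return("nrrd")
  stop("unrecognised volume format (expect .nii, .nii.gz, .nrrd, .seg.nrrd): ",
       path)
}

axis_signs_to_orientation <- function(sgn) {
  if (all(sgn == c(1, 1, 1))) return("RAS")
  if (all(sgn == c(-1, -1, 1))) return("LPS")
  stop("unsupported axis orientation (only axis-aligned RAS or LPS): signs ",
       paste(sgn, collapse = ","))
}

#' Read a volume from NIfTI or NRRD
#'
#' Spacing and origin are taken from the file header; intensities are
#' untouched. LPS files are reoriented to internal RAS (the orientation
#' tag records the on-disk convention so a later write restores it).
#'
#' @param path Path to a `.nii`, `.nii.gz`, `.nrrd` or `.seg.nrrd` file.
#' @param labels If `TRUE`, return a [label_volume()] (integer values).
#' @return A [volume()] or [label_volume()].
#' @export
read_volume <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- file_format(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    nd <- length(dim(img))
    if (nd != 3L) {
      stop("expected a 3D image, file has dimensionality ", nd, ": ", path)
    }
    aff <- RNifti::xform(img)
    rot <- aff[1:3, 1:3]
    if (max(abs(rot - diag(diag(rot)))) > 1e-4 * max(abs(diag(rot)))) {
      stop("unsupported orientation: affine is not axis-aligned in ", path)
    }
    sgn <- sign(diag(rot))
    orient <- axis_signs_to_orientation(sgn)
    dat <- as.array(img)
    spacing <- abs(diag(rot))
    origin <- aff[1:3, 4]
    if (orient == "LPS") {
      # NIfTI affines map to RAS world; flip the LPS-ordered axes and move
      # the origin to the new corner voxel
      dat <- dat[dim(dat)[1]:1, dim(dat)[2]:1, , drop = FALSE]
      origin[1:2] <- origin[1:2] - spacing[1:2] * (dim(dat)[1:2] - 1)
    }
    meta <- NULL
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
    if (labels && file.exists(sidecar)) meta <- sidecar
    if (labels) {
      storage.mode(dat) <- "integer"
      return(label_volume(dat, spacing, origin, orient))
    }
    return(volume(dat, spacing, origin, orient))
  }
  nr <- read_nrrd_raw(path)
  if (labels) {
    dat <- nr$data; storage.mode(dat) <- "integer"
    return(label_volume(dat, nr$spacing, nr$origin, nr$orientation))
  }
  volume(nr$data, nr$spacing, nr$origin, nr$orientation)
}

#' Write a volume to NIfTI or NRRD
#'
#' Format is chosen from the file extension. Label volumes written to
#' NRRD embed the label table (name, FDI code, RGB colour) as key/value
#' header fields; for NIfTI a JSON sidecar `<stem>.labels.json` is
#' written instead.
#'
#' @param v A [volume()] or [label_volume()].
#' @param path Output path (`.nii`, `.nii.gz`, `.nrrd`, `.seg.nrrd`).
#' @param scheme Label scheme embedded with segmentations
#'   (default [default_scheme()]); ignored for plain volumes.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, scheme = default_scheme()) {
  fmt <- file_format(path)
  is_lab <- inherits(v, "oralseg_labelvolume")
  dat <- grid_of(v)
  spacing <- v$spacing
  origin <- v$origin
  if (fmt == "nifti") {
    sgn <- c(1, 1, 1)
    if (v$orientation == "LPS") {
      dat <- dat[dim(dat)[1]:1, dim(dat)[2]:1, , drop = FALSE]
      origin[1:2] <- origin[1:2] + spacing[1:2] * (dim(dat)[1:2] - 1)
      sgn <- c(-1, -1, 1)
    }
    aff <- rbind(cbind(diag(sgn * spacing), origin), c(0, 0, 0, 1))
    img <- RNifti::asNifti(if (is_lab) dat + 0L else dat)
    attr(aff, "code") <- 2L
    RNifti::qform(img) <- aff
    RNifti::sform(img) <- aff
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
    if (is_lab) {
      sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
      write_scheme_json(scheme, sidecar)
    }
    return(invisible(path))
  }
  kv <- NULL
  if (is_lab) {
    kv <- c(
      "oralseg_scheme_ref" = v$scheme_ref,
      "oralseg_label_table" = gsub("\n", " ", write_scheme_json(scheme))
    )
  }
  write_nrrd_raw(dat, path, spacing = spacing, origin = origin,
                 orientation = v$orientation, integer_type = is_lab,
                 keyvals = kv)
  invisible(path)
}

# --- minimal NRRD3 reader/writer (raw and gzip encodings, 3D only) ---------

read_nrrd_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic)) stop("not an NRRD file: ", path)
  fields <- list(); keyvals <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header in ", path)
    if (line == "") break
    if (startsWith(line, "#")) next
    if (grepl(":=", line, fixed = TRUE)) {
      kv <- strsplit(line, ":=", fixed = TRUE)[[1]]
      keyvals[[kv[1]]] <- paste(kv[-1], collapse = ":=")
    } else {
      kv <- regmatches(line, regexpr("^[^:]+", line))
      fields[[tolower(kv)]] <- trimws(sub("^[^:]+:", "", line))
    }
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.null(ndim) || is.na(ndim)) stop("NRRD header missing dimension")
  if (ndim != 3L) stop("expected a 3D image, file has dimensionality ", ndim)
  sizes <- as.integer(strsplit(fields[["sizes"]], "[[:space:]]+")[[1]])
  type <- fields[["type"]]
  enc <- tolower(fields[["encoding"]])
  spacing <- c(1, 1, 1); origin <- c(0, 0, 0); orient <- "RAS"
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- sapply(vecs, function(s) {
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
    })
    if (!is.matrix(m) || any(dim(m) != c(3, 3))) {
      stop("unsupported NRRD space directions")
    }
    offd <- m; diag(offd) <- 0
    if (max(abs(offd)) > 1e-6 * max(abs(diag(m)))) {
      stop("unsupported orientation: NRRD space directions not axis-aligned")
    }
    spacing <- abs(diag(m))
  }
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  }
  if (!is.null(fields[["space"]])) {
    sp <- tolower(fields[["space"]])
    orient <- if (grepl("^left-posterior-superior", sp)) "LPS" else "RAS"
  }
  n <- prod(sizes)
  rcon <- con
  if (enc == "gzip") {
    blob <- readBin(con, "raw", n = file.size(path))
    # memDecompress copes with both gzip- and zlib-framed streams
    rcon <- rawConnection(memDecompress(blob, "gzip"))
    on.exit(close(rcon), add = TRUE)
  } else if (enc != "raw") {
    stop("unsupported NRRD encoding: ", enc)
  }
  dat <- switch(type,
    "double" = readBin(rcon, "double", n = n, size = 8, endian = "little"),
    "float" = readBin(rcon, "double", n = n, size = 4, endian = "little"),
    "int" = , "int32" = , "signed int" =
      readBin(rcon, "integer", n = n, size = 4, endian = "little"),
    "short" = , "int16" = , "signed short" =
      readBin(rcon, "integer", n = n, size = 2, endian = "little"),
    "uchar" = , "uint8" = , "unsigned char" =
      readBin(rcon, "integer", n = n, size = 1, signed = FALSE),
    stop("unsupported NRRD type: ", type)
  )
  if (length(dat) < n) stop("truncated NRRD data in ", path)
  dim(dat) <- sizes
  if (orient == "LPS") {
    dat <- dat[sizes[1]:1, sizes[2]:1, , drop = FALSE]
    origin[1:2] <- -(origin[1:2])
    origin[1:2] <- origin[1:2] - spacing[1:2] * (sizes[1:2] - 1)
  }
  list(data = dat, spacing = spacing, origin = origin, orientation = orient,
       keyvals = keyvals)
}

write_nrrd_raw <- function(dat, path, spacing, origin, orientation = "RAS",
                           integer_type = FALSE, keyvals = NULL,
                           gzip = grepl("\\.seg\\.nrrd$", path)) {
  sizes <- dim(dat)
  if (orientation == "LPS") {
    dat <- dat[sizes[1]:1, sizes[2]:1, , drop = FALSE]
    origin[1:2] <- origin[1:2] + spacing[1:2] * (sizes[1:2] - 1)
    origin[1:2] <- -origin[1:2]
  }
  space <- if (orientation == "LPS") "left-posterior-superior"
           else "right-anterior-superior"
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", if (integer_type) "int" else "double"),
    "dimension: 3",
    sprintf("space: %s", space),
    sprintf("sizes: %d %d %d", sizes[1], sizes[2], sizes[3]),
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            spacing[1], spacing[2], spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    sprintf("encoding: %s", if (gzip) "gzip" else "raw"),
    sprintf("space origin: (%.10g,%.10g,%.10g)",
            origin[1], origin[2], origin[3])
  )
  if (!is.null(keyvals)) {
    hdr <- c(hdr, sprintf("%s:=%s", names(keyvals), unname(keyvals)))
  }
  con <- file(path, "wb")
  writeLines(c(hdr, ""), con, sep = "\n")
  payload <- if (integer_type) as.integer(dat) else as.double(dat)
  if (gzip) {
    # a true gzip (RFC 1952) stream, as other NRRD readers expect
    tmp <- tempfile()
    gz <- gzcon(file(tmp, "wb"))
    writeBin(payload, gz, size = if (integer_type) 4L else 8L,
             endian = "little")
    close(gz)
    writeBin(readBin(tmp, "raw", file.size(tmp)), con)
    unlink(tmp)
  } else {
    writeBin(payload, con, size = if (integer_type) 4L else 8L,
             endian = "little")
  }
  close(con)
  invisible(path)
}

# --- resampling and normalization -------------------------------------------

round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Resample a volume to a target voxel spacing
#'
#' Output shape per axis is `round(shape * spacing / target)`
#' (round-half-away-from-zero, minimum 1). Continuous mode uses trilinear
#' interpolation; `nearest` is nearest-neighbour and is mandatory for
#' label volumes, which therefore never gain values absent from the input.
#'
#' @param v A [volume()] or [label_volume()].
#' @param target Numeric length-3 target spacing (mm), all > 0.
#' @param mode `"continuous"` (trilinear) or `"nearest"`. Defaults to
#'   `"nearest"` for label volumes, `"continuous"` for intensity volumes.
#' @return Same type as `v`, on the resampled grid.
#' @export
resample_to_spacing <- function(v, target,
                                mode = if (inherits(v, "oralseg_labelvolume"))
                                  "nearest" else "continuous") {
  target <- as.numeric(target)
  stopifnot(length(target) == 3L, all(target > 0))
  mode <- match.arg(mode, c("continuous", "nearest"))
  is_lab <- inherits(v, "oralseg_labelvolume")
  if (is_lab && mode == "continuous") {
    stop("label volumes must be resampled with mode = \"nearest\"")
  }
  dat <- grid_of(v)
  din <- dim(dat)
  if (all(abs(target - v$spacing) <= 1e-12 * v$spacing)) {
    return(v)  # identity: bit-identical data
  }
  dout <- pmax(1L, as.integer(round_half_away(din * v$spacing / target)))
  # voxel-centre alignment: out index i (0-based) sits at (i+0.5)*t mm
  idx <- lapply(1:3, function(a) {
    (seq_len(dout[a]) - 0.5) * target[a] / v$spacing[a] - 0.5
  })
  if (mode == "nearest") {
    nn <- lapply(1:3, function(a) {
      pmin(pmax(as.integer(round_half_away(idx[[a]])), 0L), din[a] - 1L) + 1L
    })
    out <- dat[nn[[1]], nn[[2]], nn[[3]], drop = FALSE]
    dim(out) <- dout
  } else {
    lo <- lapply(1:3, function(a) pmin(pmax(floor(idx[[a]]), 0), din[a] - 1))
    fr <- lapply(1:3, function(a) {
      f <- idx[[a]] - lo[[a]]
      pmin(pmax(f, 0), 1)
    })
    hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1, din[a] - 1))
    out <- array(0, dout)
    datv <- as.double(dat)
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      ix <- if (cx == 0) lo[[1]] else hi[[1]]
      iy <- if (cy == 0) lo[[2]] else hi[[2]]
      iz <- if (cz == 0) lo[[3]] else hi[[3]]
      wx <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
      wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
      wz <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
      w <- outer(outer(wx, wy), wz)
      i3 <- outer(outer(ix + 1L, iy * din[1], "+"), iz * din[1] * din[2], "+")
      out <- out + w * array(datv[i3], dout)
    }
  }
  if (is_lab) {
    label_volume(out, spacing = target, origin = v$origin,
                 orientation = v$orientation, scheme_ref = v$scheme_ref)
  } else {
    volume(out, spacing = target, origin = v$origin,
           orientation = v$orientation)
  }
}

#' Min-max normalize voxel intensities to [0, 1]
#'
#' Linearly rescales so the minimum maps to 0 and the maximum to 1, the
#' standard CBCT preprocessing before patch sampling. A constant volume
#' normalizes to all zeros (a constant carries no signal). Optional
#' percentile clipping (an extension, off by default) clips to
#' `[p_lo, p_hi]` before rescaling.
#'
#' @param v A [volume()].
#' @param clip If `TRUE`, clip to the `clip_quantiles` before min-max.
#' @param clip_quantiles Length-2 probabilities, default `c(0.005, 0.995)`.
#' @return A [volume()] with values in `[0, 1]`. Idempotent.
#' @export
normalize_intensity <- function(v, clip = FALSE,
                                clip_quantiles = c(0.005, 0.995)) {
  stopifnot(inherits(v, "oralseg_volume"))
  dat <- v$data
  if (clip) {
    q <- stats::quantile(dat, clip_quantiles, names = FALSE)
    dat[dat < q[1]] <- q[1]
    dat[dat > q[2]] <- q[2]
  }
  rng <- range(dat)
  dat <- if (rng[2] > rng[1]) (dat - rng[1]) / (rng[2] - rng[1])
         else array(0, dim(dat))
  volume(dat, spacing = v$spacing, origin = v$origin,
         orientation = v$orientation)
}
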