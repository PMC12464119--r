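#' The 36-structure dental instance label scheme
#'
#' The framework labels 36 foreground structures: the 32 permanent teeth
#' (FDI two-digit numbering, quadrants 1--4, positions 1--8), the maxilla,
#' the mandible, and the left and right mandibular canals. Index 0 is
#' background and never appears as an entry.
#'
#' Internal class indices are fixed: teeth in FDI quadrant order
#' (11..18, 21..28, 31..38, 41..48) occupy indices 1--32, maxilla is 33,
#' mandible 34, left canal 35, right canal 36. "Left" and "right" are in
#' patient coordinates (patient-left is "left"); radiological display
#' mirrors this.
#'
#' @return A `data.frame` of class `oralseg_scheme` with columns
#'   `index`, `name`, `fdi_code` (NA for non-teeth), `color_r`, `color_g`,
#'   `color_b` (0--255) and `semantic_group`
#'   (one of `"tooth"`, `"maxilla"`, `"mandible"`, `"canal"`).
#' @examples
#' sch <- default_scheme()
#' nrow(sch)                      # 36
#' sum(sch$semantic_group == "tooth")  # 32
#' @export
default_scheme <- function() {
  fdi <- c(11:18, 21:28, 31:38, 41:48)
  position_names <- c(
    "central incisor", "lateral incisor", "canine",
    "first premolar", "second premolar",
    "first molar", "second molar", "third molar"
  )
  quadrant_names <- c(
    "upper right", "upper left", "lower left", "lower right"
  )
  tooth_names <- sprintf(
    "Tooth %d (%s %s)", fdi,
    rep(quadrant_names, each = 8L),
    rep(position_names, times = 4L)
  )
  name <- c(tooth_names, "Maxilla", "Mandible",
            "Mandibular canal (left)", "Mandibular canal (right)")
  group <- c(rep("tooth", 32L), "maxilla", "mandible", "canal", "canal")

  # deterministic, well-spread colour table (golden-angle hue walk)
  h <- (0.12 + 0.381966 * (0:35)) %% 1
  s <- rep(c(0.62, 0.78), length.out = 36L)
  v <- rep(c(0.95, 0.80, 0.88), length.out = 36L)
  col <- grDevices::hsv(h, s, v)
  rgb <- t(grDevices::col2rgb(col))

  out <- data.frame(
    index = 1:36,
    name = name,
    fdi_code = c(fdi, rep(NA_integer_, 4L)),
    color_r = as.integer(rgb[, 1]),
    color_g = as.integer(rgb[, 2]),
    color_b = as.integer(rgb[, 3]),
    semantic_group = group,
    stringsAsFactors = FALSE
  )
  class(out) <- c("oralseg_scheme", "data.frame")
  out
}

#' Map an FDI tooth code to its internal class index
#'
#' @param fdi Integer vector of FDI codes (11--18, 21--28, 31--38, 41--48).
#' @return Integer vector of class indices in 1--32.
#' @examples
#' fdi_to_index(11)  # 1
#' fdi_to_index(48)  # 32
#' @export
fdi_to_index <- function(fdi) {
  fdi <- as.integer(fdi)
  q <- fdi %/% 10L
  p <- fdi %% 10L
  bad <- is.na(fdi) | q < 1L | q > 4L | p < 1L | p > 8L
  if (any(bad)) {
    stop("not a permanent-dentition FDI code: ",
         paste(fdi[bad], collapse = ", "))
  }
  (q - 1L) * 8L + p
}

#' Map an internal tooth class index back to its FDI code
#'
#' @param index Integer vector of class indices in 1--32.
#' @return Integer vector of FDI codes.
#' @export
index_to_fdi <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index) | index < 1L | index > 32L)) {
    stop("tooth class indices must lie in 1..32")
  }
  q <- (index - 1L) %/% 8L + 1L
  p <- (index - 1L) %% 8L + 1L
  q * 10L + p
}

semantic_codes <- c(background = 0L, tooth = 1L, maxilla = 2L,
                    mandible = 3L, canal = 4L)

#' Merge instance labels into semantic tissue classes
#'
#' Collapses the 36 instance classes into 4 semantic classes:
#' 1 = teeth (all 32 tooth instances), 2 = maxilla, 3 = mandible,
#' 4 = mandibular canals. Background stays 0. The merge is a pure
#' voxelwise relabelling, so total foreground volume is conserved.
#'
#' @param lv A [label_volume()].
#' @return A `label_volume` with values in 0--4 and
#'   `scheme_ref = "oralseg-semantic-v1"`.
#' @export
merge_to_semantic <- function(lv) {
  stopifnot(inherits(lv, "oralseg_labelvolume"))
  sch <- default_scheme()
  lut <- c(0L, semantic_codes[sch$semantic_group])  # position i+1 = class i
  vals <- as.integer(lv$labels)
  bad <- vals < 0L | vals > 36L
  if (any(bad)) {
    stop("unknown label value(s): ",
         paste(unique(vals[bad]), collapse = ", "))
  }
  merged <- lut[vals + 1L]
  dim(merged) <- dim(lv$labels)
  label_volume(merged, spacing = lv$spacing, origin = lv$origin,
               orientation = lv$orientation,
               scheme_ref = "oralseg-semantic-v1")
}

#' Serialize a label scheme to JSON
#'
#' Writes the scheme (index, name, FDI code, RGB colour, semantic group)
#' as a JSON array, the format embedded alongside every segmentation the
#' package writes.
#'
#' @param scheme A scheme from [default_scheme()].
#' @param path Output file path; if `NULL`, the JSON string is returned.
#' @export
write_scheme_json <- function(scheme = default_scheme(), path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(scheme), dataframe = "rows",
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Export the scheme as a viewer colour table
#'
#' Plain-text colour table (`index name R G B A`) understood by common
#' segmentation viewers.
#'
#' @param scheme A scheme from [default_scheme()].
#' @param path Output file path.
#' @export
write_color_table <- function(scheme = default_scheme(), path) {
  lines <- sprintf("%d %s %d %d %d 255",
                   scheme$index, gsub("[[:space:]]+", "_", scheme$name),
                   scheme$color_r, scheme$color_g, scheme$color_b)
  writeLines(c("0 Background 0 0 0 0", lines), path)
  invisible(path)
}
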