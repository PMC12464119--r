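#' @title Inter-annotator agreement
#' @description Per-label Dice between two raters' label maps, and the
#'   intraclass correlation coefficient used for annotation calibration.
#' @name agreement
NULL

#' Per-label Dice between two raters
#'
#' Classes empty in both maps are skipped (no voxel evidence).
#'
#' @param lv_a,lv_b [label_volume()]s from the two raters, same grid.
#' @param scheme Label scheme (default [default_scheme()]).
#' @return Named numeric vector of Dice values, names are class indices.
#' @export
pairwise_label_dsc <- function(lv_a, lv_b, scheme = default_scheme()) {
  check_same_grid(lv_a, lv_b)
  K <- max(scheme$index)
  M <- joint_confusion(lv_a$labels, lv_b$labels, K)
  na <- rowSums(M)[-1]
  nb <- colSums(M)[-1]
  inter <- diag(M)[-1]
  keep <- na + nb > 0
  dsc <- 2 * inter[keep] / (na + nb)[keep]
  stats::setNames(dsc, scheme$index[keep])
}

#' Per-label structure volumes in mm^3
#'
#' The measurement fed to the ICC: voxel count times voxel volume for
#' each foreground class.
#'
#' @param lv A [label_volume()].
#' @param scheme Label scheme.
#' @return Named numeric vector (mm^3) over all scheme classes.
#' @export
label_volumes_mm3 <- function(lv, scheme = default_scheme()) {
  K <- max(scheme$index)
  n <- tabulate(as.integer(lv$labels), nbins = K)
  stats::setNames(n * prod(lv$spacing), scheme$index)
}

#' Intraclass correlation coefficient, two-way random, absolute
#' agreement, single measures (ICC(2,1))
#'
#' Computed from the standard two-way ANOVA mean-squares decomposition:
#' with `n` targets (rows) and `k` raters (columns),
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' The mean squares are returned for auditability.
#'
#' @param table Numeric matrix: rows = targets (>= 2), columns = raters
#'   (>= 2), no missing cells.
#' @param form Only `"ICC2_1"` is implemented.
#' @return List with `estimate`, `components` (`MSR`, `MSC`, `MSE`, `n`,
#'   `k`) and `form`.
#' @export
icc <- function(table, form = "ICC2_1") {
  form <- match.arg(form)
  table <- as.matrix(table)
  if (anyNA(table)) stop("ratings table has missing cells")
  n <- nrow(table); k <- ncol(table)
  if (n < 2L) stop("ICC needs at least 2 targets")
  if (k < 2L) stop("ICC needs at least 2 raters")
  grand <- mean(table)
  rowm <- rowMeans(table)
  colm <- colMeans(table)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((table - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  est <- if (denom == 0) 1 else (msr - mse) / denom
  list(estimate = est,
       components = list(MSR = msr, MSC = msc, MSE = mse, n = n, k = k),
       form = form)
}

#' Build a ratings table from two raters' label volumes
#'
#' Rows are case x label targets (labels non-empty for at least one
#' rater), columns are raters; cells are structure volumes in mm^3.
#'
#' @param raters List of >= 2 lists of [label_volume()]s (one inner list
#'   per rater, cases aligned).
#' @param scheme Label scheme.
#' @return Numeric matrix suitable for [icc()].
#' @export
ratings_table <- function(raters, scheme = default_scheme()) {
  stopifnot(length(raters) >= 2L)
  ncase <- length(raters[[1]])
  stopifnot(all(vapply(raters, length, 1L) == ncase))
  rows <- list()
  for (ci in seq_len(ncase)) {
    vols <- sapply(raters, function(r) label_volumes_mm3(r[[ci]], scheme))
    keep <- rowSums(vols) > 0
    if (any(keep)) {
      m <- vols[keep, , drop = FALSE]
      rownames(m) <- sprintf("case%d_label%s", ci, rownames(m))
      rows[[length(rows) + 1L]] <- m
    }
  }
  out <- do.call(rbind, rows)
  colnames(out) <- sprintf("rater%d", seq_along(raters))
  out
}
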