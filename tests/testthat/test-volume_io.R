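test_that("NIfTI round-trip preserves data, spacing and labels", {
  set.seed(1)
  v <- volume(array(rnorm(6 * 5 * 4), c(6, 5, 4)), spacing = c(0.3, 0.3, 0.3),
              origin = c(1, 2, 3))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$data, v$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(v2$spacing, c(0.3, 0.3, 0.3), tolerance = 1e-6)
  expect_equal(v2$origin, c(1, 2, 3), tolerance = 1e-5)

  lab <- label_volume(array(sample(0:3, 60, TRUE), c(5, 4, 3)),
                      spacing = c(0.5, 0.5, 0.5))
  fl <- tempfile(fileext = ".nii")
  write_volume(lab, fl)
  l2 <- read_volume(fl, labels = TRUE)
  expect_identical(as.integer(l2$labels), as.integer(lab$labels))
  expect_true(file.exists(sub("\\.nii$", ".labels.json", fl)))
})

test_that("NRRD round-trip preserves data and embeds the label table", {
  set.seed(2)
  v <- volume(array(rnorm(24), c(4, 3, 2)), spacing = c(0.25, 0.5, 1))
  f <- tempfile(fileext = ".nrrd")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$data, v$data, ignore_attr = TRUE)
  expect_equal(v2$spacing, v$spacing)

  lab <- label_volume(array(sample(c(0L, 3L, 7L), 60, TRUE), c(5, 4, 3)))
  fl <- tempfile(fileext = ".seg.nrrd")
  write_volume(lab, fl)
  l2 <- read_volume(fl, labels = TRUE)
  expect_identical(as.integer(l2$labels), as.integer(lab$labels))
  hdr <- suppressWarnings(readLines(fl, n = 20, warn = FALSE))
  expect_true(any(grepl("oralseg_label_table", hdr, useBytes = TRUE)))
})

test_that("LPS volumes reorient to RAS in memory and restore on write", {
  set.seed(3)
  v <- volume(array(rnorm(60), c(5, 4, 3)), spacing = c(0.4, 0.4, 0.4),
              origin = c(0, 0, 0), orientation = "LPS")
  for (ext in c(".nii", ".nrrd")) {
    f <- tempfile(fileext = ext)
    write_volume(v, f)
    v2 <- read_volume(f)
    expect_equal(v2$orientation, "LPS")
    expect_equal(v2$data, v$data, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("malformed files raise format errors naming the problem", {
  f <- tempfile(fileext = ".nii")
  img <- RNifti::asNifti(array(1:10, c(5, 2)))  # 2D
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "dimensionality")

  ft <- tempfile(fileext = ".nrrd")
  writeLines(c("NRRD0004", "type: double", "dimension: 3", "sizes: 4 4 4",
               "encoding: raw", ""), ft)
  expect_error(read_volume(ft), "truncated")

  expect_error(read_volume(tempfile(fileext = ".nii")), "no such file")
  expect_error(volume(array(1, c(2, 2))), "3D")
})

test_that("resampling follows the round-half-away shape rule", {
  # clinical grid 440x440x344 at 0.3 mm -> 0.6 mm gives 220x220x172
  expect_identical(
    as.integer(oralseg:::round_half_away(c(440, 440, 344) * 0.3 / 0.6)),
    c(220L, 220L, 172L))
  # same ratios exercised on a real (smaller) grid
  set.seed(4)
  v <- volume(array(rnorm(44 * 44 * 34), c(44, 44, 34)), spacing = rep(0.3, 3))
  r <- resample_to_spacing(v, rep(0.6, 3))
  expect_identical(dim(r$data), c(22L, 22L, 17L))
  # round-half-away: 5 voxels at 0.3 -> 0.2 is 7.5 -> 8
  v5 <- volume(array(1.0, c(5, 5, 5)), spacing = rep(0.3, 3))
  expect_identical(dim(resample_to_spacing(v5, rep(0.2, 3))$data),
                   c(8L, 8L, 8L))
})

test_that("resampling identities and label closure hold", {
  set.seed(5)
  v <- volume(array(rnorm(20^3), c(20, 20, 20)), spacing = rep(0.5, 3))
  expect_identical(resample_to_spacing(v, rep(0.5, 3))$data, v$data)

  lab <- label_volume(array(sample(c(0L, 3L), 8000, TRUE, c(.8, .2)),
                            c(20, 20, 20)), spacing = rep(0.5, 3))
  r <- resample_to_spacing(lab, rep(0.35, 3))
  expect_true(all(unique(as.integer(r$labels)) %in% c(0L, 3L)))
  expect_error(resample_to_spacing(lab, rep(0.35, 3), mode = "continuous"),
               "nearest")

  # down-up round trip returns to within one voxel per axis
  r2 <- resample_to_spacing(resample_to_spacing(v, rep(1, 3)), rep(0.5, 3))
  expect_true(all(abs(dim(r2$data) - dim(v$data)) <= 1))
})

test_that("intensity normalization is min-max, degenerate-safe, idempotent", {
  v <- volume(array(c(100, 150, 200, 150, 100, 200), c(3, 2, 1)))
  n <- normalize_intensity(v)
  expect_equal(sort(unique(as.vector(n$data))), c(0, 0.5, 1))

  const <- normalize_intensity(volume(array(7, c(3, 3, 3))))
  expect_true(all(const$data == 0))

  n2 <- normalize_intensity(n)
  expect_equal(n2$data, n$data)

  # clipping flag caps the range before rescale
  set.seed(6)
  x <- array(rnorm(1000), c(10, 10, 10)); x[1] <- 100
  nc <- normalize_intensity(volume(x), clip = TRUE)
  expect_true(all(nc$data >= 0 & nc$data <= 1))
})
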