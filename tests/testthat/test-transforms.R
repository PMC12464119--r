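make_pair <- function(dims = c(20, 20, 12), seed = 1) {
  set.seed(seed)
  list(v = volume(array(rnorm(prod(dims)), dims)),
       lv = label_volume(array(sample(0:4, prod(dims), TRUE), dims)))
}

test_that("a certain flip applied twice is the identity on both members", {
  p <- make_pair()
  cfg <- augment_config(flip_prob = c(1, 0, 0), rotate90_prob = c(0, 0, 0),
                        intensity_scale_range = c(1, 1),
                        intensity_shift_range = c(0, 0))
  a1 <- augment_pair(p$v, p$lv, cfg, seed = 5)
  a2 <- augment_pair(a1$volume, a1$labels, cfg, seed = 6)
  expect_equal(a2$volume$data, p$v$data)
  expect_identical(a2$labels$labels, p$lv$labels)
  # the single application actually flipped
  expect_false(isTRUE(all.equal(a1$volume$data, p$v$data)))
})

test_that("intensity transforms are affine on constants and spare labels", {
  dims <- c(8, 8, 8)
  v <- volume(array(3, dims))
  lv <- label_volume(array(sample(0:2, prod(dims), TRUE), dims))
  cfg <- augment_config(flip_prob = c(0, 0, 0), rotate90_prob = c(0, 0, 0),
                        intensity_scale_range = c(1.25, 1.25),
                        intensity_shift_range = c(0.5, 0.5))
  a <- augment_pair(v, lv, cfg, seed = 1)
  expect_equal(unique(as.vector(a$volume$data)), 3 * 1.25 + 0.5)
  expect_identical(a$labels$labels, lv$labels)
})

test_that("spatial augmentation preserves the label value set", {
  p <- make_pair(c(16, 16, 16), seed = 3)
  cfg <- augment_config(flip_prob = c(.5, .5, .5), rotate90_prob = c(.5, .5, .5))
  for (s in 1:10) {
    a <- augment_pair(p$v, p$lv, cfg, seed = s)
    expect_setequal(unique(as.integer(a$labels$labels)),
                    unique(as.integer(p$lv$labels)))
    expect_identical(sort(as.vector(a$labels$labels)),
                     sort(as.vector(p$lv$labels)))
  }
})

test_that("augmentation is deterministic given a seed and applies the same
           spatial map to image and labels", {
  p <- make_pair(c(12, 12, 12), seed = 4)
  cfg <- augment_config()
  a1 <- augment_pair(p$v, p$lv, cfg, seed = 11)
  a2 <- augment_pair(p$v, p$lv, cfg, seed = 11)
  expect_identical(a1$volume$data, a2$volume$data)
  expect_identical(a1$labels$labels, a2$labels$labels)
  # recompute the logged flips independently and compare the label map
  applied <- attr(a1, "applied")
  lab <- p$lv$labels
  for (ax in 1:3) {
    if (paste0("flip", ax) %in% applied) lab <- oralseg:::flip_axis(lab, ax)
  }
  if ("rot90_12" %in% applied) lab <- oralseg:::rot90_plane(lab, c(1L, 2L))
  expect_identical(a1$labels$labels, lab)
})

test_that("patch sampling returns exact aligned crops and pads small inputs", {
  p <- make_pair(c(40, 36, 33), seed = 5)
  s <- sample_patch(p$v, p$lv, patch = c(32, 32, 32), seed = 2)
  expect_identical(dim(s$volume$data), c(32L, 32L, 32L))
  expect_identical(dim(s$labels$labels), c(32L, 32L, 32L))
  # aligned: the image crop matches the label crop location
  o <- s$origin
  expect_equal(s$volume$data,
               p$v$data[o[1] + 1:32, o[2] + 1:32, o[3] + 1:32])
  # grid exactly the patch: identity crop
  q <- make_pair(c(32, 32, 32), seed = 6)
  sq <- sample_patch(q$v, q$lv, patch = c(32, 32, 32), seed = 9)
  expect_identical(sq$volume$data, q$v$data)
  expect_identical(sq$origin, c(0L, 0L, 0L))
  # smaller grid is padded with background
  r <- make_pair(c(20, 20, 20), seed = 7)
  sr <- sample_patch(r$v, r$lv, patch = c(32, 32, 32), seed = 1)
  expect_identical(dim(sr$labels$labels), c(32L, 32L, 32L))
  expect_identical(sort(unique(as.integer(sr$labels$labels))),
                   sort(unique(c(0L, as.integer(r$lv$labels)))))
})

test_that("crop origins are uniform over the valid positions", {
  p <- make_pair(c(96, 40, 40), seed = 8)
  draws <- vapply(1:800, function(s) {
    sample_patch(p$v, p$lv, patch = c(64, 32, 32), seed = s)$origin[1]
  }, integer(1))
  # origin axis 1 ranges over {0..32}
  expect_true(all(draws >= 0 & draws <= 32))
  tab <- tabulate(draws + 1L, nbins = 33L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})
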