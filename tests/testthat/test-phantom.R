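test_that("a full-dentition phantom paints all 36 structures exactly once", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(96L, 96L, 64L),
                                      spacing_mm = 0.35, seed = 5))
  cnt <- tabulate(as.integer(ph$labels$labels), nbins = 36)
  expect_true(all(cnt > 0))
  expect_setequal(unique(as.integer(ph$labels$labels)), 0:36)
  expect_identical(dim(ph$volume$data), dim(ph$labels$labels))
  # bone intensity exceeds background by construction
  expect_gt(mean(ph$volume$data[ph$labels$labels %in% 33:34]),
            mean(ph$volume$data[ph$labels$labels == 0L]) + 50)
  # canals sit inside the mandible's z-slab bounding region
  canal_mask <- ph$labels$labels %in% 35:36
  dim(canal_mask) <- dim(ph$labels$labels)
  zc <- which(canal_mask, arr.ind = TRUE)[, 3]
  zm <- range(which(apply(ph$labels$labels == 34L, 3, any)))
  expect_true(all(zc >= zm[1] & zc <= zm[2]))
})

test_that("missing teeth leave their labels empty and generation is seeded", {
  present <- stats::setNames(rep(TRUE, 32), as.character(index_to_fdi(1:32)))
  present["18"] <- FALSE
  sp <- phantom_spec(grid_shape = c(96L, 96L, 64L), spacing_mm = 0.35,
                     teeth_present = present, seed = 9)
  ph <- generate_phantom(sp)
  expect_false(fdi_to_index(18) %in% ph$labels$labels)
  ph2 <- generate_phantom(sp)
  expect_identical(ph$volume$data, ph2$volume$data)
  expect_identical(ph$labels$labels, ph2$labels$labels)
})

test_that("each tooth is a single 6-connected component", {
  ph <- small_phantom()
  lab <- ph$labels$labels
  for (k in sort(setdiff(unique(as.integer(lab)), c(0L, 33:36)))) {
    comp <- oralseg:::label_components6(lab == k)
    expect_equal(max(comp), 1L, info = paste("tooth class", k))
  }
})

test_that("artifact toggles change the image but not the labels", {
  base <- small_phantom_spec(77)
  streak <- small_phantom_spec(77, artifacts = list(metal_streak = TRUE,
                                                    streak_fdi = 16L))
  blur <- small_phantom_spec(77, artifacts = list(motion_blur_sigma = 0.9))
  p0 <- generate_phantom(base)
  p1 <- generate_phantom(streak)
  p2 <- generate_phantom(blur)
  expect_identical(p1$labels$labels, p0$labels$labels)
  expect_identical(p2$labels$labels, p0$labels$labels)
  expect_gt(max(p1$volume$data), max(p0$volume$data) + 50)
  expect_lt(stats::sd(p2$volume$data), stats::sd(p0$volume$data))
})

test_that("cohort absence rate matches its binomial expectation", {
  n <- 50
  rate <- 0.25
  co <- generate_cohort(n, missing_rate = rate, seed = 12,
                        spec_fn = function(seed, teeth_present) {
                          small_phantom_spec(seed)  # geometry fixed & small
                        })
  # absence draws are independent of the (fixed) geometry spec
  miss <- vapply(co, function(ph) length(ph$absent_fdi), numeric(1))
  mu <- 32 * rate
  sdev <- sqrt(32 * rate * (1 - rate))
  expect_lt(abs(mean(miss) - mu), 3 * sdev / sqrt(n))
  # rate 0: all 36 labels present
  co0 <- generate_cohort(2, 0, seed = 3, spec_fn = function(seed, teeth_present)
    phantom_spec(grid_shape = c(96L, 96L, 64L), spacing_mm = 0.35,
                 teeth_present = teeth_present, seed = seed))
  for (ph in co0) {
    expect_equal(sum(tabulate(as.integer(ph$labels$labels), 36) > 0), 36L)
  }
})

test_that("rate-1 cohorts contain jaws and canals only", {
  co <- generate_cohort(1, 1, seed = 4, spec_fn = function(seed, teeth_present)
    small_phantom_spec(seed, teeth = integer(0)))
  vals <- sort(unique(as.integer(co[[1]]$labels$labels)))
  expect_identical(vals, c(0L, 33L, 34L, 35L, 36L))
})

test_that("annotation perturbation flips only boundary voxels, monotonically", {
  ph <- small_phantom()
  lv <- ph$labels
  expect_identical(perturb_annotation(lv, 0, seed = 1)$labels, lv$labels)
  mean_dsc <- function(p) mean(pairwise_label_dsc(lv,
    perturb_annotation(lv, p, seed = 8)))
  d <- vapply(c(0, 0.25, 0.5), mean_dsc, numeric(1))
  expect_identical(d[1], 1)
  expect_true(d[1] > d[2] && d[2] > d[3])
  # interior voxels untouched: differences only on label boundaries
  pert <- perturb_annotation(lv, 1, seed = 2)
  changed <- which(pert$labels != lv$labels)
  lab <- lv$labels
  d3 <- dim(lab)
  on_boundary <- vapply(changed[seq_len(min(200, length(changed)))],
    function(i) {
      ix <- arrayInd(i, d3)
      nb <- c(
        if (ix[1] > 1) lab[ix[1] - 1, ix[2], ix[3]],
        if (ix[1] < d3[1]) lab[ix[1] + 1, ix[2], ix[3]],
        if (ix[2] > 1) lab[ix[1], ix[2] - 1, ix[3]],
        if (ix[2] < d3[2]) lab[ix[1], ix[2] + 1, ix[3]],
        if (ix[3] > 1) lab[ix[1], ix[2], ix[3] - 1],
        if (ix[3] < d3[3]) lab[ix[1], ix[2], ix[3] + 1])
      any(nb != lab[ix[1], ix[2], ix[3]])
    }, logical(1))
  expect_true(all(on_boundary))
})
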