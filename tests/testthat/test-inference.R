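test_that("label decoding is argmax with low-index tie-breaking", {
  set.seed(61)
  K <- 6; dims <- c(4, 4, 4)
  sc <- array(stats::runif(K * prod(dims)), c(K, dims))
  lab <- decode_labels(sc)$labels
  # brute-force per-voxel argmax
  ref <- apply(array(sc, c(K, prod(dims))), 2, which.max) - 1L
  expect_identical(as.integer(lab), as.integer(ref))
  # one-hot scores recover exactly
  tgt <- array(sample(0:(K - 1), prod(dims), TRUE), dims)
  oh <- array(0, c(K, dims))
  for (i in seq_len(prod(dims))) oh[tgt[i] + 1 + (i - 1) * K] <- 1
  expect_identical(decode_labels(oh)$labels, tgt, ignore_attr = TRUE)
  # all-equal scores: background wins the tie
  expect_true(all(decode_labels(array(0.5, c(K, dims)))$labels == 0L))
})

test_that("blending weights form a partition of unity, borders included", {
  ns <- asNamespace("oralseg")
  for (blend in c("gaussian", "constant")) {
    win <- c(16L, 16L, 16L)
    d <- c(37L, 23L, 16L)  # deliberately uneven, forces irregular tiling
    starts <- lapply(1:3, function(a) ns$window_starts(d[a], win[a], 0.5))
    w <- ns$blend_weights(win, blend)
    den <- array(0, d)
    for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
      den[sx + 1:16, sy + 1:16, sz + 1:16] <-
        den[sx + 1:16, sy + 1:16, sz + 1:16] + w
    }
    expect_true(all(den > 0))
    # normalized per-window weights sum to exactly 1 at every voxel
    norm_sum <- array(0, d)
    for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
      norm_sum[sx + 1:16, sy + 1:16, sz + 1:16] <-
        norm_sum[sx + 1:16, sy + 1:16, sz + 1:16] +
        w / den[sx + 1:16, sy + 1:16, sz + 1:16]
    }
    expect_equal(max(abs(norm_sum - 1)), 0, tolerance = 1e-12)
  }
})

test_that("one-window tiling equals a single forward pass bitwise", {
  m <- build_model(reduced_config(), init_seed = 31)
  set.seed(62)
  v <- volume(array(stats::runif(32^3, 0, 400), c(32, 32, 32)),
              spacing = rep(0.45, 3))
  cfg <- inference_config(window = c(32L, 32L, 32L), overlap = 0,
                          blend = "constant", target_spacing = rep(0.45, 3))
  pred <- predict_volume(v, m, cfg, return_probs = TRUE)
  direct <- model_forward(m, normalize_intensity(v)$data)
  expect_identical(attr(pred, "probs"), array(direct, dim(direct)[-1]))
  expect_identical(pred$labels,
                   decode_labels(direct, spacing = v$spacing)$labels)
})

test_that("inference is deterministic and respects the input grid", {
  m <- build_model(reduced_config(), init_seed = 31)
  set.seed(63)
  v <- volume(array(stats::runif(40 * 36 * 33, 0, 300), c(40, 36, 33)),
              spacing = rep(0.45, 3))
  cfg <- inference_config(window = c(32L, 32L, 32L), overlap = 0.25,
                          target_spacing = rep(0.45, 3))
  p1 <- predict_volume(v, m, cfg)
  p2 <- predict_volume(v, m, cfg)
  expect_identical(p1$labels, p2$labels)
  expect_identical(dim(p1$labels), dim(v$data))
})

test_that("off-spacing input is resampled in and restored to its own grid", {
  m <- build_model(reduced_config(), init_seed = 31)
  set.seed(64)
  v06 <- volume(array(stats::runif(16^3, 0, 300), c(16, 16, 16)),
                spacing = rep(0.9, 3))
  cfg <- inference_config(window = c(32L, 32L, 32L), overlap = 0,
                          target_spacing = rep(0.45, 3))
  pred <- predict_volume(v06, m, cfg, return_probs = TRUE)
  expect_identical(dim(pred$labels), c(16L, 16L, 16L))
  expect_identical(pred$spacing, v06$spacing)
  # the internal grid ran at the model's spacing
  expect_identical(dim(attr(pred, "probs"))[-1], c(32L, 32L, 32L))
})

test_that("ROI restricts computation and out-of-bounds boxes error", {
  m <- build_model(reduced_config(), init_seed = 31)
  set.seed(65)
  v <- volume(array(stats::runif(48 * 40 * 36, 0, 300), c(48, 40, 36)),
              spacing = rep(0.45, 3))
  cfg <- inference_config(roi = c(9, 5, 3, 40, 36, 34),
                          window = c(32L, 32L, 32L), overlap = 0,
                          target_spacing = rep(0.45, 3))
  pred <- predict_volume(v, m, cfg)
  expect_identical(dim(pred$labels), dim(v$data))
  outside <- pred$labels[c(1:8), , ]
  expect_true(all(outside == 0L))
  bad <- inference_config(roi = c(0, 1, 1, 20, 20, 20),
                          window = c(32L, 32L, 32L))
  expect_error(predict_volume(v, m, bad), "ROI")
})

test_that("semantic output equals the semantic merge of instance output", {
  m <- build_model(reduced_config(), init_seed = 31)
  set.seed(66)
  v <- volume(array(stats::runif(32^3, 0, 300), c(32, 32, 32)),
              spacing = rep(0.45, 3))
  ci <- inference_config(window = c(32L, 32L, 32L), overlap = 0,
                         target_spacing = rep(0.45, 3))
  cs <- inference_config(window = c(32L, 32L, 32L), overlap = 0,
                         target_spacing = rep(0.45, 3),
                         output_mode = "semantic")
  inst <- predict_volume(v, m, ci)
  sem <- predict_volume(v, m, cs)
  expect_identical(sem$labels, merge_to_semantic(inst)$labels)
  expect_lte(length(unique(as.integer(sem$labels))), 5L)
})
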