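test_that("reduced-config forward produces a normalized 37-class map", {
  m <- build_model(reduced_config(), init_seed = 7)
  set.seed(1)
  x <- array(stats::runif(32^3), c(32, 32, 32))
  p <- model_forward(m, x)
  expect_identical(dim(p), c(1L, 37L, 32L, 32L, 32L))
  expect_true(all(p >= 0 & p <= 1))
  sums <- apply(array(p, dim(p)[-1]), 2:4, sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-10)
  # evaluation-mode determinism
  expect_identical(p, model_forward(m, x))
  # 5D input form is accepted
  expect_identical(model_forward(m, array(x, c(1, 1, dim(x)))), p)
})

test_that("construction is deterministic given the init seed", {
  m1 <- build_model(reduced_config(), init_seed = 3)
  m2 <- build_model(reduced_config(), init_seed = 3)
  m3 <- build_model(reduced_config(), init_seed = 4)
  expect_identical(lapply(m1$params, function(p) p$v),
                   lapply(m2$params, function(p) p$v))
  expect_false(identical(m1$params[[1]]$v, m3$params[[1]]$v))
})

test_that("encoder pyramid halves resolution per stage", {
  m <- build_model(reduced_config(), init_seed = 7)
  set.seed(2)
  pyr <- swin_encode(m, array(stats::runif(32^3), c(32, 32, 32)))
  shapes <- lapply(pyr, dim)
  expect_equal(shapes[[1]], c(24L, 16L, 16L, 16L))
  expect_equal(shapes[[2]], c(48L, 8L, 8L, 8L))
  expect_equal(shapes[[3]], c(96L, 4L, 4L, 4L))
  expect_equal(shapes[[4]], c(192L, 2L, 2L, 2L))
})

test_that("non-divisible input dims raise a config error naming the axis", {
  m <- build_model(reduced_config(), init_seed = 7)
  expect_error(model_forward(m, array(0, c(48, 32, 32))), "48")
})

test_that("ablations remove branches and the parameter census adds up", {
  cf <- function(ab) reduced_config(ablation = ab)
  mf <- build_model(cf("full"), 7)
  ms <- build_model(cf("swin_only"), 7)
  mm <- build_model(cf("smamba_only"), 7)
  expect_lt(ms$n_parameters, mf$n_parameters)
  expect_lt(mm$n_parameters, mf$n_parameters)
  cen <- parameter_census(mf)
  expect_equal(sum(cen$parameters), mf$n_parameters)
  # full = swin_only + smamba blocks + widened fusion projections
  smamba_params <- sum(cen$parameters[grepl("smamba", cen$group)])
  fuse_full <- sum(cen$parameters[grepl("fuse", cen$group)])
  cen_s <- parameter_census(ms)
  fuse_swin <- sum(cen_s$parameters[grepl("fuse", cen_s$group)])
  expect_equal(mf$n_parameters,
               ms$n_parameters + smamba_params + (fuse_full - fuse_swin))
})

test_that("constant input yields spatially constant attention features", {
  m <- build_model(reduced_config(ablation = "swin_only",
                                  attention_window = c(4L, 4L, 4L)),
                   init_seed = 5)
  pyr <- swin_encode(m, array(0.5, c(32, 32, 32)))
  for (s in seq_along(pyr)) {
    spatial_sd <- apply(pyr[[s]], 1, stats::sd)
    expect_lt(max(spatial_sd), 1e-9)
  }
})

test_that("state-space block preserves shape and reduces to the conv path
           when its scan projection is gated shut", {
  m <- build_model(reduced_config(), init_seed = 9)
  set.seed(3)
  x <- array(rnorm(24 * 8 * 8 * 8), c(24, 8, 8, 8))
  y <- smamba_block(m, x, stage = 1)
  expect_identical(dim(y), dim(x))
  # close the gate: zero the scan projection
  blk <- m$enc[[1]]$smamba
  oldW <- blk$proj$W$v; oldb <- blk$proj$b$v
  blk$proj$W$v[] <- 0; blk$proj$b$v[] <- 0
  y0 <- smamba_block(m, x, stage = 1)
  blk$proj$W$v <- oldW; blk$proj$b$v <- oldb
  # conv-only oracle computed independently from the block's parts
  ns <- asNamespace("oralseg")
  conv_ref <- ns$no_grad({
    h <- ns$ag_leaky_relu(ns$ag_add(
      ns$apply_in(ns$apply_conv(ns$ag_const(x), blk$conv1), blk$in1),
      ns$apply_in(ns$apply_conv(ns$ag_const(x), blk$conv3), blk$in3)))
    ns$ag_value(h)
  })
  expect_equal(y0, conv_ref, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(y, y0)))
})

test_that("the tied tri-axial scan commutes with axis transposition", {
  ns <- asNamespace("oralseg")
  m <- build_model(reduced_config(), init_seed = 13)
  blk <- m$enc[[1]]$smamba
  set.seed(4)
  h <- array(rnorm(24 * 6 * 6 * 6), c(24, 6, 6, 6))
  scan_sum <- function(harr) {
    ns$no_grad({
      hn <- ns$ag_const(harr)
      delta <- ns$ag_softplus(ns$apply_conv(hn, blk$delta))
      Bm <- ns$apply_conv(hn, blk$Bproj)
      Cm <- ns$apply_conv(hn, blk$Cproj)
      ssum <- NULL
      for (perm in list(c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))) {
        hp <- ns$ag_permute_grid(hn, perm)
        y <- ns$ag_sscan(
          ns$ag_grid_to_seq(hp),
          ns$ag_grid_to_seq(ns$ag_permute_grid(delta, perm)),
          ns$ag_grid_to_seq(ns$ag_permute_grid(Bm, perm)),
          ns$ag_grid_to_seq(ns$ag_permute_grid(Cm, perm)),
          blk$Alog, blk$Dskip)
        yg <- ns$ag_permute_grid(ns$ag_seq_to_grid(y, dim(ns$ag_value(hp))),
                                 order(perm))
        ssum <- if (is.null(ssum)) yg else ns$ag_add(ssum, yg)
      }
      ns$ag_value(ssum)
    })
  }
  # transpose axes (x,y,z) -> (y,z,x); parameters are tied across axes,
  # and the sum over scan directions is permutation-equivariant
  perm <- c(2L, 3L, 1L)
  a <- scan_sum(aperm(h, c(1L, perm + 1L)))
  b <- aperm(scan_sum(h), c(1L, perm + 1L))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("checkpoints round-trip weights, config and label scheme", {
  m <- build_model(reduced_config(), init_seed = 21)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f, extra = list(note = 1L))
  m2 <- load_checkpoint(f)
  expect_identical(lapply(m2$params, function(p) p$v),
                   lapply(m$params, function(p) p$v))
  expect_equal(attr(m2, "extra")$note, 1L)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$config$embed_size, 24)
  expect_equal(length(side$scheme), 36)
  set.seed(5)
  x <- array(stats::runif(32^3), c(32, 32, 32))
  expect_identical(model_forward(m, x), model_forward(m2, x))
})
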