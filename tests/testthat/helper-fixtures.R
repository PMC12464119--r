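# Shared fixtures and independent oracles, built in code at test time.

# small random label volume pair on a common grid
random_label_pair <- function(dims, K, seed) {
  set.seed(seed)
  list(
    pred = label_volume(array(sample(0:K, prod(dims), TRUE), dims)),
    gt = label_volume(array(sample(0:K, prod(dims), TRUE), dims))
  )
}

# independent brute-force metric oracle: per-voxel enumeration straight
# from the one-vs-rest definitions, no shared code with the implementation
oracle_class_metrics <- function(pred, gt, k) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == k
    g <- gt[i] == k
    if (p && g) tp <- tp + 1
    else if (p && !g) fp <- fp + 1
    else if (!p && g) fn <- fn + 1
    else tn <- tn + 1
  }
  total <- tp + fp + fn + tn
  c(dice = if (2 * tp + fp + fn == 0) NaN else 2 * tp / (2 * tp + fp + fn),
    iou = if (tp + fp + fn == 0) NaN else tp / (tp + fp + fn),
    accuracy = (tp + tn) / total,
    precision = if (tp + fp == 0) NaN else tp / (tp + fp),
    sensitivity = if (tp + fn == 0) NaN else tp / (tp + fn),
    f1 = if (tp == 0 && (fp > 0 || fn > 0)) 0
         else if (2 * tp + fp + fn == 0) NaN
         else {
           prec <- tp / (tp + fp); sens <- tp / (tp + fn)
           2 * prec * sens / (prec + sens)
         },
    TP = tp, FP = fp, FN = fn, TN = tn)
}

# sparse-dentition phantom spec small enough for fast tests
small_phantom_spec <- function(seed, teeth = c(13, 16, 23, 26, 33, 36, 43, 46),
                               grid = c(64L, 64L, 48L), spacing = 0.45,
                               ...) {
  present <- stats::setNames(rep(FALSE, 32), as.character(index_to_fdi(1:32)))
  present[as.character(teeth)] <- TRUE
  phantom_spec(grid_shape = grid, spacing_mm = spacing,
               teeth_present = present, seed = seed,
               tooth_params = list(crown_radius_scale = 1.1), ...)
}

# one small phantom, generated once per test run
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(small_phantom_spec(421))
    cache
  }
})

# reduced model config used across model/training tests
reduced_config <- function(...) {
  args <- utils::modifyList(
    list(embed_size = 24L, attention_window = c(5L, 5L, 5L),
         smamba_state_dim = 8L),
    list(...))
  do.call(model_config, args)
}
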