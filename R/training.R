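#' Training configuration
#'
#' Defaults follow the training protocol: random 70/20/10
#' train/validation/test split, learning rate 1e-5, batch size 1,
#' 64^3 random patches, DiceCE loss with 1:1 weights, AdamW with a
#' linear warm-up into cosine annealing. The clinical protocol trains
#' for 2500 epochs; the desk default is 50 (configurable). Warm-up
#' defaults to 2% of epochs (50 of 2500). One epoch draws
#' `patches_per_case` random patches from every training case.
#'
#' @param split Length-3 fractions summing to 1.
#' @param lr Peak learning rate (> 0).
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Fixed at 1 (single-volume batches).
#' @param patch Length-3 patch shape.
#' @param warmup_epochs Warm-up length; default `round(0.02 * epochs)`.
#' @param loss_weights `c(w_dice, w_ce)`.
#' @param seed RNG seed for the whole run (data stream and init).
#' @param patches_per_case Patches drawn per case per epoch.
#' @param augment An [augment_config()] or `NULL` to disable.
#' @param foreground_bias Bias patch sampling towards foreground.
#' @param validate_every Epoch interval for whole-volume validation
#'   (0 = off); validation uses sliding-window inference so curves
#'   reflect deployment behaviour.
#' @param checkpoint_every Epoch interval for checkpoints (0 = end only).
#' @param checkpoint_dir Directory for checkpoints (`NULL` = keep in
#'   memory only).
#' @param weight_decay AdamW decoupled weight decay.
#' @param adam_betas AdamW moment decay rates `c(beta1, beta2)`; the
#'   second moment's horizon matters for very short runs.
#' @param normalize Min-max normalize each case's intensities before
#'   patching (default). Disable when the cohort is already normalized
#'   on a common scale (e.g. pre-cut patches of one volume), where
#'   per-case renormalization would distort intensities.
#' @param clip_grad_norm Clip the global gradient norm to this value
#'   before each optimizer step (`Inf` = off, the default). A standard
#'   stabilizer for aggressive learning-rate schedules.
#' @return An object of class `train_config`.
#' @export
train_config <- function(split = c(0.70, 0.20, 0.10), lr = 1e-5,
                         epochs = 50L, batch_size = 1L,
                         patch = c(64L, 64L, 64L),
                         warmup_epochs = NULL,
                         loss_weights = c(1, 1), seed = 1L,
                         patches_per_case = 1L, augment = NULL,
                         foreground_bias = FALSE,
                         validate_every = 0L, checkpoint_every = 0L,
                         checkpoint_dir = NULL, weight_decay = 0.01,
                         adam_betas = c(0.9, 0.999), normalize = TRUE,
                         clip_grad_norm = Inf) {
  stopifnot(abs(sum(split) - 1) < 1e-9, lr > 0, epochs >= 1,
            batch_size == 1L, length(patch) == 3L, all(loss_weights >= 0))
  if (is.null(warmup_epochs)) warmup_epochs <- max(1L, round(0.02 * epochs))
  stopifnot(warmup_epochs >= 0, warmup_epochs < epochs)
  structure(list(split = split, lr = lr, epochs = as.integer(epochs),
                 batch_size = 1L, patch = as.integer(patch),
                 warmup_epochs = as.integer(warmup_epochs),
                 loss_weights = loss_weights, seed = as.integer(seed),
                 patches_per_case = as.integer(patches_per_case),
                 augment = augment, foreground_bias = foreground_bias,
                 validate_every = as.integer(validate_every),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir,
                 weight_decay = weight_decay,
                 adam_betas = adam_betas, normalize = normalize,
                 clip_grad_norm = clip_grad_norm),
            class = "train_config")
}

#' Random dataset split
#'
#' Disjoint, exhaustive, reproducible from the seed. Validation and test
#' sizes are `round(n * f)`; the remainder goes to training, so
#' `n = 100` with the default fractions gives 70/20/10.
#'
#' @param case_ids Vector of at least 3 case identifiers.
#' @param fractions Length-3 `(train, val, test)` fractions summing to 1.
#' @param seed Integer seed.
#' @return List with `train`, `val`, `test`.
#' @export
split_dataset <- function(case_ids, fractions = c(0.70, 0.20, 0.10),
                          seed = 1L) {
  n <- length(case_ids)
  if (n < 3L) stop("need at least 3 cases to split, got ", n)
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  n_va <- round(n * fractions[2])
  n_te <- round(n * fractions[3])
  n_tr <- n - n_va - n_te
  run_seeded(seed, {
    perm <- sample(case_ids)
    list(train = perm[seq_len(n_tr)],
         val = perm[n_tr + seq_len(n_va)],
         test = perm[n_tr + n_va + seq_len(n_te)])
  })
}

#' DiceCE composite loss
#'
#' `loss = w_dice * (1 - mean_k softDice_k) + w_ce * mean_vox(-log p[target])`
#' over all `K` class channels, with smoothing `1e-5` in the soft-Dice
#' numerator and denominator. `pred` holds per-class probabilities (e.g.
#' the output of [model_forward()]); a uniform predictor over `K`
#' classes has CE term `log(K)`, and a one-hot prediction equal to the
#' target has Dice term 0.
#'
#' @param pred Probability array `(K, X, Y, Z)` or `(1, K, X, Y, Z)`.
#' @param target Integer array `(X, Y, Z)` of labels in `0..K-1`, or a
#'   [label_volume()].
#' @param weights `c(w_dice, w_ce)`.
#' @return Nonnegative scalar.
#' @export
dice_ce_loss <- function(pred, target, weights = c(1, 1)) {
  if (inherits(target, "oralseg_labelvolume")) target <- target$labels
  if (length(dim(pred)) == 5L) pred <- array(pred, dim(pred)[-1])
  d <- dim(pred)
  if (!identical(as.integer(d[-1]), as.integer(dim(target)))) {
    stop("prediction grid ", paste(d[-1], collapse = "x"),
         " does not match target grid ", paste(dim(target), collapse = "x"))
  }
  K <- d[1]
  tgt <- as.integer(target)
  if (any(tgt < 0L | tgt >= K)) stop("target values must lie in 0..K-1")
  S <- prod(d[-1])
  p <- matrix(pred, K)
  lin <- tgt + 1L + K * (seq_len(S) - 1L)
  ce <- -mean(log(pmax(p[lin], 1e-300)))
  smooth <- 1e-5
  tcount <- tabulate(tgt + 1L, nbins = K)
  inter <- vapply(seq_len(K), function(k) sum(p[k, tgt == k - 1L]), numeric(1))
  dice_k <- (2 * inter + smooth) / (rowSums(p) + tcount + smooth)
  weights[1] * (1 - mean(dice_k)) + weights[2] * ce
}

#' Warm-up cosine learning-rate schedule
#'
#' Linear ramp from 0 to `lr` over `warmup_epochs`, then cosine decay
#' to 0 at `epochs`. Epochs are 0-based: epoch 0 gives 0, epoch
#' `warmup_epochs` gives `lr`, and the midpoint of the cosine span gives
#' `lr / 2`.
#'
#' @param epoch 0-based epoch, `0 <= epoch < cfg$epochs`.
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
lr_schedule <- function(epoch, cfg) {
  stopifnot(epoch >= 0, epoch < cfg$epochs)
  w <- cfg$warmup_epochs
  if (epoch < w) return(cfg$lr * epoch / w)
  span <- cfg$epochs - w
  cfg$lr * 0.5 * (1 + cos(pi * (epoch - w) / span))
}

# ---- AdamW ------------------------------------------------------------------

adamw_new <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0.01) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim(p$v) %||% length(p$v)))
  st$v <- lapply(params, function(p) array(0, dim(p$v) %||% length(p$v)))
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$weight_decay <- weight_decay
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamw_step <- function(st, params, lr) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    upd <- (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + st$eps)
    if (isTRUE(p$decay) && st$weight_decay > 0) {
      upd <- upd + st$weight_decay * p$v
    }
    p$v <- p$v - lr * upd
    p$grad <- NULL
  }
  invisible(st)
}

adamw_state <- function(st) list(t = st$t, m = st$m, v = st$v)
adamw_restore <- function(st, state) {
  st$t <- state$t; st$m <- state$m; st$v <- state$v
  invisible(st)
}

# hard foreground macro-Dice between two integer label arrays, averaged
# over the classes present in the ground truth (background excluded)
hard_macro_dice <- function(pred, gt, K = 36L) {
  pn <- tabulate(as.integer(pred), nbins = K)
  gn <- tabulate(as.integer(gt), nbins = K)
  keep <- which(gn > 0L)
  if (!length(keep)) return(NA_real_)
  inter <- vapply(keep, function(k) sum(pred == k & gt == k), numeric(1))
  mean(2 * inter / (pn[keep] + gn[keep]))
}

#' Train a model
#'
#' The full protocol: per epoch, draws random (optionally augmented)
#' patches from every training case, computes the DiceCE loss, and takes
#' an AdamW step at the scheduled learning rate. All randomness flows
#' from `cfg$seed`, so two runs with identical configs produce identical
#' curves, and ablation arms see the identical data stream. Training
#' aborts with a diagnostic naming the offending case if the loss goes
#' non-finite. Checkpoints carry optimizer and RNG state, so a resumed
#' run reproduces the uninterrupted run bit-for-bit.
#'
#' @param model An [build_model()] object (modified in place).
#' @param cohort List of cases, each a list with `volume` and `labels`
#'   (e.g. [generate_phantom()] output). Intensities are min-max
#'   normalized internally.
#' @param cfg A [train_config()].
#' @param val_cohort Optional validation cases (same structure).
#' @param resume Optional checkpoint path to resume from.
#' @param verbose Print a line per epoch.
#' @return List with `model`, `curves` (data frame: epoch, lr,
#'   train_loss, train_dice, val_loss, val_dice), `best` (parameter
#'   values at the best validation — or training — macro-Dice).
#' @export
fit <- function(model, cohort, cfg = train_config(), val_cohort = NULL,
                resume = NULL, verbose = FALSE) {
  stopifnot(length(cohort) >= 1L)
  K <- model$cfg$num_classes
  norm_case <- function(cs) {
    list(img = if (cfg$normalize) normalize_intensity(cs$volume)
               else cs$volume,
         lab = cs$labels)
  }
  cases <- lapply(cohort, norm_case)
  vcases <- if (!is.null(val_cohort)) lapply(val_cohort, norm_case)
  opt <- adamw_new(model$params, beta1 = cfg$adam_betas[1],
                   beta2 = cfg$adam_betas[2],
                   weight_decay = cfg$weight_decay)
  start_epoch <- 0L
  curves <- NULL
  best <- list(score = -Inf, values = NULL)
  rng_state <- NULL
  if (!is.null(resume)) {
    ck <- load_checkpoint(resume)
    for (nm in names(model$params)) model$params[[nm]]$v <- ck$params[[nm]]$v
    ex <- attr(ck, "extra")
    adamw_restore(opt, ex$opt)
    start_epoch <- ex$epoch + 1L
    curves <- ex$curves
    best <- ex$best
    rng_state <- ex$rng
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  if (is.null(rng_state)) set.seed(cfg$seed)
  else assign(".Random.seed", rng_state, envir = globalenv())

  steps_per_epoch <- length(cases) * cfg$patches_per_case
  for (epoch in start_epoch:(cfg$epochs - 1L)) {
    lr <- lr_schedule(epoch, cfg)
    order_i <- sample(seq_along(cases))
    losses <- numeric(0)
    dices <- numeric(0)
    step_in_epoch <- 0L
    for (ci in order_i) {
      for (rep in seq_len(cfg$patches_per_case)) {
        # the schedule is continuous in (fractional) epochs so short runs
        # do not spend a whole epoch at the zero end of the warm-up ramp
        lr <- lr_schedule(epoch + step_in_epoch / steps_per_epoch, cfg)
        step_in_epoch <- step_in_epoch + 1L
        sd1 <- sample.int(.Machine$integer.max - 1L, 2L)
        pat <- sample_patch(cases[[ci]]$img, cases[[ci]]$lab, cfg$patch,
                            seed = sd1[1],
                            foreground_bias = cfg$foreground_bias)
        if (!is.null(cfg$augment)) {
          aug <- augment_pair(pat$volume, pat$labels, cfg$augment,
                              seed = sd1[2])
          pat <- list(volume = aug$volume, labels = aug$labels)
        }
        logits <- forward_logits(model, pat$volume$data)
        loss <- ag_dice_ce(logits, pat$labels$labels,
                           w_dice = cfg$loss_weights[1],
                           w_ce = cfg$loss_weights[2])
        if (!is.finite(loss$v)) {
          stop(sprintf(
            "non-finite loss (%g) at epoch %d, case %d, patch %d — aborting",
            loss$v, epoch, ci, rep))
        }
        pl <- apply(matrix(ag_value(logits), K), 2L, which.max) - 1L
        dices <- c(dices, hard_macro_dice(array(pl, dim(pat$labels$labels)),
                                          pat$labels$labels, K - 1L))
        losses <- c(losses, loss$v)
        ag_backward(loss)
        if (is.finite(cfg$clip_grad_norm)) {
          gnorm <- sqrt(sum(vapply(model$params, function(p)
            if (is.null(p$grad)) 0 else sum(p$grad^2), numeric(1))))
          if (gnorm > cfg$clip_grad_norm) {
            sc <- cfg$clip_grad_norm / gnorm
            for (p in model$params) {
              if (!is.null(p$grad)) p$grad <- p$grad * sc
            }
          }
        }
        adamw_step(opt, model$params, lr)
      }
    }
    val_loss <- NA_real_; val_dice <- NA_real_
    if (!is.null(vcases) && cfg$validate_every > 0L &&
        (epoch %% cfg$validate_every == cfg$validate_every - 1L ||
         epoch == cfg$epochs - 1L)) {
      vl <- vapply(vcases, function(vc) {
        pr <- predict_volume(vc$img, model,
                             inference_config(window = cfg$patch,
                                              target_spacing = vc$img$spacing),
                             return_probs = TRUE)
        probs <- attr(pr, "probs")
        c(dice_ce_loss(probs, vc$lab$labels, cfg$loss_weights),
          hard_macro_dice(pr$labels, vc$lab$labels, K - 1L))
      }, numeric(2))
      val_loss <- mean(vl[1, ]); val_dice <- mean(vl[2, ])
    }
    row <- data.frame(epoch = epoch, lr = lr_schedule(epoch, cfg),
                      train_loss = mean(losses),
                      train_dice = mean(dices, na.rm = TRUE),
                      val_loss = val_loss, val_dice = val_dice)
    curves <- rbind(curves, row)
    score <- if (!is.na(val_dice)) val_dice else row$train_dice
    if (!is.na(score) && score > best$score) {
      best <- list(score = score, epoch = epoch,
                   values = lapply(model$params, function(p) p$v))
    }
    if (verbose) {
      message(sprintf("epoch %d lr %.3g loss %.4f dice %.4f val %.4f",
                      epoch, lr, row$train_loss, row$train_dice, val_dice))
    }
    if (!is.null(cfg$checkpoint_dir) &&
        (epoch == cfg$epochs - 1L ||
         (cfg$checkpoint_every > 0L &&
          epoch %% cfg$checkpoint_every == cfg$checkpoint_every - 1L))) {
      dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(model,
                      file.path(cfg$checkpoint_dir,
                                sprintf("epoch%04d.rds", epoch)),
                      extra = list(opt = adamw_state(opt), epoch = epoch,
                                   curves = curves, best = best,
                                   rng = get(".Random.seed",
                                             envir = globalenv())))
    }
  }
  list(model = model, curves = curves, best = best)
}
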