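#' Training configuration
#'
#' Defaults follow the shared protocol used by all three regimes: AdamW with
#' AMSGrad, initial learning rate and decoupled weight decay 0.01, betas
#' (0.9, 0.999), epsilon 1e-8, batch size 250, horizontal-flip augmentation
#' with probability 0.5, learning rate multiplied by 0.66 whenever the
#' validation loss stagnates for 10 epochs, early stopping after 25 epochs
#' without improvement, and the returned model being the best-validation-loss
#' snapshot. "Improvement" means a validation loss lower than the running
#' best by at least `min_improvement`.
#'
#' The 250-sample batch is kept for the full variant only; for the reduced
#' variant the loop scales the batch down (capped at `reduced_batch`) so
#' desk-scale runs see several optimizer steps per epoch.
#'
#' @param batch_size minibatch size for the full variant.
#' @param reduced_batch batch cap applied when training a reduced variant.
#' @param lr0 initial learning rate.
#' @param weight_decay decoupled weight decay.
#' @param betas AdamW beta parameters.
#' @param epsilon AdamW epsilon.
#' @param amsgrad use the AMSGrad variant.
#' @param scheduler_factor learning-rate multiplier on plateau, in (0, 1).
#' @param scheduler_patience epochs of stagnation before a reduction.
#' @param early_stop_patience epochs of stagnation before stopping; must
#'   exceed `scheduler_patience`.
#' @param flip_p horizontal flip probability during training.
#' @param max_epochs hard cap on epochs.
#' @param min_improvement minimum validation-loss decrease that counts as an
#'   improvement.
#' @param seed RNG seed controlling shuffling, augmentation and any fresh
#'   initialization inside the regime runners.
#' @return a `train_config`.
#' @export
train_config <- function(batch_size = 250L, reduced_batch = 64L, lr0 = 0.01,
                         weight_decay = 0.01, betas = c(0.9, 0.999),
                         epsilon = 1e-8, amsgrad = TRUE,
                         scheduler_factor = 0.66, scheduler_patience = 10L,
                         early_stop_patience = 25L, flip_p = 0.5,
                         max_epochs = 200L, min_improvement = 1e-6,
                         seed = 1L) {
  if (scheduler_factor <= 0 || scheduler_factor >= 1)
    stop("scheduler_factor must lie in (0, 1)")
  if (early_stop_patience <= scheduler_patience)
    stop("early_stop_patience must exceed scheduler_patience")
  structure(list(batch_size = as.integer(batch_size),
                 reduced_batch = as.integer(reduced_batch),
                 lr0 = lr0, weight_decay = weight_decay, betas = betas,
                 epsilon = epsilon, amsgrad = amsgrad,
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 flip_p = flip_p, max_epochs = as.integer(max_epochs),
                 min_improvement = min_improvement, seed = as.integer(seed)),
            class = "train_config")
}

#' Plateau scheduler / early-stopping state machine
#'
#' `plateau_init()` creates the state; `plateau_update()` consumes one
#' validation loss per epoch. A loss below the running best by at least
#' `min_improvement` resets both stagnation counters and marks a new best
#' epoch. Otherwise both counters advance: after `scheduler_patience`
#' stagnant epochs the learning rate is multiplied by `factor` (and the
#' scheduler counter restarts, so a second reduction follows another full
#' patience span); after `early_stop_patience` stagnant epochs `stop` is set.
#'
#' @param lr0 initial learning rate.
#' @param factor reduction multiplier in (0, 1).
#' @param patience scheduler patience in epochs.
#' @param early_stop early-stopping patience in epochs.
#' @param min_improvement improvement tolerance.
#' @return `plateau_init`: state list; `plateau_update`: updated state with
#'   fields `lr`, `best`, `best_epoch`, `epoch`, `reduced` (this epoch),
#'   `improved` (this epoch) and `stop`.
#' @export
plateau_init <- function(lr0, factor = 0.66, patience = 10L,
                         early_stop = 25L, min_improvement = 1e-6) {
  list(lr = lr0, factor = factor, patience = as.integer(patience),
       early_stop = as.integer(early_stop), min_improvement = min_improvement,
       best = Inf, best_epoch = 0L, epoch = 0L,
       bad_sched = 0L, bad_stop = 0L,
       improved = FALSE, reduced = FALSE, stop = FALSE)
}

#' @rdname plateau_init
#' @param state state from `plateau_init()`/a previous update.
#' @param val_loss this epoch's validation loss.
#' @export
plateau_update <- function(state, val_loss) {
  state$epoch <- state$epoch + 1L
  state$reduced <- FALSE
  if (val_loss < state$best - state$min_improvement) {
    state$best <- val_loss
    state$best_epoch <- state$epoch
    state$bad_sched <- 0L
    state$bad_stop <- 0L
    state$improved <- TRUE
  } else {
    state$improved <- FALSE
    state$bad_sched <- state$bad_sched + 1L
    state$bad_stop <- state$bad_stop + 1L
    if (state$bad_sched >= state$patience) {
      state$lr <- state$lr * state$factor
      state$bad_sched <- 0L
      state$reduced <- TRUE
    }
    if (state$bad_stop >= state$early_stop) state$stop <- TRUE
  }
  state
}

# Weighted loss of a model over a sample set, evaluated in inference mode.
eval_loss <- function(model, patches, y_idx, w, batch_size = 256L) {
  n <- length(y_idx)
  tot <- 0; wsum <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    logits <- nn_forward(model$net, as_nn_tensor(patches[, , idx, drop = FALSE]),
                         training = FALSE)$y
    l <- weighted_ce_loss(logits, y_idx[idx], w[idx])
    tot <- tot + l$loss * sum(w[idx])
    wsum <- wsum + sum(w[idx])
  }
  tot / wsum
}

#' Train a patch classifier
#'
#' Shared loop of all three regimes: AdamW+AMSGrad on class-weighted
#' cross-entropy (each sample's loss multiplied by its class weight),
#' per-epoch shuffling and random horizontal flips, plateau learning-rate
#' reduction, early stopping, and best-validation-loss snapshotting.
#' Validation loss uses the same class weights so it is comparable across
#' regimes. Deterministic given data, config and seed.
#'
#' @param model an `oct_model` whose `classes` cover the sample labels.
#' @param train_samples,val_samples `oct_samples`; labels must be among
#'   `model$classes`.
#' @param weights named positive class weights covering every label present
#'   in the training samples (see [class_weights()]).
#' @param config a [train_config()].
#' @return list with `model` (the best-validation snapshot) and `log`
#'   (class `training_log`): per-epoch train/val loss and learning rate,
#'   `best_epoch` and `stop_reason`.
#' @export
train_model <- function(model, train_samples, val_samples, weights, config) {
  stopifnot(inherits(model, "oct_model"), inherits(config, "train_config"))
  classes <- model$classes
  lab_tr <- as.character(train_samples$label)
  lab_va <- as.character(val_samples$label)
  missing <- setdiff(unique(c(lab_tr, lab_va)), names(weights))
  if (length(missing) > 0L)
    stop("labels without a class weight: ", paste(missing, collapse = ", "))
  if (!all(unique(c(lab_tr, lab_va)) %in% classes))
    stop("sample labels outside the model's class set")
  if (length(lab_tr) == 0L || length(lab_va) == 0L)
    stop("training and validation sets must be non-empty")

  y_tr <- match(lab_tr, classes); w_tr <- unname(weights[lab_tr])
  y_va <- match(lab_va, classes); w_va <- unname(weights[lab_va])
  x_tr <- train_samples$patches; x_va <- val_samples$patches
  n <- length(y_tr)
  batch <- if (model$variant == "reduced")
    min(config$batch_size, config$reduced_batch, n) else min(config$batch_size, n)

  params <- nn_flatten(model$net)
  opt <- adamw_init(params)
  sched <- plateau_init(config$lr0, config$scheduler_factor,
                        config$scheduler_patience, config$early_stop_patience,
                        config$min_improvement)
  best_params <- params
  best_model <- model
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), lr = numeric(0))
  stop_reason <- "max_epochs"

  with_seed(config$seed, {
    side <- dim(x_tr)[1]
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      flips <- runif(n) < config$flip_p
      ep_loss <- 0; ep_w <- 0
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(n, start + batch - 1L)]
        xb <- x_tr[, , idx, drop = FALSE]
        fl <- which(flips[idx])
        for (i in fl) xb[, , i] <- xb[, side:1, i]
        fwd <- nn_forward(model$net, as_nn_tensor(xb), training = TRUE)
        model$net <- fwd$m
        l <- weighted_ce_loss(fwd$y, y_tr[idx], w_tr[idx])
        bwd <- nn_backward(model$net, fwd$cache, l$dlogits)
        params <- nn_flatten(model$net)
        grads <- nn_flatten_grads(model$net, bwd$grads)
        upd <- adamw_step(params, grads, opt, lr = sched$lr,
                          weight_decay = config$weight_decay,
                          betas = config$betas, eps = config$epsilon,
                          amsgrad = config$amsgrad)
        opt <- upd$state
        model$net <- nn_set_params(model$net, upd$params)
        ep_loss <- ep_loss + l$loss * sum(w_tr[idx])
        ep_w <- ep_w + sum(w_tr[idx])
      }
      val_loss <- eval_loss(model, x_va, y_va, w_va)
      sched <- plateau_update(sched, val_loss)
      log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / ep_w,
                                   val_loss = val_loss, lr = sched$lr))
      if (sched$improved) best_model <- model
      if (sched$stop) { stop_reason <- "early_stop"; break }
    }
  })
  tlog <- structure(list(history = log, best_epoch = sched$best_epoch,
                         best_val_loss = sched$best,
                         stop_reason = stop_reason),
                    class = "training_log")
  list(model = best_model, log = tlog)
}

#' @export
print.training_log <- function(x, ...) {
  cat(sprintf("training_log: %d epochs, best val loss %.5f at epoch %d (%s)\n",
              nrow(x$history), x$best_val_loss, x$best_epoch, x$stop_reason))
  invisible(x)
}

# Select a sample subset by image fold membership.
samples_in_folds <- function(samples, folds, fold_ids) {
  subset_samples(samples, folds[samples$image_id] %in% fold_ids)
}

train_counts <- function(samples, with_uncertainty = FALSE) {
  need <- oct_classes(with_uncertainty)
  tab <- table(factor(as.character(samples$label), levels = need))
  stats::setNames(as.numeric(tab), need)
}

#' Baseline regime: four-class training from scratch
#'
#' Samples centered in uncertainty regions are discarded from both training
#' and validation; the remaining samples are weighted by inverse class
#' frequency ([class_weights()] with the `four_class` scheme, computed on the
#' training folds) and a fresh backbone is trained under the shared protocol.
#'
#' @param split an `experiment_split` from [enumerate_experiments()].
#' @param samples combined `oct_samples` across all images.
#' @param folds image-to-fold assignment from [make_folds()].
#' @param config a [train_config()].
#' @param backbone a [backbone_config()] with 4 classes.
#' @return list with `model`, `log`, and `info` (sample counts and weights
#'   actually used).
#' @export
run_baseline <- function(split, samples, folds, config,
                         backbone = backbone_config(n_classes = 4L)) {
  stopifnot(inherits(split, "experiment_split"))
  tr <- samples_in_folds(samples, folds, split$train)
  va <- samples_in_folds(samples, folds, split$val)
  tr <- subset_samples(tr, tr$label != "uncertainty")
  va <- subset_samples(va, va$label != "uncertainty")
  counts <- train_counts(tr)
  if (any(counts == 0))
    stop("a diagnostic class is absent from the training folds")
  w <- class_weights(counts, "four_class")
  model <- build_backbone(backbone, seed = config$seed)
  fit <- train_model(model, tr, va, w, config)
  list(model = fit$model, log = fit$log,
       info = list(n_train = length(tr$label), counts = counts, weights = w))
}

#' Synthetic generalist pretext patches
#'
#' Four generic texture families (oriented gradients, speckle fields,
#' sinusoidal gratings, Gaussian blobs) standing in for a wide-spectrum
#' natural-image pretraining corpus at desk scale. Used by
#' [pretrain_generalist()] when no externally pretrained weights are given.
#'
#' @param n_per_class patches per texture family.
#' @param side patch side in pixels.
#' @param seed RNG seed.
#' @return an `oct_samples` whose labels are the four family names.
#' @export
generate_pretext_samples <- function(n_per_class = 40L, side = 64L, seed = 1L) {
  fams <- c("gradient", "speckle", "grating", "blobs")
  n <- 4L * n_per_class
  patches <- array(0, dim = c(side, side, n))
  grid_r <- matrix(seq_len(side), side, side)
  grid_c <- t(grid_r)
  with_seed(seed, {
    for (i in seq_len(n)) {
      fam <- fams[((i - 1L) %/% n_per_class) + 1L]
      p <- switch(fam,
        gradient = {
          th <- runif(1, 0, pi)
          z <- cos(th) * grid_r + sin(th) * grid_c
          (z - min(z)) / (max(z) - min(z))
        },
        speckle = matrix(pmin(1, exp(rnorm(side^2, -1, 0.5))), side, side),
        grating = {
          th <- runif(1, 0, pi); f <- runif(1, 0.1, 0.6)
          0.5 + 0.4 * sin(f * (cos(th) * grid_r + sin(th) * grid_c))
        },
        blobs = {
          z <- matrix(0, side, side)
          for (b in seq_len(sample(2:5, 1))) {
            cy <- runif(1, 1, side); cx <- runif(1, 1, side)
            s <- runif(1, 3, 9)
            z <- z + exp(-((grid_r - cy)^2 + (grid_c - cx)^2) / (2 * s^2))
          }
          pmin(z, 1)
        })
      patches[, , i] <- pmin(pmax(p + rnorm(side^2, 0, 0.05), 0), 1)
    }
  })
  new_oct_samples(patches,
                  factor(rep(fams, each = n_per_class), levels = fams),
                  rep("pretext", n),
                  cbind(row = rep(side %/% 2L, n), col = rep(side %/% 2L, n)))
}

#' Pretrain a generalist backbone on the synthetic pretext task
#'
#' Desk-scale stand-in for pretraining on a large natural-image corpus: the
#' backbone learns the four pretext texture families before its head is
#' replaced for the retinal domain. The returned model carries provenance
#' `generalist_pretrained`.
#'
#' @param backbone a [backbone_config()] (its `n_classes` is overridden to 4
#'   pretext classes).
#' @param config a [train_config()]; a short `max_epochs` budget is typical.
#' @param n_per_class pretext patches per family.
#' @return the pretrained `oct_model`.
#' @export
pretrain_generalist <- function(backbone = backbone_config(),
                                config = train_config(max_epochs = 10L),
                                n_per_class = 40L) {
  side <- backbone$input_side
  cfgp <- backbone
  cfgp$n_classes <- 4L
  model <- build_backbone(cfgp, seed = config$seed)
  fams <- c("gradient", "speckle", "grating", "blobs")
  model$classes <- fams
  all <- generate_pretext_samples(2L * n_per_class, side, seed = config$seed)
  n <- length(all$label)
  idx_va <- with_seed(config$seed + 1L, sample.int(n, max(8L, n %/% 5L)))
  va <- subset_samples(all, idx_va)
  tr <- subset_samples(all, setdiff(seq_len(n), idx_va))
  w <- stats::setNames(rep(1, 4), fams)
  fit <- train_model(model, tr, va, w, config)
  out <- fit$model
  out$provenance <- "generalist_pretrained"
  out
}

#' Generalist transfer regime
#'
#' Replaces the head of an externally (or pretext-) pretrained backbone with
#' the four diagnostic classes, keeping the rest of the network weights, and
#' fine-tunes exactly as the baseline (uncertainty samples excluded,
#' four-class inverse-frequency weights, shared protocol).
#'
#' @param pretrained a pretrained `oct_model` (e.g. from
#'   [pretrain_generalist()]); required unless `fallback = TRUE`.
#' @param fallback pretrain the pretext model on the fly when `pretrained`
#'   is `NULL`.
#' @inheritParams run_baseline
#' @return list with `model`, `log`, `info`.
#' @export
run_generalist_transfer <- function(pretrained, split, samples, folds, config,
                                    backbone = backbone_config(n_classes = 4L),
                                    fallback = FALSE) {
  if (is.null(pretrained)) {
    if (!fallback)
      stop("no pretrained weights supplied and fallback disabled")
    pretrained <- pretrain_generalist(backbone, config)
  }
  tr <- samples_in_folds(samples, folds, split$train)
  va <- samples_in_folds(samples, folds, split$val)
  tr <- subset_samples(tr, tr$label != "uncertainty")
  va <- subset_samples(va, va$label != "uncertainty")
  counts <- train_counts(tr)
  if (any(counts == 0))
    stop("a diagnostic class is absent from the training folds")
  w <- class_weights(counts, "four_class")
  model <- replace_head(pretrained, 4L, seed = config$seed,
                        classes = oct_classes())
  model$provenance <- "generalist_pretrained"
  fit <- train_model(model, tr, va, w, config)
  list(model = fit$model, log = fit$log,
       info = list(n_train = length(tr$label), counts = counts, weights = w))
}

#' Uncertainty-aware two-stage transfer regime
#'
#' Stage 1 trains a binary classifier separating healthy from pathological
#' samples, where the pathological side pools CME, DRT, SRD and the
#' expert-labeled uncertainty samples, weighted by the binary
#' inverse-frequency scheme. Stage 2 replaces the head with the four
#' diagnostic classes (keeping the stage-1 body) and fine-tunes on samples
#' with a defined label only — zero uncertainty samples — under four-class
#' weights. The returned model carries provenance `binary_pretrained`.
#'
#' @inheritParams run_baseline
#' @return list with `model`, `log` (stage-2 log), `stage1` (model and log),
#'   and `info` including the stage-2 label table (no uncertainty entries)
#'   and both weight vectors.
#' @export
run_uncertainty_transfer <- function(split, samples, folds, config,
                                     backbone = backbone_config(n_classes = 4L)) {
  stopifnot(inherits(split, "experiment_split"))
  tr <- samples_in_folds(samples, folds, split$train)
  va <- samples_in_folds(samples, folds, split$val)
  if (!any(tr$label == "uncertainty"))
    stop("no uncertainty samples in the training folds; stage 1 degenerates")

  # stage 1: healthy vs pathological (CME + DRT + SRD + uncertainty)
  counts5 <- train_counts(tr, with_uncertainty = TRUE)
  w_bin <- class_weights(counts5, "binary_with_uncertainty")
  map_bin <- function(s) {
    out <- s
    out$label <- factor(ifelse(as.character(s$label) == "healthy",
                               "healthy", "pathological"),
                        levels = c("healthy", "pathological"))
    out
  }
  cfg_bin <- backbone
  cfg_bin$n_classes <- 2L
  m_bin <- build_backbone(cfg_bin, seed = config$seed)
  m_bin$classes <- c("healthy", "pathological")
  fit1 <- train_model(m_bin, map_bin(tr), map_bin(va), w_bin, config)

  # stage 2: head swap to the four diagnostic classes, uncertainty excluded
  tr2 <- subset_samples(tr, tr$label != "uncertainty")
  va2 <- subset_samples(va, va$label != "uncertainty")
  counts <- train_counts(tr2)
  if (any(counts == 0))
    stop("a diagnostic class is absent from the training folds")
  w4 <- class_weights(counts, "four_class")
  m2 <- replace_head(fit1$model, 4L, seed = config$seed + 1L,
                     classes = oct_classes())
  m2$provenance <- "binary_pretrained"
  fit2 <- train_model(m2, tr2, va2, w4, config)

  list(model = fit2$model, log = fit2$log,
       stage1 = list(model = fit1$model, log = fit1$log),
       info = list(stage1_counts = counts5, stage1_weights = w_bin,
                   stage2_labels = table(tr2$label),
                   stage2_weights = w4,
                   n_stage2_uncertainty = sum(tr2$label == "uncertainty")))
}
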