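# Shared fixtures and independent brute-force oracles. All fixtures are
# generated in code; heavier ones are memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# High-contrast phantom set used by the training fixtures: all three fluid
# types planted in every image.
fixture_images <- function(n = 8L, seed = 11L) {
  memo(sprintf("imgs_%d_%d", n, seed), {
    cfg <- phantom_config(seed = seed,
                          class_prevalences = c(CME = 1, DRT = 1, SRD = 1))
    generate_dataset(n, cfg, seed = seed)
  })
}

fixture_samples <- function(n_images = 8L, n_per_label = 12L, window = 32L,
                            seed = 11L) {
  memo(sprintf("samps_%d_%d_%d_%d", n_images, n_per_label, window, seed), {
    imgs <- fixture_images(n_images, seed)
    combine_samples(lapply(seq_along(imgs), function(i) {
      extract_samples(imgs[[i]], n_per_label = n_per_label, window = window,
                      seed = seed + 100L + i)
    }))
  })
}

fixture_folds <- function(n_images = 8L, k = 4L, seed = 11L) {
  make_folds(fixture_images(n_images, seed), k = k, seed = seed + 1L)
}

fixture_split <- function() {
  structure(list(train = 1:2, val = 3L, test = 4L), class = "experiment_split")
}

tiny_backbone <- function(n_classes = 4L, input_side = 32L, seed = 1L) {
  backbone_config(variant = "reduced", input_side = input_side,
                  n_classes = n_classes, block_layout = c(2L, 2L),
                  growth = 8L, init_channels = 12L, seed = seed)
}

# Pretext-pretrained model shared by transfer-regime tests (trained once).
fixture_pretrained <- function(seed = 5L) {
  memo(sprintf("pretrained_%d", seed), {
    pretrain_generalist(tiny_backbone(seed = seed),
                        train_config(max_epochs = 5L, seed = seed),
                        n_per_class = 25L)
  })
}

# ---- independent oracles ----------------------------------------------------

# Exhaustive Mann-Whitney AUC double loop.
auc_loop_oracle <- function(pos, neg) {
  s <- 0
  for (x in pos) for (y in neg)
    s <- s + if (x > y) 1 else if (x == y) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Index-reflection oracle for mirror cropping (reflect-101, scalar form).
reflect_oracle <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 2L - i
    if (i > n) i <- 2L * n - i
  }
  i
}

crop_oracle <- function(mat, center, window) {
  half <- window %/% 2L
  rows <- (center[1] - half):(center[1] + half - 1L)
  cols <- (center[2] - half):(center[2] + half - 1L)
  out <- matrix(0, window, window)
  for (a in seq_along(rows)) for (b in seq_along(cols))
    out[a, b] <- mat[reflect_oracle(rows[a], nrow(mat)),
                     reflect_oracle(cols[b], ncol(mat))]
  out
}

# Brute-force per-pixel vote recount over a window grid.
vote_oracle <- function(grid, labels, shape, roi, classes) {
  h <- shape[1]; w <- shape[2]
  props <- array(NA_real_, dim = c(h, w, length(classes)))
  coverage <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    covers <- grid$origins[, 1] <= r & r <= grid$origins[, 1] + grid$window - 1L &
      grid$origins[, 2] <= c & c <= grid$origins[, 2] + grid$window - 1L
    coverage[r, c] <- sum(covers)
    if (roi[r, c] && any(covers)) {
      for (k in seq_along(classes))
        props[r, c, k] <- sum(labels[covers] == classes[k]) / sum(covers)
    }
  }
  list(proportions = props, coverage = coverage)
}

# 4-connected component labeling by BFS (independent of EBImage).
cc_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      p <- queue[1L]; queue <- queue[-1L]
      r <- ((p - 1L) %% h) + 1L; c <- ((p - 1L) %/% h) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w) {
          q <- rr + (cc - 1L) * h
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

# Chebyshev-distance dilation ring oracle for uncertainty halos.
halo_oracle <- function(region_mask, halo) {
  h <- nrow(region_mask); w <- ncol(region_mask)
  out <- matrix(FALSE, h, w)
  px <- which(region_mask, arr.ind = TRUE)
  for (i in seq_len(nrow(px))) {
    rr <- max(1L, px[i, 1] - halo):min(h, px[i, 1] + halo)
    cc <- max(1L, px[i, 2] - halo):min(w, px[i, 2] + halo)
    out[rr, cc] <- TRUE
  }
  out & !region_mask
}

# Plain multiclass accuracy (not one-vs-rest).
multiclass_accuracy <- function(model, samples) {
  keep <- samples$label != "uncertainty"
  s <- subset_samples(samples, keep)
  pred <- predict_label(model, s$patches)
  mean(pred == as.character(s$label))
}
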