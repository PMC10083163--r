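#' Crop a window around a center, completing borders by mirroring
#'
#' Returns the `window x window` patch centered at `center` (1-based
#' `(row, col)`). An even window of side `w` centered at row `r` spans rows
#' `(r - w/2):(r + w/2 - 1)`. Positions falling outside the image are filled
#' by reflecting the image across its border without repeating the border
#' pixel (see [reflect_index()]).
#'
#' @param intensities numeric matrix.
#' @param center integer `(row, col)`, must lie inside the image.
#' @param window patch side in pixels.
#' @return numeric `window x window` matrix.
#' @export
crop_with_mirror <- function(intensities, center, window = 64L) {
  h <- nrow(intensities); w <- ncol(intensities)
  r <- as.integer(center[1]); c <- as.integer(center[2])
  if (r < 1L || r > h || c < 1L || c > w)
    stop("center lies outside the image")
  if (window > 2L * min(h, w) - 2L)
    stop("window exceeds the image extent even after mirroring")
  half <- window %/% 2L
  rows <- reflect_index((r - half):(r + half + (window %% 2L) - 1L), h)
  cols <- reflect_index((c - half):(c + half + (window %% 2L) - 1L), w)
  intensities[rows, cols]
}

# Window crop addressed by its top-left corner (used by the confidence-map
# tiling, where windows are referenced by origin rather than center).
crop_window_at <- function(intensities, origin, window) {
  h <- nrow(intensities); w <- ncol(intensities)
  rows <- reflect_index(origin[1]:(origin[1] + window - 1L), h)
  cols <- reflect_index(origin[2]:(origin[2] + window - 1L), w)
  intensities[rows, cols]
}

#' Extract labeled window samples from one image
#'
#' For every label present in the mask, draws up to `n_per_label` center
#' pixels uniformly without replacement from the pixels carrying that label
#' and crops the surrounding window (mirror-completed at image borders).
#' Labels with fewer candidate centers than `n_per_label` contribute all of
#' them. Uncertainty centers are, by mask construction, inner-retina pixels
#' only. Deterministic given `seed`.
#'
#' @param image an `oct_image`.
#' @param n_per_label samples per present label (default 25).
#' @param window window side in pixels (default 64).
#' @param seed RNG seed.
#' @return an `oct_samples` object: list with `patches` (array
#'   `window x window x n`), `label` (factor over the five sample labels),
#'   `image_id` (character vector) and `center` (n x 2 integer matrix).
#' @export
extract_samples <- function(image, n_per_label = 25L, window = 64L, seed = 1L) {
  stopifnot(inherits(image, "oct_image"), n_per_label >= 1L)
  h <- nrow(image$labels); w <- ncol(image$labels)
  if (window > 2L * min(h, w) - 2L)
    stop("window exceeds the image extent even after mirroring")
  sample_labels <- oct_classes(with_uncertainty = TRUE)
  centers <- list(); labs <- character(0)
  with_seed(seed, {
    for (lab in sample_labels) {
      code <- OCT_LABEL_CODES[[lab]]
      cand <- which(image$labels == code)
      if (length(cand) == 0L) next
      take <- min(n_per_label, length(cand))
      picked <- if (length(cand) == 1L) cand else sample(cand, take)
      centers[[lab]] <- picked
      labs <- c(labs, rep(lab, take))
    }
  })
  idx <- unlist(centers, use.names = FALSE)
  n <- length(idx)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  patches <- array(0, dim = c(window, window, n))
  for (i in seq_len(n))
    patches[, , i] <- crop_with_mirror(image$intensities, c(rows[i], cols[i]), window)
  new_oct_samples(patches,
                  factor(labs, levels = sample_labels),
                  rep(image$image_id, n),
                  cbind(row = rows, col = cols))
}

new_oct_samples <- function(patches, label, image_id, center) {
  structure(list(patches = patches, label = label,
                 image_id = image_id, center = center),
            class = "oct_samples")
}

#' @export
print.oct_samples <- function(x, ...) {
  cat(sprintf("oct_samples: %d patches of %dx%d px from %d image(s)\n",
              length(x$label), dim(x$patches)[1], dim(x$patches)[2],
              length(unique(x$image_id))))
  print(table(x$label))
  invisible(x)
}

#' Combine sample sets
#' @param ... `oct_samples` objects with equal window size.
#' @return a single `oct_samples`.
#' @export
combine_samples <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !inherits(parts[[1]], "oct_samples"))
    parts <- parts[[1]]
  stopifnot(all(vapply(parts, inherits, logical(1), "oct_samples")))
  side <- dim(parts[[1]]$patches)[1]
  n <- sum(vapply(parts, function(p) length(p$label), integer(1)))
  patches <- array(0, dim = c(side, side, n))
  off <- 0L
  for (p in parts) {
    k <- length(p$label)
    if (k > 0L) patches[, , off + seq_len(k)] <- p$patches
    off <- off + k
  }
  new_oct_samples(patches,
                  factor(unlist(lapply(parts, function(p) as.character(p$label))),
                         levels = levels(parts[[1]]$label)),
                  unlist(lapply(parts, `[[`, "image_id")),
                  do.call(rbind, lapply(parts, `[[`, "center")))
}

#' Subset a sample set
#' @param samples an `oct_samples`.
#' @param idx logical or integer index over samples.
#' @return the subset as `oct_samples`.
#' @export
subset_samples <- function(samples, idx) {
  if (is.logical(idx)) idx <- which(idx)
  new_oct_samples(samples$patches[, , idx, drop = FALSE],
                  samples$label[idx],
                  samples$image_id[idx],
                  samples$center[idx, , drop = FALSE])
}

#' Random horizontal flip augmentation
#'
#' Mirrors each patch left-right with probability `p` (labels unchanged);
#' with `p = 0` this is the identity and with `p = 1` every patch is
#' flipped. Deterministic given `seed`.
#'
#' @param samples an `oct_samples` (or a single patch matrix).
#' @param p flip probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return object of the same type with patches flipped where drawn.
#' @export
augment_flip <- function(samples, p = 0.5, seed = 1L) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (is.matrix(samples)) {
    do_flip <- with_seed(seed, runif(1) < p)
    return(if (do_flip) samples[, ncol(samples):1] else samples)
  }
  stopifnot(inherits(samples, "oct_samples"))
  n <- length(samples$label)
  flips <- with_seed(seed, runif(n) < p)
  out <- samples
  side <- dim(out$patches)[2]
  for (i in which(flips)) out$patches[, , i] <- out$patches[, side:1, i]
  out
}

#' Assign images to k folds at image level
#'
#' Folds are as even as possible (sizes differ by at most one) and the
#' assignment is random at image level, so no window from one image can ever
#' appear in two roles of a split.
#'
#' @param images list of `oct_image` (or a character vector of image ids).
#' @param k number of folds (default 6).
#' @param seed RNG seed.
#' @return named integer vector mapping image id to fold id in `1..k`.
#' @export
make_folds <- function(images, k = 6L, seed = 1L) {
  ids <- if (is.character(images)) images
         else vapply(images, `[[`, character(1), "image_id")
  n <- length(ids)
  if (n < k) stop("fewer images than folds")
  perm <- with_seed(seed, sample(ids))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stats::setNames(rep(seq_len(k), times = sizes), perm)
}

#' Enumerate all train/validation/test fold assignments
#'
#' All ordered-role partitions of `k` folds into `n_train` training,
#' `n_val` validation and `n_test` test folds, each combination exactly
#' once; the count is `choose(k, n_train) * choose(k - n_train, n_val)`.
#' With the defaults (6 folds split 3/2/1) this yields the full
#' cross-validation grid of 60 experiments.
#'
#' @param k number of folds.
#' @param n_train,n_val,n_test role sizes; must sum to `k`.
#' @return list of `experiment_split` objects: lists with integer fields
#'   `train`, `val`, `test` partitioning `1..k`.
#' @export
enumerate_experiments <- function(k = 6L, n_train = 3L, n_val = 2L, n_test = 1L) {
  if (n_train + n_val + n_test != k)
    stop("role sizes must sum to the number of folds")
  folds <- seq_len(k)
  out <- list()
  train_sets <- utils::combn(folds, n_train, simplify = FALSE)
  for (tr in train_sets) {
    rest <- setdiff(folds, tr)
    val_sets <- if (n_val == 0L) list(integer(0))
                else utils::combn(rest, n_val, simplify = FALSE)
    for (va in val_sets) {
      te <- setdiff(rest, va)
      out[[length(out) + 1L]] <- structure(list(train = tr, val = va, test = te),
                                           class = "experiment_split")
    }
  }
  out
}

#' Inverse-frequency class weights
#'
#' Under the `four_class` scheme, each class's weight is the total count of
#' the other three classes divided by its own count (so, e.g., the healthy
#' weight is `(CME + DRT + SRD) / healthy`). Under
#' `binary_with_uncertainty`, the healthy weight is
#' `(uncertainty + CME + DRT + SRD) / healthy` and the pathological weight
#' its reciprocal.
#'
#' @param counts named sample counts: the four diagnostic classes for
#'   `four_class`; those plus `uncertainty` for `binary_with_uncertainty`.
#' @param scheme weighting scheme.
#' @return named numeric vector of positive per-class weights (classes
#'   `healthy`/`CME`/`DRT`/`SRD`, or `healthy`/`pathological`).
#' @export
class_weights <- function(counts, scheme = c("four_class", "binary_with_uncertainty")) {
  scheme <- match.arg(scheme)
  need <- if (scheme == "four_class") oct_classes() else oct_classes(TRUE)
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0L)
    stop("missing counts for: ", paste(missing, collapse = ", "))
  counts <- counts[need]
  if (any(counts <= 0))
    stop("class weighting requires a positive count for every class in the scheme")
  if (scheme == "four_class") {
    vapply(need, function(cl) sum(counts[setdiff(need, cl)]) / counts[[cl]],
           numeric(1))
  } else {
    path <- sum(counts[c("uncertainty", "CME", "DRT", "SRD")])
    c(healthy = path / counts[["healthy"]],
      pathological = counts[["healthy"]] / path)
  }
}

#' Persist samples as PNG patches with a CSV manifest
#'
#' @param samples an `oct_samples`.
#' @param dir output directory.
#' @return invisibly, the manifest data frame.
#' @export
write_samples <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(samples$label)
  files <- sprintf("sample_%05d.png", seq_len(n))
  for (i in seq_len(n))
    png::writePNG(samples$patches[, , i], file.path(dir, files[i]))
  manifest <- data.frame(file = files, image_id = samples$image_id,
                         row = samples$center[, 1], col = samples$center[, 2],
                         label = as.character(samples$label))
  utils::write.csv(manifest, file.path(dir, "samples.csv"), row.names = FALSE)
  invisible(manifest)
}
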