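#' Tile overlapping windows over a region of interest
#'
#' Window origins lie on a regular lattice of stride `window - overlap`,
#' anchored at the ROI bounding box (or the image corner with
#' `anchor = "image"`), restricted to windows that intersect the ROI.
#' Trailing origins are appended so the far edges of the bounding box are
#' covered even when its extent is not a multiple of the stride (this may
#' break the uniform stride at the last row/column); consequently every ROI
#' pixel is covered by at least one window. Windows may extend beyond the
#' image; classification completes them by mirroring, and votes are only
#' ever cast on real pixels.
#'
#' @param roi logical matrix (the retina region).
#' @param window window side in pixels (default 64).
#' @param overlap overlap between consecutive windows in pixels (default
#'   60); must be smaller than `window`.
#' @param anchor `"roi"` (default) anchors the lattice at the ROI bounding
#'   box, `"image"` at pixel (1, 1).
#' @return a `window_grid`: list with `window`, `overlap`, `stride`,
#'   `origins` (n x 2 integer matrix of 1-based top-left corners) and
#'   `shape`.
#' @export
tile_windows <- function(roi, window = 64L, overlap = 60L,
                         anchor = c("roi", "image")) {
  anchor <- match.arg(anchor)
  window <- as.integer(window); overlap <- as.integer(overlap)
  if (overlap >= window) stop("overlap must be smaller than the window")
  stride <- window - overlap
  h <- nrow(roi); w <- ncol(roi)
  if (!any(roi)) stop("empty ROI")
  rr <- range(which(rowSums(roi) > 0))
  cr <- range(which(colSums(roi) > 0))
  lattice_1d <- function(lo, hi) {
    extent <- hi - lo + 1L
    if (extent <= window) return(lo - (window - extent) %/% 2L)
    last_needed <- hi - window + 1L
    v <- seq.int(lo, last_needed, by = stride)
    if (v[length(v)] < last_needed) v <- c(v, last_needed)
    v
  }
  if (anchor == "roi") {
    orr <- lattice_1d(rr[1], rr[2])
    occ <- lattice_1d(cr[1], cr[2])
  } else {
    orr <- lattice_1d(1L, h)
    occ <- lattice_1d(1L, w)
  }
  # keep windows that intersect the ROI (integral image for rectangle sums)
  I <- matrix(0, h + 1L, w + 1L)
  I[-1, -1] <- t(apply(apply(roi * 1L, 2, cumsum), 1, cumsum))
  rect_sum <- function(r1, r2, c1, c2) {
    r1 <- max(r1, 1L); c1 <- max(c1, 1L); r2 <- min(r2, h); c2 <- min(c2, w)
    if (r1 > r2 || c1 > c2) return(0L)
    I[r2 + 1L, c2 + 1L] - I[r1, c2 + 1L] - I[r2 + 1L, c1] + I[r1, c1]
  }
  origins <- as.matrix(expand.grid(row = orr, col = occ))
  keep <- vapply(seq_len(nrow(origins)), function(i) {
    rect_sum(origins[i, 1], origins[i, 1] + window - 1L,
             origins[i, 2], origins[i, 2] + window - 1L) > 0
  }, logical(1))
  structure(list(window = window, overlap = overlap, stride = stride,
                 origins = origins[keep, , drop = FALSE], shape = c(h, w)),
            class = "window_grid")
}

#' Pixel-level voting over classified windows
#'
#' Every window casts one vote (its assigned class) on each ROI pixel it
#' covers. A pixel's per-class confidence is the proportion of windows
#' covering it that voted for that class; so a pixel covered by 10 windows
#' of which 8 were labeled CME gets CME confidence 0.8. Proportions sum to 1
#' wherever coverage is positive and are undefined (`NA`) elsewhere.
#'
#' @param grid a [tile_windows()] result.
#' @param window_labels one class name per window (character or factor),
#'   same order as `grid$origins`.
#' @param shape image shape `c(h, w)`; defaults to the grid's.
#' @param roi logical ROI matrix.
#' @param classes class set of the vote (default the four diagnostic
#'   classes).
#' @return an `oct_confmap`: list with `proportions` (h x w x n_classes
#'   array, `NA` outside the ROI or where coverage is 0), `coverage`
#'   (integer matrix of windows covering each pixel), `roi`, `window`,
#'   `overlap` and `classes`.
#' @export
vote_map <- function(grid, window_labels, shape = grid$shape, roi,
                     classes = oct_classes()) {
  stopifnot(inherits(grid, "window_grid"))
  n <- nrow(grid$origins)
  if (length(window_labels) != n)
    stop("one label per window required: got ", length(window_labels),
         " labels for ", n, " windows")
  window_labels <- as.character(window_labels)
  if (!all(window_labels %in% classes))
    stop("window labels outside the class set")
  h <- shape[1]; w <- shape[2]; wd <- grid$window
  counts <- array(0L, dim = c(h, w, length(classes)),
                  dimnames = list(NULL, NULL, classes))
  coverage <- matrix(0L, h, w)
  for (i in seq_len(n)) {
    r1 <- max(grid$origins[i, 1], 1L); r2 <- min(grid$origins[i, 1] + wd - 1L, h)
    c1 <- max(grid$origins[i, 2], 1L); c2 <- min(grid$origins[i, 2] + wd - 1L, w)
    if (r1 > r2 || c1 > c2) next
    k <- match(window_labels[i], classes)
    counts[r1:r2, c1:c2, k] <- counts[r1:r2, c1:c2, k] + 1L
    coverage[r1:r2, c1:c2] <- coverage[r1:r2, c1:c2] + 1L
  }
  denom <- coverage
  denom[denom == 0L] <- NA_integer_
  props <- counts / as.vector(denom)        # recycles over the class slab
  mask <- !roi
  for (k in seq_along(classes)) {
    slab <- props[, , k]
    slab[mask] <- NA_real_
    props[, , k] <- slab
  }
  structure(list(proportions = props, coverage = coverage, roi = roi,
                 window = grid$window, overlap = grid$overlap,
                 classes = classes),
            class = "oct_confmap")
}

#' Generate a confidence map for one image
#'
#' Tiles overlapping windows over the retina ROI, classifies each
#' mirror-completed window patch, and aggregates the hard window labels into
#' per-pixel class proportions with [vote_map()]. The classifier is either a
#' trained 4-class `oct_model` or, for testing and analysis, any function
#' `f(patches, origins)` returning one class name per window. The image
#' should come from a fold whose windows the model never saw in training.
#'
#' @param model an `oct_model` with 4 classes, or a stub classifier
#'   function.
#' @param image an `oct_image`.
#' @param window,overlap window geometry (defaults 64 px / 60 px, i.e.
#'   stride 4).
#' @param anchor lattice anchoring, see [tile_windows()].
#' @param batch_size classification chunk size.
#' @return an `oct_confmap`.
#' @export
generate_confidence_map <- function(model, image, window = 64L, overlap = 60L,
                                    anchor = "roi", batch_size = 256L) {
  stopifnot(inherits(image, "oct_image"))
  if (inherits(model, "oct_model") && model$n_classes != 4L)
    stop("confidence maps require a 4-class model")
  grid <- tile_windows(image$roi, window, overlap, anchor)
  n <- nrow(grid$origins)
  patches <- array(0, dim = c(window, window, n))
  for (i in seq_len(n))
    patches[, , i] <- crop_window_at(image$intensities, grid$origins[i, ], window)
  labels <- if (is.function(model)) {
    model(patches, grid$origins)
  } else {
    predict_label(model, patches, batch_size)
  }
  vote_map(grid, labels, shape = dim(image$labels), roi = image$roi)
}

#' Cold-to-warm palette with steep mid-range gradients
#'
#' Piecewise-linear RGB control points mapping confidence 0 (cold blue)
#' through 1 (warm red), with most of the color change concentrated between
#' confidence 0.35 and 0.65 so mid-range differences stand out. The red
#' channel is nondecreasing and the blue channel nonincreasing in
#' confidence.
#'
#' @return list with `points` (confidence knots) and `rgb` (3-column matrix
#'   of channel values at the knots).
#' @export
oct_palette <- function() {
  list(points = c(0, 0.35, 0.5, 0.65, 1),
       rgb = cbind(r = c(0.00, 0.15, 0.85, 0.95, 1.00),
                   g = c(0.10, 0.55, 0.90, 0.55, 0.10),
                   b = c(0.90, 0.85, 0.30, 0.10, 0.05)))
}

#' Render a confidence map as a color overlay
#'
#' Applies the cold-to-warm palette to one class's confidence and
#' alpha-blends it over the grayscale image inside the ROI; pixels outside
#' the ROI (or without coverage) show the underlying grayscale.
#'
#' @param conf an `oct_confmap`.
#' @param class one of the map's classes.
#' @param intensities grayscale background matrix (same shape).
#' @param alpha overlay opacity in `[0, 1]`.
#' @param palette palette description as in [oct_palette()].
#' @return h x w x 3 numeric array on `[0, 1]`.
#' @export
render_map <- function(conf, class, intensities, alpha = 0.6,
                       palette = oct_palette()) {
  stopifnot(inherits(conf, "oct_confmap"))
  if (!class %in% conf$classes) stop("unknown class: ", class)
  vals <- conf$proportions[, , class]
  h <- nrow(vals); w <- ncol(vals)
  out <- array(rep(intensities, 3L), dim = c(h, w, 3L))
  sel <- !is.na(vals)
  v <- vals[sel]
  for (k in 1:3) {
    col <- stats::approx(palette$points, palette$rgb[, k], xout = v,
                         rule = 2)$y
    slab <- out[, , k]
    slab[sel] <- alpha * col + (1 - alpha) * slab[sel]
    out[, , k] <- slab
  }
  out
}

#' Write a confidence map to disk
#'
#' One grayscale PNG per class (confidence scaled to the full 8-bit range;
#' `NA` rendered 0), a JSON sidecar with the window geometry and coverage
#' statistics, and an RGB overlay PNG per class.
#'
#' @param conf an `oct_confmap`.
#' @param intensities grayscale background for the overlays.
#' @param dir output directory.
#' @param id file prefix.
#' @return invisibly, the sidecar path.
#' @export
write_confidence_map <- function(conf, intensities, dir, id = "map") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in conf$classes) {
    v <- conf$proportions[, , cl]
    v[is.na(v)] <- 0
    png::writePNG(v, file.path(dir, sprintf("%s_%s.png", id, cl)))
    png::writePNG(render_map(conf, cl, intensities),
                  file.path(dir, sprintf("%s_%s_overlay.png", id, cl)))
  }
  sidecar <- file.path(dir, paste0(id, ".json"))
  jsonlite::write_json(
    list(window = conf$window, overlap = conf$overlap,
         classes = conf$classes,
         coverage = list(min = min(conf$coverage[conf$roi]),
                         max = max(conf$coverage),
                         mean = mean(conf$coverage[conf$roi]))),
    sidecar, auto_unbox = TRUE)
  invisible(sidecar)
}
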