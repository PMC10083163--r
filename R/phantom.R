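#' Configuration for synthetic layered-retina phantoms
#'
#' Describes an OCT-like B-scan phantom: a retina band bounded by two smooth
#' curves (an ILM-like curve above and an RPE-like curve below), healthy
#' layered tissue inside the band, and optional planted fluid regions for
#' each pathological class. Each pathological region is surrounded by an
#' "uncertainty" halo, emulating expert labeling protocols in which border
#' pixels are never assigned a definite class.
#'
#' Region appearance is controlled per label by `texture_params`: a mean
#' reflectivity, a Gaussian texture standard deviation, and a pattern kind
#' (hyporeflective blobs for CME, diffuse speckle for DRT, a dome resting on
#' the retinal floor for SRD). All intensities are on `[0, 1]` before
#' quantization.
#'
#' @param height,width image size in pixels; both must be at least 128 so a
#'   64x64 analysis window always fits.
#' @param n_layers number of sinusoidal reflectivity bands drawn inside
#'   healthy tissue to mimic the layered retina.
#' @param class_prevalences named probabilities (`CME`, `DRT`, `SRD`) that a
#'   region of that class is planted in an image.
#' @param diffuse_uncertainty_p probability of planting one standalone
#'   diffuse uncertainty patch (uncertainty not attached to any region
#'   border).
#' @param texture_params named list of per-label `list(mean, sd)` entries on
#'   the unit intensity scale; labels `healthy`, `CME`, `DRT`, `SRD`,
#'   `uncertainty`, `vitreous`, `choroid`.
#' @param speckle_sd standard deviation of the multiplicative log-normal
#'   speckle field applied to every pixel (OCT noise is speckle-dominated).
#' @param uncertainty_halo halo width in pixels (Chebyshev distance) of the
#'   uncertainty band around each planted pathological region; 0 disables
#'   halos.
#' @param contrast minimum guaranteed absolute difference between the healthy
#'   mean reflectivity and each pathological mean (checked at construction).
#' @param bit_depth 8 (default) or 16; quantization applied to intensities.
#' @param seed default RNG seed used when `generate_phantom()` is called
#'   without one.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(height = 160L, width = 256L, n_layers = 4L,
                           class_prevalences = c(CME = 0.8, DRT = 0.6, SRD = 0.5),
                           diffuse_uncertainty_p = 0.25,
                           texture_params = NULL,
                           speckle_sd = 0.12,
                           uncertainty_halo = 3L,
                           contrast = 0.2,
                           bit_depth = 8L,
                           seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 128L || width < 128L)
    stop("phantom dimensions must be >= 128 px so a 64x64 window fits")
  if (any(class_prevalences < 0) || any(class_prevalences > 1))
    stop("class prevalences must lie in [0, 1]")
  if (uncertainty_halo < 0) stop("uncertainty_halo must be >= 0")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  defaults <- list(
    healthy     = list(mean = 0.58, sd = 0.05),
    CME         = list(mean = 0.10, sd = 0.04),
    DRT         = list(mean = 0.38, sd = 0.13),
    SRD         = list(mean = 0.16, sd = 0.05),
    uncertainty = list(mean = 0.45, sd = 0.10),
    vitreous    = list(mean = 0.06, sd = 0.02),
    choroid     = list(mean = 0.30, sd = 0.06)
  )
  if (!is.null(texture_params)) defaults[names(texture_params)] <- texture_params
  for (cls in c("CME", "DRT", "SRD")) {
    if (abs(defaults$healthy$mean - defaults[[cls]]$mean) < contrast - 1e-9)
      stop(sprintf("texture means for healthy and %s differ by < contrast", cls))
  }
  prev <- c(CME = 0, DRT = 0, SRD = 0)
  prev[names(class_prevalences)] <- class_prevalences
  structure(list(height = height, width = width, n_layers = as.integer(n_layers),
                 class_prevalences = prev,
                 diffuse_uncertainty_p = diffuse_uncertainty_p,
                 texture_params = defaults, speckle_sd = speckle_sd,
                 uncertainty_halo = as.integer(uncertainty_halo),
                 contrast = contrast, bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Smooth random curve through a handful of jittered control points,
# interpolated with a natural cubic spline (one value per image column).
smooth_curve <- function(width, base, jitter) {
  k <- 5L
  xs <- seq(1, width, length.out = k)
  ys <- base + rnorm(k, 0, jitter)
  stats::spline(xs, ys, xout = seq_len(width), method = "natural")$y
}

# Try to place an ellipse of label `code` inside the ROI band, rejecting
# positions that collide with existing pathological tissue (plus a halo
# margin). Axes shrink on successive retries so placement always succeeds
# on reasonably sized phantoms.
place_ellipse <- function(labels, y_top, y_bot, code, rx_range, ry_range,
                          margin, max_try = 25L) {
  h <- nrow(labels); w <- ncol(labels)
  path <- labels >= OCT_LABEL_CODES[["CME"]] & labels <= OCT_LABEL_CODES[["SRD"]]
  for (tr in seq_len(max_try)) {
    shrink <- 1 - 0.6 * (tr - 1) / max_try
    rx <- max(4L, round(runif(1, rx_range[1], rx_range[2]) * shrink))
    ry <- max(3L, round(runif(1, ry_range[1], ry_range[2]) * shrink))
    cx <- round(runif(1, rx + 2, w - rx - 1))
    span <- max(1L, cx - rx):min(w, cx + rx)
    top_lim <- max(y_top[span]) + ry + margin + 1
    bot_lim <- min(y_bot[span]) - ry - margin - 1
    if (top_lim >= bot_lim) next
    cy <- round(runif(1, top_lim, bot_lim))
    rows <- (cy - ry):(cy + ry); cols <- (cx - rx):(cx + rx)
    rr <- outer(rows, cols, function(r, c) ((r - cy) / ry)^2 + ((c - cx) / rx)^2)
    sel <- rr <= 1
    # collision check against existing pathological regions incl. margin
    rows_m <- max(1L, cy - ry - margin):min(h, cy + ry + margin)
    cols_m <- max(1L, cx - rx - margin):min(w, cx + rx + margin)
    if (any(path[rows_m, cols_m])) next
    block <- labels[rows, cols]
    block[sel] <- code
    labels[rows, cols] <- block
    return(list(labels = labels, placed = TRUE))
  }
  list(labels = labels, placed = FALSE)
}

# SRD dome: half-ellipse resting on the RPE-like floor of the ROI.
place_dome <- function(labels, y_top, y_bot, code, margin, max_try = 25L) {
  h <- nrow(labels); w <- ncol(labels)
  path <- labels >= OCT_LABEL_CODES[["CME"]] & labels <= OCT_LABEL_CODES[["SRD"]]
  for (tr in seq_len(max_try)) {
    shrink <- 1 - 0.6 * (tr - 1) / max_try
    hw <- max(8L, round(runif(1, 18, 42) * shrink))
    cx <- round(runif(1, hw + 2, w - hw - 1))
    span <- max(1L, cx - hw):min(w, cx + hw)
    max_h <- min(y_bot[span] - y_top[span]) - margin - 4
    if (max_h < 6) next
    dome_h <- round(runif(1, 6, min(max_h, 30)))
    cand <- matrix(FALSE, h, w)
    for (c in span) {
      prof <- dome_h * sqrt(pmax(0, 1 - ((c - cx) / hw)^2))
      if (prof < 1) next
      r1 <- max(1L, round(y_bot[c] - prof)); r2 <- min(h, floor(y_bot[c]))
      cand[r1:r2, c] <- TRUE
    }
    rows_m <- max(1L, min(which(rowSums(cand) > 0)) - margin)
    rows_M <- min(h, max(which(rowSums(cand) > 0)) + margin)
    cols_m <- max(1L, cx - hw - margin); cols_M <- min(w, cx + hw + margin)
    if (any(path[rows_m:rows_M, cols_m:cols_M])) next
    labels[cand] <- code
    return(list(labels = labels, placed = TRUE))
  }
  list(labels = labels, placed = FALSE)
}

#' Generate one synthetic OCT-like labeled image
#'
#' Builds the retina band between two smooth random boundary curves, plants
#' pathological regions according to the configured prevalences, relabels a
#' halo of configurable Chebyshev width around each planted region as
#' uncertainty, and synthesizes intensities as per-label Gaussian texture
#' under multiplicative log-normal speckle. Deterministic given
#' `(config, seed)`.
#'
#' @param config a [phantom_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @param image_id identifier stored with the image.
#' @return an object of class `oct_image`: list with `intensities` (numeric
#'   matrix on `[0,1]`, quantized to the configured bit depth), `labels`
#'   (integer matrix with codes 0 outside, 1 healthy, 2 CME, 3 DRT, 4 SRD,
#'   5 uncertainty), `roi` (logical matrix), `image_id`, and a `planted`
#'   logical vector naming which pathological classes were placed.
#' @export
generate_phantom <- function(config, seed = config$seed, image_id = "phantom") {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$height; w <- config$width
  with_seed(seed, {
    y_top <- smooth_curve(w, 0.22 * h, 0.03 * h)
    thick <- smooth_curve(w, 0.50 * h, 0.02 * h)
    thick <- pmax(thick, 72)                      # band must host regions + halos
    y_bot <- pmin(y_top + thick, h - 4)
    y_top <- pmax(pmin(y_top, y_bot - 72), 2)
    row_idx <- matrix(seq_len(h), h, w)
    roi <- sweep(row_idx, 2, y_top, ">=") & sweep(row_idx, 2, y_bot, "<=")

    labels <- matrix(OCT_LABEL_CODES[["outside"]], h, w)
    labels[roi] <- OCT_LABEL_CODES[["healthy"]]
    halo <- config$uncertainty_halo
    margin <- halo + 2L
    planted <- c(CME = FALSE, DRT = FALSE, SRD = FALSE)

    if (runif(1) < config$class_prevalences[["CME"]]) {
      for (i in seq_len(sample(1:3, 1))) {
        res <- place_ellipse(labels, y_top, y_bot, OCT_LABEL_CODES[["CME"]],
                             c(6, 18), c(4, 11), margin)
        labels <- res$labels; planted[["CME"]] <- planted[["CME"]] || res$placed
      }
    }
    if (runif(1) < config$class_prevalences[["DRT"]]) {
      res <- place_ellipse(labels, y_top, y_bot, OCT_LABEL_CODES[["DRT"]],
                           c(18, 40), c(7, 14), margin)
      labels <- res$labels; planted[["DRT"]] <- res$placed
    }
    if (runif(1) < config$class_prevalences[["SRD"]]) {
      res <- place_dome(labels, y_top, y_bot, OCT_LABEL_CODES[["SRD"]], margin)
      labels <- res$labels; planted[["SRD"]] <- res$placed
    }

    # uncertainty halos: Chebyshev dilation of the pathological mask minus
    # the regions themselves, restricted to the ROI
    if (halo > 0L && any(planted)) {
      path <- labels >= OCT_LABEL_CODES[["CME"]] & labels <= OCT_LABEL_CODES[["SRD"]]
      dil <- EBImage::dilate(EBImage::Image(path * 1),
                             EBImage::makeBrush(2L * halo + 1L, "box"))
      ring <- (dil > 0) & !path & roi
      labels[ring] <- OCT_LABEL_CODES[["uncertainty"]]
    }
    if (runif(1) < config$diffuse_uncertainty_p) {
      res <- place_ellipse(labels, y_top, y_bot, OCT_LABEL_CODES[["uncertainty"]],
                           c(10, 24), c(5, 10), margin)
      labels <- res$labels
    }

    tp <- config$texture_params
    base <- matrix(0, h, w)
    above <- sweep(row_idx, 2, y_top, "<")
    below <- sweep(row_idx, 2, y_bot, ">")
    base[above] <- tp$vitreous$mean + rnorm(sum(above), 0, tp$vitreous$sd)
    base[below] <- tp$choroid$mean + rnorm(sum(below), 0, tp$choroid$sd)
    for (lab in c("healthy", "CME", "DRT", "SRD", "uncertainty")) {
      sel <- labels == OCT_LABEL_CODES[[lab]]
      if (any(sel)) base[sel] <- tp[[lab]]$mean + rnorm(sum(sel), 0, tp[[lab]]$sd)
    }
    # layered-retina banding inside healthy tissue
    if (config$n_layers > 0) {
      depth <- sweep(row_idx, 2, y_top, "-") / rep(pmax(y_bot - y_top, 1), each = h)
      band <- 0.07 * sin(2 * pi * config$n_layers * depth)
      sel <- labels == OCT_LABEL_CODES[["healthy"]]
      base[sel] <- base[sel] + band[sel]
    }
    speckle <- exp(rnorm(h * w, 0, config$speckle_sd))
    intens <- pmin(pmax(base * speckle, 0), 1)
    levels <- 2^config$bit_depth - 1
    intens <- round(intens * levels) / levels

    structure(list(intensities = intens, labels = labels, roi = roi,
                   image_id = image_id, planted = planted,
                   bit_depth = config$bit_depth),
              class = "oct_image")
  })
}

#' Generate a dataset of phantoms with per-image sub-seeds
#'
#' @param n_images number of phantoms (>= 1).
#' @param config a [phantom_config()].
#' @param seed master seed; per-image seeds are derived from it, so the whole
#'   list is reproducible.
#' @return list of [generate_phantom()] results with ids `phantom_0001`, ...
#' @export
generate_dataset <- function(n_images, config, seed = config$seed) {
  if (n_images < 1) stop("n_images must be >= 1")
  seeds <- derive_seeds(seed, n_images)
  lapply(seq_len(n_images), function(i) {
    generate_phantom(config, seed = seeds[i],
                     image_id = sprintf("phantom_%04d", i))
  })
}

#' Write a labeled phantom to disk as plain PNG files
#'
#' Intensities go to `<id>_image.png` (grayscale), labels to
#' `<id>_labels.png` (8-bit grayscale whose pixel values are the palette
#' codes 0-5), and the ROI to `<id>_roi.png` (binary).
#'
#' @param image an `oct_image`.
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_labeled_image <- function(image, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    image  = file.path(dir, paste0(image$image_id, "_image.png")),
    labels = file.path(dir, paste0(image$image_id, "_labels.png")),
    roi    = file.path(dir, paste0(image$image_id, "_roi.png"))
  )
  png::writePNG(image$intensities, paths[["image"]])
  png::writePNG(image$labels / 255, paths[["labels"]])
  png::writePNG(image$roi * 1, paths[["roi"]])
  invisible(paths)
}

#' Read a labeled image triplet written by [write_labeled_image()]
#'
#' @param dir directory containing the PNG triplet.
#' @param image_id image identifier (file prefix).
#' @return an `oct_image`.
#' @export
read_labeled_image <- function(dir, image_id) {
  as_gray <- function(x) if (length(dim(x)) == 3L) x[, , 1L] else x
  intens <- as_gray(png::readPNG(file.path(dir, paste0(image_id, "_image.png"))))
  labels <- round(as_gray(png::readPNG(file.path(dir, paste0(image_id, "_labels.png")))) * 255)
  roi <- as_gray(png::readPNG(file.path(dir, paste0(image_id, "_roi.png")))) > 0.5
  structure(list(intensities = intens, labels = matrix(as.integer(labels),
                                                       nrow(labels), ncol(labels)),
                 roi = roi, image_id = image_id,
                 planted = NULL, bit_depth = 8L),
            class = "oct_image")
}

#' Write a dataset manifest (one row per image)
#'
#' @param images list of `oct_image`.
#' @param dir directory where the images were written.
#' @return invisibly, the manifest data frame (also written to
#'   `manifest.csv` in `dir`).
#' @export
write_dataset_manifest <- function(images, dir) {
  rows <- lapply(images, function(im) {
    data.frame(image_id = im$image_id,
               image = paste0(im$image_id, "_image.png"),
               labels = paste0(im$image_id, "_labels.png"),
               roi = paste0(im$image_id, "_roi.png"),
               has_CME = any(im$labels == OCT_LABEL_CODES[["CME"]]),
               has_DRT = any(im$labels == OCT_LABEL_CODES[["DRT"]]),
               has_SRD = any(im$labels == OCT_LABEL_CODES[["SRD"]]),
               has_uncertainty = any(im$labels == OCT_LABEL_CODES[["uncertainty"]]))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
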