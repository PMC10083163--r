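#' Per-connected-component maximum confidence
#'
#' Labels the 4-connected components of one class in a reference mask and,
#' for each component, records its pixel size and the maximum of that
#' class's confidence over the component's pixels. Pixels without a defined
#' confidence (no coverage) are ignored in the maximum; a component whose
#' pixels are all undefined gets `NA`.
#'
#' @param reference_mask integer label matrix (palette codes, see
#'   [generate_phantom()]) or a logical matrix already selecting the class.
#' @param conf an `oct_confmap` with the same geometry.
#' @param class one of the map's classes.
#' @param image_id identifier copied into the records.
#' @return data frame with columns `class`, `component`, `size`,
#'   `max_confidence`, `image_id` (zero rows when the class is absent).
#' @export
cc_max_confidence <- function(reference_mask, conf, class, image_id = NA_character_) {
  stopifnot(inherits(conf, "oct_confmap"))
  if (!class %in% conf$classes) stop("unknown class: ", class)
  mask <- if (is.logical(reference_mask)) reference_mask
          else reference_mask == OCT_LABEL_CODES[[class]]
  if (!all(dim(mask) == dim(conf$coverage)))
    stop("mask and map geometries differ")
  empty <- data.frame(class = character(0), component = integer(0),
                      size = integer(0), max_confidence = numeric(0),
                      image_id = character(0))
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask * 1)          # 4-connected labeling
  lab <- as.matrix(EBImage::imageData(lab))
  vals <- conf$proportions[, , class]
  ids <- sort(unique(lab[lab > 0]))
  rows <- lapply(ids, function(id) {
    px <- lab == id
    v <- vals[px]
    v <- v[!is.na(v)]
    data.frame(class = class, component = as.integer(id),
               size = sum(px),
               max_confidence = if (length(v)) max(v) else NA_real_,
               image_id = image_id)
  })
  do.call(rbind, rows)
}

#' Sliding-median trend of confidence versus component size
#'
#' Medians of `conf` are taken over sliding size windows `[s, s + range)`
#' advanced by `step`; empty windows are skipped. The support points
#' (window midpoint, median) are then smoothed by an interpolating b-spline
#' of degree 3 evaluated at `resolution` equally spaced sizes. With fewer
#' support points than the spline needs (`spline_degree + 1`), the raw
#' medians are returned and the `smoothed` flag is `FALSE` (with a warning).
#'
#' @param points data frame with columns `size` and a confidence column
#'   (`max_confidence` or `conf`), e.g. from [cc_max_confidence()].
#' @param window_range size range covered by each sliding window (default
#'   1000 px).
#' @param step window advance (default 10).
#' @param spline_degree b-spline degree (cubic).
#' @param resolution number of evaluation points of the smoothed curve.
#' @return a `trend_curve`: list with `support` (data frame `size`,
#'   `median_conf`), `curve` (data frame `size`, `conf`), and `smoothed`.
#' @export
trend_line <- function(points, window_range = 1000, step = 10,
                       spline_degree = 3L, resolution = 10L) {
  confcol <- intersect(c("max_confidence", "conf"), names(points))[1]
  if (is.na(confcol)) stop("points must carry a confidence column")
  sizes <- points$size
  confs <- points[[confcol]]
  keep <- !is.na(confs)
  sizes <- sizes[keep]; confs <- confs[keep]
  if (length(sizes) == 0L) stop("no usable points")
  starts <- seq(floor(min(sizes)), max(sizes), by = step)
  sup <- lapply(starts, function(s) {
    inw <- sizes >= s & sizes < s + window_range
    if (!any(inw)) return(NULL)
    data.frame(size = s + window_range / 2, median_conf = stats::median(confs[inw]))
  })
  sup <- do.call(rbind, sup)
  sup <- sup[!duplicated(sup$size), , drop = FALSE]
  smoothed <- FALSE
  if (nrow(sup) >= spline_degree + 1L && nrow(sup) >= 4L) {
    isp <- splines::interpSpline(sup$size, sup$median_conf)
    xs <- seq(min(sup$size), max(sup$size), length.out = resolution)
    curve <- data.frame(size = xs, conf = stats::predict(isp, xs)$y)
    smoothed <- TRUE
  } else {
    warning("too few sliding-window support points for the spline; returning raw medians")
    curve <- data.frame(size = sup$size, conf = sup$median_conf)
  }
  structure(list(support = sup, curve = curve, smoothed = smoothed),
            class = "trend_curve")
}

#' Scatter-and-trend analysis of confidence maps
#'
#' Convenience wrapper: collects [cc_max_confidence()] records for one class
#' over several (mask, map) pairs and fits the [trend_line()].
#'
#' @param images list of `oct_image`.
#' @param maps list of `oct_confmap`, parallel to `images`.
#' @param class class to analyze.
#' @param ... passed to [trend_line()].
#' @return list with `records` (combined data frame) and `trend` (a
#'   `trend_curve`, or `NULL` when fewer than 2 components were found).
#' @export
analyze_maps <- function(images, maps, class, ...) {
  stopifnot(length(images) == length(maps))
  recs <- do.call(rbind, lapply(seq_along(images), function(i) {
    cc_max_confidence(images[[i]]$labels, maps[[i]], class,
                      image_id = images[[i]]$image_id)
  }))
  trend <- if (!is.null(recs) && nrow(recs) >= 2L)
    tryCatch(trend_line(recs, ...), error = function(e) NULL) else NULL
  list(records = recs, trend = trend)
}

#' Write component records and trend to CSV
#'
#' @param analysis result of [analyze_maps()].
#' @param dir output directory.
#' @param id file prefix.
#' @return invisibly, the record CSV path.
#' @export
write_map_analysis <- function(analysis, dir, id = "analysis") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(id, "_components.csv"))
  utils::write.csv(analysis$records, path, row.names = FALSE)
  if (!is.null(analysis$trend)) {
    utils::write.csv(analysis$trend$support,
                     file.path(dir, paste0(id, "_trend_support.csv")),
                     row.names = FALSE)
    utils::write.csv(analysis$trend$curve,
                     file.path(dir, paste0(id, "_trend_curve.csv")),
                     row.names = FALSE)
  }
  invisible(path)
}
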