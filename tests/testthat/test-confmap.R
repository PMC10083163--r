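test_that("window geometry: stride, coverage counts, degenerate overlaps", {
  roi <- matrix(TRUE, 128, 128)
  g <- tile_windows(roi, 64, 60)
  expect_identical(g$stride, 4L)
  expect_error(tile_windows(roi, 64, 64), "overlap")
  expect_error(tile_windows(roi, 64, 70), "overlap")
  # interior pixel of a full-rectangle ROI is covered by 16x16 lattice windows
  labels <- rep("CME", nrow(g$origins))
  m <- vote_map(g, labels, roi = roi)
  expect_identical(m$coverage[64, 64], 256L)
  # non-overlapping tiling covers interior pixels exactly once
  g0 <- tile_windows(roi, 32, 0)
  m0 <- vote_map(g0, rep("healthy", nrow(g0$origins)), roi = roi)
  expect_true(all(m0$coverage == 1L))
})

test_that("every ROI pixel is covered on curved phantom ROIs", {
  img <- fixture_images(2)[[1]]
  g <- tile_windows(img$roi, 64, 60)
  m <- vote_map(g, rep("healthy", nrow(g$origins)), roi = img$roi)
  expect_true(all(m$coverage[img$roi] > 0L))
})

test_that("voting yields the stated proportion semantics (8 of 10 -> 0.8)", {
  # ten windows, all containing pixel (10, 10); 8 labeled CME, 2 healthy
  origins <- cbind(row = rep(1:5, 2), col = rep(c(1, 6), each = 5))
  grid <- structure(list(window = 10L, overlap = NA_integer_, stride = NA_integer_,
                         origins = origins, shape = c(24L, 24L)),
                    class = "window_grid")
  roi <- matrix(TRUE, 24, 24)
  labels <- c(rep("CME", 8), rep("healthy", 2))
  m <- vote_map(grid, labels, shape = c(24L, 24L), roi = roi)
  expect_identical(m$coverage[10, 10], 10L)
  expect_equal(unname(m$proportions[10, 10, "CME"]), 0.8)
  expect_equal(unname(m$proportions[10, 10, "healthy"]), 0.2)
  expect_equal(sum(m$proportions[10, 10, ]), 1)
})

test_that("per-pixel proportions sum to one wherever coverage is positive", {
  img <- fixture_images(2)[[2]]
  g <- tile_windows(img$roi, 64, 56)
  set.seed(4)
  labels <- sample(oct_classes(), nrow(g$origins), replace = TRUE)
  m <- vote_map(g, labels, roi = img$roi)
  s <- apply(m$proportions, c(1, 2), sum)
  covered <- img$roi & m$coverage > 0
  expect_true(all(abs(s[covered] - 1) < 1e-12))
  expect_true(all(is.na(s[!img$roi])))
})

test_that("vote_map equals the brute-force per-pixel recount", {
  set.seed(9)
  roi <- matrix(FALSE, 40, 48)
  roi[8:35, 5:44] <- TRUE
  g <- tile_windows(roi, 16, 12)
  labels <- sample(oct_classes(), nrow(g$origins), replace = TRUE)
  m <- vote_map(g, labels, shape = c(40L, 48L), roi = roi)
  oracle <- vote_oracle(g, labels, c(40L, 48L), roi, oct_classes())
  expect_identical(m$coverage, oracle$coverage)
  expect_equal(m$proportions, oracle$proportions, ignore_attr = TRUE)
})

test_that("coverage never decreases when the overlap grows", {
  roi <- matrix(TRUE, 96, 96)
  cov_of <- function(ov) {
    g <- tile_windows(roi, 32, ov)
    vote_map(g, rep("DRT", nrow(g$origins)), roi = roi)$coverage
  }
  c0 <- cov_of(0); c16 <- cov_of(16); c24 <- cov_of(24)
  expect_true(all(c16 >= c0))
  expect_true(all(c24 >= c16))
})

test_that("label list mismatches and bad classes are rejected", {
  roi <- matrix(TRUE, 128, 128)
  g <- tile_windows(roi, 64, 60)
  expect_error(vote_map(g, c("CME", "DRT"), roi = roi), "one label per window")
  expect_error(vote_map(g, rep("lesion", nrow(g$origins)), roi = roi),
               "class set")
})

test_that("stub-classified maps match a direct recomputation and are deterministic", {
  img <- fixture_images(2)[[1]]
  stub <- function(patches, origins) {
    ctr <- origins + 31L
    lab <- img$labels[cbind(pmin(pmax(ctr[, 1], 1), nrow(img$labels)),
                            pmin(pmax(ctr[, 2], 1), ncol(img$labels)))]
    c("healthy", "healthy", "CME", "DRT", "SRD", "healthy")[lab + 1L]
  }
  m1 <- generate_confidence_map(stub, img)
  m2 <- generate_confidence_map(stub, img)
  expect_identical(m1, m2)
  # class proportions peak inside matching regions (interior classes; an
  # SRD dome hugging the ROI floor lies below the deepest window center)
  for (cl in c("CME", "DRT")) {
    inside <- img$labels == octfluid:::OCT_LABEL_CODES[[cl]]
    if (!any(inside)) next
    v_in <- mean(m1$proportions[, , cl][inside], na.rm = TRUE)
    healthy_px <- img$labels == 1L
    v_out <- mean(m1$proportions[, , cl][healthy_px], na.rm = TRUE)
    expect_gt(v_in, v_out)
  }
  # constant classifier: proportion 1 for that class on all covered ROI
  mc <- generate_confidence_map(function(p, o) rep("DRT", nrow(o)), img)
  vals <- mc$proportions[, , "DRT"][img$roi & mc$coverage > 0]
  expect_true(all(vals == 1))
  # a trained-model path requires 4 classes
  m2c <- build_backbone(tiny_backbone(n_classes = 2))
  expect_error(generate_confidence_map(m2c, img), "4-class")
})

test_that("rendering is cold at 0, warm at 1, monotone along a confidence ramp", {
  roi <- matrix(TRUE, 20, 30)
  base <- matrix(0.5, 20, 30)
  mk <- function(vals) {
    props <- array(NA_real_, dim = c(20, 30, 4),
                   dimnames = list(NULL, NULL, oct_classes()))
    props[, , "CME"] <- vals
    structure(list(proportions = props, coverage = matrix(1L, 20, 30),
                   roi = roi, window = 64L, overlap = 60L,
                   classes = oct_classes()),
              class = "oct_confmap")
  }
  cold <- render_map(mk(matrix(0, 20, 30)), "CME", base, alpha = 1)
  warm <- render_map(mk(matrix(1, 20, 30)), "CME", base, alpha = 1)
  expect_true(all(cold[, , 3] > cold[, , 1]))   # blue dominates at 0
  expect_true(all(warm[, , 1] > warm[, , 3]))   # red dominates at 1
  ramp <- matrix(rep(seq(0, 1, length.out = 30), each = 20), 20, 30)
  img <- render_map(mk(ramp), "CME", base, alpha = 1)
  expect_true(all(diff(img[10, , 1]) >= 0))     # red nondecreasing
  expect_true(all(diff(img[10, , 3]) <= 0))     # blue nonincreasing
  expect_error(render_map(mk(ramp), "lesion", base), "unknown class")
  # outside-ROI pixels show the grayscale background
  roi2 <- roi; roi2[, 1:5] <- FALSE
  m <- mk(ramp); m$roi <- roi2
  m$proportions[, 1:5, ] <- NA_real_
  out <- render_map(m, "CME", base, alpha = 1)
  expect_true(all(out[, 1:5, ] == 0.5))
})

test_that("confidence maps persist with a JSON sidecar", {
  dir <- withr::local_tempdir()
  img <- fixture_images(2)[[1]]
  m <- generate_confidence_map(function(p, o) rep("CME", nrow(o)), img)
  sidecar <- write_confidence_map(m, img$intensities, dir, id = "t")
  expect_true(file.exists(sidecar))
  expect_true(file.exists(file.path(dir, "t_CME.png")))
  meta <- jsonlite::read_json(sidecar)
  expect_identical(meta$window, 64L)
  expect_identical(meta$overlap, 60L)
})
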