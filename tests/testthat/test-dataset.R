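test_that("interior crops are verbatim sub-grids", {
  m <- matrix(seq_len(40 * 50), 40, 50)
  p <- crop_with_mirror(m, c(20, 25), 8)
  expect_identical(p, m[16:23, 21:28])
})

test_that("border crops match the index-reflection oracle", {
  set.seed(3)
  m <- matrix(rnorm(30 * 26), 30, 26)
  for (ctr in list(c(1, 1), c(1, 26), c(30, 1), c(15, 2), c(2, 13), c(30, 26))) {
    expect_equal(crop_with_mirror(m, ctr, 12), crop_oracle(m, ctr, 12))
  }
  # a ramp image: top-left corner crop reflects the in-image quadrant
  ramp <- outer(1:20, 1:20, "+")
  expect_equal(crop_with_mirror(ramp, c(1, 1), 8), crop_oracle(ramp, c(1, 1), 8))
})

test_that("constant images give constant patches at any border center", {
  m <- matrix(0.7, 25, 25)
  expect_true(all(crop_with_mirror(m, c(1, 1), 10) == 0.7))
  expect_true(all(crop_with_mirror(m, c(25, 13), 10) == 0.7))
})

test_that("crop errors on invalid centers and oversized windows", {
  m <- matrix(0, 20, 20)
  expect_error(crop_with_mirror(m, c(0, 5), 8), "outside")
  expect_error(crop_with_mirror(m, c(5, 21), 8), "outside")
  expect_error(crop_with_mirror(m, c(10, 10), 40), "mirroring")
})

test_that("extraction takes n_per_label samples per present label", {
  img <- fixture_images(2)[[1]]
  present <- intersect(1:5, unique(as.vector(img$labels)))
  s <- extract_samples(img, n_per_label = 25, window = 64, seed = 5)
  expect_identical(length(s$label), 25L * length(present))
  expect_true(all(table(droplevels(s$label)) == 25))
  # center-label fidelity
  codes <- c(healthy = 1L, CME = 2L, DRT = 3L, SRD = 4L, uncertainty = 5L)
  got <- img$labels[s$center]
  expect_identical(unname(codes[as.character(s$label)]), got)
})

test_that("a single-label image yields only that label", {
  cfg <- phantom_config(class_prevalences = c(CME = 0, DRT = 0, SRD = 0),
                        diffuse_uncertainty_p = 0, seed = 2)
  img <- generate_phantom(cfg)
  s <- extract_samples(img, n_per_label = 25, seed = 1)
  expect_identical(length(s$label), 25L)
  expect_true(all(s$label == "healthy"))
})

test_that("scarce labels give all available centers without replacement", {
  img <- generate_phantom(phantom_config(
    class_prevalences = c(CME = 0, DRT = 0, SRD = 0),
    diffuse_uncertainty_p = 0, seed = 2))
  # plant exactly 7 SRD pixels inside the ROI
  px <- which(img$roi)[100:106]
  img$labels[px] <- 4L
  s <- extract_samples(img, n_per_label = 25, seed = 9)
  srd <- s$label == "SRD"
  expect_identical(sum(srd), 7L)
  ctr <- s$center[srd, , drop = FALSE]
  expect_identical(anyDuplicated(paste(ctr[, 1], ctr[, 2])), 0L)
  expect_setequal(ctr[, 1] + (ctr[, 2] - 1L) * nrow(img$labels), px)
})

test_that("extraction is deterministic and patches are mirror-completed", {
  img <- fixture_images(2)[[2]]
  s1 <- extract_samples(img, n_per_label = 10, window = 64, seed = 42)
  s2 <- extract_samples(img, n_per_label = 10, window = 64, seed = 42)
  expect_identical(s1, s2)
  i <- 1L
  expect_equal(s1$patches[, , i],
               crop_oracle(img$intensities, s1$center[i, ], 64))
})

test_that("folds partition images as evenly as possible", {
  ids <- sprintf("img%03d", 1:356)
  f <- make_folds(ids, k = 6, seed = 1)
  expect_setequal(names(f), ids)
  expect_identical(sort(as.integer(table(f)), decreasing = TRUE),
                   c(60L, 60L, 59L, 59L, 59L, 59L))
  f6 <- make_folds(sprintf("i%d", 1:6), k = 6, seed = 2)
  expect_true(all(table(f6) == 1))
  expect_error(make_folds(sprintf("i%d", 1:5), k = 6), "fewer")
})

test_that("experiment enumeration matches brute force and the 3/2/1 count", {
  sp <- enumerate_experiments(6, 3, 2, 1)
  expect_length(sp, 60L)
  # each split partitions the folds; all splits distinct
  keys <- vapply(sp, function(s) {
    expect_setequal(c(s$train, s$val, s$test), 1:6)
    paste(paste(s$train, collapse = ","), paste(s$val, collapse = ","),
          s$test, sep = "|")
  }, character(1))
  expect_identical(anyDuplicated(keys), 0L)
  expect_length(enumerate_experiments(3, 1, 1, 1), 6L)
  expect_length(enumerate_experiments(2, 1, 0, 1), 2L)
  expect_error(enumerate_experiments(6, 3, 3, 1), "sum")
  # brute-force count check for k <= 7
  for (k in 4:7) {
    n_tr <- k - 3L
    got <- length(enumerate_experiments(k, n_tr, 2, 1))
    expect_equal(got, choose(k, n_tr) * choose(k - n_tr, 2))
  }
})

test_that("no split leaks an image across roles", {
  folds <- fixture_folds(8, k = 4)
  samples <- fixture_samples(8)
  for (s in enumerate_experiments(4, 2, 1, 1)) {
    ids_tr <- unique(samples$image_id[folds[samples$image_id] %in% s$train])
    ids_va <- unique(samples$image_id[folds[samples$image_id] %in% s$val])
    ids_te <- unique(samples$image_id[folds[samples$image_id] %in% s$test])
    expect_length(intersect(ids_tr, ids_va), 0L)
    expect_length(intersect(ids_tr, ids_te), 0L)
    expect_length(intersect(ids_va, ids_te), 0L)
  }
})

test_that("class weights follow the inverse-frequency formulas", {
  counts <- c(healthy = 8900, CME = 7286, DRT = 6241, SRD = 1975)
  w <- class_weights(counts, "four_class")
  expect_equal(w[["healthy"]], (7286 + 6241 + 1975) / 8900)
  expect_equal(w[["SRD"]], (8900 + 7286 + 6241) / 1975)
  expect_true(all(class_weights(c(healthy = 5, CME = 5, DRT = 5, SRD = 5)) == 3))
  wb <- class_weights(c(counts, uncertainty = 8900), "binary_with_uncertainty")
  expect_equal(wb[["healthy"]], (8900 + 7286 + 6241 + 1975) / 8900)
  expect_equal(wb[["pathological"]], 8900 / (8900 + 7286 + 6241 + 1975))
  expect_error(class_weights(c(healthy = 0, CME = 1, DRT = 1, SRD = 1)),
               "positive")
  expect_error(class_weights(counts, "binary_with_uncertainty"), "missing")
})

test_that("weighting counteracts imbalance per the sum-of-others formula", {
  counts <- c(healthy = 120, CME = 40, DRT = 80, SRD = 10)
  w <- class_weights(counts, "four_class")
  # each class's total weight equals the total count of the other classes,
  # so rarer classes always carry larger per-sample weights
  expect_equal(unname(w * counts), unname(sum(counts) - counts))
  expect_true(all(order(w) == order(counts, decreasing = TRUE)))
  # binary scheme: the side weights are reciprocal
  wb <- class_weights(c(counts, uncertainty = 30), "binary_with_uncertainty")
  expect_equal(wb[["healthy"]] * wb[["pathological"]], 1)
})

test_that("flip augmentation is identity at p=0, involution at p=1, ~half at p=0.5", {
  s <- fixture_samples(2, n_per_label = 5, window = 32)
  expect_identical(augment_flip(s, p = 0, seed = 1)$patches, s$patches)
  ff <- augment_flip(augment_flip(s, p = 1, seed = 1), p = 1, seed = 2)
  expect_equal(ff$patches, s$patches)
  # flip fraction at p = 0.5 within 3 sigma of a binomial over many patches
  n <- 4000L
  set.seed(7)
  big <- octfluid:::new_oct_samples(
    array(runif(4 * n), dim = c(2, 2, n)),
    factor(rep("healthy", n), levels = oct_classes(TRUE)),
    rep("x", n), cbind(row = rep(1L, n), col = rep(1L, n)))
  out <- augment_flip(big, p = 0.5, seed = 7)
  flipped <- vapply(seq_len(n), function(i)
    !isTRUE(all.equal(out$patches[, , i], big$patches[, , i])), logical(1))
  expect_lt(abs(mean(flipped) - 0.5), 3 * sqrt(0.25 / n))
  # flipping changes pixels but not labels
  fl <- augment_flip(s, p = 1, seed = 3)
  expect_identical(fl$label, s$label)
  expect_false(identical(fl$patches, s$patches))
})
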