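test_that("binary metrics reproduce hand arithmetic", {
  perfect <- confusion_counts(5, 5, 0, 0)
  expect_equal(unname(binary_metrics(perfect)), c(1, 1, 1, 1))
  m <- binary_metrics(confusion_counts(3, 2, 1, 2))
  expect_equal(m[["accuracy"]], 0.625)
  expect_equal(m[["precision"]], 0.75)
  expect_equal(m[["recall"]], 0.6)
  expect_equal(m[["f1"]], 2 * 0.75 * 0.6 / 1.35)
})

test_that("undefined ratios are NA, or 0 under the aggregate convention", {
  m <- binary_metrics(confusion_counts(0, 5, 0, 2))
  expect_true(is.na(m[["precision"]]))
  expect_true(is.na(m[["f1"]]))
  m0 <- binary_metrics(confusion_counts(0, 5, 0, 2), undefined_as_zero = TRUE)
  expect_identical(m0[["precision"]], 0)
  expect_error(binary_metrics(confusion_counts(0, 0, 0, 0)), "no evaluated")
})

test_that("AUC handles separation, ties and the worked pair sum", {
  expect_equal(auc_mww(c(0.9, 0.8), 0.1), 1)
  expect_equal(auc_mww(0.5, 0.5), 0.5)
  expect_equal(auc_mww(c(0.9, 0.4, 0.4), c(0.4, 0.2)), 5 / 6)
  expect_error(auc_mww(numeric(0), 1), "empty")
})

test_that("AUC equals the exhaustive double loop for random tied lists", {
  set.seed(31)
  for (case in 1:40) {
    n <- sample(1:50, 1); m <- sample(1:50, 1)
    # coarse grid forces plenty of ties
    pos <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    neg <- sample(seq(0, 1, by = 0.1), m, replace = TRUE)
    expect_equal(auc_mww(pos, neg), auc_loop_oracle(pos, neg))
  }
})

test_that("MCC matches the closed form and its symmetries", {
  expect_equal(mcc(confusion_counts(5, 5, 0, 0)), 1)
  expect_equal(mcc(confusion_counts(0, 0, 5, 5)), -1)
  expect_equal(mcc(confusion_counts(3, 2, 1, 2)), 4 / sqrt(4 * 5 * 3 * 4))
  # swapping the positive/negative role with TP<->TN, FP<->FN is invariant
  expect_equal(mcc(confusion_counts(3, 2, 1, 2)),
               mcc(confusion_counts(2, 3, 2, 1)))
  expect_true(is.na(mcc(confusion_counts(3, 0, 0, 2))))
  expect_identical(mcc(confusion_counts(3, 0, 0, 2), undefined_as_zero = TRUE), 0)
})

test_that("F1 is symmetric in precision/recall and monotone in TP", {
  a <- binary_metrics(confusion_counts(6, 10, 2, 4))  # prec .75 rec .6
  b <- binary_metrics(confusion_counts(6, 10, 4, 2))  # prec .6 rec .75
  expect_equal(a[["f1"]], b[["f1"]])
  f1s <- vapply(1:8, function(tp)
    binary_metrics(confusion_counts(tp, 10, 2, 8 - tp))[["f1"]], numeric(1))
  expect_true(all(diff(f1s) > 0))
})

test_that("a perfect classifier scores 1 on every per-class metric", {
  cls <- oct_classes()
  truth <- rep(cls, each = 10)
  scores <- matrix(0.02, length(truth), 4, dimnames = list(NULL, cls))
  scores[cbind(seq_along(truth), match(truth, cls))] <- 0.94
  rep <- per_class_report(truth, scores)
  for (mn in c("auc", "f1", "accuracy", "precision", "recall", "mcc"))
    expect_true(all(rep[[mn]] == 1))
})

test_that("uniform random scores give chance-level AUC on balanced classes", {
  set.seed(12)
  cls <- oct_classes()
  n <- 4000
  truth <- sample(rep(cls, each = n / 4))
  raw <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, cls))
  scores <- raw / rowSums(raw)
  rep <- per_class_report(truth, scores)
  # per-class AUC ~ N(0.5, sqrt((n_pos+n_neg+1)/(12*n_pos*n_neg)))
  sd_auc <- sqrt((n + 1) / (12 * (n / 4) * (3 * n / 4)))
  aucs <- rep$auc[rep$class != "overall"]
  expect_true(all(abs(aucs - 0.5) < 3 * sd_auc))
})

test_that("the overall row is the support-weighted mean of per-class rows", {
  set.seed(5)
  cls <- oct_classes()
  truth <- sample(cls, 300, replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.1))
  raw <- matrix(runif(300 * 4), 300, 4, dimnames = list(NULL, cls))
  scores <- raw / rowSums(raw)
  rep <- per_class_report(truth, scores)
  per <- rep[rep$class != "overall", ]
  ov <- rep[rep$class == "overall", ]
  for (mn in c("auc", "f1", "accuracy", "precision", "recall", "mcc"))
    expect_equal(ov[[mn]], sum(per[[mn]] * per$support) / sum(per$support))
  # unweighted mode
  repu <- per_class_report(truth, scores, weighted = FALSE)
  ovu <- repu[repu$class == "overall", ]
  expect_equal(ovu$accuracy, mean(per$accuracy))
})

test_that("classes absent from the truth are flagged unsupported", {
  cls <- oct_classes()
  truth <- rep("healthy", 10)
  scores <- matrix(0.25, 10, 4, dimnames = list(NULL, cls))
  rep <- per_class_report(truth, scores)
  expect_true(is.na(rep$auc[rep$class == "SRD"]))
  expect_identical(rep$support[rep$class == "SRD"], 0L)
})
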