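#' Confusion counts for one positive class
#'
#' @param tp,tn,fp,fn non-negative integers.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = as.numeric(tp), tn = as.numeric(tn),
         fp = as.numeric(fp), fn = as.numeric(fn))
  if (any(v < 0)) stop("confusion counts must be non-negative")
  structure(as.list(v), class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Exact textbook formulas. Ratios with a zero denominator are reported as
#' `NA` (undefined) unless `undefined_as_zero = TRUE`, which maps them to 0
#' for aggregate rows.
#'
#' @param counts a [confusion_counts()].
#' @param undefined_as_zero replace undefined ratios by 0.
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
binary_metrics <- function(counts, undefined_as_zero = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated samples")
  safe <- function(num, den) {
    if (den == 0) { if (undefined_as_zero) 0 else NA_real_ } else num / den
  }
  acc <- (tp + tn) / total
  prec <- safe(tp, tp + fp)
  rec <- safe(tp, tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) {
    if (undefined_as_zero) 0 else NA_real_
  } else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Mann-Whitney-Wilcoxon AUC with the tie convention
#'
#' The probability that a random positive score exceeds a random negative
#' score, counting ties as 1/2: `sum_ij I(x_i, y_j) / (n m)` with
#' `I = 1` if `x > y`, `1/2` if equal, `0` otherwise. Computed through
#' midranks, which is algebraically identical to the exhaustive double loop.
#'
#' @param pos_scores,neg_scores non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_mww <- function(pos_scores, neg_scores) {
  n <- length(pos_scores); m <- length(neg_scores)
  if (n == 0L || m == 0L) stop("AUC undefined for empty score lists")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n)]) - n * (n + 1) / 2) / (n * m)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in `[-1, 1]`.
#' Undefined (any zero factor in the denominator) is reported as `NA` unless
#' `undefined_as_zero = TRUE`.
#'
#' @inheritParams binary_metrics
#' @return scalar MCC.
#' @export
mcc <- function(counts, undefined_as_zero = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(if (undefined_as_zero) 0 else NA_real_)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Per-class one-vs-rest metrics report
#'
#' Hard predictions are the argmax of each score row (ties broken by the
#' lowest class index). For each class, one-vs-rest confusion counts give
#' accuracy, precision, recall, F1 and MCC; AUC uses the class's score
#' column against all other samples. The `overall` row is the
#' class-support-weighted mean of the per-class values (supports are the
#' true-label counts); set `weighted = FALSE` for an unweighted mean.
#' Classes absent from `true_labels` are flagged unsupported (`NA` metrics,
#' excluded from the overall row).
#'
#' @param true_labels factor or character vector of true classes.
#' @param score_matrix numeric matrix, one row per sample, columns named by
#'   class, rows summing to 1.
#' @param classes class set; defaults to the score matrix columns.
#' @param weighted support-weighted overall row.
#' @return data frame with one row per class plus `overall`; columns
#'   `class`, `support`, `auc`, `f1`, `accuracy`, `precision`, `recall`,
#'   `mcc`.
#' @export
per_class_report <- function(true_labels, score_matrix,
                             classes = colnames(score_matrix),
                             weighted = TRUE) {
  true_labels <- as.character(true_labels)
  stopifnot(length(true_labels) == nrow(score_matrix),
            all(true_labels %in% classes))
  score_matrix <- score_matrix[, classes, drop = FALSE]
  pred_idx <- max.col(score_matrix, ties.method = "first")
  pred <- classes[pred_idx]
  rows <- lapply(classes, function(cl) {
    support <- sum(true_labels == cl)
    if (support == 0L) {
      return(data.frame(class = cl, support = 0L, auc = NA_real_,
                        f1 = NA_real_, accuracy = NA_real_,
                        precision = NA_real_, recall = NA_real_,
                        mcc = NA_real_))
    }
    is_pos <- true_labels == cl
    pred_pos <- pred == cl
    cc <- confusion_counts(sum(is_pos & pred_pos), sum(!is_pos & !pred_pos),
                           sum(!is_pos & pred_pos), sum(is_pos & !pred_pos))
    bm <- binary_metrics(cc, undefined_as_zero = TRUE)
    auc <- if (any(!is_pos))
      auc_mww(score_matrix[is_pos, cl], score_matrix[!is_pos, cl])
    else NA_real_
    data.frame(class = cl, support = support,
               auc = auc,
               f1 = bm[["f1"]], accuracy = bm[["accuracy"]],
               precision = bm[["precision"]], recall = bm[["recall"]],
               mcc = mcc(cc, undefined_as_zero = TRUE))
  })
  rep <- do.call(rbind, rows)
  supported <- rep$support > 0L
  wts <- if (weighted) rep$support[supported] else rep(1, sum(supported))
  overall <- vapply(c("auc", "f1", "accuracy", "precision", "recall", "mcc"),
                    function(mn) sum(rep[[mn]][supported] * wts) / sum(wts),
                    numeric(1))
  rbind(rep, data.frame(class = "overall", support = sum(rep$support),
                        auc = overall[["auc"]], f1 = overall[["f1"]],
                        accuracy = overall[["accuracy"]],
                        precision = overall[["precision"]],
                        recall = overall[["recall"]], mcc = overall[["mcc"]]))
}

#' Evaluate a trained model on a sample set
#'
#' Runs the classifier over the patches and produces a [per_class_report()].
#' Uncertainty-labeled samples are excluded by default, mirroring test-time
#' evaluation in which only samples with a definite expert label count
#' towards the metrics.
#'
#' @param model an `oct_model` (see [build_backbone()]).
#' @param samples an `oct_samples`.
#' @param exclude_uncertainty drop uncertainty-labeled samples first.
#' @param weighted passed to [per_class_report()].
#' @return the report data frame.
#' @export
evaluate_model <- function(model, samples, exclude_uncertainty = TRUE,
                           weighted = TRUE) {
  if (exclude_uncertainty)
    samples <- subset_samples(samples, samples$label != "uncertainty")
  probs <- predict_proba(model, samples$patches)
  per_class_report(droplevels(samples$label), probs, classes = model$classes,
                   weighted = weighted)
}
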