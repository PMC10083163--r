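#' Run the cross-validated experiment grid
#'
#' End-to-end evaluation over an experiment budget: extracts window samples
#' from every image, assigns image-level folds, enumerates all
#' train/val/test fold combinations, and for each selected split and regime
#' trains a model and scores it on the labeled samples of the test fold
#' (uncertainty excluded from the metrics). Per-split reports are aggregated
#' as mean and standard deviation per class and metric. Every stochastic
#' stage is seeded from `seed` deterministically per (split, approach), so a
#' run is fully re-creatable from its manifest.
#'
#' @param images list of `oct_image` (e.g. [generate_dataset()]).
#' @param approaches subset of `baseline`, `generalist`, `uncertainty`.
#' @param n_splits number of fold combinations to run, clamped (with a
#'   warning) to the available count.
#' @param k number of image-level folds.
#' @param n_train,n_val,n_test fold counts per role; the default keeps the
#'   3/2/1 pattern for 6 folds and scales it for other `k` (one test fold,
#'   a third of the folds for validation, the rest for training).
#' @param n_per_label,window passed to [extract_samples()].
#' @param backbone a [backbone_config()].
#' @param config a [train_config()].
#' @param pretrained optional pretrained model for the generalist regime;
#'   when `NULL` a pretext model is trained once and reused.
#' @param seed master seed.
#' @return an `experiment_grid` result: list with `results` (long data frame
#'   of per-split per-class metrics), `summary` (mean and sd per approach,
#'   class and metric), `splits`, `folds` and `manifest`.
#' @export
run_experiment_grid <- function(images,
                                approaches = c("baseline", "generalist", "uncertainty"),
                                n_splits = 6L, k = 6L,
                                n_train = NULL, n_val = NULL, n_test = 1L,
                                n_per_label = 25L, window = 64L,
                                backbone = backbone_config(n_classes = 4L),
                                config = train_config(),
                                pretrained = NULL, seed = 1L) {
  approaches <- match.arg(approaches, several.ok = TRUE)
  seeds <- derive_seeds(seed, 3L)
  per_image <- lapply(seq_along(images), function(i) {
    extract_samples(images[[i]], n_per_label = n_per_label, window = window,
                    seed = seeds[1] + i)
  })
  samples <- combine_samples(per_image)
  folds <- make_folds(images, k = k, seed = seeds[2])
  n_val <- n_val %||% max(1L, k %/% 3L)
  n_train <- n_train %||% (k - n_val - n_test)
  splits <- enumerate_experiments(k, n_train, n_val, n_test)
  if (n_splits > length(splits)) {
    warning(sprintf("budget of %d splits exceeds the %d available; clamped",
                    n_splits, length(splits)))
    n_splits <- length(splits)
  }
  splits <- splits[seq_len(n_splits)]
  if ("generalist" %in% approaches && is.null(pretrained))
    pretrained <- pretrain_generalist(backbone, config)

  results <- list()
  for (si in seq_along(splits)) {
    split <- splits[[si]]
    test_samples <- samples_in_folds(samples, folds, split$test)
    for (ap in approaches) {
      cfg <- config
      cfg$seed <- seeds[3] + 1000L * si + match(ap, c("baseline", "generalist", "uncertainty"))
      fit <- switch(ap,
        baseline = run_baseline(split, samples, folds, cfg, backbone),
        generalist = run_generalist_transfer(pretrained, split, samples, folds,
                                             cfg, backbone),
        uncertainty = run_uncertainty_transfer(split, samples, folds, cfg,
                                               backbone))
      rep <- evaluate_model(fit$model, test_samples)
      rep$split <- si
      rep$approach <- ap
      results[[length(results) + 1L]] <- rep
    }
  }
  results <- do.call(rbind, results)
  structure(list(results = results,
                 summary = aggregate_reports(results),
                 splits = splits, folds = folds,
                 manifest = list(seed = seed, sub_seeds = seeds,
                                 n_splits = n_splits, k = k,
                                 n_per_label = n_per_label, window = window,
                                 approaches = approaches,
                                 variant = backbone$variant,
                                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
            class = "experiment_grid")
}

#' Aggregate per-split reports into mean and standard deviation
#'
#' @param results long data frame of per-split [per_class_report()] rows
#'   (columns `approach`, `split`, `class` and the metric columns).
#' @return data frame with one row per (approach, class, metric) carrying
#'   `mean` and `sd` across splits.
#' @export
aggregate_reports <- function(results) {
  metrics <- c("auc", "f1", "accuracy", "precision", "recall", "mcc")
  if (is.null(results$approach)) results$approach <- "all"
  groups <- unique(results[, c("approach", "class")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- results$approach == groups$approach[i] & results$class == groups$class[i]
    do.call(rbind, lapply(metrics, function(mn) {
      v <- results[[mn]][sel]
      data.frame(approach = groups$approach[i], class = groups$class[i],
                 metric = mn, mean = mean(v, na.rm = TRUE),
                 sd = if (sum(!is.na(v)) > 1L) stats::sd(v, na.rm = TRUE) else NA_real_)
    }))
  })
  do.call(rbind, rows)
}

#' Write an experiment-grid manifest and reports
#'
#' @param grid an `experiment_grid`.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_experiment_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(grid$results, file.path(dir, "results.csv"), row.names = FALSE)
  utils::write.csv(grid$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(grid$manifest, path, auto_unbox = TRUE)
  invisible(path)
}
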