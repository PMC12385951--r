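# Cross-validation protocol: stratified folds, classification metrics,
# t-based confidence intervals, and penultimate-feature export.

#' Stratified k-fold partitions
#'
#' Items are dealt class-by-class into k folds after a seeded shuffle, so
#' per-class counts across folds differ by at most one.  With `groups`
#' given (e.g. record ids), whole groups are dealt instead, so every
#' segment of a record lands in the same fold (leakage-safe record-level
#' splitting).
#'
#' @param labels integer vector of 0-based class indices, one per item.
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @param groups optional grouping vector parallel to `labels`; each group
#'   must be single-class.
#' @return list of k elements, each `list(train = idx, test = idx)` with
#'   1-based item indices; the test sets partition `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L, groups = NULL) {
  if (k < 2L) stop("k must be >= 2")
  n <- length(labels)
  fold_of <- integer(n)
  if (is.null(groups)) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop("split error: class ", cl, " has ", length(idx),
             " items, fewer than k = ", k)
      idx <- withr::with_seed(seed + cl, sample(idx))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    stopifnot(length(groups) == n)
    gl <- tapply(labels, groups, unique, simplify = FALSE)
    if (any(lengths(gl) != 1L))
      stop("split error: a group spans more than one class")
    for (cl in unique(labels)) {
      gs <- names(gl)[vapply(gl, identical, logical(1), y = cl)]
      if (length(gs) < k)
        stop("split error: class ", cl, " has ", length(gs),
             " groups, fewer than k = ", k)
      gs <- withr::with_seed(seed + cl, sample(gs))
      gf <- rep_len(seq_len(k), length(gs))
      for (j in seq_along(gs))
        fold_of[groups == gs[j]] <- gf[j]
    }
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Classification metrics for one fold
#'
#' Accuracy plus macro-averaged precision, recall and F1, and their
#' support-weighted counterparts (weighted F1 is the headline metric for
#' imbalanced multi-class problems).  All metrics are percentages.
#' Per-class ratios with empty denominators (a class never predicted, or
#' absent from the fold) are counted as 0.
#'
#' @param predictions,labels equal-length integer vectors of 0-based class
#'   indices.
#' @param n_classes number of classes.
#' @return object of class `fold_result`: accuracy, precision, recall,
#'   f1, weighted_precision, weighted_recall, weighted_f1, `per_class`
#'   data frame and the C x C `confusion` matrix (rows = truth).
#' @export
compute_metrics <- function(predictions, labels, n_classes) {
  if (length(predictions) == 0L) stop("metric error: empty input")
  stopifnot(length(predictions) == length(labels))
  cm <- table(factor(labels, levels = 0:(n_classes - 1L)),
              factor(predictions, levels = 0:(n_classes - 1L)))
  cm <- unclass(cm)
  dimnames(cm) <- list(truth = rownames(cm), predicted = colnames(cm))
  tp <- diag(cm)
  support <- rowSums(cm)
  pred_n <- colSums(cm)
  prec <- ifelse(pred_n > 0, tp / pred_n, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / sum(support)
  structure(list(
    accuracy = 100 * sum(tp) / sum(cm),
    precision = 100 * mean(prec),
    recall = 100 * mean(rec),
    f1 = 100 * mean(f1),
    weighted_precision = 100 * sum(w * prec),
    weighted_recall = 100 * sum(w * rec),
    weighted_f1 = 100 * sum(w * f1),
    per_class = data.frame(class = 0:(n_classes - 1L), support = support,
                           precision = 100 * prec, recall = 100 * rec,
                           f1 = 100 * f1, row.names = NULL),
    confusion = cm), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf(
    "<fold_result> acc %.2f%%  P %.2f  R %.2f  F1 %.2f  F1w %.2f\n",
    x$accuracy, x$precision, x$recall, x$f1, x$weighted_f1))
  invisible(x)
}

#' t-based confidence interval over fold metrics
#'
#' `mean +/- qt(1 - (1 - level)/2, k - 1) * sd / sqrt(k)` with `sd` the
#' sample standard deviation.  Truncation of the upper bound (useful for
#' percentage metrics whose interval exceeds 100) is applied on request
#' only; stored report values are never truncated.
#'
#' @param values per-fold metric values (>= 2).
#' @param level confidence level.
#' @param truncate_upper optional cap for the upper bound.
#' @return named numeric vector `c(lower, upper)`.
#' @export
t_confidence_interval <- function(values, level = 0.95,
                                  truncate_upper = NULL) {
  k <- length(values)
  if (k < 2L) stop("CI error: need at least 2 values")
  m <- mean(values)
  half <- qt(1 - (1 - level) / 2, df = k - 1) * sd(values) / sqrt(k)
  upper <- m + half
  if (!is.null(truncate_upper)) upper <- min(upper, truncate_upper)
  c(lower = m - half, upper = upper)
}

metric_names <- c("accuracy", "precision", "recall", "f1", "weighted_f1")

#' Run stratified k-fold cross-validation of the full pipeline
#'
#' For each fold: segment the records, augment the training portion only,
#' train from a fresh initialization, keep the checkpoint with the best
#' training accuracy, and evaluate on the untouched test segments.
#' Per-fold confusion matrices are also summed into a pooled matrix for
#' reporting.
#'
#' @param records list of [eeg_record()] covering the task's sets.
#' @param task a [parse_task()] spec.
#' @param model_cfg a [model_config()]; its class count must match the
#'   task.
#' @param train_cfg a [train_config()].
#' @param k number of folds.
#' @param seed master seed; fold splits, initializations, augmentation
#'   noise and training streams all derive from it.
#' @param window segment length in samples.
#' @param augment an [augment_config()] applied to training folds
#'   (`copies_per_original = 0` disables augmentation).
#' @param group_by_record keep all segments of a record in one fold.
#'   Default is segment-level splitting, matching the granularity of the
#'   published protocol; record-level splitting is the leakage-safe
#'   alternative.
#' @param verbose print fold progress.
#' @return object of class `cv_report`.
#' @export
run_cv <- function(records, task, model_cfg = NULL,
                   train_cfg = train_config(), k = 10L, seed = 1L,
                   window = 512L, augment = augment_config(),
                   group_by_record = FALSE, verbose = FALSE) {
  if (is.null(model_cfg)) model_cfg <- model_config(n_classes = task$n_classes)
  if (model_cfg$n_classes != task$n_classes)
    stop("model has ", model_cfg$n_classes, " classes but task ", task$name,
         " has ", task$n_classes)
  keep <- vapply(records, function(r) r$set_label %in% names(task$class_map),
                 logical(1))
  segs <- segment_records(records[keep], window, task)
  folds <- stratified_kfold(segs$label, k, seed = seed,
                            groups = if (group_by_record) segs$origin_id)
  results <- vector("list", k)
  histories <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- segs[folds[[f]]$train]
    te <- segs[folds[[f]]$test]
    aug <- augment_gaussian(tr, augment_config(
      alpha = augment$alpha,
      copies_per_original = augment$copies_per_original,
      seed = augment$seed + 131L * f))
    if (n_segments(aug) > 0L) tr <- bind_segments(tr, aug)
    stopifnot(!any(te$is_augmented))
    tcfg <- train_cfg
    tcfg$seed <- as.integer(train_cfg$seed + 977L * f)
    model <- build_model(model_cfg, seed = seed + 389L * f)
    fit <- train_model(model, tr, tcfg)
    pred <- predict(fit$model, te, type = "class")
    results[[f]] <- compute_metrics(pred, te$label, task$n_classes)
    histories[[f]] <- fit$history
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.2f%% (epoch %d selected)",
                      f, k, results[[f]]$accuracy, fit$selected_epoch))
  }
  fold_metrics <- as.data.frame(
    lapply(setNames(metric_names, metric_names),
           function(mn) vapply(results, `[[`, numeric(1), mn)))
  fold_metrics <- cbind(fold = seq_len(k), fold_metrics)
  summarise <- function(v) {
    ci <- t_confidence_interval(v)
    c(mean = mean(v), sd = sd(v), ci)
  }
  summary <- t(vapply(fold_metrics[metric_names], summarise, numeric(4)))
  structure(list(
    task = task$name, k = k, seed = seed,
    group_by_record = group_by_record,
    fold_metrics = fold_metrics,
    summary = as.data.frame(summary),
    confusion = Reduce(`+`, lapply(results, `[[`, "confusion")),
    folds = results, histories = histories), class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 2, ...) {
  s <- x$summary["accuracy", ]
  cat(sprintf(
    "<cv_report> task %s, %d-fold%s\n  accuracy %.*f%% (sd %.*f), 95%% CI [%.*f, %.*f]\n  weighted F1 %.*f%%\n",
    x$task, x$k, if (x$group_by_record) " (record-level)" else "",
    digits, s$mean, digits, s$sd, digits, s$lower,
    digits, min(s$upper, 100), digits, x$summary["weighted_f1", "mean"]))
  invisible(x)
}

#' Export per-segment feature vectors for external 2-D projection
#'
#' Channel-wise max-pooled features of the shallow (`"rcm"`) or deep
#' (`"dcpm"`) convolutional stage, or the fused vector (`"fused"`), with
#' the segment labels attached — the input expected by external embedding
#' tools such as t-SNE.
#'
#' @param model a trained `eegnet`.
#' @param segments a labeled `segment_set`.
#' @param stage `"rcm"`, `"dcpm"` or `"fused"`.
#' @param path optional CSV output (label column + feature columns).
#' @return data frame with `label` and `f1..fD` columns, one row per
#'   segment.
#' @export
export_embeddings <- function(model, segments, stage = "fused",
                              path = NULL) {
  if (!stage %in% c("rcm", "dcpm", "fused"))
    stop("configuration error: unknown stage '", stage, "'")
  feats <- forward_features(model, segments, stage)
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  df <- cbind(data.frame(label = segments$label), as.data.frame(feats))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
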