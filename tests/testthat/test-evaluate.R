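test_that("stratified folds partition the data with balanced classes", {
  labels <- rep(0:4, each = 800) # 4000 segments, 5 classes
  folds <- stratified_kfold(labels, 10, seed = 3)
  expect_length(folds, 10)
  test_idx <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(test_idx)), seq_along(labels))
  expect_identical(anyDuplicated(unlist(test_idx)), 0L)
  for (f in folds) {
    expect_length(f$test, 400)
    counts <- table(labels[f$test])
    expect_true(all(counts == 80))
    expect_identical(sort(c(f$train, f$test)), seq_along(labels))
  }
  # per-class counts across folds differ by at most one for uneven sizes
  labels2 <- rep(0:1, c(23, 31))
  folds2 <- stratified_kfold(labels2, 4, seed = 1)
  for (cl in 0:1) {
    per_fold <- vapply(folds2, function(f) sum(labels2[f$test] == cl),
                       integer(1))
    expect_lte(diff(range(per_fold)), 1L)
  }
})

test_that("leave-one-out and error cases behave at the boundaries", {
  labels <- rep(0:1, each = 4)
  folds <- stratified_kfold(labels, 4, seed = 1)
  expect_true(all(lengths(lapply(folds, `[[`, "test")) == 2))
  expect_error(stratified_kfold(rep(0:1, c(3, 10)), 4, seed = 1),
               "split error")
  expect_error(stratified_kfold(labels, 1), "k must be")
})

test_that("record grouping keeps all segments of a record together", {
  # records r1..r8, 8 segments each, record class 0,0,0,0,1,1,1,1
  groups <- rep(sprintf("r%02d", 1:8), each = 8)
  labels <- rep(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L), each = 8)
  folds <- stratified_kfold(labels, 2, seed = 5, groups = groups)
  for (f in folds) {
    test_groups <- unique(groups[f$test])
    expect_false(any(test_groups %in% groups[f$train]))
  }
  bad_groups <- rep(c("a", "b"), 32)
  expect_error(stratified_kfold(labels, 2, groups = bad_groups),
               "split error")
})

test_that("metrics match a hand-enumerated confusion table", {
  # labels (1,1,0,0), predictions (1,0,0,0):
  # class 0: TP=2 FP=1 FN=0 -> P=2/3, R=1,   F1=0.8
  # class 1: TP=1 FP=0 FN=1 -> P=1,   R=1/2, F1=2/3
  r <- compute_metrics(c(1L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L), 2)
  expect_equal(r$accuracy, 75)
  expect_equal(r$per_class$precision, 100 * c(2 / 3, 1))
  expect_equal(r$per_class$recall, 100 * c(1, 0.5))
  expect_equal(r$f1, 100 * mean(c(0.8, 2 / 3)))
  expect_equal(r$weighted_f1, r$f1) # balanced classes
  expect_identical(as.integer(r$confusion),
                   c(2L, 1L, 0L, 1L)) # column-major (truth x predicted)

  perfect <- compute_metrics(0:4, 0:4, 5)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$weighted_f1, 100)
  expect_true(all(perfect$confusion == diag(5)))
  expect_error(compute_metrics(integer(0), integer(0), 2), "metric error")
})

test_that("metrics are invariant to pair permutation and weighting rules", {
  set.seed(4)
  y <- sample(0:2, 60, replace = TRUE)
  p <- ifelse(runif(60) < 0.7, y, sample(0:2, 60, replace = TRUE))
  r1 <- compute_metrics(p, y, 3)
  ord <- sample(60)
  r2 <- compute_metrics(p[ord], y[ord], 3)
  expect_equal(r1[c("accuracy", "f1", "weighted_f1")],
               r2[c("accuracy", "f1", "weighted_f1")])
  # exactly balanced classes: weighted equals macro
  yb <- rep(0:2, each = 10)
  pb <- c(rep(0, 8), 1, 2, rep(1, 9), 0, rep(2, 7), 0, 1, 2)
  rb <- compute_metrics(pb, yb, 3)
  expect_equal(rb$weighted_f1, rb$f1)
  expect_equal(rb$weighted_recall, rb$recall)
})

test_that("t-based confidence intervals reproduce the printed statistics", {
  # ten published five-class fold accuracies -> mean 95.10, CI (94.42, 95.78)
  expect_equal(mean(five_class_fold_acc), 95.10, tolerance = 1e-12)
  ci <- t_confidence_interval(five_class_fold_acc)
  expect_equal(round(ci[["lower"]], 2), 94.42)
  expect_equal(round(ci[["upper"]], 2), 95.78)
  # ternary A-C-E mean 99.29
  expect_equal(round(mean(ace_fold_acc), 2), 99.29)

  # identical values: zero-width interval
  expect_equal(t_confidence_interval(rep(50, 5)), c(lower = 50, upper = 50))

  # two values 90, 100: half-width = t(.975,1) * sd/sqrt(2) = 63.53
  ci2 <- t_confidence_interval(c(90, 100))
  expect_equal(ci2[["lower"]], 95 - 12.7062 * 7.0711 / sqrt(2),
               tolerance = 1e-4)
  ci2t <- t_confidence_interval(c(90, 100), truncate_upper = 100)
  expect_equal(ci2t[["upper"]], 100)
  expect_error(t_confidence_interval(95), "CI error")
})

test_that("cross-validation reports are structurally sound and seeded", {
  recs <- generate_dataset(synth_config(n_classes = 3, records_per_class = 6,
                                        length = 512, seed = 41))
  task <- parse_task("A-B-C")
  tcfg <- train_config(max_epochs = 2, batch_size = 32, seed = 1)
  rep1 <- run_cv(recs, task, tiny_model_config(), tcfg, k = 3, seed = 9,
                 window = 128, augment = augment_config(
                   copies_per_original = 1))
  expect_s3_class(rep1, "cv_report")
  expect_identical(nrow(rep1$fold_metrics), 3L)
  s <- rep1$summary["accuracy", ]
  expect_lte(s$lower, s$mean)
  expect_gte(s$upper, s$mean)
  # pooled confusion counts every test segment exactly once
  expect_identical(sum(rep1$confusion), 6L * 3L * 4L)
  # same seed -> identical report
  rep2 <- run_cv(recs, task, tiny_model_config(), tcfg, k = 3, seed = 9,
                 window = 128, augment = augment_config(
                   copies_per_original = 1))
  expect_equal(rep1$fold_metrics, rep2$fold_metrics)
  expect_identical(rep1$confusion, rep2$confusion)
})

test_that("embedding export carries stage widths and labels", {
  segs <- tiny_segments(n_classes = 3, records_per_class = 4, window = 64,
                        seed = 51)
  m <- build_model(tiny_model_config(), seed = 1)
  for (stage in c("rcm", "dcpm", "fused")) {
    df <- export_embeddings(m, segs, stage)
    expect_identical(nrow(df), n_segments(segs))
    expect_identical(ncol(df) - 1L, if (stage == "fused") 32L else 8L)
    expect_identical(df$label, segs$label)
  }
  expect_error(export_embeddings(m, segs, "pca"), "configuration error")
})
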