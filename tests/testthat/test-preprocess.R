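test_that("segmentation drops the remainder and preserves sample order", {
  r <- ramp_record(4097)
  s <- segment_record(r, 512)
  expect_identical(n_segments(s), 8L)
  expect_identical(s$segment_index, 0:7)
  # segment i covers [i*512, (i+1)*512): concatenation restores the first
  # 4096 samples exactly; the 4097th is dropped
  expect_identical(as.numeric(t(s$values)), as.numeric(1:4096))

  expect_identical(n_segments(segment_record(ramp_record(512), 512)), 1L)
  expect_identical(as.numeric(segment_record(ramp_record(512), 512)$values),
                   as.numeric(1:512))

  s2 <- segment_record(ramp_record(1000), 512)
  expect_identical(n_segments(s2), 1L)
  expect_identical(as.numeric(s2$values), as.numeric(1:512))

  expect_error(segment_record(ramp_record(100), 512), "shorter")
})

test_that("task labels attach to segments by record set", {
  task <- parse_task("AB-CD-E")
  r <- eeg_record(1:1024, set_label = "D", record_id = "d1")
  s <- segment_record(r, 512, task)
  expect_identical(s$label, c(1L, 1L))
  expect_error(segment_record(ramp_record(), 512, parse_task("C-E")),
               "not part of task")
})

test_that("zero-noise and zero-variance augmentation reproduce the source", {
  s <- segment_record(ramp_record(1024), 512)
  s$label <- c(0L, 0L)
  a0 <- augment_gaussian(s, augment_config(alpha = 0, seed = 1))
  expect_identical(n_segments(a0), 4L)
  expect_true(all(a0$is_augmented))
  expect_equal(a0$values, s$values[rep(1:2, each = 2), ])

  const <- s
  const$values[] <- 7
  ac <- augment_gaussian(const, augment_config(alpha = 0.01, seed = 1))
  expect_equal(ac$values, const$values[rep(1:2, each = 2), ])
})

test_that("perturbation follows the alpha * sigma * n noise law", {
  set.seed(3)
  vals <- matrix(rnorm(512, sd = 4), 1)
  s <- segment_record(
    eeg_record(vals, set_label = "A", record_id = "x"), 512)
  sigma <- sqrt(mean((vals - mean(vals))^2))
  a <- augment_gaussian(s, augment_config(alpha = 0.01,
                                          copies_per_original = 1000,
                                          seed = 9))
  resid <- sweep(a$values, 2, as.numeric(vals))
  # empirical noise sd ~ alpha * sigma within 5% relative error
  expect_lt(abs(sd(as.numeric(resid)) - 0.01 * sigma) / (0.01 * sigma),
            0.05)
  # empirical mean ~ 0 within 3 standard errors
  se <- sd(as.numeric(resid)) / sqrt(length(resid))
  expect_lt(abs(mean(resid)), 3 * se)
  # bitwise reproducible under the same seed
  a2 <- augment_gaussian(s, augment_config(alpha = 0.01,
                                           copies_per_original = 1000,
                                           seed = 9))
  expect_identical(a$values, a2$values)
})

test_that("fold assembly augments training only and rejects leakage", {
  recs <- lapply(1:6, function(i)
    eeg_record(rnorm(1024), set_label = c("A", "E")[1 + i %% 2],
               record_id = paste0("r", i)))
  task <- parse_task("A-E")
  ids <- vapply(recs, function(r) r$record_id, character(1))

  fd <- build_fold_data(recs, task, ids[1:4], ids[5:6], window = 512,
                        cfg = augment_config(copies_per_original = 2,
                                             seed = 2))
  # 4 records x 2 segments = 8 originals, x3 with two copies each
  expect_identical(n_segments(fd$train), 24L)
  expect_identical(sum(fd$train$is_augmented), 16L)
  expect_identical(n_segments(fd$test), 4L)
  expect_false(any(fd$test$is_augmented))
  # augmented segments reference original training records
  expect_true(all(fd$train$origin_id %in% ids[1:4]))

  fd0 <- build_fold_data(recs, task, ids[1:4], ids[5:6], window = 512,
                         cfg = augment_config(copies_per_original = 0))
  expect_identical(n_segments(fd0$train), 8L)

  expect_error(
    build_fold_data(recs, task, ids[1:4], ids[4:6], window = 512),
    "leakage")
})
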