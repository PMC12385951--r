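# Segmentation and Gaussian-perturbation augmentation.
#
# Segments are held column-oriented in a single "segment_set": a values
# matrix with one row per segment (n_channels * window columns,
# channel-major) plus parallel metadata vectors.  Coordinates are 0-based
# and half-open throughout: segment i of a record covers samples
# [i*window, (i+1)*window).

new_segment_set <- function(values, label, origin_id, segment_index,
                            is_augmented, window, n_channels = 1L) {
  stopifnot(nrow(values) == length(label),
            nrow(values) == length(origin_id),
            nrow(values) == length(segment_index),
            nrow(values) == length(is_augmented))
  structure(list(values = values, label = as.integer(label),
                 origin_id = as.character(origin_id),
                 segment_index = as.integer(segment_index),
                 is_augmented = as.logical(is_augmented),
                 window = as.integer(window),
                 n_channels = as.integer(n_channels)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf(
    "<segment_set> %d segments of %d samples (%d augmented), %d record(s)\n",
    n_segments(x), x$window, sum(x$is_augmented),
    length(unique(x$origin_id))))
  invisible(x)
}

#' Number of segments in a segment set
#' @param x a `segment_set`.
#' @return integer count.
#' @export
n_segments <- function(x) nrow(x$values)

#' Subset a segment set by row index
#' @param x a `segment_set`.
#' @param i integer or logical index vector.
#' @param ... unused.
#' @export
`[.segment_set` <- function(x, i, ...) {
  new_segment_set(x$values[i, , drop = FALSE], x$label[i], x$origin_id[i],
                  x$segment_index[i], x$is_augmented[i], x$window,
                  x$n_channels)
}

#' Concatenate segment sets
#' @param ... `segment_set` objects with identical window and channel count.
#' @return a single `segment_set`.
#' @export
bind_segments <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, function(s) n_segments(s) > 0L, logical(1))]
  if (length(sets) == 0L) stop("nothing to bind")
  w <- unique(vapply(sets, function(s) s$window, integer(1)))
  ch <- unique(vapply(sets, function(s) s$n_channels, integer(1)))
  if (length(w) != 1L || length(ch) != 1L)
    stop("segment sets have inconsistent window or channel count")
  new_segment_set(
    do.call(rbind, lapply(sets, function(s) s$values)),
    unlist(lapply(sets, function(s) s$label)),
    unlist(lapply(sets, function(s) s$origin_id)),
    unlist(lapply(sets, function(s) s$segment_index)),
    unlist(lapply(sets, function(s) s$is_augmented)),
    w, ch)
}

#' Cut a record into fixed, non-overlapping windows
#'
#' A record of length L yields floor(L/window) consecutive segments; any
#' trailing remainder is dropped (a 4097-sample Bonn record at window 512
#' gives 8 segments and drops the final sample).
#'
#' @param record an [eeg_record()].
#' @param window window length in samples.
#' @param task optional [parse_task()] spec; when given, each segment gets
#'   the class index of the record's set, otherwise the label is `NA`.
#' @return a `segment_set`.
#' @export
segment_record <- function(record, window = 512L, task = NULL) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  L <- length(record$samples)
  n <- L %/% window
  if (n == 0L)
    stop(sprintf("record %s (%d samples) is shorter than the window (%d)",
                 record$record_id, L, window))
  vals <- matrix(record$samples[seq_len(n * window)], nrow = n,
                 ncol = window, byrow = TRUE)
  lab <- if (is.null(task)) NA_integer_ else {
    if (!record$set_label %in% names(task$class_map))
      stop("record set '", record$set_label, "' not part of task ",
           task$name)
    task$class_map[[record$set_label]]
  }
  new_segment_set(vals, rep(lab, n), rep(record$record_id, n),
                  seq_len(n) - 1L, rep(FALSE, n), window,
                  record$n_channels)
}

#' Segment a list of records
#'
#' @param records list of [eeg_record()].
#' @inheritParams segment_record
#' @return a `segment_set` containing all segments in record order.
#' @export
segment_records <- function(records, window = 512L, task = NULL) {
  do.call(bind_segments,
          lapply(records, segment_record, window = window, task = task))
}

#' Augmentation settings
#'
#' @param alpha noise scaling factor (dimensionless); the perturbed copy is
#'   `x = S + alpha * sigma * n` with `n` i.i.d. standard normal and `sigma`
#'   the per-segment standard deviation of `S`.
#' @param copies_per_original number of perturbed copies per original
#'   training segment (2 doubles the augmented data relative to the
#'   originals, i.e. the final training set is three times the original
#'   size).
#' @param seed RNG seed for reproducible noise.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(alpha = 0.01, copies_per_original = 2L,
                           seed = 1L) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (copies_per_original < 0) stop("copies_per_original must be >= 0")
  structure(list(alpha = alpha,
                 copies_per_original = as.integer(copies_per_original),
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Gaussian-perturbation augmentation
#'
#' Each segment S yields `copies_per_original` perturbed copies
#' `S + alpha * sigma * n`; `sigma` is the population (N denominator)
#' standard deviation of that segment, so a constant segment is copied
#' unchanged.  Copies carry the origin id of their source and are flagged
#' augmented.
#'
#' @param segments a `segment_set`.
#' @param cfg an [augment_config()].
#' @return a `segment_set` of augmented copies only (possibly empty rows if
#'   `copies_per_original` is 0).
#' @export
augment_gaussian <- function(segments, cfg = augment_config()) {
  n <- n_segments(segments)
  k <- cfg$copies_per_original
  if (k == 0L || n == 0L)
    return(segments[integer(0)])
  vals <- segments$values
  mu <- rowMeans(vals)
  sigma <- sqrt(rowMeans((vals - mu)^2)) # population denominator
  rep_idx <- rep(seq_len(n), each = k)
  base <- vals[rep_idx, , drop = FALSE]
  noise <- withr::with_seed(cfg$seed,
    matrix(rnorm(length(base)), nrow = nrow(base)))
  out <- base + cfg$alpha * sigma[rep_idx] * noise
  new_segment_set(out, segments$label[rep_idx], segments$origin_id[rep_idx],
                  segments$segment_index[rep_idx],
                  rep(TRUE, length(rep_idx)), segments$window,
                  segments$n_channels)
}

#' Assemble augmented training and untouched test segments for one fold
#'
#' Augmentation is applied after the train/test split and to training
#' records only, so no perturbed copy of a test record ever enters
#' training and the test set contains only original segments.
#'
#' @param records list of [eeg_record()].
#' @param task a [parse_task()] spec.
#' @param train_ids,test_ids disjoint record-id vectors.
#' @param window window length in samples.
#' @param cfg an [augment_config()].
#' @return list with `train` and `test` segment sets.
#' @export
build_fold_data <- function(records, task, train_ids, test_ids,
                            window = 512L, cfg = augment_config()) {
  if (length(intersect(train_ids, test_ids)) > 0L)
    stop("leakage error: train and test record ids overlap")
  ids <- vapply(records, function(r) r$record_id, character(1))
  missing <- setdiff(c(train_ids, test_ids), ids)
  if (length(missing) > 0L)
    stop("unknown record ids: ", paste(missing, collapse = ", "))
  tr <- segment_records(records[ids %in% train_ids], window, task)
  te <- segment_records(records[ids %in% test_ids], window, task)
  aug <- augment_gaussian(tr, cfg)
  train <- if (n_segments(aug) > 0L) bind_segments(tr, aug) else tr
  stopifnot(!any(te$is_augmented))
  list(train = train, test = te)
}
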