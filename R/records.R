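# Bonn-format record I/O and task parsing.
#
# The Bonn corpus stores one recording per ASCII file, one sample per line
# (4097 samples at 173.61 Hz).  Records are represented as plain lists of
# class "eeg_record"; datasets are lists of records.

#' Construct a single-channel EEG record
#'
#' @param samples numeric vector of samples (conventionally microvolts; units
#'   are documented, not enforced).
#' @param fs sampling rate in Hz.
#' @param set_label class-set label, e.g. `"A"`..`"E"` for the Bonn sets or a
#'   synthetic class letter.
#' @param record_id unique identifier within a dataset.
#' @param n_channels number of channels (1 for Bonn-style records).
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs = 173.61, set_label, record_id,
                       n_channels = 1L) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("record '", record_id, "' has no samples")
  if (!is.numeric(fs) || fs <= 0) stop("sampling rate must be positive")
  structure(
    list(samples = samples, fs = fs, set_label = as.character(set_label),
         record_id = as.character(record_id),
         n_channels = as.integer(n_channels)),
    class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record %s> set %s: %d samples @ %.2f Hz\n",
              x$record_id, x$set_label, length(x$samples), x$fs))
  invisible(x)
}

#' Read one Bonn-format record (one numeric sample per line)
#'
#' @param path file path.
#' @param fs sampling rate in Hz (173.61 for the Bonn corpus).
#' @param set_label class-set label to attach.
#' @param record_id identifier; defaults to the file name without extension.
#' @return an [eeg_record()].
#' @export
read_bonn_record <- function(path, fs = 173.61, set_label = NA_character_,
                             record_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # tolerate trailing blank lines only
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) stop("format error: empty record file ", path)
  x <- suppressWarnings(as.numeric(trimws(lines)))
  bad <- which(is.na(x))
  if (length(bad) > 0L)
    stop(sprintf("format error in %s: non-numeric value on line %d ('%s')",
                 path, bad[1], trimws(lines[bad[1]])))
  if (is.null(record_id))
    record_id <- sub("\\.[^.]*$", "", basename(path))
  eeg_record(x, fs = fs, set_label = set_label, record_id = record_id)
}

#' Write a record in Bonn ASCII format
#'
#' Integer-valued samples are written as integers so that a
#' read-write-read round trip is exact; other values keep full precision.
#'
#' @param record an [eeg_record()] (or numeric vector).
#' @param path output file path.
#' @param round round samples to the nearest integer before writing
#'   (the convention of the original corpus, whose values are integer ADC
#'   counts).
#' @return `path`, invisibly.
#' @export
write_bonn_record <- function(record, path, round = FALSE) {
  x <- if (inherits(record, "eeg_record")) record$samples else as.numeric(record)
  if (round) x <- round(x)
  int_valued <- all(is.finite(x)) && all(x == trunc(x))
  txt <- if (int_valued) formatC(x, format = "f", digits = 0)
         else formatC(x, format = "g", digits = 17)
  writeLines(txt, path)
  invisible(path)
}

#' Load Bonn-style set directories into a list of records
#'
#' Expects one subdirectory per set under `root`, named either by the set
#' letter (A-E) or by the original corpus folder alias (Z, O, N, F, S).
#' Files within a set are sorted lexicographically so that record ids are
#' deterministic.
#'
#' @param root dataset root directory.
#' @param sets character vector of set labels to load.
#' @param fs sampling rate attached to every record.
#' @param aliases named character vector mapping set letters to alternative
#'   directory names.
#' @return list of [eeg_record()] objects.
#' @export
load_bonn_sets <- function(root, sets = c("A", "B", "C", "D", "E"),
                           fs = 173.61,
                           aliases = c(A = "Z", B = "O", C = "N", D = "F",
                                       E = "S")) {
  records <- list()
  for (set in sets) {
    dir <- file.path(root, set)
    if (!dir.exists(dir) && set %in% names(aliases))
      dir <- file.path(root, aliases[[set]])
    if (!dir.exists(dir))
      stop("configuration error: no directory for set '", set, "' under ",
           root)
    files <- sort(list.files(dir, full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (length(files) == 0L)
      stop("configuration error: set directory for '", set, "' is empty")
    for (f in files) {
      id <- paste0(set, ":", sub("\\.[^.]*$", "", basename(f)))
      records[[length(records) + 1L]] <-
        read_bonn_record(f, fs = fs, set_label = set, record_id = id)
    }
  }
  ids <- vapply(records, function(r) r$record_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate record ids in dataset")
  records
}

#' Dataset manifest
#'
#' @param records list of [eeg_record()].
#' @param path optional CSV output path.
#' @return data frame with one row per record (record_id, set, n_samples, fs).
#' @export
dataset_manifest <- function(records, path = NULL) {
  df <- data.frame(
    record_id = vapply(records, function(r) r$record_id, character(1)),
    set = vapply(records, function(r) r$set_label, character(1)),
    n_samples = vapply(records, function(r) length(r$samples), integer(1)),
    fs = vapply(records, function(r) r$fs, numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' Parse a classification task string into a class map
#'
#' A task string is a hyphen-separated list of letter groups; all sets in
#' group i are merged into class index i (0-based).  `"A-E"` is the
#' healthy-vs-ictal binary task; `"AB-CD-E"` merges the two healthy and the
#' two interictal sets into a ternary task; `"A-B-C-D-E"` is the five-class
#' task.
#'
#' @param name task string.
#' @return object of class `task_spec`: list with `name`, `class_map` (named
#'   integer vector of 0-based class indices) and `n_classes`.
#' @export
parse_task <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("parse error: task name must be a non-empty string")
  groups <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(groups) < 2L || any(!nzchar(groups)))
    stop("parse error: task '", name, "' needs at least two '-' groups")
  letters_used <- character(0)
  class_map <- integer(0)
  for (i in seq_along(groups)) {
    chars <- strsplit(groups[i], "")[[1]]
    if (any(!chars %in% LETTERS))
      stop("parse error: unknown set letter in task '", name, "'")
    if (any(chars %in% letters_used) || anyDuplicated(chars))
      stop("parse error: set letter used twice in task '", name, "'")
    letters_used <- c(letters_used, chars)
    cm <- rep(i - 1L, length(chars))
    names(cm) <- chars
    class_map <- c(class_map, cm)
  }
  structure(list(name = name, class_map = class_map,
                 n_classes = length(groups)),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task %s> %d classes; map: %s\n", x$name, x$n_classes,
              paste(names(x$class_map), x$class_map, sep = "->",
                    collapse = " ")))
  invisible(x)
}
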