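# Shared fixtures: all synthetic, generated in code at test time.

# A reduced-width model configuration for fast unit tests; the architecture
# (block structure, dilations, fusion) is identical to the full-size default.
tiny_model_config <- function(...) {
  defaults <- list(n_classes = 3L, rcm_kernel = 3L, dcpm_kernel = 3L,
                   rcm_channels = c(4L, 8L), dcpm_channels = 8L,
                   dcpm_dilations = c(1L, 2L), rcm_dropout = 0,
                   head_dropout = 0)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# Small labeled segment set with class-dependent structure, window `window`.
tiny_segments <- function(n_classes = 3L, records_per_class = 6L,
                          window = 64L, length = 512L, seed = 5L) {
  recs <- generate_dataset(synth_config(
    n_classes = n_classes, records_per_class = records_per_class,
    length = length, seed = seed))
  task <- parse_task(paste(LETTERS[seq_len(n_classes)], collapse = "-"))
  segment_records(recs, window = window, task = task)
}

# Deterministic ramp record for I/O and segmentation contracts.
ramp_record <- function(n = 4097L, id = "ramp") {
  eeg_record(seq_len(n), fs = 173.61, set_label = "A", record_id = id)
}

# The thirteen published task names (7 binary, 5 ternary, 1 five-class).
bonn_task_names <- c("A-E", "B-E", "C-E", "D-E", "AB-E", "CD-E", "ABCD-E",
                     "A-C-E", "A-D-E", "B-C-E", "B-D-E", "AB-CD-E",
                     "A-B-C-D-E")

# Ten-fold accuracies printed for the five-class and A-C-E tasks; used as
# *inputs* for the statistics recomputation checks.
five_class_fold_acc <- c(96.00, 94.50, 95.50, 96.00, 95.25, 93.50, 94.75,
                         96.50, 95.00, 94.00)
ace_fold_acc <- c(99.17, 99.58, 99.58, 100, 97.92, 98.75, 98.75, 99.58,
                  100, 99.58)
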