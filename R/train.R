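# Optimization: label-smoothed cross-entropy under Adam with gradient
# clipping, training-loss early stopping and "training set optimum"
# checkpoint selection.

#' Optimizer and regularization settings
#'
#' Defaults follow the published regimen: Adam with initial learning rate
#' 5e-4, weight decay 1e-4, batch size 64, at most 100 epochs, gradient
#' norm clipped at 1.0, label smoothing 0.2.  Early stopping monitors the
#' training loss (no validation split exists in the protocol; model
#' selection is train-set based) with patience 10 and minimum improvement
#' 1e-4.
#'
#' @param lr learning rate.
#' @param weight_decay L2 coefficient added to the gradient in the Adam
#'   step.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch cap.
#' @param clip_norm global gradient-norm clip (0 disables).
#' @param smoothing_alpha label-smoothing coefficient in \[0, 1).
#' @param seed RNG seed controlling initial shuffling/dropout streams.
#' @param early_stop_patience epochs without sufficient loss improvement
#'   before stopping.
#' @param early_stop_min_delta minimum loss decrease that counts as
#'   improvement.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 5e-4, weight_decay = 1e-4, batch_size = 64L,
                         max_epochs = 100L, clip_norm = 1.0,
                         smoothing_alpha = 0.2, seed = 1L,
                         early_stop_patience = 10L,
                         early_stop_min_delta = 1e-4) {
  stopifnot(lr > 0, weight_decay >= 0, batch_size >= 1, max_epochs >= 1,
            clip_norm >= 0, smoothing_alpha >= 0, smoothing_alpha < 1,
            early_stop_patience >= 1, early_stop_min_delta >= 0)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), clip_norm = clip_norm,
                 smoothing_alpha = smoothing_alpha, seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_min_delta = early_stop_min_delta),
            class = "train_config")
}

#' Convert hard labels to smoothed soft labels
#'
#' The true class receives `(1 - alpha) + alpha / C`, every other class
#' `alpha / C`; each row sums to 1 exactly.
#'
#' @param y integer vector of 0-based class indices.
#' @param alpha smoothing coefficient in \[0, 1).
#' @param n_classes number of classes C.
#' @return numeric matrix, one row per label.
#' @export
smooth_labels <- function(y, alpha, n_classes) {
  y <- as.integer(y)
  if (any(y < 0L | y >= n_classes))
    stop("index error: label outside 0..", n_classes - 1L)
  m <- matrix(alpha / n_classes, length(y), n_classes)
  m[cbind(seq_along(y), y + 1L)] <- (1 - alpha) + alpha / n_classes
  m
}

#' Label-smoothed cross-entropy loss
#'
#' Mean over rows of `-sum(soft * log(pmax(prob, 1e-12)))`; the floor
#' guards `log(0)` for degenerate probability inputs.
#'
#' @param prob probability matrix (rows sum to 1).
#' @param soft soft-label matrix of the same shape (e.g. from
#'   [smooth_labels()]).
#' @return scalar loss in nats.
#' @export
smoothed_ce_loss <- function(prob, soft) {
  stopifnot(all(dim(prob) == dim(soft)))
  -mean(rowSums(soft * log(pmax(prob, 1e-12))))
}

#' Select the checkpoint epoch from a training history
#'
#' Highest training accuracy, ties broken by lowest training loss, further
#' ties by the earliest epoch.
#'
#' @param history data frame with `accuracy` and `loss` columns in epoch
#'   order.
#' @return 0-based epoch index.
#' @export
select_checkpoint <- function(history) {
  if (nrow(history) == 0L) stop("empty training history")
  ord <- order(-history$accuracy, history$loss, seq_len(nrow(history)))
  ord[1] - 1L
}

adam_state <- function(params) {
  trainable <- grepl("(_W|_b|_gamma|_beta)$", names(params)) &
    !grepl("(_rmean|_rvar)$", names(params))
  zeros <- lapply(params[trainable], function(p) rep(0, length(p)))
  list(t = 0, m = zeros, v = zeros)
}

#' Train a model on a set of labeled segments
#'
#' Runs Adam with the configured settings, shuffling the data each epoch
#' with a seed derived from `cfg$seed` so two runs with identical seeds
#' produce identical histories.  Per-epoch training loss and accuracy are
#' accumulated over the mini-batch forward passes.  Training stops early
#' when the loss has not improved by `early_stop_min_delta` for
#' `early_stop_patience` consecutive epochs.  The returned model carries
#' the weights of the selected epoch ([select_checkpoint()]), not
#' necessarily the last one.
#'
#' @param model an `eegnet` from [build_model()].
#' @param segments a labeled `segment_set`.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress to stderr.
#' @return list with `model` (selected weights), `history` (data frame:
#'   epoch, loss, accuracy) and `selected_epoch` (0-based).
#' @export
train_model <- function(model, segments, cfg = train_config(),
                        verbose = FALSE) {
  if (n_segments(segments) == 0L) stop("no training data")
  y <- segments$label
  if (anyNA(y)) stop("segments carry no labels; segment with a task spec")
  C <- model$config$n_classes
  if (any(y < 0L | y >= C)) stop("index error: label outside 0..", C - 1L)

  params <- model$params
  opt <- adam_state(params)
  x <- segments$values
  loss <- acc <- numeric(0)
  best <- NULL
  best_loss <- Inf
  stale <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    epoch_seed <- (cfg$seed * 10007L + epoch * 7919L) %% .Machine$integer.max
    res <- cpp_train_epoch(params, opt, model$config, cfg, x, y,
                           as.integer(epoch_seed))
    params <- res$params
    opt <- res$opt
    loss[epoch] <- res$loss
    acc[epoch] <- res$acc
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  acc %.4f", epoch, res$loss,
                      res$acc))
    hist_now <- data.frame(epoch = seq_len(epoch) - 1L,
                           loss = loss, accuracy = acc)
    if (select_checkpoint(hist_now) == epoch - 1L)
      best <- params
    if (res$loss < best_loss - cfg$early_stop_min_delta) {
      best_loss <- res$loss
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$early_stop_patience) break
    }
  }
  history <- data.frame(epoch = seq_along(loss) - 1L, loss = loss,
                        accuracy = acc)
  sel <- select_checkpoint(history)
  model$params <- best
  # precise normalization statistics: one frozen-weight pass over the
  # training data replaces the momentum-lagged running moments with exact
  # aggregates, so evaluation mode matches converged training behavior
  model$params <- cpp_bn_recalibrate(model$params, model$config, x,
                                     cfg$batch_size)
  list(model = model, history = history, selected_epoch = sel)
}
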