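# Network construction, component forwards and parameter accounting.
#
# The architecture: two residual blocks (k=5 convolutions, 64 then 128
# channels, stride-2 downsampling, dilation 2 on the second conv of each
# block, 1x1-conv shortcut) -> five cascaded dilated convolutions (k=5,
# dilations 1,2,4,8,16, length-preserving) -> dual-pathway fusion of
# global-max-pooled and differential-entropy features from the shallow
# (residual) and deep (pyramid) pathways, each through its own batch
# normalization -> BN-ReLU-dropout-linear classifier head.
#
# Conventions pinned for reproducible parameter counts: convolutions
# followed by batch normalization carry no bias; the shortcut is 1x1 conv +
# BN; the final linear layer keeps its bias.  The default five-class,
# single-channel configuration totals 568,581 trainable scalars.

#' Architectural configuration
#'
#' Defaults reproduce the published-size network: kernels of 5, residual
#' channels (64, 128), a 128-channel pyramid with dilations 1,2,4,8,16,
#' dropout 0.3 after each residual block and 0.5 in the head.
#'
#' @param in_channels input channels (1 for Bonn-style records).
#' @param n_classes number of output classes.
#' @param rcm_kernel,dcpm_kernel convolution kernel sizes (odd, >= 3).
#' @param rcm_channels channel widths of the two residual blocks.
#' @param dcpm_channels pyramid channel width (must equal
#'   `rcm_channels[2]` when both modules are enabled).
#' @param dcpm_dilations strictly increasing positive dilation rates.
#' @param rcm_dropout,head_dropout dropout rates.
#' @param use_rcm,use_dcpm,use_entropy ablation switches.  With
#'   `use_rcm = FALSE` the input is projected to the pyramid width by a 1x1
#'   convolution followed by stride-4 max pooling; with `use_dcpm = FALSE`
#'   the pyramid is replaced by the identity so the residual output feeds
#'   both fusion pathways; with `use_entropy = FALSE` only the pooled
#'   features are fused (width 2 x channels instead of 4 x channels).
#' @param entropy an [entropy_spec()] used by the fusion module.
#' @return object of class `model_config`.
#' @export
model_config <- function(in_channels = 1L, n_classes = 5L,
                         rcm_kernel = 5L, dcpm_kernel = 5L,
                         rcm_channels = c(64L, 128L), dcpm_channels = 128L,
                         dcpm_dilations = c(1L, 2L, 4L, 8L, 16L),
                         rcm_dropout = 0.3, head_dropout = 0.5,
                         use_rcm = TRUE, use_dcpm = TRUE,
                         use_entropy = TRUE,
                         entropy = entropy_spec()) {
  if (!use_rcm && !use_dcpm)
    stop("configuration error: cannot disable both the residual module ",
         "and the dilated pyramid")
  for (k in c(rcm_kernel, dcpm_kernel))
    if (k < 3L || k %% 2L == 0L) stop("kernels must be odd and >= 3")
  d <- as.integer(dcpm_dilations)
  if (any(d < 1L) || any(diff(d) <= 0L))
    stop("dilations must be strictly increasing positive integers")
  if (use_rcm && use_dcpm && rcm_channels[2] != dcpm_channels)
    stop("rcm_channels[2] must equal dcpm_channels")
  stopifnot(inherits(entropy, "entropy_spec"))
  structure(list(
    in_channels = as.integer(in_channels), n_classes = as.integer(n_classes),
    rcm_kernel = as.integer(rcm_kernel), dcpm_kernel = as.integer(dcpm_kernel),
    rcm_channels = as.integer(rcm_channels),
    dcpm_channels = as.integer(dcpm_channels),
    dcpm_dilations = d, rcm_dropout = rcm_dropout,
    head_dropout = head_dropout, use_rcm = isTRUE(use_rcm),
    use_dcpm = isTRUE(use_dcpm), use_entropy = isTRUE(use_entropy),
    entropy = entropy), class = "model_config")
}

pathway_width <- function(cfg) {
  if (cfg$use_rcm) cfg$rcm_channels[2] else cfg$dcpm_channels
}

#' Width of the fused feature vector
#' @param cfg a [model_config()].
#' @return integer: 4 x pathway width with entropy features, 2 x without.
#' @export
fused_width <- function(cfg) {
  (if (cfg$use_entropy) 4L else 2L) * pathway_width(cfg)
}

he_mat <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

bn_params <- function(width) {
  list(gamma = rep(1, width), beta = rep(0, width),
       rmean = rep(0, width), rvar = rep(1, width))
}

add_bn <- function(params, name, width) {
  b <- bn_params(width)
  params[[paste0(name, "_gamma")]] <- b$gamma
  params[[paste0(name, "_beta")]] <- b$beta
  params[[paste0(name, "_rmean")]] <- b$rmean
  params[[paste0(name, "_rvar")]] <- b$rvar
  params
}

init_params <- function(cfg) {
  p <- list()
  k <- cfg$rcm_kernel
  if (cfg$use_rcm) {
    c1 <- cfg$rcm_channels[1]; c2 <- cfg$rcm_channels[2]
    p$rcm1_conv1_W <- he_mat(c1, cfg$in_channels * k, cfg$in_channels * k)
    p <- add_bn(p, "rcm1_bn1", c1)
    p$rcm1_conv2_W <- he_mat(c1, c1 * k, c1 * k)
    p <- add_bn(p, "rcm1_bn2", c1)
    p$rcm1_sc_W <- he_mat(c1, cfg$in_channels, cfg$in_channels)
    p <- add_bn(p, "rcm1_scbn", c1)
    p$rcm2_conv1_W <- he_mat(c2, c1 * k, c1 * k)
    p <- add_bn(p, "rcm2_bn1", c2)
    p$rcm2_conv2_W <- he_mat(c2, c2 * k, c2 * k)
    p <- add_bn(p, "rcm2_bn2", c2)
    p$rcm2_sc_W <- he_mat(c2, c1, c1)
    p <- add_bn(p, "rcm2_scbn", c2)
  } else {
    p$adapt_W <- he_mat(cfg$dcpm_channels, cfg$in_channels, cfg$in_channels)
    p <- add_bn(p, "adapt_bn", cfg$dcpm_channels)
  }
  if (cfg$use_dcpm) {
    kd <- cfg$dcpm_kernel; ch <- cfg$dcpm_channels
    for (i in seq_along(cfg$dcpm_dilations)) {
      p[[sprintf("dcpm%d_W", i)]] <- he_mat(ch, ch * kd, ch * kd)
      p <- add_bn(p, sprintf("dcpm%d_bn", i), ch)
    }
  }
  w <- pathway_width(cfg)
  p <- add_bn(p, "ffem_bn_pb", w)
  p <- add_bn(p, "ffem_bn_pm", w)
  if (cfg$use_entropy) {
    p <- add_bn(p, "ffem_bn_eb", w)
    p <- add_bn(p, "ffem_bn_em", w)
  }
  f <- fused_width(cfg)
  p <- add_bn(p, "head_bn", f)
  p$head_W <- he_mat(cfg$n_classes, f, f)
  p$head_b <- rep(0, cfg$n_classes)
  p
}

#' Build a model with freshly initialized weights
#'
#' Convolution and linear weights use fan-in-scaled (He) normal
#' initialization; batch-norm scales start at 1, shifts at 0.  The seed
#' makes initialization reproducible.
#'
#' @param cfg a [model_config()].
#' @param seed integer RNG seed.
#' @return object of class `eegnet`: list with `config` and `params`.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  params <- withr::with_seed(as.integer(seed), init_params(cfg))
  structure(list(config = cfg, params = params), class = "eegnet")
}

#' @export
print.eegnet <- function(x, ...) {
  cfg <- x$config
  mods <- c(if (cfg$use_rcm) "residual" else "1x1-adapter",
            if (cfg$use_dcpm) "dilated-pyramid",
            paste0("fusion(", if (cfg$use_entropy)
              paste0("pooled+", cfg$entropy$kind) else "pooled-only", ")"))
  cat(sprintf("<eegnet> %d-channel input, %d classes; %s; %s parameters\n",
              cfg$in_channels, cfg$n_classes, paste(mods, collapse = " -> "),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Counts convolution and linear weights, the linear bias and the
#' batch-normalization affine parameters; running statistics are buffers,
#' not parameters.
#'
#' @param model an `eegnet`.
#' @return integer total.
#' @export
count_parameters <- function(model) {
  nm <- names(model$params)
  trainable <- grepl("(_W|_b|_gamma|_beta)$", nm) &
    !grepl("(_rmean|_rvar)$", nm)
  sum(vapply(model$params[trainable], length, integer(1)))
}

#' Receptive field of a stride-1 dilated convolution stack
#'
#' `RF = 1 + sum((k_i - 1) * d_i)` over the layers; for the default
#' five-layer pyramid (k=5, dilations 1,2,4,8,16) this is 125 samples.
#'
#' @param kernels integer vector of kernel sizes.
#' @param dilations integer vector of dilation rates (recycled to the
#'   length of `kernels`).
#' @return integer receptive field in samples.
#' @export
receptive_field <- function(kernels, dilations = 1L) {
  if (length(kernels) == 0L) stop("need at least one layer")
  dilations <- rep_len(as.integer(dilations), length(kernels))
  1L + sum((as.integer(kernels) - 1L) * dilations)
}

as_value_matrix <- function(x) {
  if (inherits(x, "segment_set")) x$values else as.matrix(x)
}

#' Evaluation-mode forward pass
#'
#' @param model an `eegnet`.
#' @param x a `segment_set` or numeric matrix with one segment per row
#'   (`n_channels * window` columns, channel-major).
#' @param stage `"logits"` for class scores, `"fused"` for the fused
#'   feature vector, `"rcm"`/`"dcpm"` for channel-wise max-pooled outputs
#'   of the shallow and deep pathways.
#' @return numeric matrix, one row per segment.
#' @export
forward_features <- function(model, x, stage = "logits") {
  stages <- c("logits", "fused", "rcm", "dcpm")
  if (!stage %in% stages)
    stop("configuration error: unknown stage '", stage, "'")
  if (stage == "dcpm" && !model$config$use_dcpm)
    stop("configuration error: model was built without the dilated pyramid")
  cpp_forward(model$params, model$config, as_value_matrix(x), stage)
}

#' Softmax class probabilities from logits
#'
#' @param logits numeric matrix (rows = segments) or vector.
#' @return matrix of probabilities; rows sum to 1.
#' @export
predict_proba <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' @export
predict.eegnet <- function(object, newdata,
                           type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  z <- forward_features(object, newdata, "logits")
  switch(type,
    logits = z,
    prob = predict_proba(z),
    class = max.col(z) - 1L)
}

#' Run one residual block on a feature map
#'
#' Main path: conv(k, stride 2) - BN - ReLU - conv(k, stride 1, dilation 2)
#' - BN; shortcut: 1x1 conv (stride 2) - BN; output ReLU(main + shortcut).
#' Evaluation mode (running BN statistics, no dropout); temporal length
#' halves.
#'
#' @param model an `eegnet` with the residual module enabled.
#' @param x channels x time numeric matrix.
#' @param block 1 or 2.
#' @return channels x time/2 matrix.
#' @export
resblock_forward <- function(model, x, block = 1L) {
  cpp_resblock(model$params, model$config, as.integer(block), as.matrix(x))
}

#' Run the dilated convolution pyramid on a feature map
#'
#' Five cascaded conv-BN-ReLU stages with exponentially increasing
#' dilations; symmetric padding of `d * (k - 1) / 2` keeps the temporal
#' length unchanged.  Evaluation mode.
#'
#' @param model an `eegnet` with the pyramid enabled.
#' @param x channels x time numeric matrix (pyramid width rows).
#' @return matrix of the same shape.
#' @export
dcpm_forward <- function(model, x) {
  cpp_dcpm(model$params, model$config, as.matrix(x))
}

#' Dual-pathway feature fusion for one pair of feature maps
#'
#' Computes per-channel global max pooling and entropy descriptors for the
#' shallow (`branch`) and deep (`main`) feature maps, normalizes each of
#' the four vectors with its own batch normalization (running statistics)
#' and concatenates them in the fixed order (pooled_branch, pooled_main,
#' entropy_branch, entropy_main).
#'
#' @param model an `eegnet`.
#' @param branch,main channels x time matrices with pathway-width rows.
#' @return list with the raw pooled (and entropy) vectors and the
#'   normalized concatenated `fused` vector.
#' @export
ffem_forward <- function(model, branch, main) {
  cpp_ffem(model$params, model$config, as.matrix(branch), as.matrix(main))
}

#' Classifier head: fused features to logits
#'
#' BN - ReLU - dropout (off in evaluation) - linear.
#'
#' @param model an `eegnet`.
#' @param fused numeric vector or matrix (rows = segments) of fused
#'   features.
#' @return logits matrix, one row per segment.
#' @export
classify <- function(model, fused) {
  if (is.null(dim(fused))) fused <- matrix(fused, nrow = 1L)
  cpp_head(model$params, model$config, fused)
}

# ---------------------------------------------------------------------------
# serialization

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$entropy <- unclass(out$entropy)
  out
}

config_from_list <- function(lst) {
  ent <- do.call(entropy_spec, lst$entropy)
  lst$entropy <- NULL
  do.call(model_config, c(lst, list(entropy = ent)))
}

#' Save / load a model checkpoint
#'
#' Weights go to `<path>` (RDS); the architectural configuration goes to a
#' JSON sidecar `<path>.json` so a checkpoint is self-describing.  The
#' config round trip is lossless.
#'
#' @param model an `eegnet`.
#' @param path checkpoint file path.
#' @return `path` invisibly (`save_model`); an `eegnet` (`load_model`).
#' @export
save_model <- function(model, path) {
  saveRDS(model$params, path)
  jsonlite::write_json(config_to_list(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  cfg <- config_from_list(
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE))
  params <- readRDS(path)
  structure(list(config = cfg, params = params), class = "eegnet")
}
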