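# Entropy descriptors of 1-D feature maps.
#
# The fusion module summarises each channel of a feature map by its
# differential entropy, 1/2 * log(2*pi*e*(sigma^2 + eps)) in nats, with
# sigma^2 the unbiased (N-1) variance over time.  Four alternative
# descriptors are provided for the entropy-type sensitivity study; their
# estimator details (bin counts, orders, spectral estimator) are this
# package's own reconstructions, chosen once and documented, not claims of
# equivalence to any external variant.

#' Entropy descriptor settings
#'
#' @param kind one of `"differential"`, `"shannon"`, `"renyi"`,
#'   `"spectral"`, `"tsallis"`.
#' @param eps stability constant added to the variance (differential kind).
#' @param n_bins number of equal-width histogram bins for the discretizing
#'   kinds.
#' @param order Renyi alpha or Tsallis q (must be positive and not 1).
#' @return object of class `entropy_spec`.
#' @export
entropy_spec <- function(kind = "differential", eps = 1e-6, n_bins = 16L,
                         order = 2) {
  kinds <- c("differential", "shannon", "renyi", "spectral", "tsallis")
  if (!kind %in% kinds)
    stop("configuration error: unknown entropy kind '", kind, "'")
  if (eps <= 0) stop("eps must be > 0")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (kind %in% c("renyi", "tsallis") && (order <= 0 || order == 1))
    stop("order must be positive and != 1 for ", kind, " entropy")
  structure(list(kind = kind, eps = eps, n_bins = as.integer(n_bins),
                 order = order),
            class = "entropy_spec")
}

as_channel_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) < 2L)
    stop("undefined-variance error: need at least 2 time points per channel")
  x
}

#' Differential entropy per channel
#'
#' For each row (channel) of `x`, returns
#' `0.5 * log(2 * pi * e * (var + eps))` in nats, with `var` the unbiased
#' (N-1 denominator) variance over time.  For Gaussian data this estimates
#' the channel's differential entropy; for arbitrary data it is a monotone
#' summary of dispersion.
#'
#' @param x numeric vector (one channel) or channels x time matrix.
#' @param eps stability constant; keeps the value finite for constant
#'   channels.
#' @return numeric vector with one value per channel.
#' @export
differential_entropy <- function(x, eps = 1e-6) {
  x <- as_channel_matrix(x)
  v <- apply(x, 1L, var)
  0.5 * log(2 * pi * exp(1) * (v + eps))
}

hist_probs <- function(v, n_bins) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    p <- c(1, rep(0, n_bins - 1L))
  } else {
    bin <- pmin(floor((v - lo) / ((hi - lo) / n_bins)), n_bins - 1L)
    p <- tabulate(bin + 1L, nbins = n_bins) / length(v)
  }
  p
}

shannon_from_probs <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-channel entropy descriptor
#'
#' Dispatches on the descriptor kind: `"differential"` delegates to
#' [differential_entropy()]; `"shannon"`, `"renyi"` and `"tsallis"`
#' discretize each channel into `n_bins` equal-width bins over its own
#' min-max range and apply the respective formula to the bin frequencies;
#' `"spectral"` applies the Shannon formula to the channel's normalized
#' periodogram with the DC bin excluded (offset is not oscillatory
#' structure).  All values are in nats.
#'
#' @param x numeric vector or channels x time matrix.
#' @param spec an [entropy_spec()].
#' @return numeric vector with one value per channel.
#' @export
entropy_descriptor <- function(x, spec = entropy_spec()) {
  stopifnot(inherits(spec, "entropy_spec"))
  x <- as_channel_matrix(x)
  switch(spec$kind,
    differential = differential_entropy(x, spec$eps),
    shannon = apply(x, 1L, function(v)
      shannon_from_probs(hist_probs(v, spec$n_bins))),
    renyi = apply(x, 1L, function(v) {
      p <- hist_probs(v, spec$n_bins)
      log(sum(p^spec$order)) / (1 - spec$order)
    }),
    tsallis = apply(x, 1L, function(v) {
      p <- hist_probs(v, spec$n_bins)
      (1 - sum(p^spec$order)) / (spec$order - 1)
    }),
    spectral = apply(x, 1L, function(v) {
      P <- Mod(fft(v))^2
      nf <- length(v) %/% 2L
      P <- P[seq_len(nf) + 1L] # bins 1..floor(T/2); DC excluded
      tot <- sum(P)
      if (tot <= 0) return(0)
      shannon_from_probs(P / tot)
    }),
    stop("configuration error: unknown entropy kind"))
}
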