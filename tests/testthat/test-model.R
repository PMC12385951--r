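test_that("configuration validation enforces the architectural invariants", {
  expect_error(model_config(use_rcm = FALSE, use_dcpm = FALSE),
               "configuration error")
  expect_error(model_config(rcm_kernel = 4), "odd")
  expect_error(model_config(dcpm_dilations = c(1, 2, 2)), "increasing")
  expect_error(model_config(rcm_channels = c(64L, 96L)),
               "must equal dcpm_channels")
})

test_that("stage shapes follow the published table for any valid length", {
  m <- build_model(tiny_model_config(), seed = 1)
  w <- 8L # pathway width of the tiny config
  for (T in c(4L, 16L, 64L, 256L)) {
    x <- matrix(rnorm(3 * T), 3, T)
    expect_identical(dim(forward_features(m, x, "rcm")), c(3L, w))
    expect_identical(dim(forward_features(m, x, "dcpm")), c(3L, w))
    expect_identical(dim(forward_features(m, x, "fused")), c(3L, 4L * w))
    expect_identical(dim(forward_features(m, x, "logits")), c(3L, 3L))
  }
  # temporal halving is exact per block
  x1 <- matrix(rnorm(64), 1, 64)
  expect_identical(dim(resblock_forward(m, x1, 1)), c(4L, 32L))
  expect_identical(dim(resblock_forward(m, matrix(rnorm(4 * 32), 4), 2)),
                   c(8L, 16L))
  # the pyramid preserves length at any input length
  for (T in c(5L, 16L, 33L))
    expect_identical(dim(dcpm_forward(m, matrix(rnorm(8 * T), 8))),
                     c(8L, T))
})

test_that("ablations change the fused width and wiring as specified", {
  m_ne <- build_model(tiny_model_config(use_entropy = FALSE), seed = 1)
  x <- matrix(rnorm(2 * 32), 2, 32)
  expect_identical(ncol(forward_features(m_ne, x, "fused")), 16L) # 2 x 8
  m_nd <- build_model(tiny_model_config(use_dcpm = FALSE), seed = 1)
  f <- forward_features(m_nd, x, "fused")
  expect_identical(ncol(f), 32L)
  # identity in place of the pyramid: both pooled pathways carry the same
  # map (their freshly initialized normalizations are identical)
  expect_equal(f[, 9:16], f[, 1:8], tolerance = 1e-6)
  m_nr <- build_model(tiny_model_config(use_rcm = FALSE), seed = 1)
  z <- forward_features(m_nr, x, "logits")
  expect_identical(dim(z), c(2L, 3L))
  expect_error(resblock_forward(m_nr, x, 1), "without the residual")
})

test_that("parameter accounting matches closed-form layer enumeration", {
  # conv: out*in*k (bias-free); BN: 2*width affine; linear: in*out + out
  m <- build_model(model_config(), seed = 1)
  rb1 <- 64 * 1 * 5 + 2 * 64 + 64 * 64 * 5 + 2 * 64 + 64 * 1 + 2 * 64
  rb2 <- 128 * 64 * 5 + 2 * 128 + 128 * 128 * 5 + 2 * 128 + 128 * 64 +
    2 * 128
  dcpm <- 5 * (128 * 128 * 5 + 2 * 128)
  ffem <- 4 * 2 * 128
  head <- 2 * 512 + 512 * 5 + 5
  expect_equal(dcpm, 410880)
  expect_equal(count_parameters(m), rb1 + rb2 + dcpm + ffem + head)

  # the head is local: extra classes only add 512 + 1 weights each
  m6 <- build_model(model_config(n_classes = 6L), seed = 1)
  expect_identical(count_parameters(m6) - count_parameters(m), 512L + 1L)

  # removing the pyramid removes exactly its block total
  m_nd <- build_model(model_config(use_dcpm = FALSE), seed = 1)
  expect_identical(count_parameters(m) - count_parameters(m_nd), 410880L)

  # every ablation strictly reduces the total
  for (drop in list(list(use_rcm = FALSE), list(use_dcpm = FALSE),
                    list(use_entropy = FALSE))) {
    cfg <- do.call(model_config, drop)
    expect_lt(count_parameters(build_model(cfg, seed = 1)),
              count_parameters(m))
  }
})

test_that("receptive field formula matches a gradient-support oracle", {
  expect_identical(receptive_field(5, 1), 5L)
  expect_identical(receptive_field(rep(5, 5), c(1, 2, 4, 8, 16)), 125L)
  expect_identical(receptive_field(c(3, 3), 1), 5L)

  # oracle: with all-ones weights and no padding, probe which input
  # positions influence ONE fixed output position; the receptive field is
  # the span of that influence set
  support_oracle <- function(kernels, dilations) {
    T <- receptive_field(kernels, dilations) + 8L
    run <- function(x) {
      h <- x
      for (i in seq_along(kernels)) {
        W <- matrix(1, 1, kernels[i])
        h <- eegpyramid:::cpp_conv1d(h, W, kernels[i], 1L, dilations[i], 0L)
      }
      h
    }
    touched <- vapply(seq_len(T), function(t) {
      x <- matrix(0, 1, T); x[1, t] <- 1
      run(x)[1, 1] != 0
    }, logical(1))
    diff(range(which(touched))) + 1L
  }
  expect_identical(support_oracle(rep(5L, 5L), c(1L, 2L, 4L, 8L, 16L)),
                   125L)
  set.seed(8)
  for (i in 1:5) {
    n_layers <- sample(1:3, 1)
    ks <- sample(c(3L, 5L, 7L), n_layers, replace = TRUE)
    ds <- sample(c(1L, 2L, 4L), n_layers, replace = TRUE)
    expect_identical(support_oracle(ks, ds),
                     as.integer(receptive_field(ks, ds)),
                     info = paste("k:", toString(ks), "d:", toString(ds)))
  }
})

test_that("convolution primitive reproduces hand-computed responses", {
  # 5-tap box filter over an impulse: a width-5 box in the valid region
  x <- matrix(0, 1, 11)
  x[1, 6] <- 1
  y <- eegpyramid:::cpp_conv1d(x, matrix(1, 1, 5), 5L, 1L, 1L, 2L)
  expect_equal(as.numeric(y), c(0, 0, 0, 1, 1, 1, 1, 1, 0, 0, 0))
  # dilation spreads the taps
  y2 <- eegpyramid:::cpp_conv1d(x, matrix(1, 1, 3), 3L, 1L, 2L, 2L)
  expect_equal(which(as.numeric(y2) != 0), c(4, 6, 8))
})

test_that("residual blocks propagate zero and obey the skip identity", {
  m <- build_model(tiny_model_config(), seed = 2)
  # zero input -> zero output (BN shifts are 0 at initialization)
  y0 <- resblock_forward(m, matrix(0, 1, 32), 1)
  expect_true(all(y0 == 0))
  # zero main path + identity-like shortcut -> ReLU(shortcut(x))
  m2 <- m
  m2$params$rcm1_conv1_W[] <- 0
  m2$params$rcm1_conv2_W[] <- 0
  x <- matrix(rnorm(32), 1, 32)
  y <- resblock_forward(m2, x, 1)
  # shortcut = 1x1 conv stride 2; its initialized BN is near-identity
  sc <- outer(as.numeric(m2$params$rcm1_sc_W), x[1, seq(1, 32, 2)])
  expect_equal(y, pmax(sc, 0), tolerance = 1e-4)
})

test_that("fusion is permutation invariant and degenerate-input exact", {
  m <- build_model(tiny_model_config(), seed = 3)
  set.seed(9)
  fb <- matrix(rnorm(8 * 16), 8)
  fm <- matrix(rnorm(8 * 16), 8)
  b1 <- ffem_forward(m, fb, fm)
  perm <- sample(16)
  b2 <- ffem_forward(m, fb[, perm], fm[, perm])
  expect_equal(b1$fused, b2$fused, tolerance = 1e-6)
  expect_length(b1$fused, 32) # 4 x 8 with entropy

  # constant maps: pooled features equal the constant, entropy features
  # equal 0.5*ln(2*pi*e*eps)
  cb <- matrix(2, 8, 16)
  b3 <- ffem_forward(m, cb, cb)
  expect_equal(b3$pooled_branch, rep(2, 8), tolerance = 1e-6)
  expect_equal(b3$entropy_main,
               rep(0.5 * log(2 * pi * exp(1) * 1e-6), 8), tolerance = 1e-4)

  m_ne <- build_model(tiny_model_config(use_entropy = FALSE), seed = 3)
  expect_length(ffem_forward(m_ne, fb, fm)$fused, 16)
})

test_that("classifier softmax matches closed forms", {
  expect_equal(as.numeric(predict_proba(c(1, 1, 1))), rep(1 / 3, 3))
  expect_equal(as.numeric(predict_proba(c(0, log(3)))), c(0.25, 0.75))
  set.seed(10)
  p <- predict_proba(matrix(rnorm(40, sd = 5), 8))
  expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-6)
  # classify produces one logit row per fused vector
  m <- build_model(tiny_model_config(), seed = 4)
  z <- classify(m, matrix(rnorm(2 * 32), 2))
  expect_identical(dim(z), c(2L, 3L))
})

test_that("checkpoints round-trip losslessly with a JSON config sidecar", {
  m <- build_model(tiny_model_config(n_classes = 4L), seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  expect_equal(m2$config, m$config)
  expect_equal(m2$params, m$params)
  x <- matrix(rnorm(2 * 32), 2)
  expect_identical(forward_features(m, x), forward_features(m2, x))
})

test_that("evaluation-mode forward is deterministic", {
  m <- build_model(tiny_model_config(), seed = 6)
  x <- matrix(rnorm(5 * 64), 5)
  expect_identical(forward_features(m, x), forward_features(m, x))
})
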