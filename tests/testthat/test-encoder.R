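# Small widths keep these fast; the printed-architecture shapes at the full
# 1024-wide input are asserted in the acceptance suite.

small_cfg <- function(...) {
  encoder_config(
    epochs = 15, batch_size = 8, dropout = 0.5, seed = 3, ...
  )
}

test_that("parameter counts follow the layer shape arithmetic for every variant", {
  W <- 64L
  C <- 16L
  code <- 32L
  count <- function(variant) {
    encoder_n_params(
      encoder_config(code_dim = code, variant = variant), W
    )
  }
  conv <- C * 3 + C
  fc <- C * C + C
  head <- code * 2 + 2
  expect_equal(count("full"), conv + fc + (C * W / 2) * code + code + head)
  expect_equal(count("relu_fc_ablation"), conv + (C * W / 2) * code + code + head)
  expect_equal(count("pool_ablation"), conv + fc + (C * W) * code + code + head)
  # conv ablated: dense W x W ReLU FC on the raw input, then pool to W/2
  expect_equal(count("conv_ablation"), W * W + W + (W / 2) * code + code + head)
  expect_error(build_variant(encoder_config(), "nope"), class = "mirdap_config_error")
})

test_that("training reduces the loss on separable data and is seed-deterministic", {
  set.seed(9)
  X <- matrix(rnorm(40 * 1024), 40, 1024)
  y <- rep(c(0, 1), each = 20)
  X[y == 1, c(5, 900)] <- X[y == 1, c(5, 900)] + 4
  cfg <- encoder_config(epochs = 8, batch_size = 8, seed = 11)
  enc <- train_encoder(X, y, cfg)
  expect_lt(enc$loss_trace[enc$epochs_run], enc$loss_trace[1])
  expect_length(enc$loss_trace, enc$epochs_run)

  enc2 <- train_encoder(X, y, cfg)
  expect_identical(enc$theta, enc2$theta)
})

test_that("the reported head loss equals an independent cross-entropy recomputation", {
  set.seed(2)
  X <- matrix(rnorm(30 * 64), 30, 64)
  y <- rep(c(0, 1), c(15, 15))
  cfg <- small_cfg()
  enc <- train_encoder(X, y, cfg)
  lg <- encoder_loss_gradient(enc$theta, X, y, cfg)
  probs <- encoder_forward(enc, X)$probabilities
  ce <- -mean(log(probs[cbind(seq_along(y), y + 1)]))
  expect_equal(lg$loss, ce, tolerance = 1e-6)
})

test_that("encoding is a pure function with dropout inactive", {
  set.seed(4)
  X <- matrix(rnorm(20 * 64), 20, 64)
  y <- rep(c(0, 1), 10)
  enc <- train_encoder(X, y, small_cfg(code_dim = 16))
  c1 <- encode(enc, X)
  expect_identical(c1, encode(enc, X))
  expect_equal(dim(c1), c(20L, 16L))
  # duplicated rows encode identically
  Xd <- X[c(1, 1, 7, 7), ]
  cd <- encode(enc, Xd)
  expect_identical(cd[1, ], cd[2, ])
  expect_identical(cd[3, ], cd[4, ])
  # train-mode forward applies dropout, so it differs but stays normalized
  fw <- encoder_forward(enc, X, train_mode = TRUE, seed = 5)
  expect_equal(rowSums(fw$probabilities), rep(1, 20), tolerance = 1e-9)
})

test_that("analytic gradients match central differences on every variant", {
  set.seed(6)
  W <- 16L
  X <- matrix(rnorm(4 * W), 4, W)
  y <- c(0, 1, 0, 1)
  for (variant in encoder_variants()) {
    cfg <- encoder_config(code_dim = 8, variant = variant, seed = 7)
    th <- encoder_init(cfg, W)
    an <- encoder_loss_gradient(th, X, y, cfg)
    idx <- sample(length(th), min(20, length(th)))
    num <- numeric_gradient(
      function(s) {
        t2 <- th
        t2[idx] <- s
        encoder_loss_gradient(t2, X, y, cfg)$loss
      },
      th[idx],
      eps = 1e-3
    )
    denom <- pmax(abs(num), 1e-4)
    expect_lt(max(abs(an$grad[idx] - num) / denom), 1e-4)
  }
})

test_that("mismatched widths and single-class labels are rejected", {
  set.seed(1)
  X <- matrix(rnorm(20 * 32), 20, 32)
  y <- rep(c(0, 1), 10)
  enc <- train_encoder(X, y, small_cfg(code_dim = 8))
  expect_error(encode(enc, X[, 1:10]), class = "mirdap_shape_error")
  expect_error(
    train_encoder(X, rep(2, 20), small_cfg()),
    class = "mirdap_value_error"
  )
  expect_error(
    train_encoder(X, rep(1L, 20), small_cfg()),
    class = "mirdap_config_error"
  )
})

test_that("encoders round-trip through the portable checkpoint format", {
  set.seed(8)
  X <- matrix(rnorm(20 * 32), 20, 32)
  y <- rep(c(0, 1), 10)
  enc <- train_encoder(X, y, small_cfg(code_dim = 8, standardize = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  write_encoder(enc, path)
  back <- read_encoder(path)
  expect_equal(back$theta, enc$theta)
  expect_equal(encode(back, X), encode(enc, X))
  expect_equal(glance(back)$variant, "full")
})
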