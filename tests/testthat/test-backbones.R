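test_that("residual block is the identity when its transform branch is zeroed", {
  set.seed(3)
  blk <- residual_block(4L, 4L, 1L)
  zero_params(blk$main)
  x <- array(abs(rnorm(8 * 8 * 4)), c(8, 8, 4, 1))  # non-negative input
  y <- nn_forward(blk, x, training = TRUE)
  expect_equal(y, x, tolerance = 1e-12)

  # stride 2 halves the spatial dimensions
  blk2 <- residual_block(4L, 8L, 2L)
  y2 <- nn_forward(blk2, x, training = TRUE)
  expect_equal(dim(y2), c(4L, 4L, 8L, 1L))

  # without the shortcut the block is a plain convolution cascade
  blkm <- residual_block(4L, 4L, 1L)
  zero_params(blkm$main)
  ym <- nn_forward(blkm$main, x, training = TRUE)
  expect_equal(max(abs(ym)), 0)
})

test_that("inverted bottleneck obeys skip, stride and linear-projection contracts", {
  set.seed(4)
  x <- array(abs(rnorm(8 * 8 * 6)), c(8, 8, 6, 1))
  blk <- bottleneck_block(6L, 6L, expansion = 2L, stride = 1L)
  zero_params(blk$main)
  expect_equal(nn_forward(blk, x, training = TRUE), x, tolerance = 1e-12)

  blk2 <- bottleneck_block(6L, 8L, expansion = 2L, stride = 2L)
  y2 <- nn_forward(blk2, x, training = TRUE)
  expect_equal(dim(y2), c(4L, 4L, 8L, 1L))
  # no skip when stride 2: zeroed branch gives zero output, not the input
  zero_params(blk2$main)
  expect_equal(max(abs(nn_forward(blk2, x, training = TRUE))), 0)

  # final projection is linear: generic inputs yield negative values
  blk3 <- bottleneck_block(6L, 8L, expansion = 2L, stride = 1L)
  y3 <- nn_forward(blk3, x, training = TRUE)
  expect_true(any(y3 < 0))
  expect_error(bottleneck_block(6L, 8L, stride = 3L), "stride")
})

test_that("depthwise separable conv matches dsc_cost instrumentation", {
  set.seed(5)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  m <- depthwise_separable_conv(4L, 10L)
  y <- nn_forward(m, x)
  expect_equal(dim(y), c(8L, 8L, 10L, 1L))  # same-padding preserves size
  expect_equal(m$multiply_count(), dsc_cost(4, 10, 8, d_k = 3))
  # instrumented counts across a parameter grid
  for (di in c(2, 5)) for (do in c(3, 8)) for (df in c(6, 12)) {
    mm <- depthwise_separable_conv(di, do)
    nn_forward(mm, array(0, c(df, df, di, 1)))
    expect_equal(mm$multiply_count(), dsc_cost(di, do, df, d_k = 3))
  }
})

test_that("dsc_cost reproduces the multiplier algebra", {
  expect_equal(dsc_cost(32, 64, 14, d_k = 3), 32 * 9 * 196 + 32 * 64 * 196)
  expect_equal(dsc_cost(1, 1, 1, d_k = 1), 2)
  # halving the width multiplier (D_k = 1) scales term1 by 1/2, term2 by 1/4
  full <- dsc_cost(32, 64, 14, d_k = 1)
  half <- dsc_cost(32, 64, 14, d_k = 1, eps = 0.5)
  expect_equal(half, 16 * 196 + 16 * 32 * 196)
  expect_equal(dsc_cost(32, 64, 14, d_k = 1, delta = 0.5),
               32 * 49 + 32 * 64 * 49)
  expect_error(dsc_cost(-1, 2, 3), "positive")
  expect_error(dsc_cost(4, 4, 4, eps = 1.5), "multipliers")
})

test_that("backbones respect the stride-4 / stride-16 tap contract", {
  for (bk in c("mi-resnet18", "mi-mobilenetv2")) {
    set.seed(9)
    bb <- build_backbone(model_spec(bk, width_multiplier = 0.125))
    for (sz in c(64L, 128L)) {
      f <- nn_forward(bb, matrix(0.5, sz, sz))
      expect_equal(dim(f$low)[1:2], c(sz / 4, sz / 4))
      expect_equal(dim(f$high)[1:2], c(sz / 16, sz / 16))
    }
  }
})

test_that("forward passes are deterministic given fixed parameters", {
  m <- tiny_model(eps = 0.125, seed = 7)
  x <- matrix(stats::runif(64 * 64), 64, 64)
  expect_identical(predict_scores(m, x), predict_scores(m, x))
})

test_that("width multiplier thins MobileNet stages and parameter ordering holds", {
  set.seed(2)
  full <- build_backbone(model_spec("mi-mobilenetv2"))
  thin <- build_backbone(model_spec("mi-mobilenetv2", width_multiplier = 0.5))
  expect_equal(thin$high_channels, 160L)
  expect_equal(full$high_channels, 320L)
  expect_equal(thin$low_channels, 12L)

  p_mob <- count_params(full)
  p_r18 <- count_params(build_backbone(model_spec("mi-resnet18")))
  p_r50 <- count_params(build_backbone(model_spec("mi-resnet50")))
  expect_lt(p_mob, p_r18)
  expect_lt(p_r18, p_r50)
})

test_that("resolution multiplier shrinks the consumed image", {
  m <- tiny_model(eps = 0.125, seed = 3, resolution_multiplier = 0.5)
  x <- matrix(0.5, 128, 128)
  s <- predict_scores(m, x)
  expect_equal(dim(s)[1:2], c(128L, 128L))  # scores back at input size
  expect_equal(m$net_hw, c(64L, 64L))       # network consumed a 64x64 image
})
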