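test_that("atrous convolution follows the dilated-sampling formula", {
  f <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  h <- atrous_conv(f, c(1, 1, 1), k = 2)
  expect_equal(which(h == 1) - 1L, c(2L, 4L, 6L))  # 0-based positions 4-2, 4, 4+2
  expect_equal(sum(h), 3)

  # k = 1 reverts to conventional convolution
  set.seed(2)
  x <- rnorm(16); w <- rnorm(3)
  conv_ref <- vapply(seq_along(x), function(i) {
    acc <- 0
    for (t in -1:1) if (i + t >= 1 && i + t <= 16) acc <- acc + x[i + t] * w[t + 2]
    acc
  }, numeric(1))
  expect_equal(atrous_conv(x, w, 1), conv_ref, tolerance = 1e-12)
  expect_error(atrous_conv(x, w, 0), "k must be >= 1")
})

test_that("atrous equals convolution with the zero-inflated kernel", {
  set.seed(5)
  dilate_kernel <- function(w, k) {
    n <- length(w)
    out <- rep(0, n + (n - 1) * (k - 1))
    out[seq(1, length(out), by = k)] <- w
    out
  }
  for (k in c(1, 2, 3, 6)) {
    f <- rnorm(64)
    w <- rnorm(3)
    wk <- dilate_kernel(w, k)
    half <- (length(wk) - 1) / 2
    ref <- vapply(seq_along(f), function(i) {
      acc <- 0
      for (t in seq_along(wk)) {
        j <- i + (t - 1 - half)
        if (j >= 1 && j <= length(f)) acc <- acc + f[j] * wk[t]
      }
      acc
    }, numeric(1))
    expect_lt(max(abs(atrous_conv(f, w, k) - ref)), 1e-6)
  }
  # 2-D: same identity via the compiled dilated convolution
  fm <- matrix(rnorm(20 * 20), 20, 20)
  wm <- matrix(rnorm(9), 3, 3)
  for (k in c(1, 2, 3, 6)) {
    n <- 3 + 2 * (k - 1)
    wk <- matrix(0, n, n)
    wk[seq(1, n, by = k), seq(1, n, by = k)] <- wm
    ref <- atrous_conv(fm, wk, 1)
    expect_lt(max(abs(atrous_conv(fm, wm, k) - ref)), 1e-6)
  }
})

test_that("atrous convolution is linear and translation-equivariant", {
  set.seed(6)
  f <- rnorm(32); g <- rnorm(32); w <- rnorm(5)
  expect_lt(max(abs(atrous_conv(2 * f + 3 * g, w, 2) -
                    (2 * atrous_conv(f, w, 2) + 3 * atrous_conv(g, w, 2)))), 1e-6)
  fs <- c(rep(0, 4), f[1:28])
  h <- atrous_conv(f, w, 2)
  hs <- atrous_conv(fs, w, 2)
  expect_lt(max(abs(hs[9:24] - h[5:20])), 1e-9)  # interior values shift along
})

test_that("effective receptive field is n + (n-1)(k-1)", {
  expect_equal(effective_receptive_field(3, 1), 3)
  expect_equal(effective_receptive_field(3, 2), 5)
  expect_equal(effective_receptive_field(3, 3), 7)
  expect_equal(effective_receptive_field(5, 4), 17)
  expect_error(effective_receptive_field(4, 2), "even")
})

test_that("ASPP has four same-size branches at rates (k, 2k, 3k) fused by 1x1", {
  spec <- aspp_spec(8, branch_channels = 6, base_rate = 6)
  expect_equal(spec$rates, c(6L, 12L, 18L))
  set.seed(1)
  asp <- build_aspp(spec)
  x <- array(rnorm(10 * 10 * 8), c(10, 10, 8, 1))
  y <- nn_forward(asp, x)
  expect_equal(dim(y), c(10L, 10L, 6L, 1L))
  for (b in asp$branches) {
    yb <- nn_forward(b, x)
    expect_equal(dim(yb)[1:2], c(10L, 10L))
    expect_equal(dim(yb)[3], 6L)
  }
  # pre-projection concatenation carries 4 x branch_channels
  cat_mod <- asp$children[[1]]
  yc <- nn_forward(cat_mod, x)
  expect_equal(dim(yc)[3], 24L)
  # parameter count of a 3x3 branch is independent of its rate
  n_params <- vapply(asp$branches[2:4], count_params, numeric(1))
  expect_true(all(n_params == n_params[1]))
})
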