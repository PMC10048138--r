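test_that("median-frequency weights follow W = median(F)/F", {
  expect_equal(as.numeric(median_frequency_weights(rep(0.25, 4))), rep(1, 4))
  w <- median_frequency_weights(c(0.5, 0.25, 0.125, 0.125))
  expect_equal(as.numeric(w), c(0.375, 0.75, 1.5, 1.5))
  expect_error(median_frequency_weights(c(0.5, 0.5, 0)), "zero frequency")
})

test_that("weights are scale-invariant and permutation-equivariant", {
  set.seed(11)
  for (i in 1:20) {
    f <- stats::runif(4, 0.01, 1)
    w1 <- as.numeric(median_frequency_weights(f / sum(f)))
    w2 <- as.numeric(median_frequency_weights(f * 7.3))
    expect_equal(w1, w2, tolerance = 1e-12)
    pm <- sample.int(4)
    expect_equal(as.numeric(median_frequency_weights(f[pm])), w2[pm],
                 tolerance = 1e-12)
    expect_equal(w1 * (f / sum(f)), rep(stats::median(f / sum(f)), 4),
                 tolerance = 1e-14)
  }
})

test_that("reference clinical weights satisfy the middle-pair harmonic-mean rule", {
  # printed weights for LGE, muscle, blood, background
  w <- c(13.7678, 0.7802, 1.3923, 0.0163)
  mid <- sort(w)[2:3]
  hm <- 2 / (1 / mid[1] + 1 / mid[2])
  expect_equal(hm, 1, tolerance = 2e-3)
})

test_that("weighted pixel loss reduces to cross-entropy and hits closed forms", {
  set.seed(4)
  scores <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  labels <- random_labels(6, 6)
  wun <- weighted_pixel_loss(scores, labels, rep(1, 4))
  # unweighted cross-entropy computed directly
  ce <- 0
  for (r in 1:6) for (c in 1:6) {
    p <- exp(scores[r, c, ]); p <- p / sum(p)
    ce <- ce + -log(p[labels[r, c] + 1])
  }
  expect_equal(wun, ce / 36, tolerance = 1e-12)

  # probability one on the true class -> zero loss
  hot <- array(-1000, c(2, 2, 4))
  lab <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  for (r in 1:2) for (c in 1:2) hot[r, c, lab[r, c] + 1] <- 1000
  expect_equal(weighted_pixel_loss(hot, lab, c(1, 2, 3, 4)), 0, tolerance = 1e-9)

  # single pixel, two classes, p = (1/2, 1/2), true class 1 (code 1), W = c(1, 4)
  one <- array(0, c(1, 1, 2))
  expect_equal(weighted_pixel_loss(one, matrix(1L), c(1, 4)), 4 * log(2),
               tolerance = 1e-12)
  expect_error(weighted_pixel_loss(array(NaN, c(1, 1, 2)), matrix(0L), c(1, 1)),
               "non-finite")
})

test_that("loss gradient matches finite differences on random 4x4 inputs", {
  set.seed(9)
  for (rep in 1:3) {
    scores <- array(rnorm(4 * 4 * 4), c(4, 4, 4, 1))
    labels <- random_labels(4, 4)
    w <- stats::runif(4, 0.2, 5)
    lg <- myinet:::wce_loss_grad(scores, labels, w)
    for (i in sample(length(scores), 5)) {
      eps <- 1e-6
      sp <- scores; sp[i] <- sp[i] + eps
      sm <- scores; sm[i] <- sm[i] - eps
      fd <- (weighted_pixel_loss(sp, array(labels, c(4, 4, 1)), w) -
             weighted_pixel_loss(sm, array(labels, c(4, 4, 1)), w)) / (2 * eps)
      denom <- max(abs(fd), 1e-8)
      expect_lt(abs(fd - lg$grad[i]) / denom, 1e-4)
    }
  }
})
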