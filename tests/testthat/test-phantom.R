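test_that("phantom labels agree with the generating geometry and are seeded", {
  p <- tiny_params(noise_sd = 0)
  li <- generate_phantom(p, seed = 42)
  expect_s3_class(li, "labeled_image")
  expect_identical(dim(li$pixels), dim(li$labels))
  expect_true(all(li$labels %in% 0:3))

  # recompute labels from the sampled polar geometry
  g <- attr(li, "geometry")
  s <- p$image_size
  xs <- matrix(rep(seq_len(s), each = s), s, s)
  ys <- matrix(rep(seq_len(s), times = s), s, s)
  r <- sqrt((xs - g$cx)^2 + (ys - g$cy)^2)
  th <- (atan2(ys - g$cy, xs - g$cx) * 180 / pi) %% 360
  expected <- matrix(0L, s, s)
  expected[r <= g$r_blood + g$thickness] <- 2L
  expected[r <= g$r_blood] <- 1L
  ad <- abs(((th - g$lge_angle + 180) %% 360) - 180)
  scar <- ad <= g$lge_extent / 2 & r > g$r_blood &
    r <= g$r_blood + g$transmurality * g$thickness
  expected[scar] <- 3L
  # MVO pixels are already labeled 3 inside the scar, so labels must match
  expect_identical(li$labels, expected)

  li2 <- generate_phantom(p, seed = 42)
  expect_identical(li$pixels, li2$pixels)
  expect_identical(li$labels, li2$labels)
  li3 <- generate_phantom(p, seed = 43)
  expect_false(identical(li$labels, li3$labels))
})

test_that("zero-extent wedge produces no LGE pixels", {
  p <- tiny_params(lge_angular_extent_range = c(0, 0))
  li <- generate_phantom(p, seed = 7)
  expect_false(any(li$labels == 3L))
  expect_setequal(unique(as.vector(li$labels)), 0:2)
})

test_that("class imbalance is ordered background > blood > muscle > LGE", {
  p <- tiny_params()
  ok <- vapply(1:40, function(s) {
    li <- generate_phantom(p, seed = s)
    n <- tabulate(li$labels + 1L, 4)
    all(diff(n) < 0)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(64, blood_radius_range = c(20, 30),
                              myocardium_thickness_range = c(10, 12)),
               "must fit")
  expect_error(phantom_params(64, mvo_probability = 1.5), "\\[0, 1\\]")
  expect_error(phantom_params(64, tissue_intensity_means = c(
    background = 0.2, blood = 0.3, muscle = 0.8, lge = 0.75, mvo = 0.25)),
    "hypointense")
})

test_that("cohorts split by patient with 60/20/20 largest-remainder counts", {
  co <- generate_cohort(10, 3, tiny_params(32), seed = 5)
  expect_length(co$images, 30)
  tab <- table(co$split_assignment)
  expect_equal(unname(tab[c("train", "validation", "test")]),
               c(6L, 2L, 2L), ignore_attr = TRUE)
  # no patient appears in two splits; split sets of images are disjoint
  for (sp in c("train", "validation", "test")) {
    ids <- unique(vapply(cohort_split(co, sp), `[[`, "", "patient_id"))
    expect_true(all(co$split_assignment[ids] == sp))
  }
  expect_error(generate_cohort(4, 1, tiny_params(32)), "at least 5")

  # determinism of the whole cohort
  co2 <- generate_cohort(10, 3, tiny_params(32), seed = 5)
  expect_identical(co$split_assignment, co2$split_assignment)
  expect_identical(co$images[[17]]$pixels, co2$images[[17]]$pixels)
})

test_that("cohort LGE fraction is small under default geometry", {
  co <- generate_cohort(25, 2, tiny_params(), seed = 9)
  f <- class_frequencies(co$images)
  expect_lt(f[4], 0.05)
  expect_gt(f[4], 0)
})

test_that("class_frequencies matches brute-force counting and sums to one", {
  expect_equal(class_frequencies(matrix(c(0L, 2L, 1L, 3L), 2, 2)),
               rep(0.25, 4))
  expect_equal(class_frequencies(matrix(c(0L, 0L, 0L, 1L), 2, 2)),
               c(0.75, 0.25, 0, 0))
  set.seed(31)
  imgs <- lapply(1:20, function(i) random_labels(9, 7))
  f <- class_frequencies(imgs)
  counts <- rep(0, 4)
  for (im in imgs) for (v in as.vector(im)) counts[v + 1] <- counts[v + 1] + 1
  expect_equal(f, counts / sum(counts))
  expect_equal(sum(f), 1)
  expect_error(class_frequencies(list()), "no images")
  expect_error(class_frequencies(matrix(5L, 2, 2)), "outside")
})
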