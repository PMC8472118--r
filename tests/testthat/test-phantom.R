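# Synthetic knee phantom generator: determinism, anatomy invariants,
# class-imbalance regime, distractor similarity and dataset splitting.

test_that("case generation is deterministic and leaves the caller RNG alone", {
  p <- tiny_phantom_params()
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  cs1 <- generate_case(p, 7)
  after <- rnorm(1)
  expect_identical(before, after)   # case RNG is isolated
  cs2 <- generate_case(p, 7)
  expect_identical(cs1$volume$voxels, cs2$volume$voxels)
  expect_identical(cs1$labels6$labels, cs2$labels6$labels)
  expect_false(identical(cs1$volume$voxels, generate_case(p, 8)$volume$voxels))
})

test_that("noise-free phantoms are piecewise constant up to normalization", {
  p <- tiny_phantom_params(noise_sigma = 0, bias_field_strength = 0,
                           inhomogeneity = 0)
  cs <- generate_case(p, 3)
  expect_lte(length(unique(as.vector(cs$volume$voxels))), 7)
})

test_that("phantom cases satisfy the anatomy and intensity invariants", {
  p <- phantom_params()
  for (seed in c(1, 12, 123, 1234)) {
    cs <- generate_case(p, seed)
    lab <- cs$labels6$labels
    v <- cs$volume$voxels

    # z-score normalization over the volume
    expect_lt(abs(mean(v)), 1e-4)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-4)

    # all six classes present; meniscus under 2% of meniscus-bearing slices
    expect_setequal(unique(as.vector(lab)), 0:5)
    zs <- which(apply(lab == 5L, 3, any))
    expect_gt(length(zs), 2)
    for (k in zs) expect_lt(mean(lab[, , k] == 5L), 0.02)

    # exactly two meniscus components, matching the side masks
    comp <- menseg:::cpp_label3d(array(as.integer(lab == 5L), dim(lab)))
    expect_equal(max(comp), 2L)
    expect_identical(cs$side_masks$medial | cs$side_masks$lateral, lab == 5L)
    expect_false(any(cs$side_masks$medial & cs$side_masks$lateral))

    # distractors are background-labeled and intensity-matched to the meniscus
    expect_true(all(lab[cs$distractor_mask] == 0L))
    expect_gt(sum(cs$distractor_mask), 0)
    gap <- abs(mean(v[cs$distractor_mask]) - mean(v[lab == 5L]))
    expect_lte(gap, p$distractor_contrast * diff(range(v)))
  }
})

test_that("an intensity-window baseline over-segments into the distractors", {
  p <- phantom_params()
  ppvs <- vapply(c(5, 6), function(seed) {
    cs <- generate_case(p, seed)
    pred <- threshold_segment(cs$volume, cs$labels6$labels == 5L)
    evaluate_masks(pred, cs$labels6$labels == 5L)$ppv
  }, 0)
  expect_true(all(ppvs < 90))
})

test_that("split sizes follow largest-remainder rounding with later-split ties", {
  expect_equal(menseg:::split_counts(10, c(0.7, 0.15, 0.15)), c(7L, 1L, 2L))
  expect_equal(menseg:::split_counts(40, c(0.7, 0.15, 0.15)), c(28L, 6L, 6L))
  expect_equal(menseg:::split_counts(7, c(0.5, 0.25, 0.25)), c(3L, 2L, 2L))
  expect_equal(sum(menseg:::split_counts(11, c(1, 2, 3) / 6)), 11L)
})

test_that("dataset manifests are deterministic with disjoint splits", {
  p <- tiny_phantom_params()
  m1 <- generate_dataset(10, p, seed = 5)
  m2 <- generate_dataset(10, p, seed = 5)
  expect_identical(m1$cases, m2$cases)
  expect_equal(unname(table(factor(m1$cases$split,
                                   c("train", "val", "test")))[1:3]),
               c(7L, 1L, 2L), ignore_attr = TRUE)
  expect_equal(anyDuplicated(m1$cases$patient_id), 0L)
  expect_error(generate_dataset(2, p), "at least 3")
  expect_error(generate_dataset(10, p, split = c(0.5, 0.2, 0.2)), "sum to 1")
  cs <- load_case(m1, m1$cases$patient_id[1])
  expect_s3_class(cs, "phantom_case")
  expect_error(load_case(m1, "nope"), "unknown")
})
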