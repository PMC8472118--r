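# Z-score normalization, meniscus splitting, std-margin ROI extraction and
# crop/paste plumbing.

test_that("z-score normalization matches the two-point closed form and is idempotent", {
  v <- mr_volume(array(rep(c(0, 2), 32), c(4, 4, 4)))
  nz <- normalize_zscore(v)
  expect_true(all(sort(unique(as.vector(nz$voxels))) == c(-1, 1)))
  again <- normalize_zscore(nz)
  expect_lt(max(abs(again$voxels - nz$voxels)), 1e-12)
  expect_error(normalize_zscore(mr_volume(array(3, c(4, 4, 4)))), "constant")
})

test_that("argmax labeling breaks ties toward the lowest class code", {
  prob <- array(0, c(2, 2, 6, 1))
  prob[, , 1, ] <- 0.5
  prob[, , 2, ] <- 0.5
  expect_true(all(menseg:::prob_argmax(prob) == 0L))
  prob2 <- array(0, c(2, 2, 6, 1))
  prob2[, , 1, ] <- 1
  expect_true(all(menseg:::prob_argmax(prob2) == 0L))
  prob3 <- array(0, c(1, 1, 6, 1))
  prob3[1, 1, , 1] <- c(0, 0.1, 0, 0, 0.9, 0)
  expect_equal(as.vector(menseg:::prob_argmax(prob3)), 4L)
})

test_that("meniscus components map to sides by centroid, midline and laterality", {
  lab <- array(0L, c(20, 512, 3))
  lab[8:12, 95:105, ] <- 5L    # centroid x ~ 100
  lab[8:12, 395:405, ] <- 5L   # centroid x ~ 400
  right <- split_meniscus(label_volume(lab), "right")
  idx <- which(right$medial, arr.ind = TRUE)
  expect_true(all(idx[, 2] >= 395))
  expect_true(all(which(right$lateral, arr.ind = TRUE)[, 2] <= 105))
  left <- split_meniscus(label_volume(lab), "left")
  expect_identical(left$medial, right$lateral)
  expect_identical(left$lateral, right$medial)
})

test_that("outlier components are dropped and degenerate splits warn", {
  lab <- array(0L, c(30, 60, 3))
  lab[1:10, 1:34, 1] <- 5L               # 340 voxels, left half
  lab[12:21, 40:60, 1] <- 5L             # 210 voxels, right half
  lab[28, 50, 3] <- 5L                   # 1-voxel outlier
  out <- split_meniscus(label_volume(lab), "right")
  expect_equal(sum(out$medial) + sum(out$lateral), 550)
  expect_false(out$medial[28, 50, 3] || out$lateral[28, 50, 3])

  one <- array(0L, c(10, 40, 2))
  one[2:4, 30:35, ] <- 5L
  expect_warning(res <- split_meniscus(label_volume(one), "right"), "one-sided")
  expect_true(any(res$medial))
  expect_false(any(res$lateral))
  expect_error(split_meniscus(label_volume(array(0L, c(4, 4, 2))), "right"),
               "no meniscus")
})

test_that("ROI margins equal the pooled-extrema std rule", {
  # three slices with x-extents (10,20), (12,22), (14,24); y-extent fixed
  m <- array(0L, c(40, 40, 3))
  m[15, 10:20, 1] <- 1L
  m[15, 12:22, 2] <- 1L
  m[15, 14:24, 3] <- 1L
  roi <- compute_roi(m, min_size = 4)
  ex <- oracle_margins(m)
  expect_equal(unname(roi$margin), unname(ex))
  # pooled x sample {10,12,14,20,22,24}: population sd 5.26 -> margin 5
  expect_equal(unname(roi$margin["x"]), 5)
  expect_equal(unname(roi$x_range), c(10 - 5, 24 + 5))

  # single slice, extents (30,40) on both axes: sd of {30,40} = 5
  s1 <- array(0L, c(64, 64, 1))
  s1[30:40, 30:40, 1] <- 1L
  roi1 <- compute_roi(s1, min_size = 4)
  expect_equal(unname(roi1$margin[c("y", "x")]), c(5, 5))
  expect_equal(unname(roi1$y_range), c(25, 45))
  expect_equal(unname(roi1$x_range), c(25, 45))

  # one pixel: zero margins, expansion to min_size, clamped at the border
  px <- array(0L, c(20, 20, 2))
  px[1, 1, 1] <- 1L
  roi2 <- compute_roi(px, min_size = 8)
  expect_equal(unname(roi2$margin), c(0, 0, 0))
  expect_equal(unname(roi2$y_range), c(1, 8))
  expect_equal(unname(roi2$x_range), c(1, 8))
  expect_error(compute_roi(array(0L, c(4, 4, 2))), "empty")
})

test_that("ROI margins match the oracle on random masks and cover all foreground", {
  set.seed(42)
  for (i in 1:40) {
    m <- random_mask()
    for (mode in c("population", "sample")) {
      roi <- compute_roi(m, min_size = 4, margin_mode = mode)
      expect_equal(unname(roi$margin), unname(oracle_margins(m, mode)))
      expect_true(all(roi$margin >= 0))
    }
    roi <- compute_roi(m, min_size = 4)
    idx <- which(m != 0, arr.ind = TRUE)
    expect_true(all(idx[, 1] >= roi$y_range[1] & idx[, 1] <= roi$y_range[2]))
    expect_true(all(idx[, 2] >= roi$x_range[1] & idx[, 2] <= roi$x_range[2]))
    expect_true(all(idx[, 3] >= roi$z_range[1] & idx[, 3] <= roi$z_range[2]))
  }
})

test_that("crop at native size is bit-exact and labels stay binary", {
  set.seed(7)
  vox <- array(rnorm(40 * 40 * 4), c(40, 40, 4))
  vol <- mr_volume(vox)
  lab <- array(0L, c(40, 40, 4))
  lab[10:14, 18:25, 2:3] <- 5L
  roi <- compute_roi(lab == 5L, min_size = 16)
  side <- roi$y_range[2] - roi$y_range[1] + 1L
  st <- crop_resize(vol, label_volume(lab), roi, target_size = side)
  expect_identical(st$images[, , 1],
                   vox[roi$y_range[1]:roi$y_range[2],
                       roi$x_range[1]:roi$x_range[2], roi$z_range[1]])
  expect_true(all(st$masks %in% c(0L, 1L)))
  st64 <- crop_resize(vol, label_volume(lab), roi, target_size = 64)
  expect_true(all(st64$masks %in% c(0L, 1L)))
  bad <- roi
  bad$x_range <- c(30L, 50L)
  expect_error(crop_resize(vol, NULL, bad, 16), "outside")
})

test_that("crop then paste at resize factor one is the identity on masks", {
  set.seed(8)
  lab <- array(0L, c(48, 48, 5))
  lab[20:30, 12:26, 2:4] <- 5L
  vol <- mr_volume(array(rnorm(48 * 48 * 5), c(48, 48, 5)))
  roi <- compute_roi(lab == 5L, min_size = 4)
  side <- roi$y_range[2] - roi$y_range[1] + 1L
  st <- crop_resize(vol, label_volume(lab), roi, target_size = side)
  back <- paste_back(st$masks, roi, dim(lab))
  expect_identical(back, array(as.integer(lab == 5L), dim(lab)))
  expect_equal(evaluate_masks(back, lab == 5L)$dsc, 100)
})

test_that("paste_back zero-fills outside the ROI and unions overlapping boxes", {
  roi <- compute_roi(array(c(rep(0L, 5), 1L, rep(0L, 58)), c(8, 8, 1)),
                     min_size = 4)
  zeros <- array(0L, c(4, 4, 1))
  expect_true(all(paste_back(zeros, roi, c(8, 8, 1)) == 0L))
  a <- array(0L, c(10, 10, 1)); a[2:4, 2:4, 1] <- 1L
  b <- array(0L, c(10, 10, 1)); b[3:6, 3:6, 1] <- 1L
  u <- merge_masks(a, b)
  expect_equal(sum(u), sum((a + b) > 0))
})
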