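# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive re-implementations (per-voxel loops,
# first-principles formulas) kept separate from the package's code paths.

# per-voxel loop oracle for confusion counts
oracle_confusion <- function(pred, gt) {
  tp <- tn <- fp <- fn <- 0L
  p <- as.integer(pred)
  g <- as.integer(gt)
  for (i in seq_along(p)) {
    if (p[i] == 1L && g[i] == 1L) tp <- tp + 1L
    else if (p[i] == 1L && g[i] == 0L) fp <- fp + 1L
    else if (p[i] == 0L && g[i] == 1L) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# first-principles metric formulas from counts (NA on zero denominators)
oracle_metrics <- function(cc) {
  div <- function(a, b) if (b > 0) 100 * a / b else NA_real_
  tp <- cc[["TP"]]; tn <- cc[["TN"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]
  c(dsc = div(2 * tp, 2 * tp + fn + fp),
    accuracy = div(tp + tn, tp + tn + fp + fn),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn))
}

# independent std-margin oracle: pools per-slice (or per-column, for z)
# extrema and takes the rounded population/sample standard deviation
oracle_margins <- function(mask, mode = "population") {
  d <- dim(mask)
  sdev <- function(v) {
    if (length(v) < 2) return(0)
    if (mode == "sample") sd(v) else sqrt(sum((v - mean(v))^2) / length(v))
  }
  ys <- c(); xs <- c(); zs <- c()
  for (k in seq_len(d[3])) {
    w <- which(mask[, , k] != 0, arr.ind = TRUE)
    if (!nrow(w)) next
    ys <- c(ys, min(w[, 1]), max(w[, 1]))
    xs <- c(xs, min(w[, 2]), max(w[, 2]))
  }
  for (j in seq_len(d[2])) {
    w <- which(mask[, j, ] != 0, arr.ind = TRUE)
    if (!nrow(w)) next
    zs <- c(zs, min(w[, 2]), max(w[, 2]))
  }
  c(y = round(sdev(ys)), x = round(sdev(xs)), z = round(sdev(zs)))
}

# random blobby 3-d mask with varying per-slice extents
random_mask <- function(d = c(24, 24, 6), p_slice = 0.8) {
  m <- array(0L, d)
  for (k in seq_len(d[3])) {
    if (runif(1) > p_slice) next
    cy <- sample.int(d[1], 1); cx <- sample.int(d[2], 1)
    ry <- sample(1:5, 1); rx <- sample(1:5, 1)
    ys <- max(1, cy - ry):min(d[1], cy + ry)
    xs <- max(1, cx - rx):min(d[2], cx + rx)
    m[ys, xs, k] <- 1L
  }
  if (!any(m)) m[sample.int(length(m), 1)] <- 1L
  m
}

# tiny roi_stack fixtures for stage-2 training tests: bright square on dark
# background, mask over the square, light per-slice jitter
tiny_stacks <- function(n_stacks = 2, nz = 6, size = 16, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_stacks), function(s) {
    images <- array(rnorm(size * size * nz, sd = 0.1), c(size, size, nz))
    masks <- array(0L, c(size, size, nz))
    for (k in seq_len(nz)) {
      y0 <- sample(3:6, 1); x0 <- sample(3:6, 1)
      ys <- y0:(y0 + 5); xs <- x0:(x0 + 5)
      images[ys, xs, k] <- images[ys, xs, k] + 1
      masks[ys, xs, k] <- 1L
    }
    structure(list(images = images, masks = masks, roi = NULL,
                   target_size = size), class = "roi_stack")
  })
}

tiny_g_cfg <- function() seg_net_config(1, 2, depth = 2, base_width = 4)
tiny_d_cfg <- function() disc_net_config(1, n_levels = 3, base_width = 4)

# smallest phantom configuration that still has all structures
tiny_phantom_params <- function(...) {
  phantom_params(image_size = 64, n_slices = 8, ...)
}
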