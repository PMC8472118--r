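# U-Net and discriminator architecture contracts.

test_that("config constructors validate their arguments", {
  expect_error(seg_net_config(depth = 0), "depth")
  expect_error(seg_net_config(base_width = 0), "base_width")
  expect_error(seg_net_config(n_classes = 1), "n_classes")
  expect_error(disc_net_config(n_levels = 0), "n_levels")
})

test_that("segmentation output preserves shape and softmax-normalizes over random inits", {
  for (i in 1:10) {
    set.seed(100 + i)
    net <- build_unet(seg_net_config(1, 3, depth = 2, base_width = 2))
    x <- array(rnorm(16 * 12 * 1 * 2), c(16, 12, 1, 2))   # 12 forces padding
    fw <- menseg:::unet_forward(net, x)
    expect_identical(dim(fw$prob), c(16L, 12L, 3L, 2L))
    expect_lt(max(abs(apply(fw$prob, c(1, 2, 4), sum) - 1)), 1e-6)
    expect_true(all(fw$prob >= 0))
  }
})

test_that("six-class and two-class networks emit the documented shapes", {
  set.seed(1)
  net6 <- build_unet(seg_net_config(1, 6, depth = 4, base_width = 2))
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  expect_identical(dim(menseg:::unet_forward(net6, x)$prob), c(64L, 64L, 6L, 1L))
  net2 <- build_unet(seg_net_config(1, 2, depth = 4, base_width = 2))
  expect_identical(dim(menseg:::unet_forward(net2, x)$prob), c(64L, 64L, 2L, 1L))
})

test_that("discriminator yields one bounded score per sample", {
  set.seed(2)
  net <- build_discriminator(disc_net_config(1, n_levels = 5, base_width = 2))
  x <- array(rnorm(64 * 64 * 1 * 3) * 50, c(64, 64, 1, 3))
  sc <- menseg:::disc_forward(net, x)$score
  expect_length(sc, 3)
  expect_true(all(sc > 0 & sc < 1))
})

test_that("discriminator rejects inputs that collapse under pooling", {
  set.seed(3)
  net <- build_discriminator(disc_net_config(1, n_levels = 5, base_width = 2))
  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  expect_error(menseg:::disc_forward(net, x), "too small")
})

# closed-form parameter count from first principles, independent of the
# builder: conv k*k*cin*cout + cout, BN 2*cout, up-conv cin*4*cout + cout
expected_unet_params <- function(cin, K, depth, w0, cap = Inf) {
  w <- pmin(w0 * 2^(0:depth), cap)
  conv <- function(ci, co, k = 3) k * k * ci * co + co
  bn <- function(co) 2 * co
  total <- 0
  prev <- cin
  for (i in seq_len(depth)) {
    total <- total + conv(prev, w[i]) + bn(w[i]) + conv(w[i], w[i]) + bn(w[i])
    prev <- w[i]
  }
  total <- total + conv(w[depth], w[depth + 1]) + bn(w[depth + 1]) +
    conv(w[depth + 1], w[depth + 1]) + bn(w[depth + 1])
  for (i in seq_len(depth)) {
    total <- total + (w[i + 1] * 4 * w[i] + w[i]) +
      conv(2 * w[i], w[i]) + bn(w[i]) + conv(w[i], w[i]) + bn(w[i])
  }
  total + conv(w[1], K, k = 1)
}

test_that("parameter count is a deterministic function of the configuration", {
  for (cfg in list(seg_net_config(1, 6, 4, 8), seg_net_config(1, 2, 2, 4),
                   seg_net_config(1, 6, 4, 8, max_width = 16))) {
    set.seed(4)
    net <- build_unet(cfg)
    expect_equal(parameter_count(net),
                 expected_unet_params(cfg$in_channels, cfg$n_classes,
                                      cfg$depth, cfg$base_width,
                                      cfg$max_width))
    set.seed(99)
    expect_equal(parameter_count(build_unet(cfg)), parameter_count(net))
  }
})

test_that("network checkpoints round-trip through disk with a JSON sidecar", {
  set.seed(5)
  net <- build_unet(seg_net_config(1, 2, depth = 2, base_width = 2))
  path <- file.path(tempdir(), "ckpt.rds")
  save_network(net, path)
  back <- load_network(path)
  expect_identical(back$params, net$params)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$n_classes, 2)
  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  expect_identical(menseg:::unet_forward(back, x)$prob,
                   menseg:::unet_forward(net, x)$prob)
  unlink(c(path, paste0(path, ".json")))
})
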