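# Loss anchors, object-aware conditioning and the adversarial training loop.

test_that("object-aware map multiplies image and map elementwise", {
  img <- matrix(c(2, 4, -1, 3), 2, 2)
  expect_identical(object_aware_map(img, matrix(1, 2, 2)), img)
  expect_true(all(object_aware_map(img, matrix(0, 2, 2)) == 0))
  expect_equal(object_aware_map(matrix(c(2, 4), 1, 2),
                                matrix(c(0.5, 0.25), 1, 2)),
               matrix(c(1, 1), 1, 2))
  expect_error(object_aware_map(img, matrix(1, 3, 2)), "shapes")
  expect_error(object_aware_map(img, matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("loss functions hit their analytic anchors", {
  eps <- 1e-7
  expect_equal(adversarial_loss_d(0.5, 0.5, eps), 2 * log(2), tolerance = 1e-6)
  expect_lt(adversarial_loss_d(1 - eps, eps, eps), 1e-5)
  expect_equal(adversarial_loss_d(eps, 1 - eps, eps), 2 * log(1e7),
               tolerance = 1e-3)
  expect_equal(adversarial_loss_g(0.5, eps), log(2), tolerance = 1e-6)
  expect_lt(adversarial_loss_g(1 - eps, eps), 1e-5)
  expect_equal(adversarial_loss_g(eps, eps), log(1e7), tolerance = 1e-3)
  # minimax form: zero when the discriminator is fooled, maximal when not
  expect_equal(adversarial_loss_g(1 - eps, eps, form = "minimax"), 0,
               tolerance = 1e-5)
  expect_gt(adversarial_loss_g(eps, eps, form = "minimax"), 16)

  gt <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(segmentation_loss(gt, gt, eps), 1e-5)
  expect_equal(segmentation_loss(matrix(0.5, 2, 2), gt, eps), log(2),
               tolerance = 1e-6)
  expect_equal(segmentation_loss(matrix(1 - eps, 2, 2), matrix(0, 2, 2), eps),
               log(1e7), tolerance = 1e-3)
  expect_error(segmentation_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2)),
               "binary")

  expect_equal(total_generator_loss(log(2), log(2), 0.04),
               0.04 * log(2) + log(2))
  expect_equal(total_generator_loss(5, log(2), 0), log(2))
  expect_equal(total_generator_loss(1, 0, 0.04), 0.04)
})

test_that("losses are non-negative after clipping for arbitrary inputs", {
  set.seed(21)
  for (i in 1:20) {
    dr <- runif(1); df <- runif(1)
    expect_gte(adversarial_loss_d(dr, df), 0)
    expect_gte(adversarial_loss_g(df), 0)
    expect_gte(adversarial_loss_g(df, form = "minimax"), 0)
    p <- matrix(runif(16), 4, 4)
    y <- matrix(rbinom(16, 1, 0.5), 4, 4)
    expect_gte(segmentation_loss(p, y), 0)
  }
})

test_that("predicted masks respect the inclusive threshold and nest monotonically", {
  set.seed(22)
  g <- build_unet(tiny_g_cfg())
  imgs <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  expect_error(predict_mask(imgs, g, threshold = 0), "threshold")
  prob <- menseg:::predict_prob_stack(g, imgs)
  m40 <- array(as.integer(prob >= 0.4), dim(prob))
  expect_identical(predict_mask(imgs, g, 0.4), m40)
  for (t2 in c(0.5, 0.7, 0.9)) {
    m2 <- predict_mask(imgs, g, t2)
    expect_true(all(m2 <= m40))       # higher threshold shrinks the mask
    m40 <- m2
  }
  # inclusive boundary: a constant 0.5 map thresholded at 0.5 is full
  expect_true(all(array(0.5, c(2, 2)) >= 0.5))
})

test_that("training is deterministic and lambda = 0 equals supervised training", {
  st <- tiny_stacks(3, nz = 8)
  va <- tiny_stacks(1, nz = 6, seed = 2)
  cfg <- train_config(lambda_gan = 0.04, epochs = 2, batch_size = 8,
                      learning_rate_g = 1e-3, learning_rate_d = 1e-3,
                      seed = 31)
  f1 <- train_adversarial(st, va, tiny_g_cfg(), tiny_d_cfg(), cfg)
  f2 <- train_adversarial(st, va, tiny_g_cfg(), tiny_d_cfg(), cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$generator$params, f2$generator$params)

  cfg0 <- cfg
  cfg0$lambda_gan <- 0
  fz <- train_adversarial(st, va, tiny_g_cfg(), tiny_d_cfg(), cfg0)
  fs <- train_supervised(st, va, tiny_g_cfg(), cfg = cfg)  # sets lambda to 0
  expect_null(fz$discriminator)
  expect_identical(fz$generator$params, fs$generator$params)
  expect_identical(fz$history, fs$history)
  # supervised history differs from the adversarial one (the GAN term acts)
  expect_false(isTRUE(all.equal(fz$history$g_loss, f1$history$g_loss)))
})

test_that("generator and discriminator updates do not cross parameter boundaries", {
  st <- tiny_stacks(2, nz = 8)
  va <- tiny_stacks(1, nz = 4, seed = 3)
  base <- train_config(lambda_gan = 0.04, epochs = 1, batch_size = 8, seed = 41)

  # frozen discriminator: generator steps must leave D at its initialization
  cfg_d0 <- base
  cfg_d0$learning_rate_d <- 0
  fit <- train_adversarial(st, va, tiny_g_cfg(), tiny_d_cfg(), cfg_d0)
  set.seed(base$seed + 1L)
  d_init <- build_discriminator(
    { dc <- tiny_d_cfg(); dc$in_channels <- 1L; dc })
  expect_identical(fit$discriminator$params, d_init$params)

  # frozen generator: discriminator steps must leave G at its initialization
  cfg_g0 <- base
  cfg_g0$learning_rate_g <- 0
  fit2 <- train_adversarial(st, va, tiny_g_cfg(), tiny_d_cfg(), cfg_g0)
  set.seed(base$seed)
  g_init <- build_unet(tiny_g_cfg())
  expect_identical(fit2$generator$params, g_init$params)
})

test_that("the discriminator learns to separate real from fake early on", {
  # trend over 3 seeds: discriminator loss decreases across epochs
  st <- tiny_stacks(3, nz = 8)
  va <- tiny_stacks(1, nz = 4, seed = 4)
  drops <- vapply(1:3, function(s) {
    cfg <- train_config(lambda_gan = 0.04, epochs = 3, batch_size = 8,
                        learning_rate_g = 1e-3, learning_rate_d = 3e-3,
                        seed = 50 + s)
    h <- train_adversarial(st, va, tiny_g_cfg(), tiny_d_cfg(), cfg)$history
    h$d_loss[1] - h$d_loss[3]
  }, 0)
  expect_gt(mean(drops), 0)
})

test_that("concat conditioning feeds a two-channel discriminator", {
  st <- tiny_stacks(2, nz = 8)
  va <- tiny_stacks(1, nz = 4, seed = 5)
  cfg <- train_config(lambda_gan = 0.04, epochs = 1, batch_size = 8,
                      seed = 61, conditioning = "concat")
  fit <- train_adversarial(st, va, tiny_g_cfg(), tiny_d_cfg(), cfg)
  expect_equal(fit$discriminator$config$in_channels, 2L)
})
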