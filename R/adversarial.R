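# Stage 2: conditional adversarial training of the meniscus generator.
# The generator minimizes lambda * L_GAN + L_SEG; the discriminator judges
# real pairs (image, ground truth) against fake pairs (image, G(x)), with the
# pair encoded either as an object-aware map (element-wise product) or as
# channel concatenation.

#' Training configuration for stage-two adversarial learning
#'
#' @param lambda_gan Weight of the adversarial term in the generator loss
#'   (0.04 balances the two terms; 0 disables the discriminator and reduces
#'   training to plain supervised learning).
#' @param epochs Training epochs.
#' @param batch_size Slices per optimization step.
#' @param learning_rate_g,learning_rate_d Adam learning rates.
#' @param eps_clip Probability clip applied before any logarithm.
#' @param seed Seed controlling weight initialization and batch shuffling.
#' @param conditioning `"object_aware"` (discriminator sees image * map) or
#'   `"concat"` (channel concatenation of image and map).
#' @param gan_form `"nonsaturating"` (generator minimizes -log D(fake)) or
#'   `"minimax"` (generator minimizes log(1 - D(fake))).
#' @param threshold Probability threshold for validation masks.
#' @param slices_per_epoch Optional cap on ROI slices visited per epoch (a
#'   fresh random subset each epoch); `NULL` uses every slice.
#' @param adv_grad_clip Relative cap on the adversarial gradient reaching the
#'   generator: per batch, the weighted adversarial gradient norm is scaled
#'   down to at most `adv_grad_clip` times the segmentation gradient norm.
#'   Bounds the `-1/D` blow-up when the discriminator saturates; `NULL`
#'   disables clipping.
#' @param min_val_dsc Failed-fit guard: if the best validation DSC after
#'   training falls below this value, training restarts from a derived seed
#'   (all three RNG streams offset by 1000 per attempt, up to `max_restarts`
#'   extra attempts). Deterministic, so runs stay reproducible; applies
#'   identically at any `lambda_gan`, preserving the supervised/adversarial
#'   ablation identity at `lambda_gan = 0`. `NULL` disables the guard.
#' @param max_restarts Maximum number of restart attempts.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lambda_gan = 0.04, epochs = 10L, batch_size = 16L,
                         learning_rate_g = 1e-3, learning_rate_d = 1e-3,
                         eps_clip = 1e-7, seed = 1L,
                         conditioning = c("object_aware", "concat"),
                         gan_form = c("nonsaturating", "minimax"),
                         threshold = 0.5, slices_per_epoch = NULL,
                         adv_grad_clip = 1, min_val_dsc = NULL,
                         max_restarts = 2L) {
  conditioning <- match.arg(conditioning)
  gan_form <- match.arg(gan_form)
  if (lambda_gan < 0) stop("lambda_gan must be >= 0")
  if (eps_clip <= 0 || eps_clip >= 0.5) stop("eps_clip must lie in (0, 0.5)")
  structure(list(lambda_gan = lambda_gan, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate_g = learning_rate_g,
                 learning_rate_d = learning_rate_d,
                 eps_clip = eps_clip, seed = as.integer(seed),
                 conditioning = conditioning, gan_form = gan_form,
                 threshold = threshold,
                 slices_per_epoch = if (is.null(slices_per_epoch)) NULL
                                    else as.integer(slices_per_epoch),
                 adv_grad_clip = adv_grad_clip, min_val_dsc = min_val_dsc,
                 max_restarts = as.integer(max_restarts)),
            class = "train_config")
}

#' Object-aware map: image masked by a probability map
#'
#' Element-wise product of the image with a probability map (or binary ground
#' truth). Regions where the map is zero contribute nothing, so a
#' discriminator fed this product judges realness from the meniscus region
#' alone.
#'
#' @param image 2-d (or higher) numeric array.
#' @param map Array of matching shape with values in \[0, 1\].
#' @return Array of the same shape.
#' @export
object_aware_map <- function(image, map) {
  if (!identical(dim2(image), dim2(map))) stop("image and map shapes differ")
  if (min(map) < 0 || max(map) > 1) stop("map values must lie in [0, 1]")
  image * map
}

clip01 <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

#' Discriminator loss
#'
#' Negated discriminator objective `log D(real) + log(1 - D(fake))`, so
#' minimizing this value maximizes the classical objective. Scores are
#' clipped to `[eps, 1 - eps]` first; vectors are averaged.
#'
#' @param d_real,d_fake Discriminator scores in (0, 1).
#' @param eps Clipping bound.
#' @return Non-negative scalar loss.
#' @export
adversarial_loss_d <- function(d_real, d_fake, eps = 1e-7) {
  -(mean(log(clip01(d_real, eps))) + mean(log(1 - clip01(d_fake, eps))))
}

#' Generator adversarial loss
#'
#' Non-saturating form `-log D(fake)` by default; the direct minimax form
#' `log(1 - D(fake))` (shifted by its minimum so it is non-negative) is
#' available for comparison.
#'
#' @param d_fake Discriminator score(s) on generated pairs.
#' @param eps Clipping bound.
#' @param form `"nonsaturating"` or `"minimax"`.
#' @return Scalar loss.
#' @export
adversarial_loss_g <- function(d_fake, eps = 1e-7,
                               form = c("nonsaturating", "minimax")) {
  form <- match.arg(form)
  df <- clip01(d_fake, eps)
  if (form == "nonsaturating") -mean(log(df))
  else mean(log(1 - df)) - log(eps)
}

#' Segmentation loss (mean binary cross-entropy)
#'
#' `-(y log p + (1 - y) log(1 - p))` averaged over pixels, with `p` clipped to
#' `[eps, 1 - eps]`.
#'
#' @param prob Probability map (any shape).
#' @param gt Binary ground truth of matching shape.
#' @param eps Clipping bound.
#' @return Non-negative scalar loss.
#' @export
segmentation_loss <- function(prob, gt, eps = 1e-7) {
  if (!identical(dim2(prob), dim2(gt))) stop("prob and gt shapes differ")
  if (!all(gt %in% c(0, 1))) stop("gt must be binary")
  p <- clip01(prob, eps)
  -mean(gt * log(p) + (1 - gt) * log(1 - p))
}

#' Total generator loss
#'
#' `lambda * adversarial + segmentation`.
#'
#' @param adv Adversarial component.
#' @param seg Segmentation component.
#' @param lambda_gan Adversarial weight.
#' @return Scalar.
#' @export
total_generator_loss <- function(adv, seg, lambda_gan = 0.04) {
  lambda_gan * adv + seg
}

# flatten a list of roi_stacks (with masks) into X (t, t, 1, M), Y (t, t, M)
stacks_to_arrays <- function(stacks) {
  stacks <- purrr::compact(stacks)
  if (!length(stacks)) stop("no ROI stacks supplied")
  if (any(vapply(stacks, function(s) is.null(s$masks), TRUE))) {
    stop("all ROI stacks must carry masks for training")
  }
  t <- stacks[[1]]$target_size
  imgs <- lapply(stacks, `[[`, "images")
  msks <- lapply(stacks, `[[`, "masks")
  M <- sum(vapply(imgs, function(a) dim(a)[3], 0))
  X <- array(unlist(imgs, use.names = FALSE), c(t, t, 1L, M))
  Y <- array(as.numeric(unlist(msks, use.names = FALSE)), c(t, t, M))
  list(X = X, Y = Y)
}

# discriminator input for a (image, map) pair under the chosen conditioning
disc_input <- function(x, map4, conditioning) {
  if (conditioning == "object_aware") x * map4 else abind4(x, map4)
}

disc_in_channels <- function(conditioning) {
  if (conditioning == "object_aware") 1L else 2L
}

#' Train the stage-two generator, optionally with adversarial learning
#'
#' Alternating per-batch optimization: one discriminator step on real pairs
#' (image with ground truth) versus fake pairs (image with the generator's
#' probability map), then one generator step on
#' `lambda * L_GAN + L_SEG`. With `lambda_gan = 0` the discriminator is never
#' built or updated and the loop is exactly supervised training (same RNG
#' streams, bit-identical results). Weight initialization, batch shuffling
#' and the discriminator draw from three independent streams derived from
#' `cfg$seed`, so the generator trajectory at `lambda_gan = 0` matches the
#' supervised one exactly. Returns the generator checkpoint with the best
#' validation DSC.
#'
#' @param train_stacks List of `roi_stack` objects with masks (training).
#' @param val_stacks List of `roi_stack` objects with masks (validation).
#' @param g_cfg A [seg_net_config()] with 2 classes for the generator.
#' @param d_cfg A [disc_net_config()] for the discriminator (ignored when
#'   `lambda_gan = 0`); its `in_channels` is overridden to match the
#'   conditioning.
#' @param cfg A [train_config()].
#' @return List with `generator`, `discriminator` (`NULL` when
#'   `lambda_gan = 0`) and `history` (class `train_history` tibble: epoch,
#'   generator/discriminator loss, validation DSC).
#' @export
train_adversarial <- function(train_stacks, val_stacks, g_cfg,
                              d_cfg = disc_net_config(), cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  if (g_cfg$n_classes != 2L) stop("the stage-two generator must have 2 classes")
  for (attempt in 0:max(0L, cfg$max_restarts)) {
    fit <- train_adversarial_once(train_stacks, val_stacks, g_cfg, d_cfg, cfg,
                                  seed_offset = 1000L * attempt)
    best_val <- max(c(fit$history$val_dsc, -Inf), na.rm = TRUE)
    if (is.null(cfg$min_val_dsc) || best_val >= cfg$min_val_dsc) break
    warning(sprintf("stage-two fit stalled (best val DSC %.1f); restarting",
                    best_val))
  }
  fit
}

train_adversarial_once <- function(train_stacks, val_stacks, g_cfg, d_cfg,
                                   cfg, seed_offset = 0L) {
  tr <- stacks_to_arrays(train_stacks)
  va <- stacks_to_arrays(val_stacks)
  eps <- cfg$eps_clip
  use_gan <- cfg$lambda_gan > 0
  cfg$seed <- cfg$seed + seed_offset

  set.seed(cfg$seed)
  G <- build_unet(g_cfg)
  optG <- adam_init(G$params)
  D <- NULL
  optD <- NULL
  if (use_gan) {
    d_cfg$in_channels <- disc_in_channels(cfg$conditioning)
    set.seed(cfg$seed + 1L)
    D <- build_discriminator(d_cfg)
    optD <- adam_init(D$params)
  }
  set.seed(cfg$seed + 2L)

  M <- dim(tr$X)[4]
  npix <- prod(dim(tr$X)[1:2])
  best <- list(dsc = -Inf, net = NULL)
  hist <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(M)
    if (!is.null(cfg$slices_per_epoch)) {
      ord <- ord[seq_len(min(cfg$slices_per_epoch, M))]
    }
    g_losses <- c()
    d_losses <- c()
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      n <- length(idx)
      x <- tr$X[, , , idx, drop = FALSE]
      y <- tr$Y[, , idx, drop = FALSE]
      y4 <- array(y, c(dim(y)[1], dim(y)[2], 1L, n))

      fw <- unet_forward(G, x, train = TRUE)
      G <- fw$net
      pmap <- fw$prob[, , 2L, , drop = FALSE]   # meniscus channel

      seg <- segmentation_loss(pmap, y4, eps)
      pc <- clip01(pmap, eps)
      gp_seg <- (-y4 / pc + (1 - y4) / (1 - pc)) / (npix * n)

      if (use_gan) {
        # one forward per pair; the fake cache serves both the generator's
        # input gradient and the discriminator's parameter gradient
        dr <- disc_forward(D, disc_input(x, y4, cfg$conditioning), train = TRUE)
        D <- dr$net
        df <- disc_forward(D, disc_input(x, pmap, cfg$conditioning), train = TRUE)
        D <- df$net

        # --- generator gradient through the discriminator ---
        adv <- adversarial_loss_g(df$score, eps, cfg$gan_form)
        gscore_g <- if (cfg$gan_form == "nonsaturating") {
          -1 / (n * clip01(df$score, eps))
        } else {
          -1 / (n * (1 - clip01(df$score, eps)))
        }
        gin <- disc_backward(D, df$cache, gscore_g)$gx
        gp_adv <- if (cfg$conditioning == "object_aware") {
          gin * x
        } else {
          gin[, , 2L, , drop = FALSE]
        }
        gp_adv <- cfg$lambda_gan * gp_adv
        if (!is.null(cfg$adv_grad_clip)) {
          na <- sqrt(sum(gp_adv^2))
          ns <- sqrt(sum(gp_seg^2))
          if (na > cfg$adv_grad_clip * ns && na > 0) {
            gp_adv <- gp_adv * (cfg$adv_grad_clip * ns / na)
          }
        }
        gp_total <- gp_seg + gp_adv
        g_loss <- total_generator_loss(adv, seg, cfg$lambda_gan)

        # --- discriminator step (generator output detached) ---
        d_loss <- adversarial_loss_d(dr$score, df$score, eps)
        g_real <- -1 / (n * clip01(dr$score, eps))
        g_fake <- 1 / (n * (1 - clip01(df$score, eps)))
        grads_r <- disc_backward(D, dr$cache, g_real)$grads
        grads_f <- disc_backward(D, df$cache, g_fake)$grads
        grads_d <- purrr::map2(grads_r, grads_f,
                               function(a, b) purrr::map2(a, b, `+`))
        up <- adam_step(D$params, grads_d, optD, cfg$learning_rate_d)
        D$params <- up$params
        optD <- up$opt
        d_losses <- c(d_losses, d_loss)
      } else {
        gp_total <- gp_seg
        g_loss <- seg
      }
      if (!is.finite(g_loss)) {
        stop(sprintf("non-finite generator loss at epoch %d (seg=%.4g)",
                     epoch, seg))
      }
      gprob <- array(0, dim(fw$prob))
      gprob[, , 2L, ] <- gp_total
      grads_g <- unet_backward(G, fw$cache, gprob)
      up <- adam_step(G$params, grads_g, optG, cfg$learning_rate_g)
      G$params <- up$params
      optG <- up$opt
      g_losses <- c(g_losses, g_loss)
    }

    val_dsc <- validation_dsc(G, va, cfg$threshold)
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch,
      g_loss = mean(g_losses),
      d_loss = if (use_gan) mean(d_losses) else NA_real_,
      val_dsc = val_dsc
    )
    if (val_dsc >= best$dsc) best <- list(dsc = val_dsc, net = G)
  }

  history <- structure(dplyr::bind_rows(hist),
                       class = c("train_history", class(tibble::tibble())))
  list(generator = best$net, discriminator = D, history = history)
}

#' Supervised stage-two training (no adversarial term)
#'
#' Runs [train_adversarial()] with `lambda_gan = 0`: the plain ROI U-Net
#' baseline.
#'
#' @inheritParams train_adversarial
#' @return As [train_adversarial()]; `discriminator` is `NULL`.
#' @export
train_supervised <- function(train_stacks, val_stacks, g_cfg,
                             cfg = train_config()) {
  cfg$lambda_gan <- 0
  train_adversarial(train_stacks, val_stacks, g_cfg, cfg = cfg)
}

# pooled-pixel validation DSC at the configured threshold
validation_dsc <- function(G, va, threshold, batch_size = 32L) {
  M <- dim(va$X)[4]
  counts <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (start in seq(1L, M, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, M)
    fw <- unet_forward(G, va$X[, , , idx, drop = FALSE], train = FALSE)
    pred <- fw$prob[, , 2L, , drop = FALSE] >= threshold
    counts <- counts + cpp_confusion(as.integer(pred),
                                     as.integer(va$Y[, , idx, drop = FALSE]))
  }
  den <- 2 * counts[["TP"]] + counts[["FN"]] + counts[["FP"]]
  if (den == 0) return(NA_real_)
  100 * 2 * counts[["TP"]] / den
}

#' Threshold generator probability maps into binary masks
#'
#' @param roi_images A `roi_stack`, or a (H, W, nz) intensity array.
#' @param g A trained 2-class `unet_network`.
#' @param threshold Inclusive probability threshold in (0, 1).
#' @param batch_size Slices per forward pass.
#' @return Binary array of the input's spatial shape.
#' @export
predict_mask <- function(roi_images, g, threshold = 0.5, batch_size = 32L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  imgs <- if (inherits(roi_images, "roi_stack")) roi_images$images else roi_images
  prob <- predict_prob_stack(g, imgs, batch_size)
  array(as.integer(prob >= threshold), dim(imgs))
}

# meniscus-channel probabilities for a (H, W, nz) stack
predict_prob_stack <- function(g, imgs, batch_size = 32L) {
  d <- dim(imgs)
  out <- array(0, d)
  for (start in seq(1L, d[3], by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, d[3])
    x <- array(imgs[, , idx], c(d[1], d[2], 1L, length(idx)))
    fw <- unet_forward(g, x, train = FALSE)
    out[, , idx] <- fw$prob[, , 2L, ]
  }
  out
}
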