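# Supervised slice-wise training of multi-class segmentation networks:
# the six-class stage-one localizer and the whole-image two-class baseline.

#' Training configuration for slice-wise supervised segmentation
#'
#' @param epochs Training epochs.
#' @param batch_size Slices per optimization step.
#' @param learning_rate Adam learning rate.
#' @param seed Seed for weight initialization and shuffling.
#' @param slices_per_epoch Optional cap on slices visited per epoch (a fresh
#'   random subset each epoch); `NULL` uses every slice.
#' @param eps_clip Probability clip before logarithms.
#' @param validate_every Epoch interval between validation passes (the last
#'   epoch is always validated).
#' @param min_val_dsc Failed-fit guard: if the best validation DSC after
#'   training falls below this value, training restarts from a derived seed
#'   (seed + 1000 per attempt, up to `max_restarts` extra attempts). Rare
#'   initializations park thin-structure segmenters in the all-background
#'   basin; the restart is deterministic, so runs stay reproducible. `NULL`
#'   disables the guard.
#' @param max_restarts Maximum number of restart attempts.
#' @param class_weights `"balanced"` (inverse-frequency weights from the
#'   training labels, normalized to unit mean pixel weight), `"sqrt"`
#'   (inverse square-root frequency), `NULL` (unweighted), or a numeric
#'   vector of per-class weights. Rare thin structures (cartilage, meniscus)
#'   contribute negligibly to unweighted cross-entropy, so weighting is the
#'   default.
#' @return An object of class `segmenter_train_config`.
#' @export
segmenter_train_config <- function(epochs = 2L, batch_size = 8L,
                                   learning_rate = 1e-3, seed = 1L,
                                   slices_per_epoch = NULL, eps_clip = 1e-7,
                                   validate_every = 1L,
                                   class_weights = "balanced",
                                   min_val_dsc = NULL, max_restarts = 2L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 slices_per_epoch = if (is.null(slices_per_epoch)) NULL
                                    else as.integer(slices_per_epoch),
                 eps_clip = eps_clip, validate_every = as.integer(validate_every),
                 class_weights = class_weights, min_val_dsc = min_val_dsc,
                 max_restarts = as.integer(max_restarts)),
            class = "segmenter_train_config")
}

# per-class pixel weights from the label frequencies of the training set
resolve_class_weights <- function(spec, Y, K) {
  if (is.null(spec)) return(rep(1, K))
  if (is.numeric(spec)) {
    stopifnot(length(spec) == K)
    return(spec)
  }
  f <- tabulate(as.vector(Y) + 1L, K) / length(Y)
  f <- pmax(f, 1e-6)
  w <- switch(spec,
              balanced = 1 / f,
              sqrt = 1 / sqrt(f),
              stop("unknown class_weights spec: ", spec))
  w / sum(w * f)   # unit mean weight per pixel
}

# volumes: list of (H, W, Z) arrays; labels: list of integer arrays in
# 0..(n_classes - 1). Returns X (H, W, 1, M), Y (H, W, M).
volumes_to_slices <- function(volumes, labels) {
  d <- dim(volumes[[1]])
  M <- sum(vapply(volumes, function(v) dim(v)[3], 0))
  X <- array(unlist(volumes, use.names = FALSE), c(d[1], d[2], 1L, M))
  Y <- array(as.integer(unlist(labels, use.names = FALSE)), c(d[1], d[2], M))
  list(X = X, Y = Y)
}

#' Train a multi-class slice segmenter
#'
#' Mini-batch Adam on mean per-pixel cross-entropy over the softmax output;
#' the checkpoint with the best validation meniscus-class DSC (or best
#' validation loss when the foreground class never appears) is returned.
#'
#' @param train_data,val_data Lists with `X` (H, W, 1, M) and `Y` (H, W, M)
#'   as produced by `volumes_to_slices()`.
#' @param net_cfg A [seg_net_config()].
#' @param cfg A [segmenter_train_config()].
#' @param fg_class Integer code of the class tracked for validation DSC
#'   (meniscus by default; 1 for binary networks).
#' @return List with `net` and `history` (epoch, loss, val DSC).
#' @export
train_segmenter <- function(train_data, val_data, net_cfg,
                            cfg = segmenter_train_config(),
                            fg_class = MENISCUS_CLASS) {
  for (attempt in 0:max(0L, cfg$max_restarts)) {
    fit <- train_segmenter_once(train_data, val_data, net_cfg, cfg,
                                fg_class, seed_offset = 1000L * attempt)
    best_val <- max(c(fit$history$val_dsc, -Inf), na.rm = TRUE)
    if (is.null(cfg$min_val_dsc) || best_val >= cfg$min_val_dsc) break
    warning(sprintf("segmenter fit stalled (best val DSC %.1f); restarting",
                    best_val))
  }
  fit
}

train_segmenter_once <- function(train_data, val_data, net_cfg, cfg,
                                 fg_class, seed_offset = 0L) {
  K <- net_cfg$n_classes
  cw <- resolve_class_weights(cfg$class_weights, train_data$Y, K)
  cfg$seed <- cfg$seed + seed_offset
  set.seed(cfg$seed)
  net <- build_unet(net_cfg)
  opt <- adam_init(net$params)
  set.seed(cfg$seed + 2L)
  M <- dim(train_data$X)[4]
  hist <- vector("list", cfg$epochs)
  best <- list(dsc = -Inf, net = NULL)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(M)
    if (!is.null(cfg$slices_per_epoch)) {
      ord <- ord[seq_len(min(cfg$slices_per_epoch, M))]
    }
    losses <- c()
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      n <- length(idx)
      x <- train_data$X[, , , idx, drop = FALSE]
      y <- train_data$Y[, , idx, drop = FALSE]
      fw <- unet_forward(net, x, train = TRUE)
      net <- fw$net
      prob <- fw$prob
      npix <- prod(dim(x)[c(1, 2)]) * n
      # mean cross-entropy and its gradient w.r.t. the probabilities
      loss <- 0
      gp <- array(0, dim(prob))
      for (c in seq_len(K)) {
        oh <- (y == c - 1L) + 0
        pc <- clip01(array(prob[, , c, ], dim(oh)), cfg$eps_clip)
        loss <- loss - cw[c] * sum(oh * log(pc)) / npix
        gp[, , c, ] <- -cw[c] * oh / pc / npix
      }
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", epoch)
      grads <- unet_backward(net, fw$cache, gp)
      up <- adam_step(net$params, grads, opt, cfg$learning_rate)
      net$params <- up$params
      opt <- up$opt
      losses <- c(losses, loss)
    }
    if (epoch %% cfg$validate_every == 0L || epoch == cfg$epochs) {
      v <- validate_segmenter(net, val_data, fg_class)
    } else {
      v <- NA_real_
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean(losses),
                                    val_dsc = v)
    score <- if (is.na(v)) -Inf else v
    if (epoch == 1L || score >= best$dsc) best <- list(dsc = score, net = net)
  }
  list(net = best$net,
       history = structure(dplyr::bind_rows(hist),
                           class = c("train_history", class(tibble::tibble()))))
}

# pooled DSC of `fg_class` over (a deterministic, evenly spaced subset of)
# the validation slices
validate_segmenter <- function(net, val_data, fg_class, batch_size = 8L,
                               max_slices = 48L) {
  M <- dim(val_data$X)[4]
  keep <- if (M > max_slices) unique(round(seq(1L, M, length.out = max_slices)))
          else seq_len(M)
  val_data <- list(X = val_data$X[, , , keep, drop = FALSE],
                   Y = val_data$Y[, , keep, drop = FALSE])
  M <- length(keep)
  counts <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (start in seq(1L, M, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, M)
    fw <- unet_forward(net, val_data$X[, , , idx, drop = FALSE], train = FALSE)
    lab <- prob_argmax(fw$prob)
    counts <- counts + cpp_confusion(
      as.integer(lab == fg_class),
      as.integer(val_data$Y[, , idx, drop = FALSE] == fg_class))
  }
  den <- 2 * counts[["TP"]] + counts[["FN"]] + counts[["FP"]]
  if (den == 0) return(NA_real_)
  100 * 2 * counts[["TP"]] / den
}

#' Train the stage-one six-class localizer on a phantom manifest
#'
#' @param manifest A [generate_dataset()] manifest.
#' @param net_cfg A six-class [seg_net_config()].
#' @param cfg A [segmenter_train_config()].
#' @param cases Optional pre-generated named list of `phantom_case` objects
#'   (avoids regenerating them).
#' @return List with `net` and `history`.
#' @export
train_localizer <- function(manifest, net_cfg = seg_net_config(n_classes = 6L),
                            cfg = segmenter_train_config(), cases = NULL) {
  if (net_cfg$n_classes != 6L) stop("the localizer needs 6 classes")
  cases <- cases %||% load_split_cases(manifest, c("train", "val"))
  tr <- manifest$cases$patient_id[manifest$cases$split == "train"]
  va <- manifest$cases$patient_id[manifest$cases$split == "val"]
  train_data <- volumes_to_slices(lapply(cases[tr], function(cs) cs$volume$voxels),
                                  lapply(cases[tr], function(cs) cs$labels6$labels))
  val_data <- volumes_to_slices(lapply(cases[va], function(cs) cs$volume$voxels),
                                lapply(cases[va], function(cs) cs$labels6$labels))
  train_segmenter(train_data, val_data, net_cfg, cfg, fg_class = MENISCUS_CLASS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# generate (once) the cases of the requested splits, named by patient_id
load_split_cases <- function(manifest, splits) {
  ids <- manifest$cases$patient_id[manifest$cases$split %in% splits]
  stats::setNames(lapply(ids, function(id) load_case(manifest, id)), ids)
}
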