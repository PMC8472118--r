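#' Configuration for a U-Net style segmentation network
#'
#' Describes the encoder-decoder used both as the six-class localizer (stage
#' one, whole slices) and as the two-class generator (stage two, 64x64 ROIs).
#' The contracting path has `depth` levels, each two 3x3 convolutions with
#' batch normalization and ReLU followed by 2x2 max pooling; the expanding
#' path mirrors it with 2x2 up-convolutions and skip connections, and a final
#' 1x1 convolution with a softmax head emits per-pixel class probabilities at
#' the input resolution.
#'
#' @param in_channels Number of input channels (grayscale MR slices: 1).
#' @param n_classes Number of output classes (6 for the localizer, 2 for the
#'   meniscus generator).
#' @param depth Number of pooling levels in the contracting path.
#' @param base_width Channel count at the first level; widths double per level.
#' @param max_width Cap on the per-level channel count (doubling saturates at
#'   this width); `Inf` gives the classical schedule.
#' @return An object of class `seg_net_config`.
#' @export
seg_net_config <- function(in_channels = 1L, n_classes = 6L, depth = 4L,
                           base_width = 8L, max_width = Inf) {
  in_channels <- as.integer(in_channels)
  n_classes <- as.integer(n_classes)
  depth <- as.integer(depth)
  base_width <- as.integer(base_width)
  if (depth < 1L) stop("depth must be >= 1")
  if (base_width < 1L) stop("base_width must be >= 1")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (in_channels < 1L) stop("in_channels must be >= 1")
  structure(list(in_channels = in_channels, n_classes = n_classes,
                 depth = depth, base_width = base_width,
                 max_width = max_width),
            class = "seg_net_config")
}

#' Configuration for the encoder-style discriminator
#'
#' The discriminator mirrors the U-Net encoder: `n_levels` blocks of two 3x3
#' convolutions with batch normalization and ReLU followed by 2x2 max pooling,
#' then a 1x1 convolution to one channel, global average pooling and a sigmoid
#' producing a single realness score per input.
#'
#' @param in_channels Number of input channels (1 for an object-aware map,
#'   more under concatenation conditioning).
#' @param n_levels Number of conv+pool levels.
#' @param base_width Channel count at the first level; widths double per level.
#' @param max_width Cap on the per-level channel count.
#' @return An object of class `disc_net_config`.
#' @export
disc_net_config <- function(in_channels = 1L, n_levels = 5L, base_width = 8L,
                            max_width = Inf) {
  in_channels <- as.integer(in_channels)
  n_levels <- as.integer(n_levels)
  base_width <- as.integer(base_width)
  if (n_levels < 1L) stop("n_levels must be >= 1")
  if (base_width < 1L) stop("base_width must be >= 1")
  if (in_channels < 1L) stop("in_channels must be >= 1")
  structure(list(in_channels = in_channels, n_levels = n_levels,
                 base_width = base_width, max_width = max_width),
            class = "disc_net_config")
}

#' Build a U-Net segmentation network
#'
#' Constructs the encoder-decoder described by `config` with He-initialized
#' convolution weights (draws from the current RNG state, so seed before
#' calling for reproducible networks). Inputs whose spatial dimensions are not
#' divisible by `2^depth` are reflect-padded for the forward pass and the
#' output is cropped back, so predictions always match the input size.
#'
#' @param config A [seg_net_config()].
#' @return An object of class `unet_network`.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "seg_net_config"))
  d <- config$depth
  w <- pmin(config$base_width * 2^(0:d), config$max_width)
  params <- list()
  states <- list()
  add_block <- function(name, cin, cout) {
    params[[paste0(name, "_conv")]] <<- conv_params(cin, cout, 3L)
    params[[paste0(name, "_bn")]] <<- bn_params(cout)
    states[[paste0(name, "_bn")]] <<- bn_state(cout)
  }
  cin <- config$in_channels
  for (i in seq_len(d)) {
    add_block(paste0("enc", i, "a"), cin, w[i])
    add_block(paste0("enc", i, "b"), w[i], w[i])
    cin <- w[i]
  }
  add_block("bota", w[d], w[d + 1])
  add_block("botb", w[d + 1], w[d + 1])
  for (i in rev(seq_len(d))) {
    params[[paste0("up", i)]] <- convT_params(w[i + 1], w[i])
    add_block(paste0("dec", i, "a"), 2L * w[i], w[i])
    add_block(paste0("dec", i, "b"), w[i], w[i])
  }
  params$head <- conv_params(w[1], config$n_classes, 1L)
  structure(list(config = config, params = params, states = states),
            class = "unet_network")
}

#' Build the encoder-style discriminator
#'
#' @param config A [disc_net_config()].
#' @return An object of class `disc_network`.
#' @export
build_discriminator <- function(config) {
  stopifnot(inherits(config, "disc_net_config"))
  L <- config$n_levels
  w <- pmin(config$base_width * 2^(0:(L - 1)), config$max_width)
  params <- list()
  states <- list()
  add_block <- function(name, cin, cout) {
    params[[paste0(name, "_conv")]] <<- conv_params(cin, cout, 3L)
    params[[paste0(name, "_bn")]] <<- bn_params(cout)
    states[[paste0(name, "_bn")]] <<- bn_state(cout)
  }
  cin <- config$in_channels
  for (i in seq_len(L)) {
    add_block(paste0("lev", i, "a"), cin, w[i])
    add_block(paste0("lev", i, "b"), w[i], w[i])
    cin <- w[i]
  }
  params$head <- conv_params(w[L], 1L, 1L)
  structure(list(config = config, params = params, states = states),
            class = "disc_network")
}

#' @export
print.unet_network <- function(x, ...) {
  cat(sprintf("<unet_network> %d -> %d classes, depth %d, base width %d, %s parameters\n",
              x$config$in_channels, x$config$n_classes, x$config$depth,
              x$config$base_width, format(n_parameters(x$params), big.mark = ",")))
  invisible(x)
}

#' @export
print.disc_network <- function(x, ...) {
  cat(sprintf("<disc_network> %d channels in, %d levels, base width %d, %s parameters\n",
              x$config$in_channels, x$config$n_levels, x$config$base_width,
              format(n_parameters(x$params), big.mark = ",")))
  invisible(x)
}

#' Number of learnable parameters of a network
#'
#' @param net A `unet_network` or `disc_network`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(net) n_parameters(net$params)

# Full forward pass. x is (H, W, C, N); returns list(prob, cache, states).
# Reflect-pads to a multiple of 2^depth and crops back.
unet_forward <- function(net, x, train = FALSE) {
  cfg <- net$config
  d0 <- dim(x)
  if (length(d0) != 4) stop("input must be a (H, W, C, N) array")
  if (d0[3] != cfg$in_channels) stop("input channel count does not match config")
  mult <- 2^cfg$depth
  th <- ceiling(d0[1] / mult) * mult
  tw <- ceiling(d0[2] / mult) * mult
  padded <- !(th == d0[1] && tw == d0[2])
  if (padded) x <- reflect_pad4(x, th, tw)
  p <- net$params
  st <- net$states
  cache <- list(in_dim = d0, padded = padded)
  h <- x
  skips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    ba <- block_fwd(h, p, st, paste0("enc", i, "a"), train)
    st <- ba$states
    bb <- block_fwd(ba$out, p, st, paste0("enc", i, "b"), train)
    st <- bb$states
    skips[[i]] <- bb$out
    mp <- cpp_maxpool2_fwd(bb$out)
    cache[[paste0("enc", i)]] <- list(a = ba$cache, b = bb$cache, pool = mp$idx,
                                      hw = dim(bb$out)[1:2])
    h <- mp$out
  }
  ba <- block_fwd(h, p, st, "bota", train)
  st <- ba$states
  bb <- block_fwd(ba$out, p, st, "botb", train)
  st <- bb$states
  cache$bot <- list(a = ba$cache, b = bb$cache)
  h <- bb$out
  for (i in rev(seq_len(cfg$depth))) {
    up <- convT_fwd(h, p[[paste0("up", i)]])
    cat_in <- abind4(up$out, skips[[i]])
    ba <- block_fwd(cat_in, p, st, paste0("dec", i, "a"), train)
    st <- ba$states
    bb <- block_fwd(ba$out, p, st, paste0("dec", i, "b"), train)
    st <- bb$states
    cache[[paste0("dec", i)]] <- list(up = up$cache, a = ba$cache, b = bb$cache,
                                      up_ch = dim(up$out)[3])
    h <- bb$out
  }
  hd <- conv_fwd(h, p$head, 1L, 0L)
  cache$head <- hd$cache
  prob <- softmax4(hd$out)
  if (padded) {
    ridx <- reflect_crop_range(d0[1], th)
    cidx <- reflect_crop_range(d0[2], tw)
    prob_out <- prob[ridx, cidx, , , drop = FALSE]
  } else {
    prob_out <- prob
  }
  cache$prob_full <- prob
  net$states <- st
  list(prob = prob_out, cache = cache, net = net)
}

reflect_crop_range <- function(n, target) {
  lo <- (target - n) %/% 2
  seq_len(n) + lo
}

# gprob is the gradient w.r.t. the (cropped) probability output.
unet_backward <- function(net, cache, gprob) {
  cfg <- net$config
  p <- net$params
  prob <- cache$prob_full
  if (cache$padded) {
    g_full <- array(0, dim(prob))
    ridx <- reflect_crop_range(cache$in_dim[1], dim(prob)[1])
    cidx <- reflect_crop_range(cache$in_dim[2], dim(prob)[2])
    g_full[ridx, cidx, , ] <- gprob
    gprob <- g_full
  }
  gz <- softmax_bwd(gprob, prob)
  grads <- list()
  hb <- conv_bwd(gz, cache$head, p$head)
  grads$head <- hb$grads
  g <- hb$gx
  gskips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    cc <- cache[[paste0("dec", i)]]
    r <- block_bwd(g, cc$b, p, paste0("dec", i, "b"), grads)
    grads <- r$grads
    r <- block_bwd(r$gx, cc$a, p, paste0("dec", i, "a"), grads)
    grads <- r$grads
    gcat <- r$gx
    up_ch <- cc$up_ch
    gup <- gcat[, , seq_len(up_ch), , drop = FALSE]
    gskips[[i]] <- gcat[, , up_ch + seq_len(dim(gcat)[3] - up_ch), , drop = FALSE]
    ub <- convT_bwd(gup, cc$up, p[[paste0("up", i)]])
    grads[[paste0("up", i)]] <- ub$grads
    g <- ub$gx
  }
  r <- block_bwd(g, cache$bot$b, p, "botb", grads)
  grads <- r$grads
  r <- block_bwd(r$gx, cache$bot$a, p, "bota", grads)
  grads <- r$grads
  g <- r$gx
  for (i in rev(seq_len(cfg$depth))) {
    cc <- cache[[paste0("enc", i)]]
    g <- cpp_maxpool2_bwd(cc$pool, g, as.integer(cc$hw[1]), as.integer(cc$hw[2]))
    g <- g + gskips[[i]]
    r <- block_bwd(g, cc$b, p, paste0("enc", i, "b"), grads)
    grads <- r$grads
    r <- block_bwd(r$gx, cc$a, p, paste0("enc", i, "a"), grads)
    grads <- r$grads
    g <- r$gx
  }
  grads
}

# concatenate along the channel axis
abind4 <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Discriminator forward: returns per-sample scores in (0, 1).
disc_forward <- function(net, x, train = FALSE) {
  cfg <- net$config
  d0 <- dim(x)
  if (length(d0) != 4) stop("input must be a (H, W, C, N) array")
  if (d0[3] != cfg$in_channels) stop("input channel count does not match config")
  if (min(d0[1], d0[2]) < 2^cfg$n_levels) {
    stop(sprintf("spatial dims %dx%d too small for %d pooling levels",
                 d0[1], d0[2], cfg$n_levels))
  }
  p <- net$params
  st <- net$states
  cache <- list()
  h <- x
  for (i in seq_len(cfg$n_levels)) {
    ba <- block_fwd(h, p, st, paste0("lev", i, "a"), train)
    st <- ba$states
    bb <- block_fwd(ba$out, p, st, paste0("lev", i, "b"), train)
    st <- bb$states
    mp <- cpp_maxpool2_fwd(bb$out)
    cache[[paste0("lev", i)]] <- list(a = ba$cache, b = bb$cache, pool = mp$idx,
                                      hw = dim(bb$out)[1:2])
    h <- mp$out
  }
  hd <- conv_fwd(h, p$head, 1L, 0L)
  cache$head <- hd$cache
  cache$map_dim <- dim(hd$out)
  z <- apply(hd$out, 4, mean)            # global average pooling
  score <- 1 / (1 + exp(-z))
  # keep scores in the open interval even when the logit saturates in floating
  # point; downstream losses clip harder anyway
  score <- pmin(pmax(score, 1e-12), 1 - 1e-12)
  cache$score <- score
  net$states <- st
  list(score = score, cache = cache, net = net)
}

# gscore: gradient w.r.t. the sigmoid scores (length N).
disc_backward <- function(net, cache, gscore) {
  cfg <- net$config
  p <- net$params
  s <- cache$score
  gz <- gscore * s * (1 - s)
  md <- cache$map_dim
  gmap <- array(rep(gz / (md[1] * md[2]), each = md[1] * md[2]), md)
  grads <- list()
  hb <- conv_bwd(gmap, cache$head, p$head)
  grads$head <- hb$grads
  g <- hb$gx
  for (i in rev(seq_len(cfg$n_levels))) {
    cc <- cache[[paste0("lev", i)]]
    g <- cpp_maxpool2_bwd(cc$pool, g, as.integer(cc$hw[1]), as.integer(cc$hw[2]))
    r <- block_bwd(g, cc$b, p, paste0("lev", i, "b"), grads)
    grads <- r$grads
    r <- block_bwd(r$gx, cc$a, p, paste0("lev", i, "a"), grads)
    grads <- r$grads
    g <- r$gx
  }
  list(grads = grads, gx = g)
}

#' Save a network checkpoint
#'
#' Weights and batch-norm state are serialized with [saveRDS()]; the network
#' configuration is written alongside as a JSON sidecar for inspection.
#'
#' @param net A `unet_network` or `disc_network`.
#' @param path Checkpoint file path (an `.rds` file).
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  jsonlite::write_json(c(list(kind = class(net)), unclass(net$config)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a network checkpoint saved by [save_network()]
#'
#' @param path Checkpoint file path.
#' @return The network object.
#' @export
load_network <- function(path) readRDS(path)
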