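# Minimal CNN engine: dense (H, W, C, N) activations, manual backprop, Adam.
# Heavy kernels (conv/convT/maxpool via im2col + GEMM, fused BN+ReLU) live in
# src/nn_ops.cpp; the softmax head and Adam are vectorised R.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

he_init <- function(fan_in, n) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

conv_params <- function(cin, cout, k) {
  list(W = matrix(he_init(k * k * cin, k * k * cin * cout), k * k * cin, cout),
       b = numeric(cout))
}

convT_params <- function(cin, cout) {
  list(W = matrix(he_init(4 * cin, cin * 4 * cout), cin, 4 * cout),
       b = numeric(cout))
}

bn_params <- function(c) list(gamma = rep(1, c), beta = numeric(c))
bn_state <- function(c) list(mean = numeric(c), var = rep(1, c))

# ---- primitive layers ----------------------------------------------------

conv_fwd <- function(x, p, k = 3L, pad = (k %/% 2)) {
  out <- cpp_conv2d_fwd(x, p$W, p$b, as.integer(k), as.integer(pad))
  list(out = out, cache = list(x = x, k = as.integer(k), pad = as.integer(pad)))
}

conv_bwd <- function(gout, cache, p) {
  r <- cpp_conv2d_bwd(cache$x, p$W, gout, cache$k, cache$pad)
  list(gx = r$gx, grads = list(W = r$gW, b = as.numeric(r$gb)))
}

convT_fwd <- function(x, p) {
  list(out = cpp_convT2_fwd(x, p$W, p$b), cache = list(x = x))
}

convT_bwd <- function(gout, cache, p) {
  r <- cpp_convT2_bwd(cache$x, p$W, gout)
  list(gx = r$gx, grads = list(W = r$gW, b = as.numeric(r$gb)))
}

softmax4 <- function(z) {
  d <- dim(z)
  m <- array(z[, , 1, ], c(d[1], d[2], d[4]))
  if (d[3] > 1) {
    for (c in 2:d[3]) m <- pmax(m, array(z[, , c, ], c(d[1], d[2], d[4])))
  }
  p <- array(0, d)
  s <- array(0, c(d[1], d[2], d[4]))
  for (c in seq_len(d[3])) {
    e <- exp(array(z[, , c, ], c(d[1], d[2], d[4])) - m)
    p[, , c, ] <- e
    s <- s + e
  }
  for (c in seq_len(d[3])) p[, , c, ] <- array(p[, , c, ], dim(s)) / s
  p
}

# grad through softmax given grad w.r.t. probabilities
softmax_bwd <- function(gp, p) {
  d <- dim(p)
  dot <- array(0, c(d[1], d[2], d[4]))
  for (c in seq_len(d[3])) {
    dot <- dot + array(gp[, , c, ] * p[, , c, ], c(d[1], d[2], d[4]))
  }
  gz <- array(0, d)
  for (c in seq_len(d[3])) {
    gz[, , c, ] <- array(p[, , c, ], dim(dot)) *
      (array(gp[, , c, ], dim(dot)) - dot)
  }
  gz
}

# ---- composite conv -> BN -> ReLU block ---------------------------------

block_fwd <- function(x, params, states, name, train) {
  bn_name <- paste0(name, "_bn")
  cv <- conv_fwd(x, params[[paste0(name, "_conv")]])
  p <- params[[bn_name]]
  st <- states[[bn_name]]
  r <- cpp_bn_relu_fwd(cv$out, p$gamma, p$beta, st$mean, st$var, train,
                       BN_MOMENTUM, BN_EPS)
  if (train) states[[bn_name]] <- list(mean = r$mean, var = r$var)
  list(out = r$out, states = states,
       cache = list(conv = cv$cache, out = r$out, xhat = r$xhat, inv = r$inv))
}

block_bwd <- function(gout, cache, params, name, grads) {
  bn_name <- paste0(name, "_bn")
  bb <- cpp_bn_relu_bwd(gout, cache$out, cache$xhat, cache$inv,
                        params[[bn_name]]$gamma)
  grads[[bn_name]] <- list(gamma = as.numeric(bb$ggamma),
                           beta = as.numeric(bb$gbeta))
  cb <- conv_bwd(bb$gx, cache$conv, params[[paste0(name, "_conv")]])
  grads[[paste0(name, "_conv")]] <- cb$grads
  list(gx = cb$gx, grads = grads)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(a) a * 0)
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (ln in names(grads)) {
    for (pn in names(grads[[ln]])) {
      g <- grads[[ln]][[pn]]
      opt$m[[ln]][[pn]] <- beta1 * opt$m[[ln]][[pn]] + (1 - beta1) * g
      opt$v[[ln]][[pn]] <- beta2 * opt$v[[ln]][[pn]] + (1 - beta2) * g * g
      params[[ln]][[pn]] <- params[[ln]][[pn]] -
        lr * (opt$m[[ln]][[pn]] / c1) / (sqrt(opt$v[[ln]][[pn]] / c2) + eps)
    }
  }
  list(params = params, opt = opt)
}

n_parameters <- function(params) {
  sum(vapply(params, function(p) sum(vapply(p, length, 0L)), 0L))
}

# reflect-pad rows/cols of a (H, W, C, N) array to target spatial size
reflect_pad4 <- function(x, th, tw) {
  d <- dim(x)
  if (d[1] == th && d[2] == tw) return(x)
  ridx <- reflect_index(d[1], th)
  cidx <- reflect_index(d[2], tw)
  x[ridx, cidx, , , drop = FALSE]
}

reflect_index <- function(n, target) {
  extra <- target - n
  lo <- extra %/% 2
  hi <- extra - lo
  if (lo >= n || hi >= n) stop("input too small to reflect-pad to target size")
  c(rev(seq_len(lo) + 1L), seq_len(n), n - seq_len(hi))
}
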