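# Internal neural-network layer primitives.
#
# Activations are C x N matrices (channels by flattened positions), N =
# H*W*B with the spatial index fastest within each sample's contiguous
# block. Convolutions are im2col + one BLAS GEMM (kernels in src/ops.cpp).
# Each layer is an environment holding parameters, gradients and the
# forward cache; backward passes accumulate gradients in place.

new_conv <- function(c_in, c_out, k, stride, pad, rng) {
  l <- new.env(parent = emptyenv())
  l$type <- "conv"
  l$k <- k; l$stride <- stride; l$pad <- pad
  l$c_in <- c_in; l$c_out <- c_out
  # He / variance-scaling initialisation
  sd <- sqrt(2 / (k * k * c_in))
  l$W <- matrix(rng_rnorm(rng, c_out * k * k * c_in, sd = sd), c_out, k * k * c_in)
  l$b <- numeric(c_out)
  l
}

conv_fwd <- function(l, x, H, W, B, train = TRUE) {
  xcol <- im2col_cpp(x, H, W, B, l$k, l$k, l$stride, l$pad)
  y <- l$W %*% xcol + l$b
  if (train) { l$x <- x; l$H <- H; l$W_in <- W; l$B <- B }
  OH <- (H + 2 * l$pad - l$k) %/% l$stride + 1
  OW <- (W + 2 * l$pad - l$k) %/% l$stride + 1
  list(x = y, H = OH, W = OW, B = B)
}

conv_bwd <- function(l, dy) {
  xcol <- im2col_cpp(l$x, l$H, l$W_in, l$B, l$k, l$k, l$stride, l$pad)
  l$dW <- (l$dW %||% 0) + tcrossprod(dy, xcol)
  l$db <- (l$db %||% 0) + rowSums(dy)
  dxcol <- crossprod(l$W, dy)
  dx <- col2im_cpp(dxcol, l$c_in, l$H, l$W_in, l$B, l$k, l$k, l$stride, l$pad)
  l$x <- NULL
  dx
}

new_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  l <- new.env(parent = emptyenv())
  l$type <- "bn"
  l$gamma <- rep(1, c); l$beta <- numeric(c)
  l$run_mean <- numeric(c); l$run_var <- rep(1, c)
  l$momentum <- momentum; l$eps <- eps
  l
}

bn_fwd <- function(l, x, train = TRUE) {
  if (train) {
    r <- bn_fwd_cpp(x, l$gamma, l$beta, l$eps)
    v <- 1 / r$invstd^2 - l$eps
    if (isTRUE(l$collect)) {
      # exact population-moment accumulation for post-training calibration
      n <- ncol(x)
      l$acc_n <- (l$acc_n %||% 0) + n
      l$acc_sum <- (l$acc_sum %||% 0) + r$mean * n
      l$acc_sq <- (l$acc_sq %||% 0) + (v + r$mean^2) * n
    } else {
      l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * r$mean
      l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
    }
    l$xhat <- r$xhat; l$invstd <- r$invstd
    r$y
  } else {
    ((x - l$run_mean) / sqrt(l$run_var + l$eps)) * l$gamma + l$beta
  }
}

bn_bwd <- function(l, dy) {
  r <- bn_bwd_cpp(dy, l$xhat, l$gamma, l$invstd)
  l$dgamma <- (l$dgamma %||% 0) + r$dgamma
  l$dbeta <- (l$dbeta %||% 0) + r$dbeta
  l$xhat <- NULL; l$invstd <- NULL
  r$dx
}

relu_fwd <- function(cache, x, train = TRUE) {
  y <- relu_fwd_cpp(x)
  if (train) cache$y <- y
  y
}

relu_bwd <- function(cache, dy) {
  dx <- relu_bwd_cpp(dy, cache$y)
  cache$y <- NULL
  dx
}

new_dense <- function(c_in, c_out, rng) {
  l <- new.env(parent = emptyenv())
  l$type <- "dense"
  sd <- sqrt(2 / c_in)
  l$W <- matrix(rng_rnorm(rng, c_out * c_in, sd = sd), c_out, c_in)
  l$b <- numeric(c_out)
  l
}

dense_fwd <- function(l, x, train = TRUE) {
  if (train) l$x <- x
  l$W %*% x + l$b
}

dense_bwd <- function(l, dy) {
  l$dW <- (l$dW %||% 0) + tcrossprod(dy, l$x)
  l$db <- (l$db %||% 0) + rowSums(dy)
  l$x <- NULL
  crossprod(l$W, dy)
}

# global average pooling: C x (P*B) -> C x B
gap_fwd <- function(x, H, W, B) {
  P <- H * W
  dim(x) <- c(nrow(x), P, B)
  y <- apply(x, 3, rowMeans)
  if (is.null(dim(y))) y <- matrix(y, ncol = B)  # single-channel edge case
  y
}

gap_bwd <- function(dy, H, W, B) {
  P <- H * W
  dy[, rep(seq_len(B), each = P), drop = FALSE] / P
}

# ---- internal hybrid attention layer (matrix layout, with backward) ------

new_attention_layer <- function(channels, config, rng) {
  l <- new.env(parent = emptyenv())
  l$type <- "attention"
  l$config <- config
  l$channels <- channels
  w <- init_attention_weights(channels, config, rng)
  l$W1 <- w$W1; l$b1 <- w$b1; l$W2 <- w$W2; l$b2 <- w$b2
  k <- config$spatial_kernel
  # im2col rows are channel-fastest within each kernel tap
  l$wvec <- matrix(as.numeric(aperm(w$conv, c(3, 1, 2))), 1, k * k * 2)
  l$conv_b <- w$conv_b
  l
}

# per-sample spatial pooling helpers on C x N with P columns per sample
pool_over_space <- function(x, P, B) {
  C <- nrow(x)
  avg <- matrix(0, C, B); mx <- matrix(0, C, B); arg <- matrix(0L, C, B)
  for (b in seq_len(B)) {
    blk <- x[, (b - 1) * P + seq_len(P), drop = FALSE]
    avg[, b] <- rowMeans(blk)
    ai <- max.col(blk, ties.method = "first")
    arg[, b] <- ai
    mx[, b] <- blk[cbind(seq_len(C), ai)]
  }
  list(avg = avg, max = mx, arg = arg)
}

attention_fwd <- function(l, x, H, W, B, train = TRUE) {
  C <- nrow(x); P <- H * W; N <- ncol(x)
  sp <- pool_over_space(x, P, B)
  a1 <- l$W1 %*% sp$avg + l$b1; h1 <- a1 * (a1 > 0)
  a2 <- l$W1 %*% sp$max + l$b1; h2 <- a2 * (a2 > 0)
  o <- l$W2 %*% (h1 + h2) + 2 * l$b2
  s_c <- 1 / (1 + exp(-o))                              # C x B channel weights
  xc <- scale_cols_group_cpp(x, s_c, P)                  # channel-refined map
  cp <- channel_pool_cpp(xc)
  argch <- cp$arg
  planes <- rbind(cp$avg, cp$max)                        # 2 x N
  k <- l$config$spatial_kernel; pad <- (k - 1) %/% 2
  pcol <- im2col_cpp(planes, H, W, B, k, k, 1L, pad)
  pre <- as.numeric(l$wvec %*% pcol + l$conv_b)
  s_s <- 1 / (1 + exp(-pre))                             # length N spatial weights
  strict <- isTRUE(l$config$strict_eq2)
  base <- if (strict) x else xc
  y <- scale_cols_cpp(base, s_s)
  if (train) {
    l$x <- x; l$sp <- sp; l$a1 <- a1; l$a2 <- a2
    l$s_c <- s_c; l$xc <- xc; l$argch <- argch
    l$pcol <- pcol; l$s_s <- s_s
    l$H <- H; l$W_sp <- W; l$B <- B
  }
  y
}

attention_bwd <- function(l, dy) {
  C <- nrow(dy); N <- ncol(dy)
  H <- l$H; W <- l$W_sp; B <- l$B; P <- H * W
  strict <- isTRUE(l$config$strict_eq2)
  base <- if (strict) l$x else l$xc
  d_base <- scale_cols_cpp(dy, l$s_s)
  d_ss <- colsum_prod_cpp(dy, base)
  d_pre <- d_ss * l$s_s * (1 - l$s_s)
  # spatial conv backward
  l$dwvec <- (l$dwvec %||% 0) + tcrossprod(matrix(d_pre, 1), l$pcol)
  l$dconv_b <- (l$dconv_b %||% 0) + sum(d_pre)
  k <- l$config$spatial_kernel; pad <- (k - 1) %/% 2
  d_pcol <- crossprod(l$wvec, matrix(d_pre, 1))
  d_planes <- col2im_cpp(d_pcol, 2L, H, W, B, k, k, 1L, pad)
  # channel-pooled planes backward into the refined map xc
  d_xc <- matrix(rep(d_planes[1, ] / C, each = C), C, N)
  idx_max <- cbind(l$argch, seq_len(N))
  d_xc[idx_max] <- d_xc[idx_max] + d_planes[2, ]
  if (!strict) d_xc <- d_xc + d_base
  # xc = x * s_c (broadcast over each sample's positions)
  dx <- scale_cols_group_cpp(d_xc, l$s_c, P)
  if (strict) dx <- dx + d_base
  d_sc <- group_rowsum_prod_cpp(d_xc, l$x, P)
  d_o <- d_sc * l$s_c * (1 - l$s_c)
  # shared MLP backward (avg and max paths)
  h1 <- l$a1 * (l$a1 > 0); h2 <- l$a2 * (l$a2 > 0)
  l$dW2 <- (l$dW2 %||% 0) + tcrossprod(d_o, h1 + h2)
  l$db2 <- (l$db2 %||% 0) + 2 * rowSums(d_o)
  d_h <- crossprod(l$W2, d_o)
  d_a1 <- d_h * (l$a1 > 0); d_a2 <- d_h * (l$a2 > 0)
  l$dW1 <- (l$dW1 %||% 0) + tcrossprod(d_a1, l$sp$avg) + tcrossprod(d_a2, l$sp$max)
  l$db1 <- (l$db1 %||% 0) + rowSums(d_a1) + rowSums(d_a2)
  d_avgpool <- crossprod(l$W1, d_a1)   # C x B
  d_maxpool <- crossprod(l$W1, d_a2)
  dx <- dx + d_avgpool[, rep(seq_len(B), each = P), drop = FALSE] / P
  for (b in seq_len(B)) {
    cols <- (b - 1) * P + l$sp$arg[, b]
    ii <- cbind(seq_len(C), cols)
    dx[ii] <- dx[ii] + d_maxpool[, b]
  }
  l$x <- NULL; l$sp <- NULL; l$a1 <- NULL; l$a2 <- NULL
  l$xc <- NULL; l$pcol <- NULL
  dx
}

# ---- parameter bookkeeping ----------------------------------------------

layer_param_names <- function(l) {
  switch(l$type,
    conv = c("W", "b"),
    bn = c("gamma", "beta"),
    dense = c("W", "b"),
    attention = c("W1", "b1", "W2", "b2", "wvec", "conv_b"),
    character(0)
  )
}

zero_grads <- function(l) {
  for (p in layer_param_names(l)) l[[paste0("d", p)]] <- NULL
  invisible(l)
}

adam_step <- function(l, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in layer_param_names(l)) {
    g <- l[[paste0("d", p)]]
    if (is.null(g)) next
    mname <- paste0("m_", p); vname <- paste0("v_", p)
    if (is.null(l[[mname]])) { l[[mname]] <- 0 * g; l[[vname]] <- 0 * g }
    l[[mname]] <- beta1 * l[[mname]] + (1 - beta1) * g
    l[[vname]] <- beta2 * l[[vname]] + (1 - beta2) * g * g
    mhat <- l[[mname]] / (1 - beta1^t)
    vhat <- l[[vname]] / (1 - beta2^t)
    l[[p]] <- l[[p]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(l)
}
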