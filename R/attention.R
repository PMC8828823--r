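#' Attention configuration
#'
#' The hybrid attention module refines a feature map in two cascaded steps:
#' channel attention decides *what* to emphasise (a weight per channel from
#' spatially pooled statistics pushed through a shared bottleneck MLP), and
#' spatial attention decides *where* (a weight per position from channel-
#' pooled statistics convolved with a k x k filter). Both end in a logistic
#' sigmoid, so every weight lies strictly in (0, 1) and attention can only
#' attenuate, never amplify.
#'
#' @param reduction_ratio Bottleneck divisor of the shared MLP; the hidden
#'   width is `max(1, channels / reduction_ratio)`. Default 16, the standard
#'   setting for this attention design.
#' @param spatial_kernel Odd kernel size of the spatial convolution,
#'   default 7.
#' @param strict_eq2 If `TRUE` (default) the second element-wise product uses
#'   the *original* feature map, `M = fS(fC(F) * F) * F`; if `FALSE` the
#'   conventional cascaded form `M = fS(F') * F'` with `F' = fC(F) * F`.
#' @return An `attention_config` list.
#' @export
attention_config <- function(reduction_ratio = 16, spatial_kernel = 7,
                             strict_eq2 = TRUE) {
  if (spatial_kernel %% 2 != 1 || spatial_kernel < 1) {
    abort("spatial_kernel must be an odd positive integer")
  }
  if (reduction_ratio < 1) abort("reduction_ratio must be >= 1")
  structure(
    list(reduction_ratio = reduction_ratio, spatial_kernel = spatial_kernel,
         strict_eq2 = strict_eq2),
    class = "attention_config"
  )
}

#' Initialise attention weights for a given channel count
#'
#' @param channels Number of channels of the feature map at the use site.
#' @param config An [attention_config()].
#' @param rng Internal RNG stream; defaults to a fixed stream.
#' @param scale Standard deviation multiplier for the random init; `scale = 0`
#'   gives all-zero weights (useful for tests: sigmoid(0) = 0.5 everywhere).
#' @return List with MLP weights `W1`, `b1`, `W2`, `b2` and spatial filter
#'   `conv` (k x k x 2 array) with bias `conv_b`.
#' @export
init_attention_weights <- function(channels, config = attention_config(),
                                   rng = make_rng(1), scale = 1) {
  hidden <- max(1L, floor(channels / config$reduction_ratio))
  k <- config$spatial_kernel
  he <- function(n_in) sqrt(2 / n_in)
  list(
    W1 = matrix(scale * he(channels) * rng_rnorm(rng, hidden * channels), hidden, channels),
    b1 = numeric(hidden),
    W2 = matrix(scale * he(hidden) * rng_rnorm(rng, channels * hidden), channels, hidden),
    b2 = numeric(channels),
    conv = array(scale * he(2 * k * k) * rng_rnorm(rng, k * k * 2), dim = c(k, k, 2)),
    conv_b = 0
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# shared two-layer MLP (channels -> hidden -> channels), ReLU in between
attention_mlp <- function(v, w) {
  as.numeric(w$W2 %*% pmax(w$W1 %*% v + w$b1, 0) + w$b2)
}

#' Channel attention weights
#'
#' Spatial average- and max-pooling each reduce the map to a channel-length
#' descriptor; both pass through one shared bottleneck MLP, the results are
#' summed and squashed by the sigmoid.
#'
#' @param F_map Numeric array, height x width x channels.
#' @param config An [attention_config()].
#' @param weights From [init_attention_weights()].
#' @return Numeric vector of length `channels`, entries strictly in (0, 1).
#' @export
channel_attention <- function(F_map, config, weights) {
  stopifnot(length(dim(F_map)) == 3)
  C <- dim(F_map)[3]
  avg <- apply(F_map, 3, mean)
  mx <- apply(F_map, 3, max)
  sigmoid(attention_mlp(avg, weights) + attention_mlp(mx, weights))
}

# same-padded 2-D convolution of a small multi-channel plane stack (H x W x C_in)
# with one k x k x C_in filter; plain R, used by the reference path
conv2d_same <- function(planes, filt, bias = 0) {
  H <- dim(planes)[1]; W <- dim(planes)[2]; Cin <- dim(planes)[3]
  k <- dim(filt)[1]; p <- (k - 1) / 2
  out <- matrix(bias, H, W)
  for (ci in seq_len(Cin)) {
    padded <- matrix(0, H + 2 * p, W + 2 * p)
    padded[p + seq_len(H), p + seq_len(W)] <- planes[, , ci]
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        w <- filt[i, j, ci]
        if (w != 0) out <- out + w * padded[(i - 1) + seq_len(H), (j - 1) + seq_len(W)]
      }
    }
  }
  out
}

#' Spatial attention map
#'
#' Channel-wise average and max produce two height x width planes; their
#' 2-channel stack is convolved (same padding) with a k x k filter and
#' squashed by the sigmoid.
#'
#' @inheritParams channel_attention
#' @return Matrix height x width with entries strictly in (0, 1).
#' @export
spatial_attention <- function(F_map, config, weights) {
  stopifnot(length(dim(F_map)) == 3)
  avg <- apply(F_map, c(1, 2), mean)
  mx <- apply(F_map, c(1, 2), max)
  planes <- array(c(avg, mx), dim = c(dim(avg), 2))
  sigmoid(conv2d_same(planes, weights$conv, weights$conv_b))
}

#' Hybrid channel-then-spatial attention
#'
#' Applies channel attention, multiplies it into the map, derives the spatial
#' map from the refined features, and multiplies again. With
#' `config$strict_eq2 = TRUE` both products use the original map `F`:
#' `M = fS(fC(F) * F) * F`; otherwise the cascaded form multiplies the
#' refined map: `M = fS(F') * F'`.
#'
#' @inheritParams channel_attention
#' @return Array of the same shape as `F_map`.
#' @export
hybrid_attention <- function(F_map, config, weights) {
  cw <- channel_attention(F_map, config, weights)
  Fc <- sweep(F_map, 3, cw, `*`)
  sw <- spatial_attention(Fc, config, weights)
  base <- if (isTRUE(config$strict_eq2)) F_map else Fc
  out <- base
  for (c in seq_len(dim(F_map)[3])) out[, , c] <- base[, , c] * sw
  out
}
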