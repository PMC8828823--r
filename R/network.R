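#' Declarative specification of a residual-attention classifier
#'
#' Describes the classifier family: a 7x7/64 stride-2 stem convolution with
#' batch normalization and 3x3 stride-2 max pooling, four stages of residual
#' convolution blocks (two 3x3 convolutions each, batch-normalised, rectified)
#' with the hybrid attention module placed inside or outside the residual
#' sum, global average pooling, and a softmax head. Block counts per stage
#' select the depth: `(2,3,5,2)` gives the 26-weight-layer flagship,
#' `(2,2,2,2)` an 18-layer and `(3,4,6,3)` a 34-layer variant.
#'
#' @param stage_blocks Four positive integers: blocks per stage.
#' @param stage_channels Four non-decreasing channel widths, default
#'   `c(64, 128, 256, 512)`.
#' @param attention_placement `"inside"` (attention on the convolutional
#'   branch before the shortcut addition), `"outside"` (after the addition)
#'   or `"none"`.
#' @param residual Keep the shortcut connections? `FALSE` gives the plain
#'   stacked-convolution ablation with identical layer counts.
#' @param num_classes Output classes (3 multiclass, 2 merged-metastatic).
#' @param attention An [attention_config()].
#' @param input_shape `c(height, width)` of the single-channel input,
#'   default `c(1024, 256)`.
#' @return A `network_spec` list.
#' @export
#' @examples
#' spec <- network_spec()
#' count_weight_layers(spec)
network_spec <- function(stage_blocks = c(2, 3, 5, 2),
                         stage_channels = c(64, 128, 256, 512),
                         attention_placement = c("inside", "outside", "none"),
                         residual = TRUE,
                         num_classes = 3,
                         attention = attention_config(),
                         input_shape = c(1024, 256)) {
  attention_placement <- match.arg(attention_placement)
  if (length(stage_blocks) != 4 || any(stage_blocks < 1) ||
      any(stage_blocks != round(stage_blocks))) {
    abort("stage_blocks must be four positive integers")
  }
  if (length(stage_channels) != 4 || any(diff(stage_channels) < 0)) {
    abort("stage_channels must be four non-decreasing widths")
  }
  if (num_classes < 2) abort("num_classes must be >= 2")
  structure(
    list(
      stage_blocks = as.integer(stage_blocks),
      stage_channels = as.integer(stage_channels),
      attention_placement = attention_placement,
      residual = isTRUE(residual),
      num_classes = as.integer(num_classes),
      attention = attention,
      input_shape = as.integer(input_shape)
    ),
    class = "network_spec"
  )
}

#' Count the weight layers of a classifier specification
#'
#' Counts convolutional and fully-connected layers only: the stem
#' convolution, two 3x3 convolutions per block, and the final
#' fully-connected layer. Shortcut projections, normalization, pooling and
#' attention-internal layers are excluded, matching residual-network naming
#' (so `(2,3,5,2)` is the 26-layer network, `(2,2,2,2)` 18, `(3,4,6,3)` 34).
#'
#' @param spec A [network_spec()].
#' @return Integer layer count.
#' @export
count_weight_layers <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  1L + 2L * sum(spec$stage_blocks) + 1L
}

#' Trace feature-map shapes through a specification
#'
#' Pure shape arithmetic (no weights): spatial size after the stem
#' convolution, the stem pool, and each stage. Total downsampling is 32x in
#' each spatial dimension.
#'
#' @param spec A [network_spec()].
#' @return A tibble with `stage`, `height`, `width`, `channels`.
#' @export
feature_trace <- function(spec) {
  H <- spec$input_shape[1]; W <- spec$input_shape[2]
  down <- function(h, k, s, p) (h + 2 * p - k) %/% s + 1
  rows <- list()
  H <- down(H, 7, 2, 3); W <- down(W, 7, 2, 3)
  rows[[1]] <- tibble::tibble(stage = "stem_conv", height = H, width = W, channels = 64L)
  H <- down(H, 3, 2, 1); W <- down(W, 3, 2, 1)
  rows[[2]] <- tibble::tibble(stage = "stem_pool", height = H, width = W, channels = 64L)
  for (i in 1:4) {
    if (i > 1) { H <- down(H, 3, 2, 1); W <- down(W, 3, 2, 1) }
    rows[[i + 2]] <- tibble::tibble(
      stage = paste0("stage", i), height = H, width = W,
      channels = spec$stage_channels[i]
    )
  }
  dplyr::bind_rows(rows)
}

# ---- model construction --------------------------------------------------

new_ra_block <- function(c_in, c_out, stride, spec, rng) {
  if (!stride %in% c(1, 2)) abort("Block stride must be 1 or 2")
  blk <- new.env(parent = emptyenv())
  blk$conv1 <- new_conv(c_in, c_out, 3, stride, 1, rng)
  blk$bn1 <- new_bn(c_out)
  blk$r1 <- new.env(parent = emptyenv())
  blk$conv2 <- new_conv(c_out, c_out, 3, 1, 1, rng)
  blk$bn2 <- new_bn(c_out)
  blk$rout <- new.env(parent = emptyenv())
  blk$residual <- spec$residual
  blk$placement <- spec$attention_placement
  blk$attn <- if (blk$placement == "none") NULL else
    new_attention_layer(c_out, spec$attention, rng)
  blk$project <- spec$residual && (c_in != c_out || stride != 1)
  if (blk$project) {
    blk$conv_s <- new_conv(c_in, c_out, 1, stride, 0, rng)
    blk$bn_s <- new_bn(c_out)
  }
  blk
}

#' Build a single residual-attention convolution block
#'
#' Exposed mainly for inspection and unit testing; [build_classifier()]
#' assembles whole networks from these. The block computes two 3x3
#' batch-normalised rectified convolutions; a shortcut (identity, or a 1x1
#' stride-matched projection when shapes change) is added when
#' `spec$residual` is `TRUE`. Attention placement: `"inside"` refines the
#' convolutional branch before the addition, `"outside"` refines the
#' rectified sum.
#'
#' @param in_channels,out_channels Channel widths.
#' @param stride 1 or 2 (2 halves the spatial dimensions).
#' @param spec A [network_spec()] supplying residual/attention settings.
#' @param seed Weight-initialisation seed.
#' @return A block handle usable with [block_forward()].
#' @export
build_ra_block <- function(in_channels, out_channels, stride, spec, seed = 1) {
  new_ra_block(in_channels, out_channels, stride, spec, make_rng(seed))
}

block_fwd <- function(blk, x, H, W, B, train = TRUE) {
  c1 <- conv_fwd(blk$conv1, x, H, W, B, train)
  h1 <- relu_fwd(blk$r1, bn_fwd(blk$bn1, c1$x, train), train)
  c2 <- conv_fwd(blk$conv2, h1, c1$H, c1$W, B, train)
  f <- bn_fwd(blk$bn2, c2$x, train)
  OH <- c2$H; OW <- c2$W
  if (blk$residual) {
    if (blk$project) {
      s <- bn_fwd(blk$bn_s, conv_fwd(blk$conv_s, x, H, W, B, train)$x, train)
    } else {
      s <- x
    }
  } else {
    s <- NULL
  }
  if (blk$placement == "inside") {
    f <- attention_fwd(blk$attn, f, OH, OW, B, train)
    pre <- if (is.null(s)) f else s + f
    out <- relu_fwd(blk$rout, pre, train)
  } else {
    pre <- if (is.null(s)) f else s + f
    out <- relu_fwd(blk$rout, pre, train)
    if (blk$placement == "outside") out <- attention_fwd(blk$attn, out, OH, OW, B, train)
  }
  list(x = out, H = OH, W = OW, B = B)
}

block_bwd <- function(blk, dy) {
  if (blk$placement == "outside") dy <- attention_bwd(blk$attn, dy)
  dpre <- relu_bwd(blk$rout, dy)
  if (blk$placement == "inside") {
    df <- attention_bwd(blk$attn, dpre)
  } else {
    df <- dpre
  }
  ds <- if (blk$residual) dpre else NULL
  dh1 <- conv_bwd(blk$conv2, bn_bwd(blk$bn2, df))
  dx <- conv_bwd(blk$conv1, bn_bwd(blk$bn1, relu_bwd(blk$r1, dh1)))
  if (blk$residual) {
    if (blk$project) {
      dx <- dx + conv_bwd(blk$conv_s, bn_bwd(blk$bn_s, ds))
    } else {
      dx <- dx + ds
    }
  }
  dx
}

#' Forward an input batch through a single block
#'
#' @param block A handle from [build_ra_block()].
#' @param input Array `height x width x channels x batch` (or a
#'   `channels x (height*width*batch)` matrix plus explicit dims).
#' @param train Keep caches for a backward pass?
#' @return Array of block outputs, `oh x ow x channels x batch`.
#' @export
block_forward <- function(block, input, train = FALSE) {
  stopifnot(length(dim(input)) == 4)
  H <- dim(input)[1]; W <- dim(input)[2]; C <- dim(input)[3]; B <- dim(input)[4]
  x <- matrix(aperm(input, c(3, 1, 2, 4)), C, H * W * B)
  out <- block_fwd(block, x, H, W, B, train)
  array(aperm(array(out$x, c(nrow(out$x), out$H, out$W, B)), c(2, 3, 1, 4)),
        c(out$H, out$W, nrow(out$x), B))
}

#' Build a residual-attention classifier
#'
#' Assembles the full network described by a [network_spec()]: stem
#' convolution + batch normalization + max pooling, four block stages (the
#' first block of stages 2-4 uses stride 2), global average pooling, and a
#' fully-connected softmax head.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for variance-scaling weight initialisation.
#' @return A `scinti_model` handle (environment).
#' @export
#' @examples
#' m <- build_classifier(network_spec(input_shape = c(128, 32)), seed = 1)
#' p <- predict_proba(m, list(matrix(runif(128 * 32), 128, 32)))
#' rowSums(p)  # 1
build_classifier <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  rng <- make_rng(seed)
  m <- new.env(parent = emptyenv())
  m$spec <- spec
  m$stem_conv <- new_conv(1, 64, 7, 2, 3, rng)
  m$stem_bn <- new_bn(64)
  m$stem_relu <- new.env(parent = emptyenv())
  m$blocks <- list()
  c_in <- 64L
  for (i in 1:4) {
    for (j in seq_len(spec$stage_blocks[i])) {
      stride <- if (i > 1 && j == 1) 2L else 1L
      m$blocks[[length(m$blocks) + 1]] <-
        new_ra_block(c_in, spec$stage_channels[i], stride, spec, rng)
      c_in <- spec$stage_channels[i]
    }
  }
  m$dense <- new_dense(spec$stage_channels[4], spec$num_classes, rng)
  m$t <- 0L
  class(m) <- "scinti_model"
  m
}

all_layers <- function(m) {
  ls_ <- list(m$stem_conv, m$stem_bn)
  for (blk in m$blocks) {
    ls_ <- c(ls_, list(blk$conv1, blk$bn1, blk$conv2, blk$bn2))
    if (!is.null(blk$attn)) ls_ <- c(ls_, list(blk$attn))
    if (isTRUE(blk$project)) ls_ <- c(ls_, list(blk$conv_s, blk$bn_s))
  }
  c(ls_, list(m$dense))
}

model_clear_caches <- function(m) {
  for (l in all_layers(m)) {
    for (f in c("x", "xhat", "invstd", "sp", "a1", "a2", "xc", "pcol",
                "s_c", "s_s", "argch")) l[[f]] <- NULL
  }
  m$stem_relu$y <- NULL
  for (blk in m$blocks) { blk$r1$y <- NULL; blk$rout$y <- NULL }
  m$pool_arg <- NULL
  invisible(m)
}

model_fwd <- function(m, x, H, W, B, train = TRUE) {
  s <- conv_fwd(m$stem_conv, x, H, W, B, train)
  h <- relu_fwd(m$stem_relu, bn_fwd(m$stem_bn, s$x, train), train)
  mp <- maxpool_cpp(h, s$H, s$W, B, 3L, 2L, 1L)
  if (train) {
    m$pool_arg <- mp$argmax; m$pool_ncol <- ncol(h)
    m$stem_dims <- c(s$H, s$W)
  }
  H2 <- (s$H + 2 - 3) %/% 2 + 1; W2 <- (s$W + 2 - 3) %/% 2 + 1
  cur <- list(x = mp$values, H = H2, W = W2, B = B)
  for (blk in m$blocks) cur <- block_fwd(blk, cur$x, cur$H, cur$W, B, train)
  if (train) m$gap_dims <- c(cur$H, cur$W)
  feat <- gap_fwd(cur$x, cur$H, cur$W, B)
  logits <- dense_fwd(m$dense, feat, train)
  list(logits = logits, H = cur$H, W = cur$W, B = B)
}

model_bwd <- function(m, dlogits, B) {
  d <- dense_bwd(m$dense, dlogits)
  d <- gap_bwd(d, m$gap_dims[1], m$gap_dims[2], B)
  for (blk in rev(m$blocks)) d <- block_bwd(blk, d)
  d <- maxpool_backward_cpp(d, m$pool_arg, m$pool_ncol)
  d <- bn_bwd(m$stem_bn, relu_bwd(m$stem_relu, d))
  conv_bwd(m$stem_conv, d)
}

# images (list of H x W matrices) -> 1 x (H*W*B) input matrix
images_to_input <- function(images) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- matrix(unlist(images, use.names = FALSE), 1, H * W * length(images))
  list(x = x, H = H, W = W, B = length(images))
}

#' Class probabilities for a batch of images
#'
#' Runs the forward pass in inference mode (batch-normalization running
#' statistics) and applies the softmax head.
#'
#' @param model A `scinti_model` from [build_classifier()] or
#'   [train_classifier()].
#' @param images List of numeric matrices matching the model's input shape.
#'   Images should already be normalised to `[0, 1]`; trained models store
#'   their normalisation constant in `model$norm_max` and apply it.
#' @param batch_size Forward batch size.
#' @return Matrix `length(images) x num_classes` of probabilities; rows sum
#'   to 1.
#' @export
predict_proba <- function(model, images, batch_size = 32) {
  stopifnot(inherits(model, "scinti_model"))
  if (!is.null(model$norm_max)) {
    images <- lapply(images, function(im) im / model$norm_max)
  }
  n <- length(images)
  out <- matrix(NA_real_, n, model$spec$num_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    inp <- images_to_input(images[idx])
    lg <- model_fwd(model, inp$x, inp$H, inp$W, inp$B, train = FALSE)$logits
    out[idx, ] <- t(apply(lg, 2, softmax))
  }
  out
}

#' Softmax normalisation
#'
#' `f(x_j) = exp(x_j) / sum_i exp(x_i)`, computed with the max-shift trick
#' for numerical stability. Outputs lie in (0, 1) and sum to 1.
#'
#' @param x Finite numeric vector, length >= 1.
#' @return Probability vector of the same length.
#' @export
#' @examples
#' softmax(c(0, log(3)))  # 0.25, 0.75
softmax <- function(x) {
  if (length(x) == 0) abort("softmax of an empty vector")
  if (any(!is.finite(x))) abort("softmax requires finite inputs")
  e <- exp(x - max(x))
  e / sum(e)
}

#' @export
print.scinti_model <- function(x, ...) {
  sp <- x$spec
  cat(sprintf(
    "<scinti_model> %d weight layers, blocks (%s), channels (%s)\n  attention: %s, residual: %s, classes: %d, input %dx%d\n",
    count_weight_layers(sp), paste(sp$stage_blocks, collapse = ","),
    paste(sp$stage_channels, collapse = ","), sp$attention_placement,
    sp$residual, sp$num_classes, sp$input_shape[1], sp$input_shape[2]
  ))
  invisible(x)
}

#' Layer-by-layer summary table of a specification
#'
#' @param spec A [network_spec()].
#' @return A tibble with one row per named layer group.
#' @export
model_summary <- function(spec) {
  tr <- feature_trace(spec)
  tibble::tibble(
    layer = c("conv 7x7/2", "maxpool 3x3/2",
              paste0("stage", 1:4, " [3x3,", spec$stage_channels, "] x",
                     spec$stage_blocks),
              "global average pooling", "fully connected + softmax"),
    output = c(paste0(tr$height, "x", tr$width, "x", tr$channels),
               paste0(spec$stage_channels[4], " features"),
               paste0(spec$num_classes, " probabilities")),
    weight_layers = c(1L, 0L, 2L * spec$stage_blocks, 0L, 1L)
  )
}

#' Save / load a trained model
#'
#' The checkpoint stores the specification plus all parameter arrays and
#' batch-normalization running statistics.
#'
#' @param model A `scinti_model`.
#' @param path File path for the checkpoint.
#' @return `path` (save); a rebuilt `scinti_model` (load).
#' @export
save_model <- function(model, path) {
  layers <- all_layers(model)
  params <- lapply(layers, function(l) {
    keep <- c(layer_param_names(l), "run_mean", "run_var")
    out <- list()
    for (p in keep) if (!is.null(l[[p]])) out[[p]] <- l[[p]]
    out
  })
  saveRDS(list(spec = model$spec, params = params,
               norm_max = model$norm_max, t = model$t), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  st <- readRDS(path)
  m <- build_classifier(st$spec, seed = 1)
  layers <- all_layers(m)
  stopifnot(length(layers) == length(st$params))
  for (i in seq_along(layers)) {
    for (p in names(st$params[[i]])) layers[[i]][[p]] <- st$params[[i]][[p]]
  }
  m$norm_max <- st$norm_max
  m$t <- st$t
  m
}
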