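test_that("softmax matches the closed form and its invariants", {
  expect_equal(softmax(c(0, log(3))), c(0.25, 0.75), tolerance = 1e-9)
  expect_equal(softmax(c(5, 5, 5)), rep(1 / 3, 3))
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1), sd = 10)
    p <- softmax(x)
    expect_true(all(p > 0 & p < 1))
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
  # numerically stable for large magnitudes
  expect_equal(sum(softmax(c(1000, 1001))), 1)
  expect_error(softmax(numeric(0)), "empty")
  expect_error(softmax(c(1, NaN)), "finite")
})

test_that("weight-layer counts match the named depths", {
  expect_equal(count_weight_layers(network_spec(c(2, 3, 5, 2))), 26)
  expect_equal(count_weight_layers(network_spec(c(2, 2, 2, 2))), 18)
  expect_equal(count_weight_layers(network_spec(c(3, 4, 6, 3))), 34)
})

test_that("feature trace follows the /32 downsampling arithmetic", {
  tr <- feature_trace(network_spec(c(2, 3, 5, 2)))
  expect_equal(tr$height, c(512, 256, 256, 128, 64, 32))
  expect_equal(tr$width, c(128, 64, 64, 32, 16, 8))
  expect_equal(tr$channels, c(64L, 64L, 64L, 128L, 256L, 512L))
  # last stage: 512-vector after GAP, /32 in each spatial dimension
  expect_equal(1024 / tr$height[6], 32)
  expect_equal(256 / tr$width[6], 32)
})

test_that("network_spec validates its fields", {
  expect_error(network_spec(c(2, 3, 5)), "four")
  expect_error(network_spec(stage_channels = c(64, 32, 128, 256)),
               "non-decreasing")
  expect_error(network_spec(num_classes = 1), ">= 2")
  expect_error(build_ra_block(4, 8, 3, network_spec()), "stride")
})

test_that("a zero conv branch residual block is a rectified shortcut", {
  spec <- network_spec(attention_placement = "none",
                       input_shape = c(16, 8))
  blk <- build_ra_block(4, 4, 1, spec, seed = 2)
  blk$conv1$W[] <- 0; blk$conv1$b[] <- 0
  blk$conv2$W[] <- 0; blk$conv2$b[] <- 0
  # with a zero branch, batch normalization emits only beta = 0
  set.seed(5)
  input <- array(rnorm(6 * 4 * 4 * 2), c(6, 4, 4, 2))
  out <- block_forward(blk, input)
  expect_equal(out, pmax(input, 0), tolerance = 1e-12)
})

test_that("inside and outside attention placements compute differently", {
  set.seed(6)
  input <- array(abs(rnorm(8 * 8 * 4 * 1)) + 0.5, c(8, 8, 4, 1))
  mk <- function(pl) {
    spec <- network_spec(attention_placement = pl,
                         attention = attention_config(reduction_ratio = 2,
                                                      spatial_kernel = 3),
                         input_shape = c(16, 8))
    build_ra_block(4, 4, 1, spec, seed = 11)
  }
  o_in <- block_forward(mk("inside"), input)
  o_out <- block_forward(mk("outside"), input)
  expect_equal(dim(o_in), dim(o_out))
  expect_gt(max(abs(o_in - o_out)), 1e-6)
})

test_that("stride-2 blocks halve the spatial dimensions and remap channels", {
  spec <- network_spec(input_shape = c(16, 8),
                       attention = attention_config(reduction_ratio = 8,
                                                    spatial_kernel = 3))
  blk <- build_ra_block(64, 128, 2, spec, seed = 3)
  input <- array(rnorm(8 * 4 * 64 * 2), c(8, 4, 64, 2))
  out <- block_forward(blk, input)
  expect_equal(dim(out), c(4, 2, 128, 2))
})

test_that("classifier forward emits valid probability rows for batches", {
  spec <- network_spec(stage_blocks = c(1, 1, 1, 1),
                       stage_channels = c(4, 4, 8, 8),
                       attention = attention_config(reduction_ratio = 2,
                                                    spatial_kernel = 3),
                       input_shape = c(64, 32))
  m <- build_classifier(spec, seed = 4)
  set.seed(10)
  imgs <- lapply(1:5, function(i) matrix(runif(64 * 32), 64, 32))
  p <- predict_proba(m, imgs, batch_size = 2)
  expect_equal(dim(p), c(5, 3))
  expect_true(all(p > 0 & p < 1))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  # deterministic given fixed weights and input
  expect_equal(predict_proba(m, imgs), p, tolerance = 1e-12)
})

test_that("all four residual x attention ablation variants build and run", {
  set.seed(12)
  imgs <- lapply(1:2, function(i) matrix(runif(64 * 32), 64, 32))
  for (res in c(TRUE, FALSE)) {
    for (att in c("inside", "none")) {
      spec <- network_spec(stage_blocks = c(1, 1, 1, 1),
                           stage_channels = c(4, 4, 8, 8),
                           attention_placement = att, residual = res,
                           attention = attention_config(reduction_ratio = 2,
                                                        spatial_kernel = 3),
                           input_shape = c(64, 32))
      m <- build_classifier(spec, seed = 1)
      p <- predict_proba(m, imgs)
      expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
    }
  }
})

test_that("analytic gradients match finite differences through the network", {
  spec <- network_spec(stage_blocks = c(1, 1, 1, 1),
                       stage_channels = c(4, 4, 8, 8),
                       attention_placement = "inside",
                       attention = attention_config(reduction_ratio = 2,
                                                    spatial_kernel = 3),
                       input_shape = c(32, 16))
  m <- build_classifier(spec, seed = 3)
  rng <- scintimet:::make_rng(99)
  B <- 3
  imgs <- lapply(1:B, function(i) matrix(scintimet:::rng_runif(rng, 32 * 16), 32, 16))
  y <- c(1L, 2L, 3L)
  inp <- scintimet:::images_to_input(imgs)
  layers <- scintimet:::all_layers(m)
  loss_fn <- function() {
    out <- scintimet:::model_fwd(m, inp$x, inp$H, inp$W, inp$B, train = TRUE)
    scintimet:::softmax_xent(out$logits, y)
  }
  ce <- loss_fn()
  for (l in layers) scintimet:::zero_grads(l)
  invisible(scintimet:::model_bwd(m, ce$dlogits, B))
  set.seed(11)
  for (trial in 1:25) {
    l <- layers[[sample(length(layers), 1)]]
    p <- sample(scintimet:::layer_param_names(l), 1)
    i <- sample(length(l[[p]]), 1)
    g_an <- l[[paste0("d", p)]][i]
    eps <- 1e-5; old <- l[[p]][i]
    l[[p]][i] <- old + eps; lp <- loss_fn()$loss
    l[[p]][i] <- old - eps; lm <- loss_fn()$loss
    l[[p]][i] <- old
    g_num <- (lp - lm) / (2 * eps)
    expect_lt(abs(g_an - g_num) / max(1e-6, abs(g_an) + abs(g_num)), 1e-3)
  }
})

test_that("checkpoints round-trip through save/load", {
  spec <- network_spec(stage_blocks = c(1, 1, 1, 1),
                       stage_channels = c(4, 4, 8, 8),
                       attention = attention_config(reduction_ratio = 2,
                                                    spatial_kernel = 3),
                       input_shape = c(64, 32))
  m <- build_classifier(spec, seed = 7)
  m$norm_max <- 123
  set.seed(13)
  imgs <- lapply(1:3, function(i) matrix(runif(64 * 32) * 123, 64, 32))
  p1 <- predict_proba(m, imgs)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict_proba(m2, imgs), p1, tolerance = 1e-12)
})
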