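test_that("train_config validates the recipe", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 0.01)
  expect_equal(cfg$optimizer, "Adam")
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$epochs, 300L)
  expect_error(train_config(learning_rate = 0), "> 0")
  expect_error(train_config(learning_rate = -1), "> 0")
  expect_error(train_config(batch_size = 0), ">= 1")
  expect_error(train_config(optimizer = "SGD"), "Adam")
})

test_that("100 single-image patients split exactly 70/30", {
  m <- records_manifest(c(NoMet = 40, ADMet = 30, nADMet = 30))
  s <- split_dataset(m, 0.7, seed = 1)
  expect_equal(length(s$train_ids), 70)
  expect_equal(length(s$test_ids), 30)
  expect_equal(s$train_fraction, 0.7)
  # partition: disjoint and exhaustive
  expect_length(intersect(s$train_ids, s$test_ids), 0)
  expect_setequal(c(s$train_ids, s$test_ids), m$study_id)
  # deterministic under the seed
  s2 <- split_dataset(m, 0.7, seed = 1)
  expect_identical(s$train_ids, s2$train_ids)
})

test_that("no patient ever spans both sides, across many seeds", {
  m <- records_manifest(c(NoMet = 12, ADMet = 9, nADMet = 9),
                        studies_per_patient = 3)
  for (seed in 1:100) {
    s <- split_dataset(m, 0.7, seed = seed)
    pt <- function(ids) unique(m$patient_id[m$study_id %in% ids])
    expect_length(intersect(pt(s$train_ids), pt(s$test_ids)), 0)
  }
})

test_that("augmented derivatives follow their source patient's side", {
  coh <- small_cohort(3, seed = 41, shape = c(128, 32))
  man <- aggregate_manifest(coh$manifest)
  aug <- augment_dataset(man, c(ADMet = 6, nADMet = 6, NoMet = 6),
                         augment_params(seed = 2))
  s <- split_dataset(aug, 0.7, seed = 3)
  derived <- aug[!is.na(aug$source_study), ]
  for (i in seq_len(nrow(derived))) {
    src_side <- derived$source_study[i] %in% s$train_ids
    der_side <- derived$study_id[i] %in% s$train_ids
    expect_equal(der_side, src_side)
  }
})

test_that("a dominant patient triggers the best-effort warning", {
  rows <- data.frame(
    study_id = paste0("s", 1:10),
    patient_id = c(rep("big", 8), "a", "b"),
    label = "NoMet"
  )
  expect_warning(split_dataset(build_manifest(rows), 0.7, seed = 1),
                 "best-effort")
})

test_that("training rejects degenerate setups", {
  coh <- small_cohort(2, seed = 51, shape = c(128, 32))
  man <- aggregate_manifest(coh$manifest)
  spec <- network_spec(input_shape = c(32, 8))
  only_two <- man[man$label != "nADMet", ]
  expect_error(
    train_classifier(spec, only_two, train_config(epochs = 1)),
    "absent from the training split: nADMet"
  )
  expect_error(
    train_classifier(spec, man, train_config(epochs = 1), image_col = "nope"),
    "no 'nope' image column"
  )
})

test_that("hard labels are the argmax with ties to the lowest index", {
  probs <- matrix(c(0.2, 0.5, 0.3), 1)
  expect_equal(which.max(probs[1, ]), 2L)
  tie <- c(0.5, 0.5)
  expect_equal(which.max(tie), 1L)  # tie rule: first (lowest) index
})

test_that("predictions are per-image: batch order does not matter", {
  spec <- network_spec(stage_blocks = c(1, 1, 1, 1),
                       stage_channels = c(4, 4, 8, 8),
                       attention = attention_config(reduction_ratio = 2,
                                                    spatial_kernel = 3),
                       input_shape = c(64, 32))
  m <- build_classifier(spec, seed = 9)
  set.seed(14)
  imgs <- lapply(1:7, function(i) matrix(runif(64 * 32), 64, 32))
  p <- predict_proba(m, imgs, batch_size = 3)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  p2 <- predict_proba(m, imgs[perm], batch_size = 3)
  expect_equal(p2, p[perm, ], tolerance = 1e-10)
})

test_that("a short fit learns, records history, and predicts tidily", {
  coh <- small_cohort(4, seed = 61, shape = c(128, 32))
  man <- aggregate_manifest(coh$manifest)
  spec <- network_spec(stage_blocks = c(1, 1, 1, 1),
                       stage_channels = c(8, 8, 16, 16),
                       attention = attention_config(reduction_ratio = 4,
                                                    spatial_kernel = 3),
                       input_shape = c(32, 8))
  cfg <- train_config(epochs = 4, batch_size = 6, seed = 2,
                      desk_scale = TRUE, downscale = 4)
  fit <- train_classifier(spec, man, cfg)
  h <- tidy(fit)
  expect_equal(nrow(h), 4)
  expect_true(all(is.finite(h$loss)))
  g <- glance(fit)
  expect_equal(g$epochs, 4L)
  expect_gt(g$parameters, 1000)
  preds <- predict(fit, man)
  expect_equal(nrow(preds), nrow(man))
  expect_true(all(preds$.pred_class %in% scinti_classes()))
  prob_sum <- preds$.pred_NoMet + preds$.pred_ADMet + preds$.pred_nADMet
  expect_equal(prob_sum, rep(1, nrow(man)), tolerance = 1e-6)
})
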