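#' Training configuration
#'
#' Defaults follow the full-scale recipe for this classifier family:
#' Adam, learning rate 0.01, batch size 32, 300 epochs. `desk_scale` enables
#' a reduced regime for laptop/CI runs: inputs are block-averaged down by
#' `downscale` in each dimension and `epochs` is typically lowered by the
#' caller; nothing else changes.
#'
#' @param learning_rate Positive step size (default 0.01).
#' @param optimizer Only `"Adam"` is provided.
#' @param batch_size Mini-batch size, `>= 1` (default 32).
#' @param epochs Number of passes over the training set, `>= 1`.
#' @param seed Integer seed for shuffling and weight init.
#' @param desk_scale Reduced-resolution mode for quick runs.
#' @param downscale Integer downscale factor applied when `desk_scale` is
#'   `TRUE` (default 4).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, optimizer = "Adam",
                         batch_size = 32, epochs = 300, seed = 1,
                         desk_scale = FALSE, downscale = 4) {
  if (!identical(optimizer, "Adam")) abort("Only the Adam optimizer is provided")
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (batch_size < 1 || epochs < 1) abort("batch_size and epochs must be >= 1")
  structure(
    list(learning_rate = learning_rate, optimizer = optimizer,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         seed = seed, desk_scale = isTRUE(desk_scale),
         downscale = as.integer(downscale)),
    class = "train_config"
  )
}

#' Block-average an image down by an integer factor
#'
#' @param image Numeric matrix.
#' @param factor Integer >= 1; trailing rows/columns that do not fill a
#'   block are dropped.
#' @return Matrix of shape `floor(dim / factor)`.
#' @export
downscale_image <- function(image, factor) {
  f <- as.integer(factor)
  if (f <= 1) return(image)
  Hn <- nrow(image) %/% f; Wn <- ncol(image) %/% f
  a <- array(image[seq_len(Hn * f), seq_len(Wn * f)], c(f, Hn, f, Wn))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

#' Patient-grouped train/test split
#'
#' Partitions *patients* (never single images) between the training and
#' testing sides so that no study — including augmented derivatives, which
#' inherit their source's `patient_id` — appears on both sides. Within each
#' class the patient order is randomised under the seed and patients are
#' assigned greedily until the class's train image count reaches
#' `train_ratio` of its images, which makes the split stratified and, when
#' every patient contributes one image, exact.
#'
#' @param manifest A manifest tibble.
#' @param train_ratio Fraction of images on the training side, in (0, 1).
#' @param seed Integer seed.
#' @return A `scinti_split`: list with `train_ids`, `test_ids` (study ids)
#'   and the achieved `train_fraction`.
#' @export
split_dataset <- function(manifest, train_ratio = 0.7, seed = 1) {
  if (nrow(manifest) == 0) abort("Cannot split an empty manifest")
  if (train_ratio <= 0 || train_ratio >= 1) abort("train_ratio must be in (0, 1)")
  rng <- make_rng(seed)
  # a patient's class = class of most of their images (phantom and clinical
  # cohorts are one-class-per-patient; ties go to the first class by order)
  pat <- manifest |>
    dplyr::count(.data$patient_id, .data$label) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      class = .data$label[which.max(.data$n)],
      images = sum(.data$n), .groups = "drop"
    )
  biggest <- max(pat$images) / nrow(manifest)
  if (biggest > max(train_ratio, 1 - train_ratio)) {
    warn(sprintf(
      "One patient holds %.0f%% of all images; the split can only be best-effort",
      100 * biggest
    ))
  }
  train_patients <- character(0)
  for (cl in unique(pat$class)) {
    sub <- pat[pat$class == cl, , drop = FALSE]
    sub <- sub[rng_sample(rng, seq_len(nrow(sub))), , drop = FALSE]
    target <- round(train_ratio * sum(sub$images))
    got <- 0
    for (i in seq_len(nrow(sub))) {
      if (got < target) {
        train_patients <- c(train_patients, sub$patient_id[i])
        got <- got + sub$images[i]
      }
    }
  }
  is_train <- manifest$patient_id %in% train_patients
  structure(
    list(
      train_ids = manifest$study_id[is_train],
      test_ids = manifest$study_id[!is_train],
      train_fraction = mean(is_train)
    ),
    class = "scinti_split"
  )
}

#' @export
print.scinti_split <- function(x, ...) {
  cat(sprintf("<scinti_split> %d train / %d test (train fraction %.3f)\n",
              length(x$train_ids), length(x$test_ids), x$train_fraction))
  invisible(x)
}

# softmax cross-entropy on a logits matrix (classes x batch)
softmax_xent <- function(logits, y_idx) {
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  p <- sweep(e, 2, colSums(e), "/")
  B <- ncol(logits)
  ii <- cbind(y_idx, seq_len(B))
  loss <- -mean(log(pmax(p[ii], 1e-12)))
  onehot <- matrix(0, nrow(logits), B)
  onehot[ii] <- 1
  list(loss = loss, dlogits = (p - onehot) / B, p = p)
}

#' Train a classifier on a manifest
#'
#' Runs the configured optimiser over the manifest's images. Inputs are
#' normalised to `[0, 1]` by division by the training-set maximum (stored in
#' the model and re-applied at prediction time); in `desk_scale` mode they
#' are first block-averaged down by the configured factor. Per-epoch
#' training loss and accuracy are recorded in `model$history`.
#'
#' @param spec A [network_spec()].
#' @param manifest Manifest carrying an image list-column.
#' @param config A [train_config()].
#' @param split Optional [split_dataset()] result; only `train_ids` rows are
#'   used for fitting. `NULL` trains on the whole manifest.
#' @param image_col Which list-column holds the inputs (default
#'   `"composite"`).
#' @param verbose Print a line per epoch?
#' @return The trained `scinti_model`, with `history` (tibble), `norm_max`,
#'   `downscale` and `config` fields set.
#' @export
train_classifier <- function(spec, manifest, config = train_config(),
                             split = NULL, image_col = "composite",
                             verbose = FALSE) {
  stopifnot(inherits(spec, "network_spec"), inherits(config, "train_config"))
  if (!image_col %in% names(manifest)) {
    abort(sprintf("Manifest has no '%s' image column", image_col))
  }
  rows <- if (is.null(split)) manifest else
    manifest[manifest$study_id %in% split$train_ids, , drop = FALSE]
  labels <- factor(rows$label, levels = scinti_classes())
  labels <- droplevels(labels)
  if (spec$num_classes == 3) {
    present <- table(factor(rows$label, levels = scinti_classes()))
    if (any(present == 0)) {
      abort(paste0("Class(es) absent from the training split: ",
                   paste(names(present)[present == 0], collapse = ", ")))
    }
    y <- as.integer(factor(rows$label, levels = scinti_classes()))
  } else {
    # merged two-class problem: metastatic vs not
    y <- ifelse(rows$label == "NoMet", 1L, 2L)
  }
  f <- if (config$desk_scale) config$downscale else 1L
  images <- lapply(rows[[image_col]], downscale_image, factor = f)
  norm_max <- max(vapply(images, max, numeric(1)))
  if (norm_max <= 0) abort("Training images are identically zero")
  images <- lapply(images, function(im) im / norm_max)
  model <- build_classifier(spec, seed = config$seed)
  model$norm_max <- norm_max
  model$downscale <- f
  model$config <- config
  rng <- make_rng(config$seed + 1)
  n <- length(images)
  hist <- vector("list", config$epochs)
  layers <- all_layers(model)
  for (ep in seq_len(config$epochs)) {
    ord <- rng_sample(rng, seq_len(n))
    ep_loss <- 0; ep_hits <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      inp <- images_to_input(images[idx])
      out <- model_fwd(model, inp$x, inp$H, inp$W, inp$B, train = TRUE)
      ce <- softmax_xent(out$logits, y[idx])
      for (l in layers) zero_grads(l)
      model_bwd(model, ce$dlogits, inp$B)
      model$t <- model$t + 1L
      for (l in layers) adam_step(l, config$learning_rate, model$t)
      ep_loss <- ep_loss + ce$loss * length(idx)
      ep_hits <- ep_hits + sum(apply(ce$p, 2, which.max) == y[idx])
    }
    hist[[ep]] <- tibble::tibble(
      epoch = ep, loss = ep_loss / n, accuracy = ep_hits / n
    )
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f",
                      ep, ep_loss / n, ep_hits / n))
    }
    if (!is.finite(ep_loss)) abort(sprintf("Training diverged at epoch %d", ep))
  }
  model$history <- dplyr::bind_rows(hist)
  calibrate_bn(model, images, config$batch_size)
  model_clear_caches(model)
  model
}

# Recompute batch-normalization running statistics as exact population
# moments over the training images (weights frozen). With few training
# batches the momentum-smoothed estimates are still biased toward their
# initial values; this one extra forward sweep removes the train/inference
# mismatch deterministically.
calibrate_bn <- function(model, images, batch_size) {
  layers <- all_layers(model)
  bns <- Filter(function(l) l$type == "bn", layers)
  for (l in bns) { l$collect <- TRUE; l$acc_n <- NULL; l$acc_sum <- NULL; l$acc_sq <- NULL }
  n <- length(images)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    inp <- images_to_input(images[idx])
    model_fwd(model, inp$x, inp$H, inp$W, inp$B, train = TRUE)
  }
  for (l in bns) {
    mu <- l$acc_sum / l$acc_n
    l$run_mean <- mu
    l$run_var <- pmax(l$acc_sq / l$acc_n - mu^2, 0)
    l$collect <- FALSE
    l$acc_n <- NULL; l$acc_sum <- NULL; l$acc_sq <- NULL
    l$xhat <- NULL; l$invstd <- NULL
  }
  invisible(model)
}

#' Predict classes for manifest rows or an image list
#'
#' @param object A trained `scinti_model`.
#' @param newdata A manifest tibble with the model's image column, or a bare
#'   list of image matrices.
#' @param image_col List-column to read when `newdata` is a manifest.
#' @param ... Unused.
#' @return A tibble with one row per image: `.pred_class` (ties broken
#'   toward the lowest class index) and one `.pred_<class>` probability
#'   column per class.
#' @export
predict.scinti_model <- function(object, newdata, image_col = "composite", ...) {
  images <- if (is.data.frame(newdata)) newdata[[image_col]] else newdata
  stopifnot(is.list(images))
  f <- object$downscale %||% 1L
  images <- lapply(images, downscale_image, factor = f)
  probs <- predict_proba(object, images)
  cls <- if (object$spec$num_classes == 3) scinti_classes() else c("NoMet", "Met")
  hard <- apply(probs, 1, which.max)  # which.max takes the first maximum
  out <- tibble::tibble(.pred_class = cls[hard])
  for (j in seq_along(cls)) out[[paste0(".pred_", cls[j])]] <- probs[, j]
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted classifier
#'
#' @param x A trained `scinti_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `accuracy`.
#' @export
tidy.scinti_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), loss = numeric(),
                                accuracy = numeric())
}

#' One-row fit summary of a trained classifier
#'
#' @param x A trained `scinti_model`.
#' @param ... Unused.
#' @return Tibble with depth, parameter count, epochs and final training
#'   loss/accuracy.
#' @export
glance.scinti_model <- function(x, ...) {
  n_par <- sum(vapply(all_layers(x), function(l) {
    sum(vapply(layer_param_names(l), function(p) length(l[[p]]), numeric(1)))
  }, numeric(1)))
  h <- x$history
  tibble::tibble(
    weight_layers = count_weight_layers(x$spec),
    parameters = n_par,
    epochs = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    final_accuracy = if (is.null(h)) NA_real_ else h$accuracy[nrow(h)]
  )
}
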