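#' Augmentation parameters
#'
#' Bounds for the parametric-variation augmentation: rotation magnitude is
#' drawn uniformly from `[0, r_T]` degrees with a uniformly random direction
#' (left/right), translation magnitude uniformly from the integers
#' `[0, t_T]` pixels with uniformly random sign and axis. Defaults of 3
#' degrees / 3 pixels match the magnitudes of the worked augmentation
#' examples for whole-body scans; both bounds are tunable.
#'
#' @param r_T Maximum rotation, degrees, in `[0, 45]`.
#' @param t_T Maximum translation, whole pixels, `>= 0`.
#' @param seed Integer seed for the augmentation stream.
#' @return An `augment_params` list.
#' @export
augment_params <- function(r_T = 3, t_T = 3, seed = 1) {
  if (r_T < 0 || r_T > 45) abort("r_T must lie in [0, 45] degrees")
  if (t_T < 0 || t_T != round(t_T)) abort("t_T must be a non-negative integer")
  structure(list(r_T = r_T, t_T = t_T, seed = seed), class = "augment_params")
}

#' Rotate an image about its geometric center
#'
#' Bilinear interpolation; the canvas keeps its size, exposed corners are
#' zero-filled and any interpolation undershoot is clamped to zero so count
#' images stay non-negative. Positive `degrees` rotates the displayed image
#' to the right (clockwise), negative to the left.
#'
#' @param image Numeric matrix (height x width).
#' @param degrees Rotation angle.
#' @return Rotated matrix, same shape.
#' @export
rotate_image <- function(image, degrees) {
  stopifnot(is.matrix(image))
  if (degrees == 0) return(image)
  # EBImage works in (x, y) order, the transpose of our (row, col) frame,
  # which mirrors the sense of rotation; negate to keep "positive = right".
  out <- EBImage::rotate(image, -degrees,
                         output.dim = c(nrow(image), ncol(image)), bg.col = 0)
  out <- as.matrix(out)
  out[out < 0] <- 0
  out
}

#' Translate an image by whole pixels
#'
#' Integer shift with zero fill. `dr > 0` moves content down, `dc > 0`
#' moves it right.
#'
#' @param image Numeric matrix.
#' @param dr,dc Row/column shifts in pixels.
#' @return Shifted matrix, same shape.
#' @export
translate_image <- function(image, dr = 0, dc = 0) {
  stopifnot(is.matrix(image), dr == round(dr), dc == round(dc))
  shift_image(image, dr, dc)
}

#' Randomly rotate / translate an image within the configured bounds
#'
#' @param image Numeric matrix.
#' @param params An [augment_params()].
#' @param rng Internal RNG stream (from a seed via the calling function);
#'   pass the same stream to reproduce a draw sequence.
#' @return Transformed matrix, same shape, non-negative.
#' @name random_transforms
NULL

#' @rdname random_transforms
#' @export
random_rotate <- function(image, params, rng = make_rng(params$seed)) {
  angle <- rng_runif(rng, 1, 0, params$r_T)
  dir <- if (rng_runif(rng, 1) < 0.5) -1 else 1
  rotate_image(image, dir * angle)
}

#' @rdname random_transforms
#' @export
random_translate <- function(image, params, rng = make_rng(params$seed)) {
  stopifnot(params$t_T < min(dim(image)))
  t <- rng_rint(rng, 1, params$t_T + 1L) - 1L  # uniform on 0..t_T
  sign <- if (rng_runif(rng, 1) < 0.5) -1L else 1L
  if (rng_runif(rng, 1) < 0.5) {
    translate_image(image, dr = sign * t, dc = 0)
  } else {
    translate_image(image, dr = 0, dc = sign * t)
  }
}

# apply one randomly composed rotation and/or translation to a set of images
# (all images get the same transform, keeping a study's views consistent)
random_augment_once <- function(images, params, rng) {
  do_rot <- rng_runif(rng, 1) < 0.5
  do_trans <- rng_runif(rng, 1) < 0.5
  if (!do_rot && !do_trans) do_rot <- TRUE  # never emit an identical copy
  if (do_rot) {
    angle <- rng_runif(rng, 1, 0, params$r_T)
    dir <- if (rng_runif(rng, 1) < 0.5) -1 else 1
    images <- lapply(images, rotate_image, degrees = dir * angle)
  }
  if (do_trans) {
    t <- rng_rint(rng, 1, params$t_T + 1L) - 1L
    sign <- if (rng_runif(rng, 1) < 0.5) -1L else 1L
    vert <- rng_runif(rng, 1) < 0.5
    images <- lapply(images, function(im) {
      if (vert) translate_image(im, dr = sign * t) else translate_image(im, dc = sign * t)
    })
  }
  images
}

#' Expand a dataset to target per-class counts by augmentation
#'
#' Keeps every original record and adds `target - available` augmented
#' records per class, each produced by randomly composing one bounded
#' rotation and/or one bounded translation of a randomly chosen original of
#' that class. Augmented records inherit their source's `patient_id` (so
#' patient-grouped splitting keeps derivatives with their source) and record
#' it in a `source_study` column.
#'
#' Which images are transformed depends on `stage`: `"composite"` (default)
#' augments the fused `composite` image directly; `"view"` augments the
#' `anterior`/`posterior` views with a shared transform, leaving downstream
#' re-aggregation to the caller.
#'
#' @param manifest Manifest carrying image list-columns.
#' @param target_counts Named vector of target per-class record counts;
#'   classes not named are left untouched.
#' @param params An [augment_params()] (its `seed` drives all draws).
#' @param stage `"composite"` or `"view"`.
#' @return The expanded manifest; class counts equal the targets.
#' @export
augment_dataset <- function(manifest, target_counts, params = augment_params(),
                            stage = c("composite", "view")) {
  stage <- match.arg(stage)
  check_labels(names(target_counts))
  cols <- if (stage == "composite") "composite" else c("anterior", "posterior")
  missing_cols <- setdiff(cols, names(manifest))
  if (length(missing_cols) > 0) {
    abort(paste0("augment_dataset(stage = \"", stage, "\") needs column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  avail <- class_counts(manifest)
  rng <- make_rng(params$seed)
  new_rows <- list()
  for (cl in names(target_counts)) {
    n_new <- target_counts[[cl]] - avail[[cl]]
    if (n_new < 0) {
      abort(sprintf("Target for class %s (%d) is below availability (%d); use balance_classes() to thin",
                    cl, target_counts[[cl]], avail[[cl]]))
    }
    if (n_new == 0) next
    src_idx <- which(manifest$label == cl)
    picks <- rng_sample(rng, src_idx, n_new, replace = TRUE)
    for (k in seq_len(n_new)) {
      row <- manifest[picks[k], , drop = FALSE]
      imgs <- random_augment_once(lapply(cols, function(cc) row[[cc]][[1]]), params, rng)
      for (j in seq_along(cols)) row[[cols[j]]][[1]] <- imgs[[j]]
      row$source_study <- row$study_id
      row$study_id <- sprintf("%s_aug%s%03d", row$study_id, cl, k)
      new_rows[[length(new_rows) + 1]] <- row
    }
  }
  if (!"source_study" %in% names(manifest)) manifest$source_study <- NA_character_
  out <- dplyr::bind_rows(c(list(manifest), new_rows))
  class(out) <- class(manifest)
  out
}
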