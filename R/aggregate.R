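#' Flip an image horizontally
#'
#' Mirrors the image around its central vertical line: output column `c`
#' equals input column `W - c + 1`. Applied to the posterior view before
#' alignment, because the posterior projection is mirror-imaged relative to
#' the anterior one.
#'
#' @param image Numeric matrix (height x width).
#' @return Matrix of the same shape.
#' @export
#' @examples
#' flip_horizontal(matrix(1:6, 2, byrow = TRUE))
flip_horizontal <- function(image) {
  stopifnot(is.matrix(image))
  image[, ncol(image):1, drop = FALSE]
}

#' Locate the critical points of the body region
#'
#' Sweeps the image row by row and column by column for pixels whose uptake
#' strictly exceeds `threshold`. The first/last such row are the ceiling and
#' floor points; the first/last such column the left and right points. These
#' four indices bound the supra-threshold body region and drive view
#' alignment.
#'
#' @param image Numeric matrix.
#' @param threshold Uptake level a pixel must strictly exceed to count as
#'   body. Default 0: any recorded count marks the body.
#' @return A list with `ceil_row`, `floor_row`, `left_col`, `right_col`
#'   (1-based indices).
#' @export
find_critical_points <- function(image, threshold = 0) {
  stopifnot(is.matrix(image))
  rows <- which(apply(image > threshold, 1, any))
  cols <- which(apply(image > threshold, 2, any))
  if (length(rows) == 0) abort("empty body region: no pixel exceeds the threshold")
  structure(
    list(
      ceil_row = rows[1], floor_row = rows[length(rows)],
      left_col = cols[1], right_col = cols[length(cols)]
    ),
    class = "critical_points"
  )
}

# integer translate with zero fill; dr > 0 moves content down, dc > 0 right
shift_image <- function(image, dr, dc) {
  H <- nrow(image); W <- ncol(image)
  out <- matrix(if (is.integer(image)) 0L else 0, H, W)
  src_r <- seq_len(H) - dr
  src_c <- seq_len(W) - dc
  ok_r <- src_r >= 1 & src_r <= H
  ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- image[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Align a flipped posterior view onto the anterior view
#'
#' Translates the flipped posterior by integer offsets so that its top-left
#' critical corner (ceiling row, left column) coincides with the anterior's.
#' Translation only: no rescaling or rotation, so count statistics are
#' preserved except for pixels shifted out of bounds (dropped; vacated pixels
#' are zero-filled).
#'
#' @param anterior Numeric matrix, returned unchanged.
#' @param flipped_posterior Numeric matrix, already mirrored.
#' @param threshold Body-region threshold passed to [find_critical_points()].
#' @return List with `anterior`, `posterior` (the shifted view) and
#'   `offsets = c(rows, cols)` applied to the posterior.
#' @export
align_pair <- function(anterior, flipped_posterior, threshold = 0) {
  cp_a <- find_critical_points(anterior, threshold)
  cp_p <- find_critical_points(flipped_posterior, threshold)
  dr <- cp_a$ceil_row - cp_p$ceil_row
  dc <- cp_a$left_col - cp_p$left_col
  list(
    anterior = anterior,
    posterior = shift_image(flipped_posterior, dr, dc),
    offsets = c(rows = dr, cols = dc)
  )
}

#' Aggregate the two views of a study into a composite image
#'
#' The posterior view is flipped horizontally, aligned to the anterior via
#' the critical points, and added pixel-wise to the anterior view. Addition
#' is performed in double precision (no 16-bit clipping), so co-located
#' lesions are "excited": their excess counts above background sum across
#' views, while background stays background.
#'
#' @param pair A [scan_pair()].
#' @param threshold Body threshold for alignment, default 0.
#' @return A `composite_image`: list with `pixels` (matrix), `study_id`,
#'   `patient_id`, `label`, `offsets`.
#' @export
#' @examples
#' a <- matrix(0L, 32, 8); a[10:12, 3:5] <- 100L
#' p <- flip_horizontal(a)
#' comp <- aggregate_views(scan_pair(a, p, "p1", "s1", "ADMet"))
#' max(comp$pixels)  # 200: the views add
aggregate_views <- function(pair, threshold = 0) {
  stopifnot(inherits(pair, "scan_pair"))
  flipped <- flip_horizontal(pair$posterior)
  aligned <- align_pair(pair$anterior, flipped, threshold)
  comp <- pair$anterior + aligned$posterior
  structure(
    list(
      pixels = comp, study_id = pair$study_id, patient_id = pair$patient_id,
      label = pair$label, offsets = aligned$offsets
    ),
    class = "composite_image"
  )
}

#' @export
print.composite_image <- function(x, ...) {
  cat(sprintf(
    "<composite_image> study %s (%s), %d x %d, max %g, offsets (%d, %d)\n",
    x$study_id, x$label, nrow(x$pixels), ncol(x$pixels), max(x$pixels),
    x$offsets[1], x$offsets[2]
  ))
  invisible(x)
}

#' Aggregate every study in a manifest
#'
#' Maps [aggregate_views()] over a manifest carrying `anterior`/`posterior`
#' image list-columns and stores the fused images in a `composite`
#' list-column.
#'
#' @param manifest Manifest with image list-columns (see
#'   [load_manifest_images()] or [generate_cohort()]).
#' @param threshold Body threshold for alignment.
#' @return The manifest with a `composite` list-column of matrices.
#' @export
aggregate_manifest <- function(manifest, threshold = 0) {
  stopifnot(all(c("anterior", "posterior") %in% names(manifest)))
  manifest$composite <- purrr::pmap(
    list(manifest$anterior, manifest$posterior,
         manifest$study_id, manifest$patient_id, manifest$label),
    function(a, p, sid, pid, lab) {
      aggregate_views(scan_pair(a, p, pid, sid, lab), threshold)$pixels
    }
  )
  manifest
}
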