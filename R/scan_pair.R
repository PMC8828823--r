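#' Construct and validate a scan pair
#'
#' A scan pair holds the two whole-body projections acquired in one bone-scan
#' study: the anterior view and the posterior view. Images are stored as
#' integer-valued matrices with rows = vertical axis (0 at top in pixel terms;
#' row 1 in R), columns = horizontal axis, i.e. shape `height x width`
#' (1024 x 256 for clinical-format scans). Pixel values are radiotracer
#' counts and must lie in the 16-bit unsigned range `[0, 65535]`.
#'
#' @param anterior,posterior Integer-valued matrices of identical shape with
#'   values in `[0, 65535]`.
#' @param patient_id Non-empty string identifying the patient (several studies
#'   may share one patient).
#' @param study_id Non-empty string identifying this study; unique per study.
#' @param label One of `"NoMet"`, `"ADMet"`, `"nADMet"`.
#'
#' @return An object of class `scan_pair`: a list with elements `anterior`,
#'   `posterior`, `patient_id`, `study_id`, `label`.
#' @export
#' @examples
#' a <- matrix(0L, 64, 16)
#' p <- matrix(0L, 64, 16)
#' sp <- scan_pair(a, p, patient_id = "P1", study_id = "S1", label = "NoMet")
#' dim(sp$anterior)
scan_pair <- function(anterior, posterior, patient_id, study_id = patient_id,
                      label = c("NoMet", "ADMet", "nADMet")) {
  label <- match.arg(label)
  if (!is.matrix(anterior) || !is.matrix(posterior)) {
    abort("anterior and posterior must be matrices (height x width)")
  }
  if (!identical(dim(anterior), dim(posterior))) {
    abort(sprintf(
      "View shape mismatch: anterior is %d x %d but posterior is %d x %d",
      nrow(anterior), ncol(anterior), nrow(posterior), ncol(posterior)
    ))
  }
  for (nm in c("anterior", "posterior")) {
    img <- get(nm)
    if (anyNA(img)) abort(sprintf("%s view contains missing values", nm))
    if (any(img < 0)) abort(sprintf("%s view contains negative counts", nm))
    if (any(img > 65535)) {
      abort(sprintf("%s view exceeds the 16-bit range (max %g)", nm, max(img)))
    }
    if (any(img != round(img))) {
      abort(sprintf("%s view contains non-integer counts", nm))
    }
  }
  if (!is.character(patient_id) || length(patient_id) != 1 || !nzchar(patient_id)) {
    abort("patient_id must be a non-empty string")
  }
  structure(
    list(
      anterior = anterior, posterior = posterior,
      patient_id = patient_id, study_id = study_id, label = label
    ),
    class = "scan_pair"
  )
}

#' @export
print.scan_pair <- function(x, ...) {
  cat(sprintf(
    "<scan_pair> study %s, patient %s, label %s, %d x %d, counts [%d, %d]\n",
    x$study_id, x$patient_id, x$label, nrow(x$anterior), ncol(x$anterior),
    min(x$anterior, x$posterior), max(x$anterior, x$posterior)
  ))
  invisible(x)
}

#' Read a single-channel scintigraphic image from disk
#'
#' TIFF is the primary format: `tiff::readTIFF(as.is = TRUE)` returns raw
#' integer sample values, so 16-bit counts round-trip bit-exactly. 16-bit
#' grayscale PNG is also accepted (the png reader rescales to `[0, 1]`; values
#' are mapped back onto the 16-bit grid). 8-bit inputs are accepted and
#' widened to the 16-bit container without rescaling, with a warning.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Integer matrix (height x width).
#' @export
read_scinti_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read image: no file at '%s'", path))
  ext <- tolower(tools::file_ext(path))
  bits <- NA_integer_
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(img, "bits.per.sample") %||% NA_integer_
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("Reading PNG requires the 'png' package")
    }
    raw <- png::readPNG(path)
    # readPNG normalizes to [0,1]; recover the integer grid the file was on
    v8 <- raw * 255
    if (all(abs(v8 - round(v8)) < 1e-9)) {
      img <- round(v8)  # 8-bit file: keep raw 0..255 counts, no rescaling
      bits <- 8L
    } else {
      img <- round(raw * 65535)
      bits <- 16L
    }
  } else {
    abort(sprintf("Unsupported image format '.%s' (use TIFF or PNG)", ext))
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[3] != 1) abort(sprintf("Expected a single-channel image, got %d channels", dim(img)[3]))
    img <- img[, , 1]
  }
  if (max(img) > 65535 || (!is.na(bits) && bits > 16)) {
    abort("Pixel depth exceeds 16 bits")
  }
  if (!is.na(bits) && bits <= 8) {
    warn("8-bit image widened to the 16-bit container without rescaling")
  }
  matrix(as.integer(round(img)), nrow(img), ncol(img))
}

#' Write a single-channel count image as TIFF
#'
#' Counts within the 16-bit range are written as 16-bit samples; wider values
#' (e.g. aggregated composites) are written as 32-bit floating-point samples.
#'
#' @param image Integer-valued matrix.
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_scinti_image <- function(image, path) {
  stopifnot(is.matrix(image))
  if (max(image) <= 65535) {
    tiff::writeTIFF(image / 65535, path, bits.per.sample = 16)
  } else {
    tiff::writeTIFF(image, path, bits.per.sample = 32, reduce = FALSE)
  }
  invisible(path)
}

#' Load a scan pair from image files
#'
#' Reads the anterior and posterior views, validates shape and bit depth, and
#' returns a [scan_pair()]. Pixel data are preserved bit-exactly for TIFF
#' sources; no rescaling is applied.
#'
#' @param anterior_source,posterior_source Image file paths (TIFF or PNG).
#' @inheritParams scan_pair
#' @return A validated [scan_pair()].
#' @export
load_scan_pair <- function(anterior_source, posterior_source, patient_id,
                           label, study_id = patient_id) {
  ant <- read_scinti_image(anterior_source)
  pos <- read_scinti_image(posterior_source)
  scan_pair(ant, pos, patient_id = patient_id, study_id = study_id, label = label)
}

#' Write a scan pair's views to a directory
#'
#' @param pair A [scan_pair()].
#' @param dir Output directory (created if missing).
#' @return Named character vector with the two file paths, invisibly.
#' @export
write_scan_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "scan_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ant <- file.path(dir, paste0(pair$study_id, "_ant.tif"))
  pos <- file.path(dir, paste0(pair$study_id, "_post.tif"))
  write_scinti_image(pair$anterior, ant)
  write_scinti_image(pair$posterior, pos)
  invisible(c(anterior = ant, posterior = pos))
}
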