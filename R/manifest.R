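#' Build a dataset manifest from study records
#'
#' A manifest is the tabular backbone of the pipeline: one row per study with
#' `study_id`, `patient_id` and `label` columns, plus whatever payload columns
#' the stage carries (file paths `anterior_path`/`posterior_path`, in-memory
#' image list-columns `anterior`/`posterior`/`composite`, augmentation
#' provenance `source_study`). Record order is preserved; per-class tallies
#' are available via [class_counts()].
#'
#' @param records A data frame with at least `study_id`, `patient_id`,
#'   `label`; extra columns are kept.
#' @return A tibble of class `scinti_manifest`.
#' @export
#' @examples
#' m <- build_manifest(data.frame(
#'   study_id = c("s1", "s2"), patient_id = c("p1", "p2"),
#'   label = c("ADMet", "NoMet")
#' ))
#' class_counts(m)
build_manifest <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) abort("Manifest records must be non-empty")
  need <- c("study_id", "patient_id", "label")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Manifest is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  records$study_id <- as.character(records$study_id)
  records$patient_id <- as.character(records$patient_id)
  records$label <- as.character(records$label)
  check_labels(records$label)
  if (any(!nzchar(records$patient_id)) || anyNA(records$patient_id)) {
    abort("Every record needs a non-empty patient_id")
  }
  dup <- records$study_id[duplicated(records$study_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate study_id(s): ", paste(unique(dup), collapse = ", ")))
  }
  class(records) <- c("scinti_manifest", class(records))
  records
}

#' Per-class record tallies of a manifest
#'
#' @param manifest A manifest tibble from [build_manifest()].
#' @return Named integer vector over all three classes (zero where absent),
#'   in [scinti_classes()] order.
#' @export
class_counts <- function(manifest) {
  tab <- table(factor(manifest$label, levels = scinti_classes()))
  setNames(as.integer(tab), names(tab))
}

#' Subsample classes to target counts
#'
#' Draws a uniform without-replacement subsample within each targeted class so
#' its record count equals the target; classes without a target entry are kept
#' in full. This reproduces balanced-dataset assembly in which the majority
#' no-metastasis class is randomly thinned to match the metastatic classes.
#'
#' @param manifest A manifest tibble.
#' @param target_counts Named integer vector, e.g. `c(NoMet = 226)`.
#' @param seed Integer seed making the draw reproducible.
#' @return A manifest whose class counts equal the targets; original row
#'   order is preserved among the kept records.
#' @export
#' @examples
#' m <- build_manifest(data.frame(
#'   study_id = paste0("s", 1:10), patient_id = paste0("p", 1:10),
#'   label = rep(c("NoMet", "ADMet"), each = 5)
#' ))
#' class_counts(balance_classes(m, c(NoMet = 3), seed = 1))
balance_classes <- function(manifest, target_counts, seed) {
  check_labels(names(target_counts))
  avail <- class_counts(manifest)
  for (cl in names(target_counts)) {
    if (target_counts[[cl]] > avail[[cl]]) {
      abort(sprintf(
        "Target for class %s (%d) exceeds availability (%d)",
        cl, target_counts[[cl]], avail[[cl]]
      ))
    }
  }
  keep <- rep(TRUE, nrow(manifest))
  rng <- make_rng(seed)
  for (cl in names(target_counts)) {
    idx <- which(manifest$label == cl)
    chosen <- rng_sample(rng, idx, target_counts[[cl]])
    keep[setdiff(idx, chosen)] <- FALSE
  }
  out <- manifest[keep, , drop = FALSE]
  class(out) <- class(manifest)
  out
}

#' Write / read a manifest as delimited text
#'
#' Only scalar columns are written (image list-columns are dropped); the
#' standard columns are `study_id`, `patient_id`, `label`, and path columns
#' when present.
#'
#' @param manifest A manifest tibble.
#' @param path Output CSV path.
#' @return `path` (write) or a manifest tibble (read).
#' @export
write_manifest <- function(manifest, path) {
  scalar <- !vapply(manifest, is.list, logical(1))
  write.csv(as.data.frame(manifest)[, scalar, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  build_manifest(read.csv(path, stringsAsFactors = FALSE))
}

#' Load the images referenced by a manifest into list-columns
#'
#' @param manifest A manifest with `anterior_path`/`posterior_path` columns.
#' @return The manifest with `anterior` and `posterior` matrix list-columns.
#' @export
load_manifest_images <- function(manifest) {
  stopifnot(all(c("anterior_path", "posterior_path") %in% names(manifest)))
  manifest$anterior <- purrr::map(manifest$anterior_path, read_scinti_image)
  manifest$posterior <- purrr::map(manifest$posterior_path, read_scinti_image)
  manifest
}
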