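# Fixtures built in code: tiny deterministic images and small phantom
# cohorts at reduced resolution (rendering at 256 x 64 keeps the geometry of
# the 1024 x 256 clinical format while tests stay fast).

toy_image <- function(H = 32, W = 8, fill = 0L) matrix(as.integer(fill), H, W)

# a body-like blob occupying rows r1:r2, cols c1:c2 on a zero background
toy_body <- function(H = 32, W = 16, r = 8:24, c = 5:12, level = 50L) {
  img <- matrix(0L, H, W)
  img[r, c] <- level
  img
}

toy_scan_pair <- function(H = 32, W = 16, label = "ADMet", level = 50L) {
  a <- toy_body(H, W, level = level)
  scan_pair(a, flip_horizontal(a), patient_id = "p1", study_id = "s1",
            label = label)
}

small_cohort <- function(n_per_class = 3, seed = 7, preset = "easy",
                         shape = c(256, 64), studies_per_patient = 1) {
  generate_cohort(n_per_class, seed = seed, preset = preset,
                  image_shape = shape,
                  studies_per_patient = studies_per_patient)
}

# manifest of bare records (no images) with the given per-class counts
records_manifest <- function(counts, studies_per_patient = 1) {
  rows <- list()
  i <- 0
  for (cl in names(counts)) {
    for (k in seq_len(counts[[cl]])) {
      i <- i + 1
      rows[[i]] <- data.frame(
        study_id = sprintf("s%04d", i),
        patient_id = sprintf("%s_p%03d", cl, ceiling(k / studies_per_patient)),
        label = cl
      )
    }
  }
  build_manifest(do.call(rbind, rows))
}
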