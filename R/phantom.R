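# Synthetic whole-body scintigram phantoms.
#
# The skeleton is procedural (head ellipse, spine column, rib bands, pelvis,
# shoulder/arm and leg strips) drawn as an expected-count template; anterior
# and posterior views share lesion anatomy (the posterior is the mirrored
# projection with its own Poisson noise and a mild per-study intensity
# asymmetry). Lesion shape/region/amplitude distributions are configurable
# per class; the default amplitude law is calibrated so ~44% of lesion
# amplitudes fall in [50, 100] counts, with much hotter bladder and
# injection-point confounders.

phantom_regions <- function(H, W) {
  list(
    chest = list(rows = c(0.16, 0.45), cols = c(0.25, 0.75)),
    pelvis = list(rows = c(0.62, 0.72), cols = c(0.30, 0.70)),
    skull = list(rows = c(0.03, 0.11), cols = c(0.35, 0.65)),
    limbs = list(rows = c(0.72, 0.95), cols = c(0.33, 0.67))
  )
}

# expected-count template of the healthy skeleton, cached per image size
phantom_template_env <- new.env(parent = emptyenv())

skeleton_template <- function(H, W, background_level = 10) {
  key <- paste(H, W, background_level, sep = "x")
  hit <- phantom_template_env[[key]]
  if (!is.null(hit)) return(hit)
  tpl <- matrix(0, H, W)
  rr <- function(a, b) max(1, round(a * H)):min(H, round(b * H))
  cc <- function(a, b) max(1, round(a * W)):min(W, round(b * W))
  put <- function(rows, cols, value) tpl[rows, cols] <<- pmax(tpl[rows, cols], value)
  # soft-tissue silhouette
  put(rr(0.02, 0.12), cc(0.32, 0.68), background_level)   # head
  put(rr(0.12, 0.72), cc(0.18, 0.82), background_level)   # trunk + arms
  put(rr(0.72, 0.97), cc(0.30, 0.70), background_level)   # legs
  # skull rim (elliptical ring)
  r0 <- 0.07 * H; c0 <- 0.5 * W
  rows <- rr(0.02, 0.12); cols <- cc(0.30, 0.70)
  d <- outer(((rows - r0) / (0.05 * H))^2, rep(1, length(cols))) +
       outer(rep(1, length(rows)), ((cols - c0) / (0.17 * W))^2)
  ring <- d >= 0.55 & d <= 1.15
  tpl[rows, cols][ring] <- pmax(tpl[rows, cols][ring], 45)
  # rib bands: alternating horizontal bands across the chest
  chest_r <- rr(0.17, 0.42); chest_c <- cc(0.25, 0.75)
  band <- 1 + 0.45 * sin(2 * pi * (chest_r - chest_r[1]) / (0.035 * H))
  tpl[chest_r, chest_c] <- pmax(tpl[chest_r, chest_c],
                                outer(band, rep(1, length(chest_c))) * 22)
  # spine column with elevated uptake
  put(rr(0.13, 0.62), cc(0.47, 0.53), 60)
  # shoulders and arms
  put(rr(0.155, 0.185), cc(0.18, 0.82), 35)
  put(rr(0.18, 0.48), cc(0.19, 0.24), 28)
  put(rr(0.18, 0.48), cc(0.76, 0.81), 28)
  # pelvis and hips
  put(rr(0.62, 0.72), cc(0.30, 0.70), 48)
  # legs (femur/tibia strips)
  put(rr(0.72, 0.97), cc(0.35, 0.42), 32)
  put(rr(0.72, 0.97), cc(0.58, 0.65), 32)
  phantom_template_env[[key]] <- tpl
  tpl
}

# additive anisotropic gaussian hotspot, truncated at 4 sigma
add_blob <- function(img, r0, c0, amp, sr, sc) {
  H <- nrow(img); W <- ncol(img)
  rows <- max(1, floor(r0 - 4 * sr)):min(H, ceiling(r0 + 4 * sr))
  cols <- max(1, floor(c0 - 4 * sc)):min(W, ceiling(c0 + 4 * sc))
  g <- outer(exp(-(rows - r0)^2 / (2 * sr^2)), exp(-(cols - c0)^2 / (2 * sc^2)))
  img[rows, cols] <- img[rows, cols] + amp * g
  img
}

#' Phantom configuration for one class
#'
#' @param class_label `"NoMet"`, `"ADMet"` or `"nADMet"`. `NoMet` forces the
#'   lesion count to zero.
#' @param image_shape `c(height, width)`, default `c(1024, 256)`.
#' @param background_level Mean soft-tissue count level.
#' @param lesion_count_range Integer interval for the per-study lesion count.
#' @param shape_mix Named probabilities over `mottling`, `patchy`,
#'   `punctate`; must sum to 1.
#' @param region_mix Named probabilities over `chest`, `pelvis`, `skull`,
#'   `limbs`; must sum to 1 (chest-dominant by default).
#' @param intensity List `(meanlog, sdlog, scale)` of the log-normal lesion
#'   amplitude law, in counts. The default `meanlog = log(72), sdlog = 0.6`
#'   puts ~44% of amplitudes in `[50, 100]`.
#' @param confounders Add the high-uptake bladder and injection-point
#'   hotspots?
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(class_label,
                           image_shape = c(1024, 256),
                           background_level = 10,
                           lesion_count_range = c(2, 8),
                           shape_mix = c(mottling = 0.30, patchy = 0.35, punctate = 0.35),
                           region_mix = c(chest = 0.55, pelvis = 0.20, skull = 0.10, limbs = 0.15),
                           intensity = list(meanlog = log(72), sdlog = 0.6, scale = 1),
                           confounders = TRUE) {
  check_labels(class_label)
  if (abs(sum(shape_mix) - 1) > 1e-8 || any(shape_mix < 0)) {
    abort("shape_mix must be non-negative probabilities summing to 1")
  }
  if (abs(sum(region_mix) - 1) > 1e-8 || any(region_mix < 0)) {
    abort("region_mix must be non-negative probabilities summing to 1")
  }
  if (class_label == "NoMet") lesion_count_range <- c(0, 0)
  structure(
    list(class_label = class_label, image_shape = as.integer(image_shape),
         background_level = background_level,
         lesion_count_range = as.integer(lesion_count_range),
         shape_mix = shape_mix, region_mix = region_mix,
         intensity = intensity, confounders = confounders),
    class = "phantom_config"
  )
}

#' Per-class phantom presets
#'
#' `"easy"` gives classes with well-separated lesion statistics (few large
#' hot patchy chest lesions for ADMet; many punctate moderate-intensity
#' pelvis/limb lesions for nADMet) for pipeline sanity checks; `"hard"` gives heavily
#' overlapping shape/region/intensity mixes closer to the clinical
#' difficulty of separating the two metastatic subclasses.
#'
#' @param preset `"easy"` or `"hard"`.
#' @param image_shape Passed through to [phantom_config()].
#' @return Named list of three `phantom_config`s.
#' @export
phantom_presets <- function(preset = c("easy", "hard"),
                            image_shape = c(1024, 256)) {
  preset <- match.arg(preset)
  if (preset == "easy") {
    list(
      NoMet = phantom_config("NoMet", image_shape),
      ADMet = phantom_config(
        "ADMet", image_shape,
        lesion_count_range = c(5, 9),
        shape_mix = c(mottling = 0.1, patchy = 0.8, punctate = 0.1),
        region_mix = c(chest = 0.85, pelvis = 0.05, skull = 0.05, limbs = 0.05),
        intensity = list(meanlog = log(600), sdlog = 0.15, scale = 1)
      ),
      nADMet = phantom_config(
        "nADMet", image_shape,
        lesion_count_range = c(7, 12),
        shape_mix = c(mottling = 0.1, patchy = 0.1, punctate = 0.8),
        region_mix = c(chest = 0.05, pelvis = 0.45, skull = 0.10, limbs = 0.40),
        intensity = list(meanlog = log(350), sdlog = 0.15, scale = 1)
      )
    )
  } else {
    list(
      NoMet = phantom_config("NoMet", image_shape),
      ADMet = phantom_config(
        "ADMet", image_shape,
        lesion_count_range = c(2, 8),
        shape_mix = c(mottling = 0.32, patchy = 0.40, punctate = 0.28),
        intensity = list(meanlog = log(75), sdlog = 0.6, scale = 1)
      ),
      nADMet = phantom_config(
        "nADMet", image_shape,
        lesion_count_range = c(1, 7),
        shape_mix = c(mottling = 0.36, patchy = 0.30, punctate = 0.34),
        intensity = list(meanlog = log(68), sdlog = 0.6, scale = 1)
      )
    )
  }
}

sample_mix <- function(rng, mix) {
  names(mix)[which(cumsum(mix) >= rng_runif(rng, 1))[1]]
}

#' Generate one synthetic anterior/posterior phantom pair
#'
#' Renders the skeleton template, draws the class's lesions (shape, body
#' region and amplitude from the configured mixes), adds bladder and
#' injection-point confounders, and emits the two views: the anterior with
#' Poisson count noise, and the posterior as the horizontally mirrored
#' projection with a mild per-study intensity asymmetry and independent
#' Poisson noise. Pixel values are clipped to the 16-bit range.
#'
#' @param config A [phantom_config()].
#' @param rng Internal RNG stream; create one per study from a seed.
#' @param patient_id,study_id Identifiers for the emitted [scan_pair()].
#' @return List with `pair` (a [scan_pair()]) and `truth` (tibble of lesion
#'   centres, shapes, regions and amplitudes; zero rows for `NoMet`).
#' @export
#' @examples
#' res <- generate_phantom_pair(
#'   phantom_config("ADMet", image_shape = c(256, 64)), make_rng(7)
#' )
#' nrow(res$truth) >= 1
generate_phantom_pair <- function(config, rng = make_rng(1),
                                  patient_id = "phantom", study_id = patient_id) {
  H <- config$image_shape[1]; W <- config$image_shape[2]
  tpl <- skeleton_template(H, W, config$background_level)
  clean <- tpl
  regions <- phantom_regions(H, W)
  n_lesions <- if (config$lesion_count_range[2] == 0) 0L else
    rng_rint(rng, 1, config$lesion_count_range[2] - config$lesion_count_range[1] + 1L) +
      config$lesion_count_range[1] - 1L
  truth <- list()
  for (k in seq_len(n_lesions)) {
    shape <- sample_mix(rng, config$shape_mix)
    region <- sample_mix(rng, config$region_mix)
    box <- regions[[region]]
    r0 <- rng_runif(rng, 1, box$rows[1], box$rows[2]) * H
    c0 <- rng_runif(rng, 1, box$cols[1], box$cols[2]) * W
    amp <- config$intensity$scale *
      rng_rlnorm(rng, 1, config$intensity$meanlog, config$intensity$sdlog)
    scale_px <- H / 1024
    if (shape == "punctate") {
      clean <- add_blob(clean, r0, c0, amp, 2.2 * scale_px + 0.8, 2.2 * scale_px + 0.8)
    } else if (shape == "patchy") {
      sr <- (5 + rng_runif(rng, 1, 0, 4)) * scale_px + 1
      sc <- (5 + rng_runif(rng, 1, 0, 4)) * scale_px + 1
      clean <- add_blob(clean, r0, c0, amp, sr, sc)
    } else { # mottling: a cluster of small blobs
      n_sub <- 3 + rng_rint(rng, 1, 3L)
      for (s in seq_len(n_sub)) {
        dr <- rng_rnorm(rng, 1, 0, 6 * scale_px + 1)
        dc <- rng_rnorm(rng, 1, 0, 6 * scale_px + 1)
        clean <- add_blob(clean, r0 + dr, c0 + dc, amp * 0.7,
                          2 * scale_px + 0.8, 2 * scale_px + 0.8)
      }
    }
    truth[[k]] <- tibble::tibble(
      study_id = study_id, lesion = k, row = r0, col = c0,
      shape = shape, region = region, amplitude = amp
    )
  }
  if (config$confounders) {
    clean <- add_blob(clean, 0.705 * H, 0.5 * W,
                      rng_rlnorm(rng, 1, log(400), 0.4),
                      0.015 * H, 0.035 * W)                      # bladder
    clean <- add_blob(clean, 0.46 * H, 0.215 * W,
                      rng_rlnorm(rng, 1, log(500), 0.5),
                      0.006 * H, 0.012 * W)                      # injection point
  }
  asym <- rng_runif(rng, 1, 0.9, 1.1)
  ant <- matrix(rng_rpois(rng, H * W, pmax(clean, 0)), H, W)
  post_mean <- flip_horizontal(clean) * asym
  post <- matrix(rng_rpois(rng, H * W, pmax(post_mean, 0)), H, W)
  ant[ant > 65535] <- 65535L
  post[post > 65535] <- 65535L
  storage.mode(ant) <- "integer"; storage.mode(post) <- "integer"
  pair <- scan_pair(ant, post, patient_id = patient_id, study_id = study_id,
                    label = config$class_label)
  list(pair = pair, truth = dplyr::bind_rows(truth))
}

#' Generate a labelled phantom cohort
#'
#' Produces a class-balanced manifest with in-memory image list-columns
#' (`anterior`, `posterior`) plus the lesion ground truth for every study.
#' Patients receive `studies_per_patient` studies each, so patient-grouped
#' splitting has real grouping structure to respect.
#'
#' @param n_per_class Studies per class.
#' @param configs Named list of three `phantom_config`s (one per class);
#'   defaults to [phantom_presets()] of the chosen `preset`.
#' @param seed Integer seed; each study gets its own derived stream.
#' @param preset Used when `configs` is `NULL`.
#' @param studies_per_patient Studies sharing each synthetic patient id.
#' @param image_shape Image size, default `c(1024, 256)`.
#' @param dir Optional directory: when given, views are written as 16-bit
#'   TIFFs and path columns are added.
#' @return List with `manifest` (a manifest tibble) and `truth` (tibble).
#' @export
generate_cohort <- function(n_per_class, configs = NULL, seed = 1,
                            preset = c("easy", "hard"),
                            studies_per_patient = 1,
                            image_shape = c(1024, 256), dir = NULL) {
  stopifnot(n_per_class >= 1)
  preset <- match.arg(preset)
  configs <- configs %||% phantom_presets(preset, image_shape)
  stopifnot(setequal(names(configs), scinti_classes()))
  root <- make_rng(seed)
  rows <- list(); truths <- list()
  for (cl in scinti_classes()) {
    for (i in seq_len(n_per_class)) {
      pid <- sprintf("%s_pat%03d", cl, ceiling(i / studies_per_patient))
      sid <- sprintf("%s_%03d", cl, i)
      res <- generate_phantom_pair(configs[[cl]], rng_spawn(root),
                                   patient_id = pid, study_id = sid)
      row <- tibble::tibble(
        study_id = sid, patient_id = pid, label = cl,
        anterior = list(res$pair$anterior), posterior = list(res$pair$posterior)
      )
      if (!is.null(dir)) {
        paths <- write_scan_pair(res$pair, dir)
        row$anterior_path <- paths[["anterior"]]
        row$posterior_path <- paths[["posterior"]]
      }
      rows[[length(rows) + 1]] <- row
      truths[[length(truths) + 1]] <- res$truth
    }
  }
  manifest <- build_manifest(dplyr::bind_rows(rows))
  if (!is.null(dir)) {
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    truth_all <- dplyr::bind_rows(truths)
    write.csv(as.data.frame(truth_all), file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(manifest = manifest, truth = dplyr::bind_rows(truths))
}
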