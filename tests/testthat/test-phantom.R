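test_that("phantom pairs satisfy the scan-pair contract", {
  cfgs <- phantom_presets("hard", image_shape = c(256, 64))
  for (cl in scinti_classes()) {
    res <- generate_phantom_pair(cfgs[[cl]], scintimet:::make_rng(5),
                                 patient_id = "p", study_id = cl)
    expect_s3_class(res$pair, "scan_pair")
    expect_equal(dim(res$pair$anterior), c(256, 64))
    expect_true(all(res$pair$anterior >= 0 & res$pair$anterior <= 65535))
    expect_true(all(res$pair$posterior >= 0 & res$pair$posterior <= 65535))
    expect_equal(res$pair$label, cl)
  }
})

test_that("NoMet phantoms have no lesions; metastatic phantoms do", {
  cfgs <- phantom_presets("hard", image_shape = c(256, 64))
  no <- generate_phantom_pair(cfgs$NoMet, scintimet:::make_rng(2))
  expect_equal(nrow(no$truth), 0)
  ad <- generate_phantom_pair(cfgs$ADMet, scintimet:::make_rng(2))
  expect_gte(nrow(ad$truth), cfgs$ADMet$lesion_count_range[1])
  expect_lte(nrow(ad$truth), cfgs$ADMet$lesion_count_range[2])
})

test_that("the same seed reproduces a phantom bit-exactly", {
  cfg <- phantom_config("ADMet", image_shape = c(128, 32))
  a <- generate_phantom_pair(cfg, scintimet:::make_rng(77))
  b <- generate_phantom_pair(cfg, scintimet:::make_rng(77))
  expect_identical(a$pair$anterior, b$pair$anterior)
  expect_identical(a$pair$posterior, b$pair$posterior)
  expect_identical(a$truth, b$truth)
  c <- generate_phantom_pair(cfg, scintimet:::make_rng(78))
  expect_false(identical(a$pair$anterior, c$pair$anterior))
})

test_that("lesions appear in both views at mirrored positions", {
  cfg <- phantom_config("ADMet", image_shape = c(256, 64),
                        lesion_count_range = c(3, 3),
                        shape_mix = c(mottling = 0, patchy = 1, punctate = 0),
                        intensity = list(meanlog = log(500), sdlog = 0.1, scale = 1),
                        confounders = FALSE)
  res <- generate_phantom_pair(cfg, scintimet:::make_rng(9))
  tpl <- scintimet:::skeleton_template(256, 64, cfg$background_level)
  flipped <- flip_horizontal(res$pair$posterior)
  for (i in seq_len(nrow(res$truth))) {
    r0 <- round(res$truth$row[i]); c0 <- round(res$truth$col[i])
    win <- function(img) mean(img[max(1, r0 - 2):min(256, r0 + 2),
                                  max(1, c0 - 2):min(64, c0 + 2)])
    bg <- win(tpl)
    expect_gt(win(res$pair$anterior), bg + 100)   # present in anterior
    expect_gt(win(flipped), bg + 80)              # mirrored into posterior
  }
})

test_that("about 44% of default lesion amplitudes fall in [50, 100]", {
  # the amplitude law is the lognormal of the default (hard) config;
  # pool lesions from many small studies
  cfg <- phantom_config("ADMet", image_shape = c(64, 16),
                        lesion_count_range = c(8, 8), confounders = FALSE)
  rng <- scintimet:::make_rng(123)
  amps <- c()
  while (length(amps) < 1000) {
    amps <- c(amps, generate_phantom_pair(cfg, rng)$truth$amplitude)
  }
  frac <- mean(amps >= 50 & amps <= 100)
  expect_gt(frac, 0.39)
  expect_lt(frac, 0.49)
})

test_that("lesion placement is chest-dominant per the default region mix", {
  cfg <- phantom_config("nADMet", image_shape = c(64, 16),
                        lesion_count_range = c(8, 8), confounders = FALSE)
  rng <- scintimet:::make_rng(31)
  regions <- c()
  for (i in 1:40) {
    regions <- c(regions, generate_phantom_pair(cfg, rng)$truth$region)
  }
  frac <- table(factor(regions, levels = names(cfg$region_mix))) / length(regions)
  expect_gt(frac[["chest"]], 0.45)   # 0.55 nominal, binomial slack
  for (rg in names(cfg$region_mix)) {
    expect_lt(abs(frac[[rg]] - cfg$region_mix[[rg]]), 0.1)
  }
})

test_that("generate_cohort balances classes and groups studies by patient", {
  coh <- generate_cohort(4, seed = 15, preset = "easy",
                         image_shape = c(128, 32), studies_per_patient = 2)
  expect_equal(class_counts(coh$manifest),
               c(NoMet = 4L, ADMet = 4L, nADMet = 4L))
  expect_equal(length(unique(coh$manifest$patient_id)), 6)  # 2 per patient
  expect_true(all(table(coh$manifest$patient_id) == 2))
  # truths reference only manifest studies, never NoMet ones
  expect_true(all(coh$truth$study_id %in% coh$manifest$study_id))
  lab <- coh$manifest$label[match(coh$truth$study_id, coh$manifest$study_id)]
  expect_false(any(lab == "NoMet"))
})

test_that("cohorts can be written to disk and reloaded losslessly", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(1, seed = 8, preset = "easy",
                         image_shape = c(128, 32), dir = dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 3)
  loaded <- load_manifest_images(man)
  i <- match(coh$manifest$study_id[1], loaded$study_id)
  expect_identical(loaded$anterior[[i]], coh$manifest$anterior[[1]])
})

test_that("phantom_config rejects invalid mixes and forces NoMet lesion-free", {
  expect_error(phantom_config("ADMet", shape_mix = c(mottling = 0.5, patchy = 0.2,
                                                     punctate = 0.2)),
               "summing to 1")
  cfg <- phantom_config("NoMet", lesion_count_range = c(2, 5))
  expect_equal(cfg$lesion_count_range, c(0L, 0L))
})
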