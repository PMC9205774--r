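test_that("config validation rejects out-of-range parameters", {
  expect_error(synthetic_config(patients_per_cohort = c(10.5, 20)),
               "positive integers")
  expect_error(synthetic_config(prevalence = 1), "strictly between")
  expect_error(synthetic_config(witness_rate = 0), "witness_rate")
  expect_error(synthetic_config(tiles_per_patient = 0), "tiles_per_patient")
  expect_error(synthetic_config(mode = "images", image_size = 7),
               ">= 8 pixels")
})

test_that("feature generation is a pure function of the config", {
  cfg <- synthetic_config(patients_per_cohort = c(8, 12),
                          tiles_per_patient = 5, feature_dim = 16, seed = 7)
  a <- generate_feature_cohorts(cfg)
  b <- generate_feature_cohorts(cfg)
  expect_identical(a$tiles$features, b$tiles$features)
  expect_identical(a$manifest, b$manifest)
})

test_that("cohort sizes, prevalence and witness structure match the config", {
  cfg <- synthetic_config(patients_per_cohort = c(20, 40),
                          prevalence = c(0.25, 0.5), tiles_per_patient = 8,
                          witness_rate = 0.5, feature_dim = 16, seed = 3)
  ch <- generate_feature_cohorts(cfg)
  counts <- dplyr::count(ch$manifest, cohort_id, label)
  expect_equal(counts$n[counts$cohort_id == "cohort1" & counts$label == 1], 5)
  expect_equal(counts$n[counts$cohort_id == "cohort2" & counts$label == 1], 20)
  per_pat <- dplyr::count(ch$tiles, patient_id)
  expect_true(all(per_pat$n == 8))
  sig <- dplyr::count(dplyr::filter(ch$tiles, label == 1),
                      patient_id, wt = is_signal)
  expect_true(all(sig$n == 4))  # round(0.5 * 8) signal tiles per positive
  expect_true(all(!ch$tiles$is_signal[ch$tiles$label == 0]))
})

test_that("signal tiles are shifted by effect_size along the signal direction", {
  cfg <- synthetic_config(patients_per_cohort = c(60, 60),
                          tiles_per_patient = 16, feature_dim = 32,
                          effect_size = 2, site_shift = 3, seed = 5)
  ch <- generate_feature_cohorts(cfg)
  proj <- as.vector(ch$tiles$features %*% ch$signal_direction)
  gap <- mean(proj[ch$tiles$is_signal]) - mean(proj[!ch$tiles$is_signal])
  se <- sqrt(1 / sum(ch$tiles$is_signal) + 1 / sum(!ch$tiles$is_signal))
  expect_lt(abs(gap - 2), 3 * se)
  # site offsets are orthogonal to the signal direction
  for (off in ch$site_offsets) {
    expect_lt(abs(sum(off * ch$signal_direction)), 1e-10)
  }
})

test_that("a patient bag depends only on its cohort/position, not on cohort company", {
  base <- list(patients_per_cohort = c(6, 9), tiles_per_patient = 4,
               feature_dim = 12, seed = 21)
  a <- generate_feature_cohorts(do.call(synthetic_config, base))
  base2 <- base
  base2$patients_per_cohort <- c(6, 5)  # shrink second cohort
  b <- generate_feature_cohorts(do.call(synthetic_config, base2))
  fa <- a$tiles$features[a$tiles$cohort_id == "cohort1", ]
  fb <- b$tiles$features[b$tiles$cohort_id == "cohort1", ]
  expect_identical(fa, fb)
})

test_that("zero effect size carries no class signal to any classifier", {
  cfg <- synthetic_config(patients_per_cohort = c(40, 40),
                          tiles_per_patient = 6, feature_dim = 16,
                          effect_size = 0, seed = 9)
  ch <- generate_feature_cohorts(cfg)
  # oracle check: class-conditional means coincide up to noise
  mu1 <- colMeans(ch$tiles$features[ch$tiles$label == 1, ])
  mu0 <- colMeans(ch$tiles$features[ch$tiles$label == 0, ])
  expect_lt(max(abs(mu1 - mu0)), 6 / sqrt(min(table(ch$tiles$label))))
})

test_that("make_partition returns disjoint deterministic index sets", {
  p <- make_partition(5, c(2, 3), seed = 1)
  expect_length(unlist(p), 5)
  expect_equal(sort(unname(unlist(p))), 1:5)
  expect_identical(p, make_partition(5, c(2, 3), seed = 1))
  expect_false(identical(p, make_partition(5, c(2, 3), seed = 2)))
  expect_error(make_partition(5, c(3, 3), seed = 1), "exceeds")
})

test_that("image mode renders deterministic mosaics with exact blank counts", {
  cfg <- synthetic_config(patients_per_cohort = c(2, 2),
                          tiles_per_patient = 25, prevalence = 0.5,
                          mode = "images", image_size = 16,
                          blank_fraction = 0.2, seed = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ic1 <- generate_tile_images(cfg, dir = d1)
  ic2 <- generate_tile_images(cfg, dir = d2)
  blanks <- dplyr::count(dplyr::filter(ic1$manifest, role == "blank"),
                         slide_id)
  expect_true(all(blanks$n == 5))  # round(0.2 * 25) per slide
  f1 <- ic1$manifest$slide_path[1]
  f2 <- file.path(d2, basename(f1))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("the QC filter at threshold 4 removes exactly the blank tiles", {
  cfg <- synthetic_config(patients_per_cohort = c(1, 2),
                          tiles_per_patient = 16, prevalence = 0.5,
                          mode = "images", image_size = 32,
                          blank_fraction = 0.25, seed = 8)
  ic <- generate_tile_images(cfg, dir = withr::local_tempdir())
  man <- ic$manifest
  removed_roles <- character()
  for (sp in unique(man$slide_path)) {
    slide <- png::readPNG(sp)
    tl <- compute_qc_scores(tessellate(slide, 32))
    kept <- qc_filter(tl, threshold = 4)
    sm <- man[man$slide_path == sp, ]
    dropped <- dplyr::anti_join(tl, kept, by = c("x", "y"))
    removed_roles <- c(removed_roles,
                       sm$role[match(paste(dropped$x, dropped$y),
                                     paste(sm$x, sm$y))])
    kept_roles <- sm$role[match(paste(kept$x, kept$y),
                                paste(sm$x, sm$y))]
    expect_false(any(kept_roles == "blank"))
  }
  expect_true(all(removed_roles == "blank"))
  expect_gt(length(removed_roles), 0)
})
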