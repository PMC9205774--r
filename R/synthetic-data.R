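#' Configure a synthetic multi-cohort dataset
#'
#' Builds the configuration object consumed by [generate_feature_cohorts()]
#' and [generate_tile_images()]. The generator emulates the multi-site
#' setting of decentralized histopathology studies: several cohorts of
#' unequal size hold patients with a binary molecular label (e.g. mutant vs
#' wild type), each patient is a weakly labeled bag of tiles in which only a
#' fraction of tiles carries class signal, and each cohort is subject to its
#' own systematic distribution shift (site effect).
#'
#' @param patients_per_cohort Integer vector; number of patients in each
#'   cohort. The default 100/300/150 mirrors a smallest/largest/middle
#'   three-site inequality so that basic-swarm checkpoint ordering is
#'   exercised.
#' @param prevalence Fraction of positive (label 1) patients per cohort, in
#'   (0, 1). Scalar or one value per cohort.
#' @param tiles_per_patient Number of tiles in each patient bag.
#' @param witness_rate Fraction of tiles in a positive patient's bag that
#'   carry class signal, in (0, 1].
#' @param effect_size Standardized mean shift of signal tiles along the
#'   (hidden) signal direction, in units of the per-feature noise s.d.
#' @param site_shift Magnitude of the cohort-specific additive offset,
#'   applied orthogonally to the signal direction.
#' @param feature_dim Feature dimensionality in `"features"` mode.
#' @param mode `"features"` (per-tile feature vectors) or `"images"`
#'   (rendered RGB tiles assembled into slide mosaics).
#' @param image_size Tile edge length in pixels (`"images"` mode).
#' @param blank_fraction Fraction of constant-color (blank) tiles per slide
#'   (`"images"` mode) so the tile QC filter has work to do.
#' @param seed Integer seed; generation is a pure function of the config.
#'
#' @return An object of class `sl_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(patients_per_cohort = c(10, 20), seed = 7)
#' cfg$prevalence
#' @export
synthetic_config <- function(patients_per_cohort = c(100, 300, 150),
                             prevalence = 0.3,
                             tiles_per_patient = 32,
                             witness_rate = 0.5,
                             effect_size = 2.0,
                             site_shift = 1.5,
                             feature_dim = 512,
                             mode = c("features", "images"),
                             image_size = 64,
                             blank_fraction = 0.1,
                             seed = 1) {
  mode <- match.arg(mode)
  n_cohorts <- length(patients_per_cohort)
  assert_that(n_cohorts >= 1, "at least one cohort is required")
  assert_that(all(vapply(patients_per_cohort, is_count, logical(1))) &&
                all(patients_per_cohort >= 1),
              "patients_per_cohort must be positive integers")
  if (length(prevalence) == 1) prevalence <- rep(prevalence, n_cohorts)
  assert_that(length(prevalence) == n_cohorts,
              "prevalence must be scalar or one value per cohort")
  assert_that(all(prevalence > 0 & prevalence < 1),
              "prevalence must be strictly between 0 and 1")
  assert_that(is_count(tiles_per_patient) && tiles_per_patient >= 1,
              "tiles_per_patient must be an integer >= 1")
  assert_that(witness_rate > 0 && witness_rate <= 1,
              "witness_rate must be in (0, 1]")
  assert_that(effect_size >= 0, "effect_size must be non-negative")
  assert_that(site_shift >= 0, "site_shift must be non-negative")
  assert_that(is_count(feature_dim) && feature_dim >= 2,
              "feature_dim must be an integer >= 2")
  if (mode == "images") {
    assert_that(is_count(image_size) && image_size >= 8,
                "image_size must be an integer >= 8 pixels")
    assert_that(blank_fraction >= 0 && blank_fraction < 1,
                "blank_fraction must be in [0, 1)")
  }
  assert_that(is_count(seed), "seed must be an integer")
  structure(
    list(
      n_cohorts = n_cohorts,
      patients_per_cohort = as.integer(patients_per_cohort),
      prevalence = prevalence,
      tiles_per_patient = as.integer(tiles_per_patient),
      witness_rate = witness_rate,
      effect_size = effect_size,
      site_shift = site_shift,
      feature_dim = as.integer(feature_dim),
      mode = mode,
      image_size = as.integer(image_size),
      blank_fraction = blank_fraction,
      seed = as.integer(seed)
    ),
    class = "sl_config"
  )
}

#' @export
print.sl_config <- function(x, ...) {
  cat("<sl_config> mode:", x$mode,
      "| cohorts:", paste(x$patients_per_cohort, collapse = "/"),
      "| prevalence:", paste(signif(x$prevalence, 3), collapse = "/"),
      "\n  tiles/patient:", x$tiles_per_patient,
      "| witness:", x$witness_rate,
      "| effect:", x$effect_size,
      "| site shift:", x$site_shift,
      "| seed:", x$seed, "\n")
  invisible(x)
}

# Number of positive patients in a cohort: nearest integer, at least one of
# each class so both labels are always present.
cohort_label_counts <- function(n, prevalence) {
  npos <- round(n * prevalence)
  npos <- min(max(npos, 1L), n - 1L)
  c(pos = as.integer(npos), neg = as.integer(n - npos))
}

# Cohort-specific unit offset directions, orthogonal to the signal direction
# (Gram-Schmidt), so the site effect shifts cohorts without moving class
# means apart.
site_offset_directions <- function(n_cohorts, signal_dir, seed) {
  d <- length(signal_dir)
  with_seed(derive_seed(seed, 7L), {
    lapply(seq_len(n_cohorts), function(i) {
      v <- rnorm(d)
      v <- v - sum(v * signal_dir) * signal_dir
      v / sqrt(sum(v^2))
    })
  })
}

#' Generate multi-cohort tile feature data with known ground truth
#'
#' Draws per-tile feature vectors for every patient in every cohort of the
#' configuration. Background tiles are isotropic Gaussian; signal tiles (a
#' `witness_rate` fraction of each positive patient's bag) are mean-shifted
#' by `effect_size` along a fixed hidden unit direction; every tile in a
#' cohort receives that cohort's site offset, drawn orthogonal to the signal
#' direction. Labels are recorded at the patient level only.
#'
#' Each patient bag is generated under its own derived seed, so the content
#' of a bag depends only on the configuration and the patient's position,
#' and the same config always yields identical output.
#'
#' @param config An [synthetic_config()] object with `mode = "features"`.
#'
#' @return An object of class `sl_cohorts`: a list with
#'   * `manifest` — tibble with one row per patient
#'     (`patient_id`, `cohort_id`, `label`),
#'   * `tiles` — tibble with one row per tile (`patient_id`, `cohort_id`,
#'     `label`, `tile_id`, `is_signal`, and a matrix column `features` of
#'     `feature_dim` columns),
#'   * `config`, and the hidden `signal_direction` / `site_offsets` used
#'     (ground truth, for diagnostics only).
#' @examples
#' cfg <- synthetic_config(patients_per_cohort = c(6, 8), tiles_per_patient = 4,
#'                         feature_dim = 16, seed = 1)
#' ch <- generate_feature_cohorts(cfg)
#' dplyr::count(ch$manifest, cohort_id, label)
#' @export
generate_feature_cohorts <- function(config) {
  assert_that(inherits(config, "sl_config"), "config must be an sl_config")
  assert_that(config$mode == "features",
              "config must have mode = 'features'")
  d <- config$feature_dim
  signal_dir <- with_seed(derive_seed(config$seed, 3L), {
    v <- rnorm(d)
    v / sqrt(sum(v^2))
  })
  offsets <- site_offset_directions(config$n_cohorts, signal_dir, config$seed)

  cohort_tbls <- lapply(seq_len(config$n_cohorts), function(ci) {
    n <- config$patients_per_cohort[ci]
    counts <- cohort_label_counts(n, config$prevalence[ci])
    labels <- with_seed(derive_seed(config$seed, 11L, ci), {
      sample(c(rep(1L, counts["pos"]), rep(0L, counts["neg"])))
    })
    offset <- offsets[[ci]] * config$site_shift
    t_per <- config$tiles_per_patient
    n_sig_pos <- as.integer(round(config$witness_rate * t_per))
    n_sig_pos <- max(n_sig_pos, 1L)

    bags <- lapply(seq_len(n), function(pi) {
      with_seed(derive_seed(config$seed, 13L, ci, pi), {
        x <- matrix(rnorm(t_per * d), nrow = t_per, ncol = d)
        is_signal <- rep(FALSE, t_per)
        if (labels[pi] == 1L) {
          sig_idx <- sample.int(t_per, n_sig_pos)
          x[sig_idx, ] <- x[sig_idx, , drop = FALSE] +
            rep(config$effect_size * signal_dir, each = length(sig_idx))
          is_signal[sig_idx] <- TRUE
        }
        x <- x + rep(offset, each = t_per)
        list(x = x, is_signal = is_signal)
      })
    })
    tibble(
      patient_id = rep(sprintf("C%d_P%03d", ci, seq_len(n)),
                       each = t_per),
      cohort_id = sprintf("cohort%d", ci),
      label = rep(labels, each = t_per),
      tile_id = rep(seq_len(t_per), times = n),
      is_signal = unlist(lapply(bags, `[[`, "is_signal")),
      features = do.call(rbind, lapply(bags, `[[`, "x"))
    )
  })
  tiles <- bind_rows(cohort_tbls)
  manifest <- tiles %>%
    dplyr::distinct(.data$patient_id, .data$cohort_id, .data$label)
  structure(
    list(manifest = manifest, tiles = tiles, config = config,
         signal_direction = signal_dir,
         site_offsets = offsets),
    class = "sl_cohorts"
  )
}

#' @export
print.sl_cohorts <- function(x, ...) {
  cat("<sl_cohorts>", nrow(x$manifest), "patients in",
      x$config$n_cohorts, "cohorts;",
      nrow(x$tiles), "tiles of dim", x$config$feature_dim, "\n")
  print(count(x$manifest, .data$cohort_id, .data$label))
  invisible(x)
}

# ---- image mode ------------------------------------------------------------

stripe_tile <- function(size) {
  theta <- runif(1, 0, pi)
  period <- runif(1, 8, 14) * size / 64
  phase <- runif(1, 0, 2 * pi)
  xy <- expand.grid(x = seq_len(size), y = seq_len(size))
  g <- 0.55 + 0.3 * sin(2 * pi * (cos(theta) * xy$x + sin(theta) * xy$y) /
                          period + phase)
  g <- g + rnorm(size * size, sd = 0.02)
  matrix(pmin(pmax(g, 0), 1), size, size)
}

blob_tile <- function(size) {
  k <- max(6L, round(size / 6))
  cx <- runif(k, 1, size)
  cy <- runif(k, 1, size)
  sig <- runif(k, size / 24, size / 12)
  xs <- seq_len(size)
  field <- matrix(0, size, size)
  for (j in seq_len(k)) {
    dx2 <- outer((xs - cx[j])^2, (xs - cy[j])^2, "+")
    field <- field + exp(-dx2 / (2 * sig[j]^2))
  }
  field <- field / max(field)
  # steep nucleus-like rims give the blob family strong edge content
  g <- 0.9 - 0.75 * pmin(field * 1.6, 1) + rnorm(size * size, sd = 0.02)
  matrix(pmin(pmax(g, 0), 1), size, size)
}

# Map a gray texture to an H&E-like tint by composing hematoxylin and
# eosin optical densities (dark texture = nuclear/hematoxylin-rich), so the
# tiles are true two-stain mixtures and stain-vector estimation is
# well-posed. RGB in [0,1], H x W x 3.
tint_hne <- function(g) {
  s <- default_stain_reference()$stain_matrix
  # independent eosin variation keeps the two concentrations from being
  # perfectly correlated (a rank-1 mixture would make stain-vector
  # estimation ill-posed)
  c_h <- 1.6 * as.vector(1 - g)
  c_e <- pmax(0.35 + 0.3 * as.vector(g) + rnorm(length(g), sd = 0.08), 0.05)
  od <- s %*% rbind(c_h, c_e)
  rgb <- t((256 * 10^(-od) - 1) / 255)
  rgb <- pmin(pmax(rgb, 0), 1)
  array(rgb, dim = c(nrow(g), ncol(g), 3))
}

blank_tile <- function(size) {
  # constant pastel color; constant after 8-bit quantization too
  col <- round(runif(3, 0.75, 0.95) * 255) / 255
  arr <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) arr[, , ch] <- col[ch]
  arr
}

#' Generate synthetic slide mosaics of textured tiles
#'
#' Renders each patient as one slide: a mosaic of RGB tiles on a
#' non-overlapping grid. Signal tiles are blob-textured, background tiles
#' stripe-textured, and a configurable fraction of tiles per slide is blank
#' (constant color) so that the edge-based QC filter has something to
#' remove. The weak-label bag structure matches [generate_feature_cohorts()]:
#' a `witness_rate` fraction of the non-blank tiles in positive patients is
#' signal-textured.
#'
#' @param config An [synthetic_config()] object with `mode = "images"`.
#' @param dir Directory for the slide PNG files (created if needed).
#'
#' @return An object of class `sl_image_cohorts`: a list with `manifest`
#'   (one row per tile: `patient_id`, `cohort_id`, `label`, `slide_id`,
#'   `x`, `y`, `role` in signal/background/blank, `slide_path`), and
#'   `config`.
#' @export
generate_tile_images <- function(config, dir = tempfile("slides")) {
  assert_that(inherits(config, "sl_config"), "config must be an sl_config")
  assert_that(config$mode == "images", "config must have mode = 'images'")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  size <- config$image_size
  t_per <- config$tiles_per_patient
  grid_cols <- ceiling(sqrt(t_per))
  grid_rows <- ceiling(t_per / grid_cols)

  rows <- list()
  for (ci in seq_len(config$n_cohorts)) {
    n <- config$patients_per_cohort[ci]
    counts <- cohort_label_counts(n, config$prevalence[ci])
    labels <- with_seed(derive_seed(config$seed, 11L, ci), {
      sample(c(rep(1L, counts["pos"]), rep(0L, counts["neg"])))
    })
    for (pi in seq_len(n)) {
      slide_id <- sprintf("C%d_S%03d", ci, pi)
      patient_id <- sprintf("C%d_P%03d", ci, pi)
      res <- with_seed(derive_seed(config$seed, 17L, ci, pi), {
        n_blank <- as.integer(round(config$blank_fraction * t_per))
        roles <- rep("background", t_per)
        blank_idx <- if (n_blank > 0) sample.int(t_per, n_blank) else integer(0)
        roles[blank_idx] <- "blank"
        non_blank <- setdiff(seq_len(t_per), blank_idx)
        if (labels[pi] == 1L) {
          n_sig <- max(1L, as.integer(round(config$witness_rate *
                                              length(non_blank))))
          roles[sample(non_blank, n_sig)] <- "signal"
        }
        mosaic <- array(1, dim = c(grid_rows * size, grid_cols * size, 3))
        xs <- ys <- integer(t_per)
        for (ti in seq_len(t_per)) {
          gr <- (ti - 1) %/% grid_cols  # 0-based grid row
          gc <- (ti - 1) %% grid_cols
          tile <- switch(roles[ti],
                         blank = blank_tile(size),
                         signal = tint_hne(blob_tile(size)),
                         background = tint_hne(stripe_tile(size)))
          mosaic[gr * size + seq_len(size), gc * size + seq_len(size), ] <- tile
          xs[ti] <- gc * size
          ys[ti] <- gr * size
        }
        list(mosaic = mosaic, roles = roles, xs = xs, ys = ys)
      })
      path <- file.path(dir, paste0(slide_id, ".png"))
      png::writePNG(res$mosaic, path)
      rows[[length(rows) + 1L]] <- tibble(
        patient_id = patient_id,
        cohort_id = sprintf("cohort%d", ci),
        label = labels[pi],
        slide_id = slide_id,
        x = res$xs, y = res$ys,
        role = res$roles,
        slide_path = path
      )
    }
  }
  structure(
    list(manifest = bind_rows(rows), config = config, dir = dir),
    class = "sl_image_cohorts"
  )
}

#' Partition patients into disjoint cohort index sets
#'
#' @param total_patients Total number of patients available.
#' @param sizes Integer vector of requested cohort sizes;
#'   `sum(sizes) <= total_patients`.
#' @param seed Integer seed; the partition is deterministic given the seed.
#'
#' @return A list of disjoint integer index vectors, one per requested size.
#' @examples
#' make_partition(5, c(2, 3), seed = 1)
#' @export
make_partition <- function(total_patients, sizes, seed) {
  assert_that(is_count(total_patients) && total_patients >= 1,
              "total_patients must be a positive integer")
  assert_that(all(vapply(sizes, is_count, logical(1))) && all(sizes >= 0),
              "sizes must be non-negative integers")
  assert_that(sum(sizes) <= total_patients,
              "sum(sizes) exceeds total_patients")
  idx <- with_seed(derive_seed(seed, 23L),
                   sample.int(total_patients, sum(sizes)))
  split(idx, rep(seq_along(sizes), times = sizes))
}
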