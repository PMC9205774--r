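# Tile -> feature-vector mapping behind a pluggable backbone contract.
# Every backbone maps one tile to one fixed-length vector, independently of
# how tiles are batched, so feature extraction commutes with any reordering.

avg_pool <- function(m, factor) {
  if (factor == 1) return(m)
  nr <- floor(nrow(m) / factor) * factor
  nc <- floor(ncol(m) / factor) * factor
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  ri <- (seq_len(nr) - 1L) %/% factor + 1L
  ci <- (seq_len(nc) - 1L) %/% factor + 1L
  t(rowsum(t(rowsum(m, ri)), ci)) / factor^2
}

# Multi-scale intensity/gradient statistics of one tile (raw descriptor).
texture_descriptor <- function(tile) {
  g <- to_gray255(tile) / 255
  out <- c()
  for (f in c(1L, 2L, 4L)) {
    gs <- avg_pool(g, f)
    gx <- gs[, c(2:ncol(gs), ncol(gs))] - gs[, c(1, 1:(ncol(gs) - 1))]
    gy <- gs[c(2:nrow(gs), nrow(gs)), ] - gs[c(1, 1:(nrow(gs) - 1)), ]
    mag <- sqrt(gx^2 + gy^2)
    ori <- atan2(gy, gx) %% pi
    bins <- pmin(floor(ori / (pi / 8)) + 1, 8)
    hist8 <- vapply(1:8, function(b) sum(mag[bins == b]), numeric(1))
    hist8 <- hist8 / (sum(hist8) + 1e-8)
    out <- c(out,
             mean(gs), sd(as.vector(gs)),
             quantile(gs, c(0.1, 0.5, 0.9), names = FALSE),
             mean(mag), sd(as.vector(mag)),
             quantile(mag, 0.9, names = FALSE),
             hist8)
  }
  ch <- if (max(tile) <= 1) tile else tile / 255
  c(out,
    vapply(1:3, function(k) mean(ch[, , k]), numeric(1)),
    vapply(1:3, function(k) sd(as.vector(ch[, , k])), numeric(1)))
}

# Fixed projection matrices; the texture backbone always uses the same
# internal constant so its features are stable across sessions.
projection_matrix <- function(nrow_out, ncol_in, seed) {
  with_seed(seed, matrix(rnorm(nrow_out * ncol_in, sd = 1 / sqrt(ncol_in)),
                         nrow_out, ncol_in))
}

TEXTURE_PROJECTION_SEED <- 424243L

backbone_texture <- function(tile, feature_dim) {
  raw <- texture_descriptor(tile)
  p <- projection_matrix(feature_dim, length(raw), TEXTURE_PROJECTION_SEED)
  as.vector(p %*% raw)
}

backbone_random_projection <- function(tile, feature_dim, seed) {
  g <- if (max(tile) <= 1) tile else tile / 255
  pooled <- lapply(1:3, function(k) {
    m <- g[, , k]
    f <- max(1L, floor(min(dim(m)) / 16))
    small <- avg_pool(m, f)
    small[seq_len(min(16, nrow(small))), seq_len(min(16, ncol(small))),
          drop = FALSE]
  })
  raw <- unlist(lapply(pooled, as.vector))
  p <- projection_matrix(feature_dim, length(raw), derive_seed(seed, 31L))
  as.vector(p %*% raw)
}

#' Extract per-tile feature vectors
#'
#' Maps each tile to a `feature_dim`-length vector through a pluggable
#' backbone. The desk-scale default is a handcrafted multi-scale texture
#' backbone (intensity and gradient statistics plus orientation histograms,
#' projected to `feature_dim` dimensions by a fixed matrix), which needs no
#' pretrained weights. A seeded random-projection backbone is available, and
#' any user function `function(tile) -> numeric(feature_dim)` can be passed
#' to plug in an external CNN behind the same contract.
#'
#' Tiles are processed independently, so output does not depend on batch
#' grouping and permuting tiles permutes the rows identically.
#'
#' @param tiles Tibble with a `tile` list column (e.g. from
#'   [tessellate()]); id columns are carried through.
#' @param backbone `"texture"`, `"random_projection"`, or a function.
#' @param feature_dim Output dimensionality (default 512).
#' @param seed Seed for the `"random_projection"` backbone.
#'
#' @return The input tibble without the `tile` column, plus a matrix column
#'   `features` with `feature_dim` columns.
#' @export
extract_features <- function(tiles, backbone = "texture", feature_dim = 512,
                             seed = 1) {
  assert_that(is.data.frame(tiles) && "tile" %in% names(tiles),
              "tiles must contain a 'tile' list column")
  fn <- if (is.function(backbone)) {
    backbone
  } else if (identical(backbone, "texture")) {
    function(t) backbone_texture(t, feature_dim)
  } else if (identical(backbone, "random_projection")) {
    function(t) backbone_random_projection(t, feature_dim, seed)
  } else {
    abort(paste0("unknown backbone '", backbone, "'"))
  }
  mats <- lapply(tiles$tile, fn)
  bad <- vapply(mats, function(v) length(v) != feature_dim || !all(is.finite(v)),
                logical(1))
  assert_that(!any(bad),
              "backbone returned a vector of wrong length or non-finite values")
  out <- tiles[setdiff(names(tiles), "tile")]
  out$features <- do.call(rbind, mats)
  as_tibble(out)
}

#' Write / read a plain-text feature store
#'
#' Persists a feature table as one CSV per patient (rows = tiles, columns =
#' feature dimensions) plus a sidecar JSON recording the backbone id, seed,
#' feature dimension and layout version.
#'
#' @param features Tibble with `patient_id` and a `features` matrix column.
#' @param dir Target directory.
#' @param backbone,seed Provenance recorded in the sidecar.
#' @return `dir`, invisibly. `read_feature_store()` returns the tibble.
#' @export
write_feature_store <- function(features, dir, backbone = "texture",
                                seed = NA) {
  assert_that(all(c("patient_id", "features") %in% names(features)),
              "features must have patient_id and features columns")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in unique(features$patient_id)) {
    m <- features$features[features$patient_id == pid, , drop = FALSE]
    utils::write.csv(as.data.frame(m),
                     file.path(dir, paste0(pid, ".csv")),
                     row.names = FALSE)
  }
  sidecar <- list(layout_version = 1L, backbone = backbone, seed = seed,
                  feature_dim = ncol(features$features),
                  patients = sort(unique(features$patient_id)))
  jsonlite::write_json(sidecar, file.path(dir, "store.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "store.json"),
                                 simplifyVector = TRUE)
  tabs <- lapply(sidecar$patients, function(pid) {
    m <- as.matrix(utils::read.csv(file.path(dir, paste0(pid, ".csv"))))
    dimnames(m) <- NULL
    tibble(patient_id = pid, tile_id = seq_len(nrow(m)), features = m)
  })
  out <- bind_rows(tabs)
  attr(out, "sidecar") <- sidecar
  out
}
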