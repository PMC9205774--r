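# Model examination: whole-slide prediction heatmaps and export of the
# highest-scoring tiles of the highest-scoring patients.

#' Whole-slide prediction heatmap
#'
#' Places tile class-1 probabilities at their tile centers on the slide's
#' tile lattice, fills lattice cells without a score (e.g. QC-removed
#' tiles) by linear interpolation from scored neighbors along rows and
#' columns, fills cells outside the span of scored tiles with the nearest
#' scored value, and exposes a continuous bilinear sampler over the full
#' raster. Interpolation runs on the tile lattice (not pixel space) and is
#' then upscaled, so the result is resolution-independent.
#'
#' @param tile_positions Tibble/data frame with 0-based pixel offsets `x`,
#'   `y` of each scored tile (multiples of `tile_size`).
#' @param tile_scores Numeric vector of per-tile probabilities in \[0,1\].
#' @param tile_size Tile edge length in pixels.
#' @param slide_shape Optional `c(height, width)` in pixels; defaults to
#'   the bounding box of the scored tiles.
#'
#' @return Object of class `sl_heatmap`: `lattice` (grid of values, rows =
#'   y), `scored` (logical grid), `tile_size`, and `raster` (per-pixel
#'   values at the slide scale).
#' @examples
#' hm <- slide_heatmap(data.frame(x = c(0, 32), y = c(0, 0)),
#'                     c(0, 1), tile_size = 32)
#' heatmap_value(hm, x = 32, y = 16)  # midpoint between centers: 0.5
#' @export
slide_heatmap <- function(tile_positions, tile_scores, tile_size,
                          slide_shape = NULL) {
  assert_that(length(tile_scores) >= 1, "at least one scored tile is required")
  assert_that(nrow(tile_positions) == length(tile_scores),
              "one score per tile position is required")
  assert_that(all(tile_scores >= 0 & tile_scores <= 1),
              "scores must be probabilities in [0, 1]")
  gi <- tile_positions$y / tile_size + 1  # lattice row
  gj <- tile_positions$x / tile_size + 1  # lattice column
  assert_that(all(gi == round(gi)) && all(gj == round(gj)),
              "x and y must be multiples of tile_size")
  if (is.null(slide_shape)) {
    nr <- max(gi); nc <- max(gj)
  } else {
    nr <- floor(slide_shape[1] / tile_size)
    nc <- floor(slide_shape[2] / tile_size)
  }
  lattice <- matrix(NA_real_, nr, nc)
  lattice[cbind(gi, gj)] <- tile_scores
  scored <- !is.na(lattice)

  filled <- fill_lattice(lattice)
  raster <- upscale_lattice(filled, tile_size)
  structure(list(lattice = filled, scored = scored,
                 tile_size = as.integer(tile_size), raster = raster),
            class = "sl_heatmap")
}

# Linear interpolation of missing lattice cells from scored neighbors:
# row-wise and column-wise 1-D linear interpolation averaged where both
# exist; remaining cells (outside the scored convex span) take the value
# of the nearest scored cell (lattice Euclidean distance, row-major tie
# break).
fill_lattice <- function(lat) {
  nr <- nrow(lat); nc <- ncol(lat)
  interp_1d <- function(v) {
    known <- which(!is.na(v))
    if (length(known) < 2) return(rep(NA_real_, length(v)))
    stats::approx(known, v[known], xout = seq_along(v), method = "linear",
                  rule = 1)$y
  }
  by_row <- t(apply(lat, 1, interp_1d))
  by_col <- apply(lat, 2, interp_1d)
  if (nc == 1) by_row <- matrix(by_row, nr, nc)
  if (nr == 1) by_col <- matrix(by_col, nr, nc)
  est <- ifelse(is.na(by_row), by_col,
                ifelse(is.na(by_col), by_row, (by_row + by_col) / 2))
  out <- ifelse(is.na(lat), est, lat)
  if (any(is.na(out))) {
    known_idx <- which(!is.na(lat), arr.ind = TRUE)
    known_val <- lat[known_idx]
    missing_idx <- which(is.na(out), arr.ind = TRUE)
    for (k in seq_len(nrow(missing_idx))) {
      d2 <- (known_idx[, 1] - missing_idx[k, 1])^2 +
        (known_idx[, 2] - missing_idx[k, 2])^2
      out[missing_idx[k, 1], missing_idx[k, 2]] <-
        known_val[which.min(d2)]
    }
  }
  out
}

# Bilinear upscale of the lattice to pixel resolution; lattice point k sits
# at pixel coordinate (k - 0.5) * tile_size (tile center).
upscale_lattice <- function(lat, tile_size) {
  nr <- nrow(lat) * tile_size
  nc <- ncol(lat) * tile_size
  u <- pmin(pmax((seq_len(nr) - 0.5) / tile_size + 0.5, 1), nrow(lat))
  v <- pmin(pmax((seq_len(nc) - 0.5) / tile_size + 0.5, 1), ncol(lat))
  i0 <- pmin(floor(u), nrow(lat) - 1); i0[nrow(lat) == 1] <- 1
  j0 <- pmin(floor(v), ncol(lat) - 1); j0[ncol(lat) == 1] <- 1
  fi <- u - i0; fj <- v - j0
  if (nrow(lat) == 1) fi <- rep(0, nr)
  if (ncol(lat) == 1) fj <- rep(0, nc)
  i1 <- pmin(i0 + 1, nrow(lat)); j1 <- pmin(j0 + 1, ncol(lat))
  a <- lat[i0, j0, drop = FALSE] * outer(1 - fi, 1 - fj) +
    lat[i1, j0, drop = FALSE] * outer(fi, 1 - fj) +
    lat[i0, j1, drop = FALSE] * outer(1 - fi, fj) +
    lat[i1, j1, drop = FALSE] * outer(fi, fj)
  a
}

#' Sample a heatmap at continuous slide coordinates
#'
#' Bilinear interpolation of the filled tile lattice; exact at tile
#' centers.
#'
#' @param hm An `sl_heatmap`.
#' @param x,y Pixel coordinates (0-based, as in [tessellate()]).
#' @return Interpolated probability value(s).
#' @export
heatmap_value <- function(hm, x, y) {
  lat <- hm$lattice
  u <- pmin(pmax(y / hm$tile_size + 0.5, 1), nrow(lat))
  v <- pmin(pmax(x / hm$tile_size + 0.5, 1), ncol(lat))
  i0 <- pmax(pmin(floor(u), nrow(lat) - 1), 1)
  j0 <- pmax(pmin(floor(v), ncol(lat) - 1), 1)
  if (nrow(lat) == 1) { i0 <- rep(1, length(u)); fi <- rep(0, length(u)) } else fi <- u - i0
  if (ncol(lat) == 1) { j0 <- rep(1, length(v)); fj <- rep(0, length(v)) } else fj <- v - j0
  i1 <- pmin(i0 + 1, nrow(lat)); j1 <- pmin(j0 + 1, ncol(lat))
  lat[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    lat[cbind(i1, j0)] * fi * (1 - fj) +
    lat[cbind(i0, j1)] * (1 - fi) * fj +
    lat[cbind(i1, j1)] * fi * fj
}

#' @export
print.sl_heatmap <- function(x, ...) {
  cat("<sl_heatmap>", nrow(x$lattice), "x", ncol(x$lattice),
      "tile lattice (", sum(x$scored), "scored ), tile size",
      x$tile_size, "px\n")
  invisible(x)
}

#' Plot a prediction heatmap
#'
#' @param object An `sl_heatmap`.
#' @param ... Unused.
#' @return A ggplot object (univariate color map over the raster).
#' @export
autoplot.sl_heatmap <- function(object, ...) {
  df <- expand.grid(y = seq_len(nrow(object$raster)),
                    x = seq_len(ncol(object$raster)))
  df$value <- as.vector(object$raster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "P(class 1)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Highest-scoring tiles of the highest-scoring patients
#'
#' Ranks patients by their aggregate score toward `class_label`, takes the
#' top `m`, and within each selected patient takes the `n` highest-scoring
#' tiles. Ties are broken lexicographically by (`patient_id`, `x`, `y`) so
#' the selection is a total, permutation-invariant order. The conventional
#' export for reader studies is m = n = 5.
#'
#' @param patient_scores Tibble with `patient_id` and `score`.
#' @param tile_scores Tibble with `patient_id`, `slide_id`, `x`, `y`,
#'   `score`.
#' @param m Number of patients; if fewer are available all are used, with
#'   a warning.
#' @param n Tiles per patient.
#' @param class_label Ranking direction: 1 ranks by score, 0 by 1 - score.
#' @return Tibble of at most `m * n` tile references with `patient_rank`
#'   and `tile_rank`.
#' @export
top_tiles <- function(patient_scores, tile_scores, m = 5, n = 5,
                      class_label = 1) {
  assert_that(is_count(m) && m >= 1 && is_count(n) && n >= 1,
              "m and n must be positive integers")
  assert_that(class_label %in% c(0, 1), "class_label must be 0 or 1")
  ps <- as_tibble(patient_scores)
  ts <- as_tibble(tile_scores)
  dir_score <- function(s) if (class_label == 1) s else 1 - s
  if (nrow(ps) < m) {
    warn(sprintf("only %d patients available (m = %d); using all",
                 nrow(ps), m))
    m <- nrow(ps)
  }
  sel <- ps %>%
    mutate(.s = dir_score(.data$score)) %>%
    arrange(desc(.data$.s), .data$patient_id) %>%
    slice(seq_len(m)) %>%
    mutate(patient_rank = dplyr::row_number())
  out <- ts %>%
    filter(.data$patient_id %in% sel$patient_id) %>%
    mutate(.s = dir_score(.data$score)) %>%
    dplyr::inner_join(sel[, c("patient_id", "patient_rank")],
                      by = "patient_id") %>%
    group_by(.data$patient_id) %>%
    arrange(desc(.data$.s), .data$patient_id, .data$x, .data$y,
            .by_group = TRUE) %>%
    slice(seq_len(n)) %>%
    mutate(tile_rank = dplyr::row_number()) %>%
    ungroup() %>%
    arrange(.data$patient_rank, .data$tile_rank) %>%
    select(-".s")
  out
}

#' Export a heatmap and its score table
#'
#' Writes the heatmap raster as a PNG (viridis-free grayscale values) and
#' a sidecar CSV of (x, y, score) lattice entries.
#'
#' @param hm An `sl_heatmap`.
#' @param path PNG output path; the CSV lands next to it.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(hm, path) {
  png::writePNG(hm$raster, path)
  idx <- which(hm$scored, arr.ind = TRUE)
  utils::write.csv(
    data.frame(x = (idx[, 2] - 1L) * hm$tile_size,
               y = (idx[, 1] - 1L) * hm$tile_size,
               score = hm$lattice[idx]),
    sub("\\.png$", ".csv", path), row.names = FALSE)
  invisible(path)
}
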