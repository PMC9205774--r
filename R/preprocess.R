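# Slide preprocessing: tessellation into fixed-size tiles, edge-based tile
# quality control, stain normalization, and per-patient tile sampling.

shift_mat <- function(m, dr, dc, fill = 0) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Luminance grayscale on the 0-255 scale (input [0,1] or 0-255).
to_gray255 <- function(tile) {
  if (length(dim(tile)) != 3 || dim(tile)[3] != 3)
    abort("tile must be an H x W x 3 RGB array")
  g <- 0.299 * tile[, , 1] + 0.587 * tile[, , 2] + 0.114 * tile[, , 3]
  if (max(tile) <= 1) g <- g * 255
  g
}

# Canny edge map: 3x3 Sobel, L1 gradient magnitude, non-maximum suppression
# over 4 quantized directions, double-threshold hysteresis with 8-connected
# propagation. Returns a matrix of 0/255.
canny_edge_map <- function(gray, low = 40, high = 100) {
  pad <- rbind(gray[1, , drop = FALSE], gray, gray[nrow(gray), , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, ncol(pad), drop = FALSE])
  s <- function(dr, dc) {
    pad[(2 + dr):(nrow(gray) + 1 + dr), (2 + dc):(ncol(gray) + 1 + dc)]
  }
  # dim1 = image rows (y), dim2 = columns (x)
  gx <- -s(-1, -1) + s(-1, 1) - 2 * s(0, -1) + 2 * s(0, 1) - s(1, -1) + s(1, 1)
  gy <- -s(-1, -1) - 2 * s(-1, 0) - s(-1, 1) + s(1, -1) + 2 * s(1, 0) + s(1, 1)
  mag <- abs(gx) + abs(gy)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180

  n1 <- matrix(0, nrow(mag), ncol(mag))
  n2 <- n1
  sector <- matrix(0L, nrow(mag), ncol(mag))
  sector[(ang < 22.5) | (ang >= 157.5)] <- 0L   # gradient ~ horizontal
  sector[ang >= 22.5 & ang < 67.5] <- 1L
  sector[ang >= 67.5 & ang < 112.5] <- 2L       # gradient ~ vertical
  sector[ang >= 112.5 & ang < 157.5] <- 3L
  neigh <- list(
    `0` = list(c(0, -1), c(0, 1)),
    `1` = list(c(-1, 1), c(1, -1)),
    `2` = list(c(-1, 0), c(1, 0)),
    `3` = list(c(-1, -1), c(1, 1))
  )
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (sct in 0:3) {
    o <- neigh[[as.character(sct)]]
    m1 <- shift_mat(mag, o[[1]][1], o[[1]][2])
    m2 <- shift_mat(mag, o[[2]][1], o[[2]][2])
    keep <- keep | (sector == sct & mag >= m1 & mag >= m2)
  }
  nms <- ifelse(keep, mag, 0)
  # 1-px border suppressed (replicated padding makes it unreliable)
  nms[c(1, nrow(nms)), ] <- 0
  nms[, c(1, ncol(nms))] <- 0

  strong <- nms >= high
  weak <- nms >= low & !strong
  repeat {
    grown <- strong
    for (dr in -1:1) for (dc in -1:1) {
      if (dr || dc) grown <- grown | shift_mat(strong, dr, dc, FALSE)
    }
    newly <- weak & grown & !strong
    if (!any(newly)) break
    strong <- strong | newly
  }
  matrix(as.numeric(strong) * 255, nrow(nms), ncol(nms))
}

#' Tessellate a slide raster into non-overlapping tiles
#'
#' Cuts an RGB slide into fixed-size tiles on a non-overlapping grid
#' anchored at the top-left corner; partial tiles at the right/bottom edges
#' are discarded. Coordinates are 0-based pixel offsets of each tile's
#' top-left corner, with `x` along columns and `y` along rows.
#'
#' @param slide H x W x 3 numeric array (values in \[0,1\] or 0-255).
#' @param tile_size Tile edge length in pixels.
#' @param slide_id Identifier recorded on every tile row.
#'
#' @return Tibble with columns `slide_id`, `x`, `y` and a list column
#'   `tile` of `tile_size` x `tile_size` x 3 arrays.
#' @examples
#' slide <- array(runif(64 * 96 * 3), dim = c(64, 96, 3))
#' nrow(tessellate(slide, 32))  # 2 x 3 grid
#' @export
tessellate <- function(slide, tile_size, slide_id = "slide") {
  assert_that(is.array(slide) && length(dim(slide)) == 3 &&
                dim(slide)[3] == 3,
              "slide must be an H x W x 3 RGB array")
  assert_that(all(dim(slide)[1:2] > 0), "slide raster is empty")
  assert_that(is_count(tile_size) && tile_size >= 1,
              "tile_size must be a positive integer")
  ny <- floor(dim(slide)[1] / tile_size)
  nx <- floor(dim(slide)[2] / tile_size)
  if (nx * ny == 0) {
    return(tibble(slide_id = character(), x = integer(), y = integer(),
                  tile = list()))
  }
  grid <- expand.grid(gy = seq_len(ny) - 1L, gx = seq_len(nx) - 1L)
  tiles <- lapply(seq_len(nrow(grid)), function(i) {
    gy <- grid$gy[i]; gx <- grid$gx[i]
    slide[gy * tile_size + seq_len(tile_size),
          gx * tile_size + seq_len(tile_size), , drop = FALSE]
  })
  tibble(
    slide_id = slide_id,
    x = as.integer(grid$gx * tile_size),
    y = as.integer(grid$gy * tile_size),
    tile = tiles
  )
}

#' Edge-based quality score of a tile
#'
#' Converts the tile to grayscale (luminance weights 0.299/0.587/0.114),
#' computes a Canny edge map (edge pixels 255, others 0) and returns its
#' mean. Blank or blurred tiles have few edges and score near 0; tissue
#' tiles score well above typical QC thresholds.
#'
#' @param tile H x W x 3 RGB array.
#' @param canny_low,canny_high Hysteresis thresholds on the L1 gradient
#'   magnitude (0-255 intensity scale).
#'
#' @return Scalar score in \[0, 255\].
#' @export
edge_qc_score <- function(tile, canny_low = 40, canny_high = 100) {
  g <- to_gray255(tile)
  mean(canny_edge_map(g, low = canny_low, high = canny_high))
}

#' Score and filter tiles by edge content
#'
#' `compute_qc_scores()` adds a `qc_score` column to a tile table;
#' `qc_filter()` retains tiles whose score is at or above the threshold
#' (tiles *below* the threshold are removed), preserving order.
#'
#' @param tiles Tibble with a `tile` list column (see [tessellate()]),
#'   or for `qc_filter()` any tibble with a `qc_score` column.
#' @param canny_low,canny_high Passed to [edge_qc_score()].
#' @param threshold QC threshold on the mean edge map; the conventional
#'   value for 0-255 edge maps is 4.
#'
#' @return The input tibble with a `qc_score` column; `qc_filter()`
#'   returns the retained subset (a sublist of its input).
#' @export
compute_qc_scores <- function(tiles, canny_low = 40, canny_high = 100) {
  assert_that(is.data.frame(tiles) && "tile" %in% names(tiles),
              "tiles must contain a 'tile' list column")
  tiles$qc_score <- vapply(tiles$tile, edge_qc_score, numeric(1),
                           canny_low = canny_low, canny_high = canny_high)
  tiles
}

#' @rdname compute_qc_scores
#' @export
qc_filter <- function(tiles, threshold = 4) {
  assert_that(is.data.frame(tiles) && "qc_score" %in% names(tiles),
              "tiles must contain a 'qc_score' column; see compute_qc_scores()")
  tiles[tiles$qc_score >= threshold, , drop = FALSE]
}

# Macenko stain-vector estimation from stained-pixel optical densities:
# top-2 principal directions, extreme (1st/99th percentile) angles of the
# projected pixels, hematoxylin ordered first by red-channel density.
macenko_estimate <- function(odh) {
  ev <- eigen(stats::cov(odh), symmetric = TRUE)$vectors[, 1:2]
  proj <- odh %*% ev
  phi <- atan2(proj[, 2], proj[, 1])
  q <- quantile(phi, c(0.01, 0.99), names = FALSE)
  v1 <- ev %*% c(cos(q[1]), sin(q[1]))
  v2 <- ev %*% c(cos(q[2]), sin(q[2]))
  if (v1[1] < 0) v1 <- -v1
  if (v2[1] < 0) v2 <- -v2
  he <- if (v1[1] > v2[1]) cbind(v1, v2) else cbind(v2, v1)
  list(stain_matrix = unname(he))
}

#' Estimate a stain reference profile from a tile
#'
#' Runs the Macenko stain-vector estimation on one tile and returns its
#' stain matrix and 99th-percentile concentrations in the form accepted by
#' [normalize_stain()]'s `reference` argument. Normalizing a tile against
#' its own estimated profile is (approximately) the identity.
#'
#' @inheritParams normalize_stain
#' @return List with `stain_matrix` (3 x 2) and `max_conc` (length 2).
#' @export
estimate_stain_reference <- function(tile, beta = 0.15) {
  rgb255 <- if (max(tile) <= 1) tile * 255 else tile
  px <- cbind(as.vector(rgb255[, , 1]), as.vector(rgb255[, , 2]),
              as.vector(rgb255[, , 3]))
  od <- -log10((px + 1) / 256)
  stained <- rowSums(od > beta) == 3
  assert_that(sum(stained) >= 50,
              "tile has too few stained pixels to estimate a profile")
  est <- macenko_estimate(od[stained, , drop = FALSE])
  he <- est$stain_matrix
  conc <- solve(crossprod(he), crossprod(he, t(od)))
  est$max_conc <- apply(conc, 1, quantile, probs = 0.99)
  est
}

# Packaged reference stain profile: the standard H&E stain matrix and
# maximum concentrations commonly used as a Macenko normalization target.
default_stain_reference <- function() {
  list(
    stain_matrix = matrix(c(0.5626, 0.7201, 0.4062,
                            0.2159, 0.8012, 0.5581),
                          nrow = 3, ncol = 2),
    max_conc = c(1.9705, 1.0308)
  )
}

#' Macenko stain normalization
#'
#' Maps a tile's stain profile onto a reference H&E target: pixels are
#' converted to optical density, the two dominant stain vectors are
#' estimated from the extreme angles of the projection onto the top two
#' principal directions, per-pixel stain concentrations are solved by least
#' squares, scaled so their 99th percentile matches the reference maxima,
#' and the tile is reconstructed with the reference stain matrix. Tiles
#' with almost no stained pixels (near-white background) are passed through
#' unchanged with attribute `flag = "no_stain"` and a warning.
#'
#' @param tile H x W x 3 RGB array in \[0,1\] or 0-255.
#' @param reference List with `stain_matrix` (3 x 2) and `max_conc`
#'   (length 2); defaults to a packaged standard H&E target.
#' @param method `"macenko"` or `"none"` (pass-through).
#' @param beta Optical-density threshold below which pixels count as
#'   unstained.
#'
#' @return Normalized tile, same shape and value range as the input.
#' @export
normalize_stain <- function(tile, reference = NULL,
                            method = c("macenko", "none"), beta = 0.15) {
  method <- match.arg(method)
  assert_that(is.array(tile) && length(dim(tile)) == 3 && dim(tile)[3] == 3,
              "tile must be an H x W x 3 RGB array")
  if (method == "none") return(tile)
  reference <- reference %||% default_stain_reference()

  scale01 <- max(tile) <= 1
  rgb255 <- if (scale01) tile * 255 else tile
  h <- dim(tile)[1]; w <- dim(tile)[2]
  px <- cbind(as.vector(rgb255[, , 1]), as.vector(rgb255[, , 2]),
              as.vector(rgb255[, , 3]))
  od <- -log10((px + 1) / 256)
  stained <- rowSums(od > beta) == 3
  if (sum(stained) < max(50, 0.005 * h * w)) {
    warn("tile has no appreciable stain signal; passed through unnormalized")
    out <- tile
    attr(out, "flag") <- "no_stain"
    return(out)
  }
  est <- macenko_estimate(od[stained, , drop = FALSE])
  he <- est$stain_matrix
  conc <- solve(crossprod(he), crossprod(he, t(od)))  # 2 x npix
  max_c <- apply(conc, 1, quantile, probs = 0.99)
  max_c[max_c <= 0] <- 1e-6
  conc_n <- conc * (reference$max_conc / max_c)
  od_new <- t(reference$stain_matrix %*% conc_n)
  rgb_new <- 256 * 10^(-od_new) - 1
  rgb_new <- pmin(pmax(rgb_new, 0), 255)
  out <- array(0, dim = dim(tile))
  out[, , 1] <- rgb_new[, 1]
  out[, , 2] <- rgb_new[, 2]
  out[, , 3] <- rgb_new[, 3]
  if (scale01) out <- out / 255
  out
}

#' Sample a fixed number of tiles per patient
#'
#' Samples `n` tiles without replacement from one patient's tile table,
#' deterministically under the seed. Patients with fewer than `n` tiles
#' keep all their tiles; a patient with no tiles yields an empty result
#' with a warning (to be excluded downstream).
#'
#' @param tiles Tibble of one patient's tiles (any columns).
#' @param n Number of tiles to retain (the conventional per-patient budget
#'   is 150).
#' @param seed Integer seed.
#'
#' @return Subset of `tiles` with `min(n, nrow(tiles))` rows.
#' @export
sample_patient_tiles <- function(tiles, n = 150, seed = 1) {
  assert_that(is.data.frame(tiles), "tiles must be a data frame")
  assert_that(is_count(n) && n >= 1, "n must be a positive integer")
  if (nrow(tiles) == 0) {
    warn("patient has no tiles after QC; returning empty selection")
    return(tiles)
  }
  if (nrow(tiles) <= n) return(tiles)
  idx <- with_seed(derive_seed(seed, 29L), sample.int(nrow(tiles), n))
  tiles[sort(idx), , drop = FALSE]
}
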