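## Preprocessing: green-channel extraction and contrast-limited adaptive
## histogram equalization (CLAHE). CLAHE follows the classical five-step
## scheme: tile the image, per-tile histogram, clip threshold, single-pass
## clipped redistribution, then per-pixel bilinear blending of the four
## surrounding tile mappings. Written from first principles because the
## clipping/redistribution rule is part of this package's contract.

#' CLAHE parameters
#'
#' @param grid_rows,grid_cols Number of tile rows/columns (default 8x8, so
#'   a 512x512 image is processed in 64x64 tiles).
#' @param clip_alpha Normalized clipping coefficient in `[0, 1]`: 0 clips
#'   every histogram to the uniform floor, 1 disables clipping. Default
#'   0.05.
#' @param gray_levels Number of gray levels `L` (default 256, for 8-bit
#'   images in `[0, 255]`).
#' @return An object of class `"clahe_params"`.
#' @export
clahe_params <- function(grid_rows = 8L, grid_cols = 8L, clip_alpha = 0.05,
                         gray_levels = 256L) {
  grid_rows <- as.integer(grid_rows)
  grid_cols <- as.integer(grid_cols)
  if (grid_rows < 1L || grid_cols < 1L)
    stop("clahe_params: grid must have at least one tile per axis")
  if (clip_alpha < 0 || clip_alpha > 1)
    stop("clahe_params: clip_alpha must be in [0, 1]")
  if (gray_levels < 2L) stop("clahe_params: gray_levels must be >= 2")
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 clip_alpha = clip_alpha,
                 gray_levels = as.integer(gray_levels)),
            class = "clahe_params")
}

#' Extract the green channel of an RGB image
#'
#' In fundus photographs the green channel carries the highest contrast
#' between vessels and background, so it is the standard monochrome input
#' for vessel segmentation.
#'
#' @param image `H x W x 3` array of intensities in `[0, 255]`.
#' @return `H x W` numeric matrix (uint8 domain, `[0, 255]`).
#' @export
green_channel <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("green_channel: expected an H x W x 3 array, got dim ",
         paste(d, collapse = "x"))
  image[, , 2L]
}

#' Histogram clip threshold
#'
#' `T_clip = n_tile/L + alpha * (n_tile - n_tile/L)`: the uniform floor
#' plus a fraction `alpha` of the head-room up to the tile's pixel count.
#' At `alpha = 0` every bin is clipped to the uniform histogram; at
#' `alpha = 1` clipping is impossible.
#'
#' @param n_tile Number of pixels in one tile.
#' @param params A [clahe_params()].
#' @return The clip threshold (float, in pixel counts).
#' @export
clip_threshold <- function(n_tile, params = clahe_params()) {
  if (n_tile < 1) stop("clip_threshold: n_tile must be >= 1")
  L <- params$gray_levels
  n_tile / L + params$clip_alpha * (n_tile - n_tile / L)
}

#' Clip a tile histogram and redistribute the excess
#'
#' Single-pass contrast limiting: the total excess above the clip
#' threshold, `N_tol = sum(max(h - T_clip, 0))`, is spread uniformly as
#' `N_ace = N_tol / L` per bin; bins above the limit `T_lim = T_clip -
#' N_ace` are set to `T_clip`, all others receive `+ N_ace`. One pass only:
#' bins close to the limit may end slightly above it, and the total count
#' is conserved to within `L` (tested as an invariant).
#'
#' @param counts Numeric vector of per-gray-level pixel counts (length
#'   `gray_levels`).
#' @param params A [clahe_params()].
#' @return Redistributed histogram (same length).
#' @export
clip_and_redistribute <- function(counts, params = clahe_params()) {
  L <- params$gray_levels
  if (length(counts) != L)
    stop("clip_and_redistribute: expected ", L, " bins, got ",
         length(counts))
  if (any(counts < 0)) stop("clip_and_redistribute: negative counts")
  n_tile <- sum(counts)
  if (n_tile == 0) return(counts)
  t_clip <- clip_threshold(n_tile, params)
  n_tol <- sum(pmax(counts - t_clip, 0))
  n_ace <- n_tol / L
  t_lim <- t_clip - n_ace
  ifelse(counts > t_lim, t_clip, counts + n_ace)
}

## monotone per-tile equalization mapping from a redistributed histogram,
## with the classic cdf-minimum normalization so the lowest occupied gray
## level maps to 0 (full-range inputs keep their contrast); a degenerate
## denominator (all mass in one bin, no redistribution) maps identically
tile_mapping <- function(counts, params) {
  h <- clip_and_redistribute(counts, params)
  cdf <- cumsum(h)
  tot <- cdf[length(cdf)]
  pos <- cdf[cdf > 0]
  cmin <- if (length(pos)) pos[1] else 0
  if (tot - cmin <= 0) return(seq_len(params$gray_levels) - 1)
  round((params$gray_levels - 1) * pmax(cdf - cmin, 0) / (tot - cmin))
}

## reflect-pad a matrix on the bottom/right
pad_reflect <- function(m, pb, pr) {
  H <- nrow(m); W <- ncol(m)
  if (pb > 0) m <- rbind(m, m[H - seq_len(pb) + 1L, , drop = FALSE])
  if (pr > 0) m <- cbind(m, m[, W - seq_len(pr) + 1L, drop = FALSE])
  m
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tiles the image on a `grid_rows x grid_cols` grid, equalizes each tile
#' with a clipped histogram ([clip_and_redistribute()]), and reconstructs
#' every pixel by bilinear interpolation between the mappings of the four
#' surrounding tile centers (clamped at edges and corners). Images whose
#' sides are not divisible by the grid are reflect-padded, processed, and
#' cropped back.
#'
#' @param image Numeric matrix in the uint8 domain `[0, 255]` (values are
#'   rounded to integer gray levels internally).
#' @param params A [clahe_params()].
#' @return Matrix of the same size, integer gray values in
#'   `[0, gray_levels - 1]`.
#' @export
clahe <- function(image, params = clahe_params()) {
  if (!is.matrix(image)) stop("clahe: image must be a matrix")
  H0 <- nrow(image); W0 <- ncol(image)
  gr <- params$grid_rows; gc <- params$grid_cols
  if (H0 < gr || W0 < gc)
    stop("clahe: image ", H0, "x", W0, " smaller than the tile grid ",
         gr, "x", gc)
  L <- params$gray_levels
  img <- pad_reflect(image, (gr - H0 %% gr) %% gr, (gc - W0 %% gc) %% gc)
  H <- nrow(img); W <- ncol(img)
  th <- H %/% gr; tw <- W %/% gc
  g <- pmin(pmax(round(img), 0), L - 1)

  ## per-tile equalization mappings (L x gr x gc)
  maps <- array(0, c(L, gr, gc))
  for (r in seq_len(gr)) {
    for (cl in seq_len(gc)) {
      tile <- g[(r - 1L) * th + seq_len(th), (cl - 1L) * tw + seq_len(tw)]
      counts <- tabulate(tile + 1L, nbins = L)
      maps[, r, cl] <- tile_mapping(counts, params)
    }
  }

  ## bilinear blend of the four surrounding tile mappings at each pixel
  ri <- (seq_len(H) - 0.5) / th - 0.5   # tile-center coordinate, 0-based
  ci <- (seq_len(W) - 0.5) / tw - 0.5
  r0 <- pmin(pmax(floor(ri), 0), gr - 1L)
  r1 <- pmin(r0 + 1L, gr - 1L)
  fr <- pmin(pmax(ri - floor(ri), 0), 1)
  fr[ri < 0 | ri > gr - 1] <- 0
  c0 <- pmin(pmax(floor(ci), 0), gc - 1L)
  c1 <- pmin(c0 + 1L, gc - 1L)
  fc <- pmin(pmax(ci - floor(ci), 0), 1)
  fc[ci < 0 | ci > gc - 1] <- 0

  gi <- as.integer(g) + 1L
  R0 <- rep(as.integer(r0) + 1L, times = W); R1 <- rep(as.integer(r1) + 1L, times = W)
  C0 <- rep(as.integer(c0) + 1L, each = H); C1 <- rep(as.integer(c1) + 1L, each = H)
  FR <- rep(fr, times = W); FC <- rep(fc, each = H)
  m00 <- maps[cbind(gi, R0, C0)]
  m10 <- maps[cbind(gi, R1, C0)]
  m01 <- maps[cbind(gi, R0, C1)]
  m11 <- maps[cbind(gi, R1, C1)]
  out <- (1 - FR) * ((1 - FC) * m00 + FC * m01) +
    FR * ((1 - FC) * m10 + FC * m11)
  out <- matrix(round(out), H, W)
  out[seq_len(H0), seq_len(W0), drop = FALSE]
}

#' Standard preprocessing for a fundus-style image
#'
#' Green channel, CLAHE contrast enhancement, then rescaling to `[0, 1]` —
#' the network's expected input domain.
#'
#' @param image `H x W x 3` array in `[0, 255]` (or an `H x W` gray matrix,
#'   used as-is).
#' @param params A [clahe_params()].
#' @return `H x W` matrix in `[0, 1]`.
#' @export
preprocess_image <- function(image, params = clahe_params()) {
  gimg <- if (is.matrix(image)) image else green_channel(image)
  clahe(gimg, params) / (params$gray_levels - 1)
}
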