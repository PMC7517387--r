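## Synthetic vessel phantoms: low-contrast curvilinear vessel trees drawn
## dark on a smooth, vignetted background with additive Gaussian noise and
## 8-bit quantization, plus an exact binary truth mask and a circular
## field-of-view mask. The generator emulates the pixel statistics the
## segmentation pipeline assumes (vessel widths of a few pixels, roughly
## 10-13% vessel prevalence, vessels darker than background) so every stage
## is testable without clinical images.

#' Phantom specification
#'
#' @param size Side length of the square phantom in pixels (default 128;
#'   use 512 for display-scale phantoms).
#' @param n_trees Number of vessel trees seeded on the field-of-view rim.
#' @param branch_depth Maximum branching generations per tree.
#' @param width_range Two-element vector, minimum and maximum stroke width
#'   in pixels (trunks start at the maximum and taper; default `c(1, 8)`).
#' @param vessel_contrast Intensity gap between background and vessel
#'   centerlines on the normalized `[0, 1]` scale (default 0.25 - the
#'   low-contrast regime typical of fundus green channels).
#' @param noise_sigma Standard deviation of the additive Gaussian noise on
#'   the normalized scale (default 0.05).
#' @param vignette_strength Peak radial darkening toward the field-of-view
#'   rim (default 0.3).
#' @param target_vessel_fraction Vessel pixels as a fraction of all frame
#'   pixels; branches are added until it is reached (default 0.12, matching
#'   the 10-13% prevalence reported for expert-annotated fundus images).
#' @param seed Integer seed; the phantom is a deterministic function of it.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(size = 128L, n_trees = 3L, branch_depth = 4L,
                         width_range = c(1, 8), vessel_contrast = 0.25,
                         noise_sigma = 0.05, vignette_strength = 0.3,
                         target_vessel_fraction = 0.12, seed = 1L) {
  size <- as.integer(size)
  if (size < 32L) stop("phantom_spec: size must be >= 32")
  if (any(width_range <= 0) || width_range[1] > width_range[2])
    stop("phantom_spec: invalid width_range")
  if (target_vessel_fraction <= 0 || target_vessel_fraction >= 0.5)
    stop("phantom_spec: target_vessel_fraction must be in (0, 0.5)")
  structure(list(size = size, n_trees = as.integer(n_trees),
                 branch_depth = as.integer(branch_depth),
                 width_range = width_range,
                 vessel_contrast = vessel_contrast,
                 noise_sigma = noise_sigma,
                 vignette_strength = vignette_strength,
                 target_vessel_fraction = target_vessel_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## stamp a disk of diameter ~w onto a logical mask at (r, c)
stamp_disk <- function(mask, r, c, w) {
  n <- nrow(mask)
  rad <- max(w / 2, 0.5)
  ir <- max(1L, floor(r - rad)):min(n, ceiling(r + rad))
  ic <- max(1L, floor(c - rad)):min(n, ceiling(c + rad))
  dd <- outer((ir - r)^2, (ic - c)^2, `+`)
  mask[ir, ic] <- mask[ir, ic] | (dd <= rad^2)
  mask
}

#' Rasterize a stroke as a union of disks
#'
#' Marks every pixel within `width/2` of any of the given centerline
#' points. This is the primitive the phantom generator draws vessels with,
#' exposed so strokes can be checked against direct geometric computation.
#'
#' @param size Side of the square raster.
#' @param centers Two-column matrix of (row, col) centerline points.
#' @param width Stroke width in pixels (disk diameter).
#' @return Integer 0/1 matrix of dimension `size x size`.
#' @export
rasterize_stroke <- function(size, centers, width) {
  mask <- matrix(FALSE, size, size)
  for (k in seq_len(nrow(centers)))
    mask <- stamp_disk(mask, centers[k, 1], centers[k, 2], width)
  mask * 1L
}

## rasterize one random-walk branch; returns the updated mask and the
## branch's end state so children can continue from it
walk_branch <- function(mask, r, c, angle, width, len, turn_sd = 0.25) {
  n <- nrow(mask)
  taper <- 0.995
  for (i in seq_len(len)) {
    mask <- stamp_disk(mask, r, c, width)
    angle <- angle + stats::rnorm(1, 0, turn_sd)
    r <- r + sin(angle)
    c <- c + cos(angle)
    width <- max(width * taper, 0.8)
    if (r < 2 || r > n - 1 || c < 2 || c > n - 1) break
  }
  list(mask = mask, r = r, c = c, angle = angle, width = width,
       steps = i)
}

## grow one tree, stopping as soon as the global vessel-pixel budget is
## met so the achieved fraction never overshoots the target by more than
## roughly one branch's area
grow_tree <- function(mask, r, c, angle, width, depth, spec, target) {
  if (mean(mask) >= target) return(mask)
  len <- round(stats::runif(1, 0.25, 0.6) * nrow(mask))
  res <- walk_branch(mask, r, c, angle, width, len)
  mask <- res$mask
  if (depth > 1L && res$steps > 4L) {
    for (s in c(-1, 1)) {
      if (stats::runif(1) < 0.8 && mean(mask) < target) {
        child_w <- max(res$width * stats::runif(1, 0.55, 0.75),
                       spec$width_range[1])
        mask <- grow_tree(mask, res$r, res$c,
                          res$angle + s * stats::runif(1, 0.3, 0.8),
                          child_w, depth - 1L, spec, target)
      }
    }
  }
  mask
}

#' Generate one synthetic vessel phantom
#'
#' Draws a branching vessel tree by a randomly turning walk with tapering
#' stroke width, rasterizes it as the exact binary truth mask, then renders
#' the image as a smooth bright background, a radial vignette, the vessel
#' strokes darkened by `vessel_contrast`, additive Gaussian noise, and
#' 8-bit quantization. Trees are seeded until `target_vessel_fraction` is
#' reached (a warning reports the achieved fraction when the geometry
#' cannot reach it). The result is byte-identical across runs for a fixed
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @return A `sample_pair`: `image` (`size x size x 3` array, `[0, 255]`),
#'   `truth` (0/1 matrix, the pre-noise stroke raster), `fov` (0/1 disk
#'   mask) and `id`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  n <- spec$size
  cen <- (n + 1) / 2
  rr <- outer(seq_len(n) - cen, rep(0, n), `+`)
  cc <- outer(rep(0, n), seq_len(n) - cen, `+`)
  rad <- sqrt(rr^2 + cc^2)
  fov_r <- 0.49 * n
  fov <- (rad <= fov_r) * 1L

  ## vessel tree: seed trunks on the rim pointing inward, add trees until
  ## the target pixel fraction is met
  mask <- matrix(FALSE, n, n)
  target <- spec$target_vessel_fraction
  max_trees <- spec$n_trees + 40L
  tree <- 0L
  while (mean(mask) < target && tree < max_trees) {
    tree <- tree + 1L
    theta <- stats::runif(1, 0, 2 * pi)
    r0 <- cen + 0.85 * fov_r * sin(theta)
    c0 <- cen + 0.85 * fov_r * cos(theta)
    inward <- atan2(cen - r0, cen - c0) + stats::rnorm(1, 0, 0.3)
    w0 <- stats::runif(1, 0.6, 1) * spec$width_range[2]
    mask <- grow_tree(mask, r0, c0, inward, w0, spec$branch_depth, spec,
                      target)
  }
  if (mean(mask) < target - 0.04)
    warning(sprintf(paste0("generate_phantom: reached vessel fraction ",
                           "%.3f < target %.3f"), mean(mask), target))
  truth <- mask * 1L

  ## background: smooth low-frequency field (bilinear upsample of a coarse
  ## random grid) + radial vignette
  coarse <- matrix(stats::runif(25, -0.05, 0.05), 5, 5)
  bg <- 0.75 + bilinear_upsample(coarse, n) -
    spec$vignette_strength * (rad / fov_r)^2 * 0.5
  img <- bg - spec$vessel_contrast * mask
  img <- img + stats::rnorm(n * n, 0, spec$noise_sigma)
  img8 <- matrix(pmin(pmax(round(img * 255), 0), 255), n, n)
  rgb <- array(0, c(n, n, 3))
  rgb[, , 1] <- pmin(255, img8 * 1.15)  # fundus-like warm cast
  rgb[, , 2] <- img8                    # green carries the signal
  rgb[, , 3] <- img8 * 0.6
  sample_pair(rgb, truth, fov, sprintf("phantom%04d", spec$seed))
}

bilinear_upsample <- function(m, n) {
  g <- nrow(m)
  x <- seq(1, g, length.out = n)
  i0 <- pmin(floor(x), g - 1L)
  f <- x - i0
  row_interp <- m[i0, , drop = FALSE] * (1 - f) + m[i0 + 1L, , drop = FALSE] * f
  t(t(row_interp)[i0, , drop = FALSE] * (1 - f) +
      t(row_interp)[i0 + 1L, , drop = FALSE] * f)
}

#' Write a phantom dataset in a scannable directory layout
#'
#' Generates `n_train + n_test` phantoms with consecutive seeds and writes
#' them under `out_dir/train` and `out_dir/test` in the `drive_like` layout
#' ([scan_dataset()] reads them back), plus a JSON manifest recording every
#' sample's seed and the generating spec so any file can be regenerated.
#'
#' @param spec A [phantom_spec()]; its `seed` seeds the first sample.
#' @param n_train,n_test Number of training/test phantoms.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
generate_dataset <- function(spec = phantom_spec(), n_train = 20L,
                             n_test = 20L, out_dir) {
  splits <- list(train = n_train, test = n_test)
  manifest <- list(spec = unclass(spec), samples = list())
  k <- 0L
  for (sp in names(splits)) {
    for (sub in c("images", "truth", "fov"))
      dir.create(file.path(out_dir, sp, sub), recursive = TRUE,
                 showWarnings = FALSE)
    for (i in seq_len(splits[[sp]])) {
      s <- spec
      s$seed <- spec$seed + k
      pr <- generate_phantom(s)
      png::writePNG(pr$image / 255,
                    file.path(out_dir, sp, "images",
                              paste0(pr$id, ".png")))
      write_mask(pr$truth, file.path(out_dir, sp, "truth",
                                     paste0(pr$id, ".png")))
      write_mask(pr$fov, file.path(out_dir, sp, "fov",
                                   paste0(pr$id, ".png")))
      manifest$samples[[length(manifest$samples) + 1L]] <-
        list(id = pr$id, split = sp, seed = s$seed)
      k <- k + 1L
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
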