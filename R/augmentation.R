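## Paired image/mask augmentation: rotation at fixed angular steps,
## mirroring, bounded random corner-ward shifts and random crops. Every
## geometric transform is applied identically to the image, the truth mask
## and the field-of-view mask; images are interpolated bilinearly, masks
## with nearest neighbor so they stay binary.

#' Augmentation plan
#'
#' @param rotation_step_deg Angular interval of the rotation stage
#'   (default 30, i.e. 12 orientations including the identity).
#' @param shift_min_px,shift_max_px Per-axis bounds (inclusive) of the
#'   random shift magnitude in pixels (defaults 20 and 50).
#' @param n_crops Number of random crops taken per sample (default 4).
#' @param crop_size Side length of the square crops in pixels (default
#'   512).
#' @param n_shifts Number of independently shifted copies appended per
#'   sample (default 1; the corner-ward shift direction is drawn uniformly
#'   per copy). 0 disables the stage.
#' @param mirror Logical; append a left-right mirrored copy of every sample
#'   (default `TRUE`).
#' @param seed Integer seed making the whole augmented set reproducible.
#' @return An object of class `"augment_plan"`.
#' @export
augment_plan <- function(rotation_step_deg = 30, shift_min_px = 20L,
                         shift_max_px = 50L, n_crops = 4L, crop_size = 512L,
                         n_shifts = 1L, mirror = TRUE, seed = 1L) {
  if (rotation_step_deg <= 0 || rotation_step_deg > 360)
    stop("augment_plan: rotation_step_deg must be in (0, 360]")
  if (shift_min_px > shift_max_px)
    stop("augment_plan: shift_min_px must be <= shift_max_px")
  structure(list(rotation_step_deg = rotation_step_deg,
                 shift_min_px = as.integer(shift_min_px),
                 shift_max_px = as.integer(shift_max_px),
                 n_crops = as.integer(n_crops),
                 crop_size = as.integer(crop_size),
                 n_shifts = as.integer(n_shifts), mirror = isTRUE(mirror),
                 seed = as.integer(seed)),
            class = "augment_plan")
}

sample_pair <- function(image, truth, fov = NULL, id = "sample") {
  structure(list(image = image, truth = truth, fov = fov, id = id),
            class = "sample_pair")
}

#' @export
print.sample_pair <- function(x, ...) {
  d <- dim(x$truth)
  cat(sprintf("<sample_pair> '%s' %dx%d%s\n", x$id, d[1], d[2],
              if (is.null(x$fov)) "" else " (+fov)"))
  invisible(x)
}

## rotate one plane about the image center; inverse mapping with either
## bilinear sampling (images) or nearest neighbor (masks); zero fill
rotate_plane <- function(m, angle_deg, nearest) {
  H <- nrow(m); W <- ncol(m)
  if (angle_deg %% 360 == 0) return(m)
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yi <- rep(seq_len(H), times = W) - cy
  xi <- rep(seq_len(W), each = H) - cx
  ## inverse rotation of output coords back into the source frame
  sy <- cos(th) * yi + sin(th) * xi + cy
  sx <- -sin(th) * yi + cos(th) * xi + cx
  out <- numeric(H * W)
  if (nearest) {
    ry <- round(sy); rx <- round(sx)
    ok <- ry >= 1 & ry <= H & rx >= 1 & rx <= W
    out[ok] <- m[cbind(ry[ok], rx[ok])]
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    for (dy in 0:1) for (dx in 0:1) {
      yy <- y0 + dy; xx <- x0 + dx
      ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
      wgt <- (if (dy == 1) fy else 1 - fy) * (if (dx == 1) fx else 1 - fx)
      out[ok] <- out[ok] + wgt[ok] * m[cbind(yy[ok], xx[ok])]
    }
  }
  matrix(out, H, W)
}

apply_geom <- function(pair, img_fun, mask_fun, tag) {
  img <- pair$image
  if (is.matrix(img)) {
    img <- img_fun(img)
  } else {
    chans <- lapply(seq_len(dim(img)[3]), function(ch) img_fun(img[, , ch]))
    img <- array(unlist(chans), c(dim(chans[[1]]), length(chans)))
  }
  sample_pair(img, mask_fun(pair$truth),
              if (is.null(pair$fov)) NULL else mask_fun(pair$fov),
              paste0(pair$id, "/", tag))
}

#' Rotated copies of a sample
#'
#' Rotates image and masks together about the frame center at every
#' multiple of `step_deg` in `[0, 360)` (the identity copy included).
#' Images are interpolated bilinearly, masks with nearest neighbor;
#' out-of-frame regions are zero-filled.
#'
#' @param pair A `sample_pair`.
#' @param step_deg Rotation interval in degrees; a final partial step is
#'   dropped.
#' @return List of `floor(360/step_deg)` sample pairs (one when
#'   `step_deg = 360`).
#' @export
rotations <- function(pair, step_deg = 30) {
  if (step_deg <= 0) stop("rotations: step must be positive")
  angles <- seq(0, 359.999, by = step_deg)
  lapply(angles, function(a) {
    if (a %% 360 == 0) return(pair)  # identity copy keeps its id
    apply_geom(pair,
               function(m) rotate_plane(m, a, nearest = FALSE),
               function(m) rotate_plane(m, a, nearest = TRUE),
               sprintf("rot%03d", round(a)))
  })
}

#' Mirror a sample
#'
#' @param pair A `sample_pair`.
#' @param axis `"horizontal"` flips left-right (columns), `"vertical"`
#'   flips top-bottom (rows). Applying the same mirror twice restores the
#'   original.
#' @return The mirrored `sample_pair`.
#' @export
mirror <- function(pair, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  f <- if (axis == "horizontal") function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
       else function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  apply_geom(pair, f, f, paste0("mir", substr(axis, 1, 1)))
}

shift_plane <- function(m, dr, dc) {
  if (dr == 0 && dc == 0) return(m)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  sr <- seq_len(H) - dr
  sc <- seq_len(W) - dc
  okr <- sr >= 1 & sr <= H
  okc <- sc >= 1 & sc <= W
  out[okr, okc] <- m[sr[okr], sc[okc], drop = FALSE]
  out
}

#' Randomly shift a sample toward one of its corners
#'
#' Draws one of the four diagonal (corner) directions uniformly and an
#' integer magnitude per axis uniformly in `[shift_min_px, shift_max_px]`,
#' then translates image and masks together, zero-filling vacated pixels.
#' Uses the current RNG state; seed it (or use [augment_dataset()]) for
#' reproducibility.
#'
#' @param pair A `sample_pair`.
#' @param plan An [augment_plan()] providing the shift bounds.
#' @return The shifted `sample_pair`.
#' @export
random_shift <- function(pair, plan = augment_plan()) {
  d <- dim(pair$truth)
  if (plan$shift_max_px >= min(d))
    stop("random_shift: shift bound ", plan$shift_max_px,
         " exceeds image size ", min(d))
  corner <- sample(4L, 1L)  # 1 TL, 2 TR, 3 BL, 4 BR
  mag <- if (plan$shift_max_px == plan$shift_min_px)
    c(plan$shift_min_px, plan$shift_min_px)
  else sample(seq(plan$shift_min_px, plan$shift_max_px), 2L, replace = TRUE)
  dr <- ifelse(corner %in% c(1L, 2L), -mag[1], mag[1])
  dc <- ifelse(corner %in% c(1L, 3L), -mag[2], mag[2])
  apply_geom(pair, function(m) shift_plane(m, dr, dc),
             function(m) shift_plane(m, dr, dc),
             sprintf("shift%+d%+d", dr, dc))
}

#' Random square crops of a sample
#'
#' Draws `n_crops` top-left offsets uniformly over the valid positions and
#' extracts contiguous `crop_size x crop_size` patches, identical offsets
#' for image and masks.
#'
#' @param pair A `sample_pair`.
#' @param plan An [augment_plan()] providing `n_crops` and `crop_size`.
#' @return List of `n_crops` sample pairs.
#' @export
random_crops <- function(pair, plan = augment_plan()) {
  d <- dim(pair$truth)
  cs <- plan$crop_size
  if (cs > d[1] || cs > d[2])
    stop("random_crops: crop size ", cs, " larger than image ",
         d[1], "x", d[2])
  lapply(seq_len(plan$n_crops), function(k) {
    r0 <- sample.int(d[1] - cs + 1L, 1L) - 1L
    c0 <- sample.int(d[2] - cs + 1L, 1L) - 1L
    crop <- function(m) m[r0 + seq_len(cs), c0 + seq_len(cs), drop = FALSE]
    apply_geom(pair, crop, crop, sprintf("crop%d_%d_%d", k, r0, c0))
  })
}

#' Run the full augmentation pipeline over a dataset
#'
#' Stages run in order rotate, mirror, shift, crop. Rotation replaces each
#' sample by its `floor(360/step)` orientations; mirroring appends a
#' left-right flipped copy of every sample; shifting appends `n_shifts`
#' randomly shifted copies; cropping replaces each sample by its `n_crops`
#' random patches. Each output id records its transform chain. The whole
#' set is a deterministic function of `plan$seed`.
#'
#' @param pairs List of `sample_pair` objects.
#' @param plan An [augment_plan()]. Set `rotation_step_deg = 360`,
#'   `n_shifts = 0`, `n_crops = 0` etc. to disable stages.
#' @return List of augmented sample pairs.
#' @export
augment_dataset <- function(pairs, plan = augment_plan()) {
  if (length(pairs) == 0L) stop("augment_dataset: empty input")
  set.seed(plan$seed)
  out <- list()
  for (pr in pairs) out <- c(out, rotations(pr, plan$rotation_step_deg))
  if (plan$mirror) out <- c(out, lapply(out, mirror, axis = "horizontal"))
  if (plan$n_shifts > 0L) {
    shifted <- list()
    for (pr in out)
      for (k in seq_len(plan$n_shifts))
        shifted <- c(shifted, list(random_shift(pr, plan)))
    out <- c(out, shifted)
  }
  if (plan$n_crops > 0L) {
    cropped <- list()
    for (pr in out) cropped <- c(cropped, random_crops(pr, plan))
    out <- cropped
  }
  out
}
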