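## Raster I/O and dataset directory scanning. PNG via the 'png' package,
## TIFF via 'tiff' (Suggests), plain/raw PPM/PGM parsed directly (no
## installed reader exists for them). Masks round-trip losslessly through
## 8-bit PNG.

#' Read a raster image as an RGB array
#'
#' Decodes PNG, TIFF or PPM/PGM rasters into an `H x W x 3` array of 8-bit
#' intensities. Grayscale sources are replicated across the three channels;
#' alpha channels are dropped.
#'
#' @param path Path to the image file.
#' @return Numeric `H x W x 3` array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = decode_or_fail(path, function(p) png::readPNG(p) * 255),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("read_image: the 'tiff' package is required for TIFF input")
      decode_or_fail(path, function(p) tiff::readTIFF(p) * 255)
    },
    ppm = ,
    pgm = read_pnm(path),
    gif = stop("read_image: GIF is not supported; convert to PNG first"),
    stop("read_image: unsupported format '.", ext, "'"))
  to_rgb(arr)
}

decode_or_fail <- function(path, decoder) {
  tryCatch(decoder(path),
           error = function(e)
             stop("read_image: cannot decode '", path, "': ",
                  conditionMessage(e)))
}

to_rgb <- function(arr) {
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  d <- dim(arr)
  out <- if (d[3] >= 3L) arr[, , 1:3, drop = FALSE]
         else array(rep(arr[, , 1L], 3L), c(d[1], d[2], 3L))
  pmin(pmax(out, 0), 255)
}

## minimal PPM/PGM reader, plain (P2/P3) and raw 8-bit (P5/P6) variants
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("read_image: cannot decode '", path, "': not a PPM/PGM file")
  head <- integer(0)
  buf <- character(0)
  while (length(head) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "")
      stop("read_image: cannot decode '", path, "': truncated header")
    if (ch == "#") {  # comment to end of line
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "")) break
      }
    } else if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0L) {
      head <- c(head, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- head[1]; h <- head[2]; maxv <- head[3]
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.integer(readBin(con, "raw", n))
  } else {
    txt <- paste(readLines(con, warn = FALSE), collapse = " ")
    as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
  }
  if (length(vals) < n)
    stop("read_image: cannot decode '", path, "': truncated pixel data")
  vals <- vals[seq_len(n)] * (255 / maxv)
  ## PNM is row-major, channel-interleaved
  arr <- array(0, c(h, w, nch))
  for (ch in seq_len(nch))
    arr[, , ch] <- matrix(vals[seq(ch, n, by = nch)], h, w, byrow = TRUE)
  arr
}

#' Read a grayscale raster as a binary mask
#'
#' @param path Path to the raster (any format [read_image()] accepts).
#' @param threshold Intensity at or above which a pixel becomes 1
#'   (default 128).
#' @return Integer 0/1 matrix.
#' @export
read_mask <- function(path, threshold = 128) {
  arr <- read_image(path)
  g <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
  (g >= threshold) * 1L
}

#' Write a mask or probability map as an 8-bit PNG
#'
#' Binary masks are written as 0/255; probability maps in `[0, 1]` are
#' scaled by 255 and rounded to the nearest integer (ties to even, R's
#' `round`), so a 0.5 map stores 128. Binary masks round-trip exactly
#' through [read_mask()].
#'
#' @param mask 0/1 matrix or probability matrix in `[0, 1]`.
#' @param path Output path; the parent directory must exist.
#' @export
write_mask <- function(mask, path) {
  if (!dir.exists(dirname(path)))
    stop("write_mask: directory does not exist: ", dirname(path))
  if (any(mask < 0 | mask > 1))
    stop("write_mask: values must lie in [0, 1]")
  v8 <- round(mask * 255)
  png::writePNG(v8 / 255, path)
  invisible(path)
}

#' Enumerate a dataset directory into sample pairs
#'
#' Matches images to ground-truth (and optional field-of-view) rasters by
#' shared file stem and returns them in deterministic lexicographic stem
#' order. Layouts `"drive_like"` and `"stare_like"` expect subdirectories
#' `images/` and `truth/` (plus optional `fov/`; STARE-style trees simply
#' have none). Layout `"flat"` expects `<stem>.<ext>`, `<stem>_truth.<ext>`
#' and optional `<stem>_fov.<ext>` side by side in the root.
#'
#' @param root Dataset directory.
#' @param layout One of `"drive_like"`, `"stare_like"`, `"flat"`.
#' @return List of `sample_pair` objects (image, truth, optional fov, id).
#' @export
scan_dataset <- function(root, layout = c("drive_like", "stare_like",
                                          "flat")) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) stop("scan_dataset: no such directory: ", root)
  exts <- "\\.(png|tif|tiff|ppm|pgm)$"
  stem <- function(f) sub(exts, "", basename(f), ignore.case = TRUE)
  if (layout == "flat") {
    files <- sort(list.files(root, pattern = exts, ignore.case = TRUE))
    st <- stem(files)
    truth_f <- files[grepl("_truth$", st)]
    fov_f <- files[grepl("_fov$", st)]
    img_f <- setdiff(files, c(truth_f, fov_f))
    img_s <- stem(img_f)
    tr_s <- sub("_truth$", "", stem(truth_f))
    fov_s <- sub("_fov$", "", stem(fov_f))
  } else {
    img_f <- sort(list.files(file.path(root, "images"), pattern = exts,
                             full.names = FALSE, ignore.case = TRUE))
    truth_f <- sort(list.files(file.path(root, "truth"), pattern = exts,
                               full.names = FALSE, ignore.case = TRUE))
    fov_f <- if (dir.exists(file.path(root, "fov")))
      sort(list.files(file.path(root, "fov"), pattern = exts,
                      ignore.case = TRUE)) else character(0)
    img_s <- stem(img_f)
    tr_s <- stem(truth_f)
    fov_s <- stem(fov_f)
  }
  orphans <- c(setdiff(img_s, tr_s), setdiff(tr_s, img_s))
  if (length(orphans) > 0L)
    stop("scan_dataset: unpaired images/truths: ",
         paste(sort(unique(orphans)), collapse = ", "))
  o <- order(img_s)
  img_f <- img_f[o]; img_s <- img_s[o]
  prefix <- function(f, sub) if (layout == "flat") file.path(root, f)
    else file.path(root, sub, f)
  lapply(seq_along(img_f), function(k) {
    s <- img_s[k]
    tf <- truth_f[match(s, tr_s)]
    ff <- if (s %in% fov_s) fov_f[match(s, fov_s)] else NA
    sample_pair(
      image = read_image(prefix(img_f[k], "images")),
      truth = read_mask(prefix(tf, "truth")),
      fov = if (is.na(ff)) NULL else read_mask(prefix(ff, "fov")),
      id = s)
  })
}
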