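# Shared fixtures built in code: tiny phantoms, toy tensors, temp rasters.

tiny_phantom <- function(seed = 1L, size = 64L)
  generate_phantom(phantom_spec(size = size, seed = seed))

random_tensor <- function(H, W, C = 1L, N = 1L)
  array(stats::rnorm(H * W * C * N), c(H, W, C, N))

# probabilities strictly inside (0, 1) and away from the penalty kink
interior_probs <- function(n, margin = 0.02) {
  p <- stats::runif(n, 0.02, 0.98)
  shift <- abs(p - 0.5) < margin
  p[shift] <- p[shift] + ifelse(p[shift] >= 0.5, margin, -margin)
  p
}

write_tmp_png <- function(img01, name = "img.png") {
  path <- withr::local_tempfile(fileext = ".png",
                                .local_envir = parent.frame())
  png::writePNG(img01, path)
  path
}

# brute-force Mann-Whitney pair-counting AUC (ties count one half)
pair_count_auc <- function(p, y) {
  pp <- p[y == 1]
  pn <- p[y == 0]
  cmp <- outer(pp, pn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
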