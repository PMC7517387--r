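toy_pair <- function(H = 9, W = 9) {
  img <- array(runif(H * W * 3, 0, 255), c(H, W, 3))
  truth <- matrix(0L, H, W)
  truth[3, 4] <- 1L
  sample_pair(img, truth, fov = matrix(1L, H, W), id = "toy")
}

test_that("rotation count follows the angular step", {
  pr <- toy_pair()
  expect_length(rotations(pr, 30), 12)
  expect_length(rotations(pr, 90), 4)
  # step = 360 yields the identity copy only
  r360 <- rotations(pr, 360)
  expect_length(r360, 1)
  expect_identical(r360[[1]]$truth, pr$truth)
  expect_error(rotations(pr, 0), "positive")
})

test_that("90-degree rotations move a corner pixel around the corners", {
  # 3x3 mask with a single on-pixel at (1,1): under successive 90-degree
  # rotations about the center it must visit all four corners
  truth <- matrix(0L, 3, 3); truth[1, 1] <- 1L
  pr <- sample_pair(array(0, c(3, 3, 3)), truth, id = "c")
  rots <- rotations(pr, 90)
  corners <- lapply(rots, function(p) which(p$truth == 1, arr.ind = TRUE))
  got <- do.call(rbind, corners)
  expect_equal(nrow(got), 4)
  expect_setequal(paste(got[, 1], got[, 2]),
                  c("1 1", "1 3", "3 3", "3 1"))
})

test_that("rotation keeps masks binary and transforms image and mask together", {
  set.seed(5)
  pr <- toy_pair(16, 16)
  pr$truth <- matrix(rbinom(256, 1, 0.3), 16, 16)
  for (a in c(30, 45, 120)) {
    rp <- rotations(pr, a)[[2]]
    expect_true(all(rp$truth %in% c(0, 1)))
    # the same geometric map applies to image and mask: rotating a mask
    # embedded as an image channel must agree with the mask rotation
    pr2 <- pr
    pr2$image <- array(rep(pr$truth * 255, 3), c(16, 16, 3))
    rp2 <- rotations(pr2, a)[[2]]
    near <- abs((rp2$image[, , 1] >= 127.5) * 1 - rp2$truth)
    expect_lt(mean(near), 0.1)  # bilinear vs nearest differ only at edges
  }
})

test_that("mirroring is an involution that preserves vessel count", {
  pr <- toy_pair()
  mh <- mirror(pr, "horizontal")
  expect_equal(sum(mh$truth), sum(pr$truth))
  # on-pixel at column 4 of width 9 moves to column 9 - 4 + 1 = 6
  expect_equal(which(mh$truth == 1, arr.ind = TRUE)[1, "col"],
               c(col = 6))
  back <- mirror(mh, "horizontal")
  expect_identical(back$truth, pr$truth)
  expect_equal(back$image, pr$image)
  mv <- mirror(pr, "vertical")
  expect_equal(which(mv$truth == 1, arr.ind = TRUE)[1, "row"],
               c(row = 7))
})

test_that("shifts move pixels by the drawn offset and zero-fill", {
  pr <- toy_pair(40, 40)
  pr$truth <- matrix(0L, 40, 40); pr$truth[25, 25] <- 1L
  plan <- augment_plan(shift_min_px = 20, shift_max_px = 20)
  # force the top-left corner draw
  set.seed(1)
  repeat {
    st <- .Random.seed
    s <- random_shift(pr, plan)
    pos <- which(s$truth == 1, arr.ind = TRUE)
    if (grepl("shift-20-20", s$id)) break
  }
  expect_equal(unname(pos), matrix(c(5, 5), 1))
  # zero-magnitude shift is the identity
  plan0 <- augment_plan(shift_min_px = 0, shift_max_px = 0)
  s0 <- random_shift(pr, plan0)
  expect_identical(s0$truth, pr$truth)
  expect_error(random_shift(toy_pair(9, 9), plan), "exceeds")
  # determinism under a fixed seed
  set.seed(99); a <- random_shift(pr, plan)
  set.seed(99); b <- random_shift(pr, plan)
  expect_identical(a, b)
})

test_that("random crops are contiguous sub-arrays with shared offsets", {
  set.seed(3)
  pr <- toy_pair(20, 20)
  plan <- augment_plan(n_crops = 4, crop_size = 8)
  crops <- random_crops(pr, plan)
  expect_length(crops, 4)
  for (cp in crops) {
    expect_equal(dim(cp$truth), c(8, 8))
    off <- as.integer(strsplit(sub(".*crop\\d+_", "", cp$id), "_")[[1]])
    expect_identical(cp$truth,
                     pr$truth[off[1] + 1:8, off[2] + 1:8])
    expect_equal(cp$image, pr$image[off[1] + 1:8, off[2] + 1:8, ])
  }
  # crop the full frame: all copies identical to the source
  full <- random_crops(pr, augment_plan(n_crops = 2, crop_size = 20))
  expect_identical(full[[1]]$truth, pr$truth)
  expect_identical(full[[2]]$truth, pr$truth)
  expect_error(random_crops(pr, augment_plan(crop_size = 64)), "larger")
})

test_that("the pipeline multiplies counts predictably and reproducibly", {
  set.seed(8)
  prs <- list(toy_pair(24, 24), toy_pair(24, 24))
  plan <- augment_plan(rotation_step_deg = 90, shift_min_px = 2,
                       shift_max_px = 4, n_crops = 2, crop_size = 16,
                       n_shifts = 1, seed = 7)
  out <- augment_dataset(prs, plan)
  # 2 sources x 4 rotations x 2 (mirror) x 2 (original + shifted) x 2 crops
  expect_length(out, 2 * 4 * 2 * 2 * 2)
  expect_true(all(vapply(out, function(p) all(p$truth %in% 0:1),
                         logical(1))))
  # byte-identical under the same plan seed
  out2 <- augment_dataset(prs, plan)
  expect_identical(out, out2)
  # disabled pipeline returns the input unchanged
  off <- augment_plan(rotation_step_deg = 360, n_shifts = 0, n_crops = 0,
                      mirror = FALSE)
  expect_identical(augment_dataset(prs, off), prs)
})
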