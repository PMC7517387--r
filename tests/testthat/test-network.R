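test_that("max pooling records the argmax of each window", {
  # window [[1,3],[2,0]] -> max 3 at in-window position (0,1)
  x <- matrix(c(1, 2, 3, 0), 2, 2)  # column-major: rows (1,3),(2,0)
  res <- max_pool_with_indices(x)
  expect_equal(as.numeric(res$y), 3)
  expect_equal(as.integer(res$idx), 1L)  # code 2*di + dj = 0*2 + 1
  # constant window: first position in row-major scan wins the tie
  res2 <- max_pool_with_indices(matrix(5, 2, 2))
  expect_equal(as.numeric(res2$y), 5)
  expect_equal(as.integer(res2$idx), 0L)
})

test_that("pooled values equal a brute-force window maximum", {
  set.seed(4)
  x <- random_tensor(8, 8, 3, 2)
  res <- max_pool_with_indices(x)
  for (n in 1:2) for (ch in 1:3) for (i in 1:4) for (j in 1:4) {
    win <- x[2 * i - 1:0, 2 * j - 1:0, ch, n]
    expect_equal(res$y[i, j, ch, n], max(win))
  }
})

test_that("unpooling places window maxima back at their argmax positions", {
  # value 3 recorded at in-window position (0,1) -> window [[0,3],[0,0]]
  v <- array(3, c(1, 1, 1, 1))
  idx <- array(1L, c(1, 1, 1, 1))
  up <- unpool_with_indices(v, idx)
  expect_equal(up[, , 1, 1], matrix(c(0, 0, 3, 0), 2, 2))
  # round trip: one nonzero per window, exactly at the argmax of x
  set.seed(8)
  for (rep in 1:20) {
    x <- random_tensor(8, 8, 2, 2)
    pool <- max_pool_with_indices(x)
    up <- unpool_with_indices(pool$y, pool$idx)
    expect_equal(sum(up != 0), 8 * 8 / 4 * 2 * 2)
    nz <- which(up != 0)
    expect_true(all(up[nz] == x[nz]))
    ok <- TRUE
    for (n in 1:2) for (ch in 1:2) for (i in 1:4) for (j in 1:4) {
      win <- up[2 * i - 1:0, 2 * j - 1:0, ch, n]
      src <- x[2 * i - 1:0, 2 * j - 1:0, ch, n]
      ok <- ok && win[which.max(src)] == max(src)
    }
    expect_true(ok)
  }
  expect_error(unpool_with_indices(array(0, c(2, 2, 1, 1)),
                                   array(0L, c(1, 1, 1, 1))), "shape")
})

test_that("multi-scale block concatenates branch widths out/4 : out/2 : out/4", {
  net <- build_msffu_net(network_spec(depth = 1, base_channels = 16),
                         seed = 1)
  s <- net_summary(net)
  blk <- s[grepl("^enc1_b1", s$layer), ]
  expect_equal(blk$out_channels[blk$layer == "enc1_b1_a"], 4)
  expect_equal(blk$out_channels[blk$layer == "enc1_b1_b2"], 8)
  expect_equal(blk$out_channels[blk$layer == "enc1_b1_c3"], 4)
  expect_equal(blk$out_channels[blk$layer == "enc1_b1_out"], 16)
  # the stacked-3x3 branch has two 3x3 stages (5x5 receptive field)
  c_layers <- net$layers[vapply(net$layers, function(l)
    grepl("^enc1_b1_c[23]$", l$name), logical(1))]
  expect_equal(vapply(c_layers, `[[`, integer(1), "kh"), c(3L, 3L))
  expect_error(network_spec(base_channels = 6), "divisible by 4")
})

test_that("encoder channel widths double at every stage", {
  net <- build_msffu_net(network_spec(depth = 3, base_channels = 8),
                         seed = 1)
  s <- net_summary(net)
  stage_out <- s$out_channels[match(paste0("enc", 1:3, "_b2_out"), s$layer)]
  expect_equal(stage_out, c(8, 16, 32))
  expect_equal(s$out_channels[s$layer == "bott_b2_out"], 64)
})

test_that("forward pass preserves spatial size and stays in [0, 1]", {
  set.seed(6)
  for (depth in 1:2) for (base in c(8L, 16L)) {
    net <- build_msffu_net(network_spec(depth = depth,
                                        base_channels = base), seed = 1)
    x <- array(runif(32 * 32), c(32, 32, 1, 1))
    out <- forward_net(net, x)$out
    expect_equal(dim(out), c(32, 32, 1, 1))
    expect_true(all(is.finite(out)))
    expect_true(all(out >= 0 & out <= 1))
  }
  # baseline U-Net obeys the same contract
  netu <- build_unet(network_spec(depth = 2, base_channels = 8,
                                  block = "unet"), seed = 2)
  outu <- forward_net(netu, array(runif(32 * 32), c(32, 32, 1, 1)))$out
  expect_true(all(outu >= 0 & outu <= 1))
  # indivisible input raises an explicit shape error
  net1 <- build_msffu_net(network_spec(depth = 2, base_channels = 8),
                          seed = 1)
  expect_error(forward_net(net1, array(0, c(30, 30, 1, 1))),
               "divisible")
})

test_that("pooling halves and upsampling doubles sizes stage by stage", {
  net <- build_msffu_net(network_spec(depth = 2, base_channels = 8),
                         seed = 3)
  fw <- forward_net(net, array(runif(64 * 64), c(64, 64, 1, 1)))
  expect_equal(dim(fw$buf$pool1)[1:2], c(32, 32))
  expect_equal(dim(fw$buf$pool2)[1:2], c(16, 16))
  expect_equal(dim(fw$buf$bott_b2_out)[1:2], c(16, 16))
  expect_equal(dim(fw$buf$dec2_up)[1:2], c(32, 32))
  expect_equal(dim(fw$buf$dec1_c2)[1:2], c(64, 64))
})

test_that("network builds are reproducible from a seed", {
  n1 <- build_msffu_net(network_spec(depth = 1, base_channels = 8), seed = 9)
  n2 <- build_msffu_net(network_spec(depth = 1, base_channels = 8), seed = 9)
  expect_identical(n1$params, n2$params)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  expect_identical(forward_net(n1, x)$out, forward_net(n2, x)$out)
  # parameter count is positive and reported
  expect_gt(sum(net_summary(n1)$n_params), 0)
})

test_that("prediction thresholds behave monotonically", {
  net <- build_msffu_net(network_spec(depth = 1, base_channels = 8),
                         seed = 5)
  img <- matrix(runif(32 * 32), 32, 32)
  r0 <- predict_mask(net, img, threshold = 0)
  r1 <- predict_mask(net, img, threshold = 1 + 1e-9)
  expect_true(all(r0$mask == 1))
  expect_true(all(r1$mask == 0))
  ths <- c(0.2, 0.4, 0.6, 0.8)
  counts <- vapply(ths, function(t) sum(predict_mask(net, img, t)$mask),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # undivisible sizes are padded and cropped back
  odd <- matrix(runif(33 * 37), 33, 37)
  res <- predict_mask(net, odd)
  expect_equal(dim(res$prob), c(33, 37))
  expect_true(all(res$prob >= 0 & res$prob <= 1))
})

test_that("network parameter gradients match finite differences", {
  set.seed(12)
  net <- build_msffu_net(network_spec(depth = 1, base_channels = 8),
                         seed = 31)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  y <- array(rbinom(256, 1, 0.2), c(16, 16, 1, 1))
  lp <- loss_params(lambda_l2 = 0)
  fw <- forward_net(net, x, train = TRUE)
  dp <- vesselseg:::combined_grad(fw$out, y, lp)
  bw <- vesselseg:::backward_net(net, fw, dp)
  h <- 1e-6
  lossfun <- function(n)
    combined_cost(forward_net(n, x, train = TRUE)$out, y, lp)
  worst <- 0
  for (nm in sample(names(bw$grads), 6)) {
    f <- "w"
    g <- bw$grads[[nm]][[f]]
    for (i in sample(length(g), 2)) {
      n2 <- net
      n2$params[[nm]][[f]][i] <- net$params[[nm]][[f]][i] + h
      up <- lossfun(n2)
      n2$params[[nm]][[f]][i] <- net$params[[nm]][[f]][i] - h
      dn <- lossfun(n2)
      fd <- (up - dn) / (2 * h)
      worst <- max(worst, abs(fd - g[i]) / max(abs(fd), abs(g[i]), 1e-4))
    }
  }
  expect_lt(worst, 1e-2)  # finite differences cross leaky-ReLU kinks
})
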