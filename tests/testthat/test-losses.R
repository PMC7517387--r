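test_that("soft Dice matches direct evaluation of the overlap formula", {
  lp <- loss_params(dice_smooth = 0)
  # |A| = |B| = 10, overlap 5  ->  1 - 2*5/20 = 0.5
  y <- c(rep(1, 10), rep(0, 10))
  p <- c(rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 5))
  expect_equal(dice_loss(p, y, lp), 0.5, tolerance = 1e-12)
  # identical binary prediction -> 0; disjoint supports -> 1
  expect_equal(dice_loss(y, y, lp), 0)
  expect_equal(dice_loss(1 - y, y, lp), 1)
  # smoothing keeps the empty-prediction case finite
  expect_lt(dice_loss(rep(0, 4), rep(0, 4), loss_params()), 1e-6)
  expect_error(dice_loss(numeric(0), numeric(0)), "empty")
})

test_that("cost-sensitive cross-entropy applies the penalty matrix per pixel", {
  lp <- loss_params()
  # vessel pixel confidently right: weight 1
  expect_equal(cost_sensitive_ce(0.9, 1, lp), -log(0.9), tolerance = 1e-9)
  # vessel pixel predicted background (p <= 0.5): weight 1 + 6 = 7
  expect_equal(cost_sensitive_ce(0.4, 1, lp), -7 * log(0.4),
               tolerance = 1e-9)
  # background pixels are never re-weighted
  expect_equal(cost_sensitive_ce(0.1, 0, lp), -log(0.9), tolerance = 1e-9)
  expect_equal(cost_sensitive_ce(0.6, 0, lp), -log(0.4), tolerance = 1e-9)
  # mean over pixels
  expect_equal(cost_sensitive_ce(c(0.9, 0.4), c(1, 1), lp),
               (-log(0.9) - 7 * log(0.4)) / 2, tolerance = 1e-9)
  expect_error(cost_sensitive_ce(1.2, 1, lp), "\\[0, 1\\]")
})

test_that("cost-sensitive CE dominates plain CE exactly when the indicator fires", {
  set.seed(42)
  plain <- loss_params(vessel_penalty = 0)
  lp <- loss_params()
  for (i in 1:20) {
    n <- sample(5:40, 1)
    y <- rbinom(n, 1, 0.3)
    p <- runif(n, 0.01, 0.99)
    cs <- cost_sensitive_ce(p, y, lp)
    pl <- cost_sensitive_ce(p, y, plain)
    if (any(y == 1 & p <= 0.5)) expect_gt(cs, pl) else expect_equal(cs, pl)
  }
})

test_that("combined cost blends linearly in alpha with the L2 term added", {
  set.seed(7)
  y <- rbinom(16, 1, 0.4)
  p <- interior_probs(16)
  d <- dice_loss(p, y, loss_params(alpha = 1, lambda_l2 = 0))
  ce <- cost_sensitive_ce(p, y, loss_params())
  # endpoint identities
  expect_identical(combined_cost(p, y, loss_params(alpha = 1, lambda_l2 = 0)), d)
  expect_identical(combined_cost(p, y, loss_params(alpha = 0, lambda_l2 = 0)), ce)
  # alpha = 0.5, lambda = 0.1, sum(W^2) = 4  ->  0.5 d + 0.5 ce + 0.2
  expect_equal(combined_cost(p, y, loss_params(alpha = 0.5, lambda_l2 = 0.1),
                             weight_norm_sq = 4),
               0.5 * d + 0.5 * ce + 0.2, tolerance = 1e-12)
  # three-point collinearity in alpha
  at <- function(a) combined_cost(p, y, loss_params(alpha = a, lambda_l2 = 0))
  expect_equal(at(0.5), (at(0) + at(1)) / 2, tolerance = 1e-12)
  expect_error(loss_params(alpha = 1.5), "alpha")
})

test_that("Dice of a multi-image batch is averaged per image", {
  set.seed(11)
  p <- array(runif(4 * 4 * 2), c(4, 4, 1, 2))
  y <- array(rbinom(32, 1, 0.4), c(4, 4, 1, 2))
  lp <- loss_params(alpha = 1, lambda_l2 = 0)
  per_img <- mean(c(dice_loss(p[, , , 1], y[, , , 1], lp),
                    dice_loss(p[, , , 2], y[, , , 2], lp)))
  expect_equal(combined_cost(p, y, lp), per_img, tolerance = 1e-12)
})

test_that("analytic loss gradients agree with central finite differences", {
  set.seed(3)
  y <- rbinom(50, 1, 0.3)
  p <- interior_probs(50)
  expect_lt(gradient_check("dice", p, y), 1e-4)
  expect_lt(gradient_check("cross_entropy", p, y), 1e-4)
  expect_lt(gradient_check("combined", p, y), 1e-4)
})

test_that("gradient check flags evaluation across the indicator kink", {
  p <- c(0.5, 0.8)   # first pixel sits exactly on the threshold
  y <- c(1, 1)
  expect_warning(res <- gradient_check("cross_entropy", p, y), "kink")
  expect_true(isTRUE(attr(res, "kink")))
})

test_that("loss is monotone in p on either side of the penalty threshold", {
  lp <- loss_params()
  left <- seq(0.05, 0.45, by = 0.05)
  right <- seq(0.55, 0.95, by = 0.05)
  vl <- vapply(left, function(p) cost_sensitive_ce(p, 1, lp), numeric(1))
  vr <- vapply(right, function(p) cost_sensitive_ce(p, 1, lp), numeric(1))
  expect_true(all(diff(vl) < 0))
  expect_true(all(diff(vr) < 0))
})
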