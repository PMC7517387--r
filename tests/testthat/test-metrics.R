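test_that("confusion counts match hand enumeration and respect the FOV", {
  truth <- matrix(c(1, 1, 0, 0), 2, 2)
  pred <- matrix(c(1, 0, 0, 1), 2, 2)
  cc <- confusion(pred, truth)
  expect_equal(unclass(cc)[c("tp", "fn", "tn", "fp")],
               list(tp = 1, fn = 1, tn = 1, fp = 1))
  # perfect self-agreement
  m <- matrix(rbinom(36, 1, 0.4), 6, 6)
  cc2 <- confusion(m, m)
  expect_equal(cc2$tp, sum(m))
  expect_equal(cc2$tn, sum(m == 0))
  expect_equal(cc2$fp + cc2$fn, 0)
  # FOV restriction drops outside pixels
  fov <- matrix(0, 2, 2); fov[1, 1] <- 1
  cc3 <- confusion(pred, truth, fov)
  expect_equal(cc3$tp + cc3$tn + cc3$fp + cc3$fn, 1)
  expect_warning(confusion(pred, truth, matrix(0, 2, 2)), "empty")
  expect_error(confusion(matrix(0, 2, 3), truth), "shape")
})

test_that("sensitivity/specificity/accuracy follow their defining ratios", {
  m <- sen_spe_acc(list(tp = 1, fn = 1, tn = 1, fp = 1))
  expect_equal(unname(m), c(0.5, 0.5, 0.5))
  expect_equal(unname(sen_spe_acc(list(tp = 5, fn = 0, tn = 7, fp = 0))),
               c(1, 1, 1))
  # all-background prediction on mixed truth
  expect_equal(unname(sen_spe_acc(list(tp = 0, fn = 4, tn = 6, fp = 0))),
               c(0, 1, 0.6))
  # undefined metrics are NA with a reason, not silent zeros
  expect_warning(m2 <- sen_spe_acc(list(tp = 0, fn = 0, tn = 3, fp = 1)),
                 "no positive")
  expect_true(is.na(m2["sen"]))
})

test_that("accuracy is the prevalence-weighted mix of sen and spe", {
  set.seed(5)
  for (i in 1:25) {
    cc <- list(tp = sample(0:50, 1), fn = sample(0:50, 1),
               tn = sample(0:50, 1), fp = sample(0:50, 1))
    npos <- cc$tp + cc$fn
    nneg <- cc$tn + cc$fp
    if (npos == 0 || nneg == 0) next
    m <- sen_spe_acc(cc)
    expect_equal(unname(m["acc"]),
                 unname((npos * m["sen"] + nneg * m["spe"]) / (npos + nneg)),
                 tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC equals the pair-counting statistic", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(50:400, 1)
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0 || sum(y) == n) next
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    roc <- roc_auc(p, y)
    expect_equal(roc$auc, pair_count_auc(p, y), tolerance = 1e-9)
  }
})

test_that("ROC endpoints, monotonicity, and limit cases hold", {
  set.seed(2)
  y <- rbinom(200, 1, 0.25)
  p <- runif(200)
  roc <- roc_auc(p, y)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(roc$points$fpr[nrow(roc$points)], 1)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  # perfect ranking and constant prediction
  expect_equal(roc_auc(y * 0.9 + 0.05, y)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 200), y)$auc, 0.5)
  expect_warning(r <- roc_auc(p, rep(1, 200)), "single class")
  expect_true(is.na(r$auc))
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(13)
  y <- rbinom(300, 1, 0.2)
  p <- runif(300)
  a0 <- roc_auc(p, y)$auc
  expect_equal(roc_auc(plogis(5 * p - 2), y)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(p^3, y)$auc, a0, tolerance = 1e-12)
})

test_that("hand-built AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- rbinom(500, 1, 0.3)
  p <- runif(500)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE)))
  expect_equal(roc_auc(p, y)$auc, ref, tolerance = 1e-9)
})

test_that("dataset evaluation pools confusion counts across images", {
  pr <- tiny_phantom(seed = 31, size = 64)
  net <- build_msffu_net(network_spec(depth = 1, base_channels = 8),
                         seed = 1)
  tab <- evaluate_dataset(net, list(pr), threshold = 0.5)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$id[2], "pooled")
  # single image: pooled row equals the per-image row
  expect_equal(tab$sen[1], tab$sen[2])
  expect_equal(tab$acc[1], tab$acc[2])
  # duplicating the image leaves pooled rates unchanged
  tab2 <- evaluate_dataset(net, list(pr, pr), threshold = 0.5)
  expect_equal(tab2$sen[3], tab$sen[2], tolerance = 1e-12)
  expect_equal(tab2$spe[3], tab$spe[2], tolerance = 1e-12)
})
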