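## Pixel-classification evaluation: confusion counts, sensitivity /
## specificity / accuracy, ROC curves with trapezoidal AUC, and dataset
## level aggregation. "Positive" is always the vessel class.

#' Confusion counts between a predicted and a reference mask
#'
#' @param pred Binary 0/1 prediction matrix.
#' @param truth Binary 0/1 reference matrix of the same size.
#' @param fov Optional 0/1 field-of-view mask: only pixels with `fov == 1`
#'   are counted. When absent the whole frame is evaluated.
#' @return Object of class `"confusion_counts"`: list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(pred, truth, fov = NULL) {
  if (!identical(dim(pred), dim(truth)))
    stop("confusion: pred and truth shapes differ")
  keep <- if (is.null(fov)) TRUE else {
    if (!identical(dim(fov), dim(truth)))
      stop("confusion: fov shape differs from truth")
    fov == 1
  }
  p <- as.numeric(pred)[keep]
  t <- as.numeric(truth)[keep]
  if (length(p) == 0L)
    warning("confusion: field of view is empty; all counts are zero")
  structure(list(tp = sum(p == 1 & t == 1), tn = sum(p == 0 & t == 0),
                 fp = sum(p == 1 & t == 0), fn = sum(p == 0 & t == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  FN %d  FP %d  TN %d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sen = TP/(TP+FN), Spe = TN/(FP+TN), Acc = (TP+TN)/(TP+FN+TN+FP). A zero
#' denominator yields `NA` for that metric with a warning naming the cause,
#' never a silent zero.
#'
#' @param counts A `"confusion_counts"` object (or list with tp/tn/fp/fn).
#' @return Named numeric vector `c(sen, spe, acc)`, entries in `[0, 1]` or
#'   `NA`.
#' @export
sen_spe_acc <- function(counts) {
  with(counts, {
    tot <- tp + fn + tn + fp
    sen <- if (tp + fn > 0) tp / (tp + fn) else {
      warning("sensitivity undefined: no positive pixels in reference")
      NA_real_
    }
    spe <- if (fp + tn > 0) tn / (fp + tn) else {
      warning("specificity undefined: no negative pixels in reference")
      NA_real_
    }
    acc <- if (tot > 0) (tp + tn) / tot else {
      warning("accuracy undefined: no pixels evaluated")
      NA_real_
    }
    c(sen = sen, spe = spe, acc = acc)
  })
}

#' ROC curve and trapezoidal AUC for a probability map
#'
#' Sweeps the decision threshold over the sorted unique predicted
#' probabilities, computing (FPR, TPR) at each, forces the (0,0) and (1,1)
#' endpoints, and integrates by the trapezoidal rule. The AUC is computed on
#' the full unique-threshold curve (and therefore equals the Mann-Whitney
#' two-sample statistic, ties counted one half); the stored `points` are
#' subsampled to at most `n_thresholds` rows for plotting.
#'
#' @param prob Matrix (or vector) of vessel probabilities in `[0, 1]`.
#' @param truth Binary 0/1 reference of the same size.
#' @param fov Optional 0/1 field-of-view mask restricting evaluation.
#' @param n_thresholds Maximum number of stored curve points.
#' @return Object of class `"roc_curve"`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`) and `auc`. Single-class truth yields
#'   `auc = NA` with a warning.
#' @export
roc_auc <- function(prob, truth, fov = NULL, n_thresholds = 256L) {
  keep <- if (is.null(fov)) rep(TRUE, length(prob)) else as.numeric(fov) == 1
  p <- as.numeric(prob)[keep]
  y <- as.numeric(truth)[keep]
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  if (npos == 0L || nneg == 0L) {
    warning("roc_auc: truth contains a single class; AUC undefined")
    return(structure(list(points = data.frame(threshold = numeric(0),
                                              fpr = numeric(0),
                                              tpr = numeric(0)),
                          auc = NA_real_), class = "roc_curve"))
  }
  o <- order(p, decreasing = TRUE)
  ps <- p[o]
  ys <- y[o]
  ct <- cumsum(ys)            # TP when thresholding at ps[i] (inclusive)
  cf <- seq_along(ys) - ct    # FP
  last <- cumsum(rle(ps)$lengths)  # last index of each tied block
  tpr <- c(0, ct[last] / npos, 1)
  fpr <- c(0, cf[last] / nneg, 1)
  thr <- c(Inf, ps[last], -Inf)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  ii <- unique(round(seq(1, length(thr), length.out =
                           min(n_thresholds, length(thr)))))
  structure(list(points = data.frame(threshold = thr[ii], fpr = fpr[ii],
                                     tpr = tpr[ii]),
                 auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.4f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Evaluate a model over a dataset of sample pairs
#'
#' Preprocesses each image (green channel + CLAHE + rescale to `[0, 1]`),
#' segments it, and tabulates per-image sensitivity, specificity, accuracy
#' and AUC plus a micro-pooled row (confusion counts summed over images
#' before computing the rates; its AUC is computed over the pooled pixels).
#'
#' @param model A `"vessel_net"` or fitted `"vessel_model"`.
#' @param pairs List of `sample_pair` objects (see [scan_dataset()] /
#'   [generate_phantom()]).
#' @param preprocessing A [clahe_params()] used on every image.
#' @param threshold Probability cutoff for the binary mask.
#' @param use_fov Restrict metrics to the field-of-view mask when one is
#'   present (default `TRUE`).
#' @return Data frame with one row per image plus a final `"pooled"` row;
#'   columns `id`, `sen`, `spe`, `acc`, `auc`.
#' @export
evaluate_dataset <- function(model, pairs, preprocessing = clahe_params(),
                             threshold = 0.5, use_fov = TRUE) {
  if (length(pairs) == 0L) stop("evaluate_dataset: empty dataset")
  rows <- vector("list", length(pairs))
  pool <- list(tp = 0, tn = 0, fp = 0, fn = 0)
  pool_p <- list()
  pool_y <- list()
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    img <- preprocess_image(pr$image, preprocessing)
    res <- tryCatch(predict_mask(model, img, threshold),
                    error = function(e)
                      stop("evaluate_dataset: image '", pr$id, "': ",
                           conditionMessage(e)))
    fov <- if (use_fov) pr$fov else NULL
    cc <- confusion(res$mask, pr$truth, fov)
    m <- suppressWarnings(sen_spe_acc(cc))
    au <- suppressWarnings(roc_auc(res$prob, pr$truth, fov)$auc)
    rows[[k]] <- data.frame(id = pr$id, sen = m["sen"], spe = m["spe"],
                            acc = m["acc"], auc = au)
    for (nm in names(pool)) pool[[nm]] <- pool[[nm]] + cc[[nm]]
    keep <- if (is.null(fov)) TRUE else fov == 1
    pool_p[[k]] <- as.numeric(res$prob)[keep]
    pool_y[[k]] <- as.numeric(pr$truth)[keep]
  }
  mp <- suppressWarnings(sen_spe_acc(structure(pool,
                                               class = "confusion_counts")))
  aup <- suppressWarnings(roc_auc(unlist(pool_p), unlist(pool_y))$auc)
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(id = "pooled", sen = mp["sen"],
                               spe = mp["spe"], acc = mp["acc"], auc = aup))
  rownames(out) <- NULL
  out
}
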