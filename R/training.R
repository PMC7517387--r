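## Training: plain stochastic gradient descent on the combined
## Dice + cost-sensitive cross-entropy objective, with a step learning-rate
## schedule (multiply by a fixed factor every fixed number of epochs),
## per-epoch validation metrics, and best-by-validation-Dice retention.

#' Training configuration
#'
#' Defaults follow the reference optimization recipe for full-scale runs:
#' initial learning rate 0.001 multiplied by 0.1 every 20 epochs, batch
#' size 20, 100 epochs, plain SGD. Scaled-down runs override these.
#'
#' @param lr_init Initial learning rate (> 0).
#' @param lr_decay_factor Multiplier applied to the learning rate at every
#'   decay step (in `(0, 1]`).
#' @param lr_decay_every Number of epochs between decays.
#' @param batch_size Images per SGD step.
#' @param epochs Number of full passes over the training set.
#' @param momentum SGD momentum (default 0, plain SGD).
#' @param seed Integer seed for initialization and batch shuffling.
#' @param loss A [loss_params()].
#' @param network A [network_spec()].
#' @param checkpoint_every Keep a parameter snapshot every this many epochs
#'   (0 = only the best-by-validation snapshot).
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(lr_init = 0.001, lr_decay_factor = 0.1,
                         lr_decay_every = 20L, batch_size = 20L,
                         epochs = 100L, momentum = 0, seed = 1L,
                         loss = loss_params(), network = network_spec(),
                         checkpoint_every = 0L) {
  if (lr_init <= 0) stop("train_config: lr_init must be > 0")
  if (lr_decay_factor <= 0 || lr_decay_factor > 1)
    stop("train_config: lr_decay_factor must be in (0, 1]")
  if (batch_size < 1L) stop("train_config: batch_size must be >= 1")
  if (epochs < 1L) stop("train_config: epochs must be >= 1")
  structure(list(lr_init = lr_init, lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 seed = as.integer(seed), loss = loss, network = network,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step schedule: `lr_init * lr_decay_factor^(epoch %/% lr_decay_every)`
#' (epochs counted from 0), i.e. the rate is multiplied by the decay factor
#' every `lr_decay_every` epochs.
#'
#' @param cfg A [train_config()].
#' @param epoch Zero-based epoch index.
#' @return The learning rate (scalar).
#' @export
lr_at_epoch <- function(cfg, epoch) {
  if (any(epoch < 0)) stop("lr_at_epoch: epoch must be >= 0")
  cfg$lr_init * cfg$lr_decay_factor^(epoch %/% cfg$lr_decay_every)
}

## stack preprocessed sample pairs into (x, y) tensors
pairs_to_tensors <- function(pairs, preprocessing = clahe_params()) {
  imgs <- lapply(pairs, function(pr) preprocess_image(pr$image,
                                                      preprocessing))
  d <- dim(imgs[[1]])
  x <- array(0, c(d[1], d[2], 1L, length(pairs)))
  y <- array(0, c(d[1], d[2], 1L, length(pairs)))
  for (k in seq_along(pairs)) {
    x[, , 1L, k] <- imgs[[k]]
    y[, , 1L, k] <- pairs[[k]]$truth
  }
  list(x = x, y = y)
}

soft_dice_score <- function(p, y) {
  s <- 1e-6
  (2 * sum(p * y) + s) / (sum(p) + sum(y) + s)
}

#' Fit a vessel segmentation network by stochastic gradient descent
#'
#' Builds the network described by `config$network`, preprocesses the
#' sample pairs (green channel + CLAHE + rescale), and minimizes the
#' combined objective `alpha * Dice + (1 - alpha) * cost-sensitive CE +
#' lambda/2 * sum(W^2)` with plain (optionally momentum) SGD under the step
#' learning-rate schedule. Per-epoch training loss and validation metrics
#' are logged; the parameter snapshot with the best validation soft-Dice is
#' retained and restored in the returned model. The run is a deterministic
#' function of `config$seed`.
#'
#' @param pairs Training samples: a list of `sample_pair` objects, or a
#'   list `list(x =, y =)` of pre-built `H x W x 1 x N` tensors.
#' @param config A [train_config()].
#' @param val_pairs Optional validation samples (same forms as `pairs`).
#' @param preprocessing A [clahe_params()] applied to all images.
#' @param verbose Print one line per epoch.
#' @return An object of class `"vessel_model"`: list with the fitted `net`,
#'   the `config`, the epoch `log` (data frame: epoch, lr, train_loss,
#'   val_dice, val_sen, val_spe), and `best_epoch`.
#' @export
train_segmenter <- function(pairs, config = train_config(),
                            val_pairs = NULL,
                            preprocessing = clahe_params(),
                            verbose = FALSE) {
  tensors <- if (!is.null(pairs$x)) pairs else pairs_to_tensors(pairs,
                                                                preprocessing)
  x <- tensors$x; y <- tensors$y
  n <- dim(x)[4]
  if (n == 0L) stop("train_segmenter: empty training set")
  val <- if (is.null(val_pairs)) NULL
         else if (!is.null(val_pairs$x)) val_pairs
         else pairs_to_tensors(val_pairs, preprocessing)

  set.seed(config$seed)
  builder <- if (config$network$block == "msffu") build_msffu_net
             else build_unet
  net <- builder(config$network, in_channels = 1L, seed = NULL)
  lp <- config$loss
  vel <- NULL  # momentum buffers
  log_rows <- vector("list", config$epochs)
  best <- list(dice = -Inf, params = net$params, state = NULL, epoch = 0L)

  for (ep in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, ep - 1L)
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      ids <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x[, , , ids, drop = FALSE]
      yb <- y[, , , ids, drop = FALSE]
      fw <- forward_net(net, xb, train = TRUE)
      p <- fw$out
      if (!all(is.finite(p)))
        stop(sprintf(paste0("train_segmenter: non-finite network output at",
                            " epoch %d (lr %.2g, batch starting at %d);",
                            " aborting"), ep, lr, start))
      wns <- weight_norm_sq(net)
      loss <- combined_cost(p, yb, lp, wns)
      if (!is.finite(loss))
        stop(sprintf(paste0("train_segmenter: non-finite loss at epoch %d",
                            " (lr %.2g, batch starting at %d); aborting"),
                     ep, lr, start))
      dp <- combined_grad(p, yb, lp)
      bw <- backward_net(net, fw, dp)
      upd <- sgd_step(net$params, bw$grads, lr, lp$lambda_l2,
                      config$momentum, vel)
      net$params <- upd$params
      vel <- upd$vel
      ep_loss <- ep_loss + loss
      nb <- nb + 1L
    }
    row <- data.frame(epoch = ep, lr = lr, train_loss = ep_loss / nb,
                      val_dice = NA_real_, val_sen = NA_real_,
                      val_spe = NA_real_)
    if (!is.null(val)) {
      vm <- validate_tensors(net, val)
      row$val_dice <- vm["dice"]
      row$val_sen <- vm["sen"]
      row$val_spe <- vm["spe"]
      if (vm["dice"] > best$dice)
        best <- list(dice = vm["dice"], params = net$params,
                     state = bn_state_copy(net$bn_state), epoch = ep)
    }
    log_rows[[ep]] <- row
    if (verbose)
      cat(sprintf("epoch %3d  lr %.2g  loss %.4f  val_dice %s\n", ep, lr,
                  row$train_loss,
                  ifelse(is.na(row$val_dice), "-",
                         sprintf("%.4f", row$val_dice))))
  }
  if (!is.null(val) && is.finite(best$dice)) {
    net$params <- best$params
    if (!is.null(best$state))
      for (nm in ls(best$state)) net$bn_state[[nm]] <- best$state[[nm]]
  }
  structure(list(net = net, config = config,
                 log = do.call(rbind, log_rows),
                 best_epoch = if (is.null(val)) NA_integer_ else best$epoch),
            class = "vessel_model")
}

bn_state_copy <- function(state) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(state)) out[[nm]] <- state[[nm]]
  out
}

sgd_step <- function(params, grads, lr, lambda, momentum, vel) {
  if (is.null(vel)) vel <- list()
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      if (f == "w") g <- g + lambda * params[[nm]][[f]]  # L2 on weights
      key <- paste0(nm, ".", f)
      v <- if (momentum > 0 && !is.null(vel[[key]]))
        momentum * vel[[key]] + g else g
      if (momentum > 0) vel[[key]] <- v
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * v
    }
  }
  list(params = params, vel = vel)
}

validate_tensors <- function(net, val, threshold = 0.5) {
  p <- forward_net(net, val$x, train = FALSE)$out
  cc <- confusion((p >= threshold) * 1, val$y * 1)
  m <- suppressWarnings(sen_spe_acc(cc))
  c(dice = soft_dice_score(p, val$y), sen = unname(m["sen"]),
    spe = unname(m["spe"]))
}

#' Train twin models differing only in the loss
#'
#' For each seed, trains one model with plain (unweighted, pure
#' cross-entropy) loss and one with the cost-sensitive combined loss, from
#' identical initialization and batch order, and evaluates both on the
#' validation set. This isolates the effect of the cost-sensitive design,
#' whose purpose is to keep the rare vessel class from being ceded to the
#' background.
#'
#' @param config A [train_config()]; its `loss` is the cost-sensitive arm.
#' @param pairs Training samples (see [train_segmenter()]).
#' @param val_pairs Validation samples.
#' @param seeds Integer vector of seeds (default `1:3`).
#' @param preprocessing A [clahe_params()].
#' @return Data frame with two rows per seed (`loss` = `"plain_ce"` /
#'   `"cost_sensitive"`), columns `seed`, `loss`, `dice`, `sen`, `spe`.
#' @export
compare_losses <- function(config, pairs, val_pairs, seeds = 1:3,
                           preprocessing = clahe_params()) {
  tensors <- if (!is.null(pairs$x)) pairs else pairs_to_tensors(pairs,
                                                                preprocessing)
  val <- if (!is.null(val_pairs$x)) val_pairs
         else pairs_to_tensors(val_pairs, preprocessing)
  plain <- config
  plain$loss <- loss_params(alpha = 0, lambda_l2 = config$loss$lambda_l2,
                            vessel_penalty = 0)
  rows <- list()
  for (s in seeds) {
    for (arm in c("plain_ce", "cost_sensitive")) {
      cfg <- if (arm == "plain_ce") plain else config
      cfg$seed <- as.integer(s)
      m <- train_segmenter(tensors, cfg, val_pairs = val)
      vm <- validate_tensors(m$net, val)
      rows[[length(rows) + 1L]] <-
        data.frame(seed = s, loss = arm, dice = vm["dice"],
                   sen = vm["sen"], spe = vm["spe"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Save / load a fitted model
#'
#' The model (architecture, parameters, batch-norm running statistics,
#' config and training log) is serialized with `saveRDS`, and a JSON
#' sidecar (`<path>.json`) records the architecture spec and training
#' configuration for inspection without loading the binary file. Reloading
#' reproduces validation metrics bit for bit.
#'
#' @param model A `"vessel_model"`.
#' @param path Destination file (conventionally `.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `"vessel_model"`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "vessel_model"))
  obj <- model
  obj$net$bn_state <- as.list(model$net$bn_state)
  saveRDS(obj, path)
  side <- list(network = unclass(model$config$network),
               loss = unclass(model$config$loss),
               epochs = model$config$epochs, seed = model$config$seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  st <- new.env(parent = emptyenv())
  for (nm in names(obj$net$bn_state)) st[[nm]] <- obj$net$bn_state[[nm]]
  obj$net$bn_state <- st
  obj
}

## ---- S3 methods for the fitted model ------------------------------------

#' @export
print.vessel_model <- function(x, ...) {
  s <- net_summary(x$net)
  cat(sprintf(paste0("<vessel_model> %s (depth %d, base %d), %d parameters",
                     "\n  trained %d epochs, final loss %.4f%s\n"),
              x$net$spec$block, x$net$spec$depth, x$net$spec$base_channels,
              sum(s$n_params), nrow(x$log),
              x$log$train_loss[nrow(x$log)],
              if (is.na(x$best_epoch)) "" else
                sprintf(", best val dice %.4f (epoch %d)",
                        max(x$log$val_dice, na.rm = TRUE), x$best_epoch)))
  invisible(x)
}

#' @export
summary.vessel_model <- function(object, ...) {
  structure(list(layers = net_summary(object$net), log = object$log,
                 config = object$config), class = "summary.vessel_model")
}

#' @export
print.summary.vessel_model <- function(x, ...) {
  cat("Layers:\n")
  print(x$layers)
  cat("\nLast epochs:\n")
  print(utils::tail(x$log, 5))
  invisible(x)
}

#' @export
coef.vessel_model <- function(object, ...) object$net$params

#' @export
predict.vessel_model <- function(object, image, threshold = 0.5, ...)
  predict_mask(object$net, image, threshold)

#' @export
plot.vessel_model <- function(x, ...) {
  graphics::plot(x$log$epoch, x$log$train_loss, type = "l",
                 xlab = "epoch", ylab = "training loss", ...)
  if (any(!is.na(x$log$val_dice))) {
    graphics::par(new = TRUE)
    graphics::plot(x$log$epoch, x$log$val_dice, type = "l", col = 2,
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = 2)
    graphics::mtext("validation Dice", side = 4, line = 2, col = 2)
  }
  invisible(x)
}
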