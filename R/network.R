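## Network builders: the multi-scale feature-fusion U-Net ("msffu") and the
## classic U-Net baseline ("unet"). A network is a flat list of layer
## descriptors executed in order by forward_net()/backward_net(); named
## buffers carry the skip connections and pooling indices.

#' Architecture specification
#'
#' Declarative description of an encoder-decoder segmentation network.
#'
#' @param depth Number of 2x2 pooling stages (the encoder repeats its block
#'   pair + pool this many times; default 4).
#' @param base_channels Channel width of the first encoder stage. Widths
#'   double at every downsampling step. Must be divisible by 4 so the
#'   multi-scale block can split its output 1/4 : 1/2 : 1/4 across branches.
#' @param block `"msffu"` for the inception-style multi-scale block with
#'   batch norm and leaky-ReLU, `"unet"` for the plain double 3x3
#'   convolution block with ReLU.
#' @param activation Activation for convolution layers; defaults to
#'   `"leaky_relu"` for `"msffu"` and `"relu"` for `"unet"`.
#' @param leaky_slope Negative-side slope of the leaky ReLU.
#' @param use_batchnorm Insert batch normalization after every convolution.
#'   Defaults to `TRUE` for `"msffu"`, `FALSE` for `"unet"`.
#' @param out_channels Number of output probability channels (1 = vessel
#'   probability through a sigmoid head).
#' @return An object of class `"network_spec"`.
#' @export
network_spec <- function(depth = 4L, base_channels = 32L,
                         block = c("msffu", "unet"),
                         activation = NULL, leaky_slope = 0.01,
                         use_batchnorm = NULL, out_channels = 1L) {
  block <- match.arg(block)
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  if (depth < 1L) stop("network_spec: depth must be >= 1")
  if (base_channels < 4L || base_channels %% 4L != 0L)
    stop("network_spec: base_channels must be >= 4 and divisible by 4 ",
         "(needed for the 1/4 : 1/2 : 1/4 branch split)")
  if (out_channels < 1L) stop("network_spec: out_channels must be >= 1")
  if (is.null(activation))
    activation <- if (block == "msffu") "leaky_relu" else "relu"
  activation <- match.arg(activation, c("leaky_relu", "relu"))
  if (is.null(use_batchnorm)) use_batchnorm <- block == "msffu"
  structure(list(depth = depth, base_channels = base_channels,
                 block = block, activation = activation,
                 leaky_slope = leaky_slope, use_batchnorm = use_batchnorm,
                 out_channels = as.integer(out_channels)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s: depth %d, base %d channels, %s%s, %d out\n",
              x$block, x$depth, x$base_channels, x$activation,
              if (x$use_batchnorm) " + BN" else "", x$out_channels))
  invisible(x)
}

## ---- builder internals -------------------------------------------------

new_builder <- function(spec, in_channels) {
  env <- new.env(parent = emptyenv())
  env$layers <- list()
  env$channels <- c(input = in_channels)
  env$spec <- spec
  env
}

bld_add <- function(b, layer) {
  b$layers[[length(b$layers) + 1L]] <- layer
  b$channels[[layer$name]] <- layer$cout
  invisible(layer$name)
}

bld_conv <- function(b, name, input, kh, cout, bn = NULL, act = NULL) {
  spec <- b$spec
  if (is.null(bn)) bn <- spec$use_batchnorm
  if (is.null(act))
    act <- if (spec$activation == "leaky_relu") "lrelu" else "relu"
  bld_add(b, list(op = "conv", name = name, input = input, kh = kh, kw = kh,
                  cin = b$channels[[input]], cout = as.integer(cout),
                  bn = bn, act = act))
}

bld_tconv <- function(b, name, input, cout) {
  spec <- b$spec
  act <- if (spec$activation == "leaky_relu") "lrelu" else "relu"
  bld_add(b, list(op = "tconv", name = name, input = input,
                  cin = b$channels[[input]], cout = as.integer(cout),
                  bn = spec$use_batchnorm, act = act))
}

bld_pool <- function(b, name, input)
  bld_add(b, list(op = "pool", name = name, input = input,
                  cin = b$channels[[input]], cout = b$channels[[input]]))

bld_unpool <- function(b, name, input, idx_from)
  bld_add(b, list(op = "unpool", name = name, input = input,
                  idx_from = idx_from, cin = b$channels[[input]],
                  cout = b$channels[[input]]))

bld_concat <- function(b, name, inputs) {
  cs <- vapply(inputs, function(nm) b$channels[[nm]], integer(1))
  bld_add(b, list(op = "concat", name = name, input = inputs,
                  cin = sum(cs), cout = sum(cs), widths = cs))
}

bld_sigmoid <- function(b, name, input)
  bld_add(b, list(op = "sigmoid", name = name, input = input,
                  cin = b$channels[[input]], cout = b$channels[[input]]))

## Inception-style multi-scale block: three parallel branches
##   (a) 1x1 -> out/4
##   (b) 1x1 reduce -> out/4, then 3x3 -> out/2
##   (c) 1x1 reduce -> out/8, then 3x3 -> out/4, then 3x3 -> out/4
## concatenated to `cout` channels; every conv gets BN + leaky ReLU.
## The stacked 3x3 pair in (c) covers a 5x5 receptive field.
bld_msblock <- function(b, prefix, input, cout) {
  q <- cout %/% 4L
  a <- bld_conv(b, paste0(prefix, "_a"), input, 1L, q)
  b1 <- bld_conv(b, paste0(prefix, "_b1"), input, 1L, q)
  b2 <- bld_conv(b, paste0(prefix, "_b2"), b1, 3L, 2L * q)
  c1 <- bld_conv(b, paste0(prefix, "_c1"), input, 1L, max(1L, cout %/% 8L))
  c2 <- bld_conv(b, paste0(prefix, "_c2"), c1, 3L, q)
  c3 <- bld_conv(b, paste0(prefix, "_c3"), c2, 3L, q)
  bld_concat(b, paste0(prefix, "_out"), c(a, b2, c3))
}

bld_doubleconv <- function(b, prefix, input, cout) {
  c1 <- bld_conv(b, paste0(prefix, "_1"), input, 3L, cout)
  bld_conv(b, paste0(prefix, "_2"), c1, 3L, cout)
}

## ---- parameter initialization ------------------------------------------

he_uniform <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

init_params <- function(layers) {
  params <- list()
  state <- new.env(parent = emptyenv())
  for (ly in layers) {
    if (ly$op == "conv") {
      fan_in <- ly$kh * ly$kw * ly$cin
      p <- list(w = he_uniform(fan_in, ly$cout, fan_in),
                b = numeric(ly$cout))
    } else if (ly$op == "tconv") {
      p <- list(w = he_uniform(4L * ly$cin, ly$cout, ly$cin),
                b = numeric(ly$cout))
    } else next
    if (isTRUE(ly$bn)) {
      p$gamma <- rep(1, ly$cout)
      p$beta <- numeric(ly$cout)
      state[[ly$name]] <- list(mean = numeric(ly$cout),
                               var = rep(1, ly$cout))
    }
    params[[ly$name]] <- p
  }
  list(params = params, state = state)
}

finish_net <- function(b, in_channels, seed) {
  if (!is.null(seed)) set.seed(seed)
  ini <- init_params(b$layers)
  structure(list(spec = b$spec, in_channels = in_channels,
                 layers = b$layers, params = ini$params,
                 bn_state = ini$state),
            class = "vessel_net")
}

## ---- public builders ----------------------------------------------------

#' Build the multi-scale feature-fusion segmentation network
#'
#' Encoder: `depth` repetitions of two multi-scale (inception-style) blocks
#' followed by a 2x2 index-recording max-pool, doubling channel width per
#' stage; a two-block bottleneck. Decoder: at each stage the incoming stream
#' is (i) upsampled by a 2x2 stride-2 transpose convolution (halving
#' channels) and (ii) reduced by a 1x1 convolution and unpooled with the
#' stage's stored max-pool indices; both are concatenated with the encoder
#' skip feature map and fused by two 3x3 convolutions. A 1x1 convolution and
#' sigmoid produce per-pixel vessel probabilities.
#'
#' @param spec A [network_spec()] with `block = "msffu"`.
#' @param in_channels Number of input channels (1 for preprocessed
#'   green-channel images).
#' @param seed Optional integer seed for the He-uniform weight
#'   initialization; fixing it makes builds reproducible.
#' @return An object of class `"vessel_net"`.
#' @examples
#' net <- build_msffu_net(network_spec(depth = 1, base_channels = 8), seed = 1)
#' p <- forward_net(net, array(stats::runif(16 * 16), c(16, 16, 1, 1)))$out
#' range(p)
#' @export
build_msffu_net <- function(spec = network_spec(), in_channels = 1L,
                            seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  b <- new_builder(spec, as.integer(in_channels))
  cur <- "input"
  skips <- character(spec$depth)
  pools <- character(spec$depth)
  for (s in seq_len(spec$depth)) {
    cs <- spec$base_channels * 2L^(s - 1L)
    cur <- bld_msblock(b, sprintf("enc%d_b1", s), cur, cs)
    cur <- bld_msblock(b, sprintf("enc%d_b2", s), cur, cs)
    skips[s] <- cur
    cur <- bld_pool(b, sprintf("pool%d", s), cur)
    pools[s] <- cur
  }
  cb <- spec$base_channels * 2L^spec$depth
  cur <- bld_msblock(b, "bott_b1", cur, cb)
  cur <- bld_msblock(b, "bott_b2", cur, cb)
  for (s in rev(seq_len(spec$depth))) {
    cs <- spec$base_channels * 2L^(s - 1L)
    up <- bld_tconv(b, sprintf("dec%d_up", s), cur, cs)
    red <- bld_conv(b, sprintf("dec%d_red", s), cur, 1L, cs)
    unp <- bld_unpool(b, sprintf("dec%d_unp", s), red, pools[s])
    cat_ <- bld_concat(b, sprintf("dec%d_cat", s), c(up, unp, skips[s]))
    c1 <- bld_conv(b, sprintf("dec%d_c1", s), cat_, 3L, cs)
    cur <- bld_conv(b, sprintf("dec%d_c2", s), c1, 3L, cs)
  }
  head <- bld_conv(b, "head", cur, 1L, spec$out_channels,
                   bn = FALSE, act = "none")
  bld_sigmoid(b, "prob", head)
  finish_net(b, in_channels, seed)
}

#' Build the classic U-Net baseline
#'
#' Plain double 3x3 convolution blocks with ReLU, 2x2 max pooling, 2x2
#' transpose-convolution upsampling and a single concatenation skip per
#' stage, ending in a 1x1 convolution + sigmoid head.
#'
#' @inheritParams build_msffu_net
#' @param spec A [network_spec()]; `block` should be `"unet"`.
#' @return An object of class `"vessel_net"`.
#' @export
build_unet <- function(spec = network_spec(block = "unet"), in_channels = 1L,
                       seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  b <- new_builder(spec, as.integer(in_channels))
  cur <- "input"
  skips <- character(spec$depth)
  for (s in seq_len(spec$depth)) {
    cs <- spec$base_channels * 2L^(s - 1L)
    cur <- bld_doubleconv(b, sprintf("enc%d", s), cur, cs)
    skips[s] <- cur
    cur <- bld_pool(b, sprintf("pool%d", s), cur)
  }
  cb <- spec$base_channels * 2L^spec$depth
  cur <- bld_doubleconv(b, "bott", cur, cb)
  for (s in rev(seq_len(spec$depth))) {
    cs <- spec$base_channels * 2L^(s - 1L)
    up <- bld_tconv(b, sprintf("dec%d_up", s), cur, cs)
    cat_ <- bld_concat(b, sprintf("dec%d_cat", s), c(up, skips[s]))
    cur <- bld_doubleconv(b, sprintf("dec%d", s), cat_, cs)
  }
  bld_conv(b, "head", cur, 1L, spec$out_channels, bn = FALSE, act = "none")
  bld_sigmoid(b, "prob", "head")
  finish_net(b, in_channels, seed)
}

## ---- forward / backward -------------------------------------------------

check_input_size <- function(net, d) {
  f <- 2L^net$spec$depth
  if (d[1] %% f != 0L || d[2] %% f != 0L)
    stop(sprintf(paste0("input size %dx%d is not divisible by 2^depth = %d; ",
                        "pad or crop the image first"), d[1], d[2], f))
  if (d[3] != net$in_channels)
    stop(sprintf("expected %d input channel(s), got %d", net$in_channels,
                 d[3]))
}

#' Run a network forward
#'
#' @param net A `"vessel_net"` from [build_msffu_net()] or [build_unet()].
#' @param x Input tensor `H x W x C x N` (matrix/3-D inputs are promoted);
#'   `H`, `W` must be divisible by `2^depth`.
#' @param train Logical; `TRUE` uses batch statistics in batch norm (and
#'   updates running averages), `FALSE` uses the stored running averages.
#' @return A list with `out` (the sigmoid probability tensor) and `cache`
#'   (per-layer intermediates consumed by `backward_net`).
#' @export
forward_net <- function(net, x, train = FALSE) {
  x <- as_feature_tensor(x)
  check_input_size(net, dim(x))
  buf <- new.env(parent = emptyenv())
  cache <- new.env(parent = emptyenv())
  buf$input <- x
  for (ly in net$layers) {
    p <- net$params[[ly$name]]
    out <- switch(ly$op,
      conv = ,
      tconv = {
        z <- if (ly$op == "conv")
          conv_fw(buf[[ly$input]], p$w, p$b, ly$kh, ly$kw)
        else
          tconv_fw(buf[[ly$input]], p$w, p$b)
        if (ly$bn) {
          bn <- bn_forward(z, p$gamma, p$beta, net$bn_state[[ly$name]],
                           train)
          if (train)
            net$bn_state[[ly$name]] <-
              bn_update_running(net$bn_state[[ly$name]], bn)
          cache[[ly$name]] <- list(bn = bn[c("xhat", "std")], a = bn$y)
          act_forward(bn$y, ly$act, net$spec$leaky_slope)
        } else {
          cache[[ly$name]] <- list(a = z)
          act_forward(z, ly$act, net$spec$leaky_slope)
        }
      },
      pool = {
        pr <- max_pool_with_indices(buf[[ly$input]])
        cache[[ly$name]] <- list(idx = pr$idx, in_dim = dim(buf[[ly$input]]))
        pr$y
      },
      unpool = {
        idx <- cache[[ly$idx_from]]$idx
        unpool_with_indices(buf[[ly$input]], idx)
      },
      concat = {
        parts <- lapply(ly$input, function(nm) buf[[nm]])
        abind_channels(parts)
      },
      sigmoid = {
        y <- sigmoid(buf[[ly$input]])
        cache[[ly$name]] <- list(y = y)
        y
      })
    buf[[ly$name]] <- out
  }
  list(out = buf$prob, buf = buf, cache = cache)
}

abind_channels <- function(parts) {
  d <- dim(parts[[1]])
  cs <- vapply(parts, function(p) dim(p)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (p in parts) {
    cp <- dim(p)[3]
    out[, , at + seq_len(cp), ] <- p
    at <- at + cp
  }
  out
}

## Reverse pass: returns gradients for every parameterized layer plus the
## gradient w.r.t. the input buffer (rarely needed, but free).
backward_net <- function(net, fw, dout) {
  buf <- fw$buf
  cache <- fw$cache
  gr <- new.env(parent = emptyenv())
  gr$prob <- dout
  grads <- list()
  addg <- function(nm, val) {
    cur <- gr[[nm]]
    gr[[nm]] <- if (is.null(cur)) val else cur + val
  }
  slope <- net$spec$leaky_slope
  for (ly in rev(net$layers)) {
    g <- gr[[ly$name]]
    if (is.null(g)) next
    p <- net$params[[ly$name]]
    switch(ly$op,
      conv = {
        ca <- cache[[ly$name]]
        g <- act_backward(g, ca$a, ly$act, slope)
        if (ly$bn) {
          bb <- bn_backward(g, ca$bn, p$gamma)
          g <- bb$dx
        }
        cb <- conv_bw(buf[[ly$input]], g, p$w, ly$kh, ly$kw)
        pg <- list(w = cb$dw, b = as.numeric(cb$db))
        if (ly$bn) { pg$gamma <- bb$dgamma; pg$beta <- bb$dbeta }
        grads[[ly$name]] <- pg
        addg(ly$input, cb$dx)
      },
      tconv = {
        ca <- cache[[ly$name]]
        g <- act_backward(g, ca$a, ly$act, slope)
        if (ly$bn) {
          bb <- bn_backward(g, ca$bn, p$gamma)
          g <- bb$dx
        }
        tb <- tconv_bw(buf[[ly$input]], g, p$w)
        pg <- list(w = tb$dw, b = as.numeric(tb$db))
        if (ly$bn) { pg$gamma <- bb$dgamma; pg$beta <- bb$dbeta }
        grads[[ly$name]] <- pg
        addg(ly$input, tb$dx)
      },
      pool = {
        idx <- cache[[ly$name]]$idx
        addg(ly$input, .pool_scatter(g, idx))
      },
      unpool = {
        idx <- cache[[ly$idx_from]]$idx
        addg(ly$input, .pool_gather(g, idx))
      },
      concat = {
        at <- 0L
        for (k in seq_along(ly$input)) {
          cp <- ly$widths[k]
          addg(ly$input[k],
               g[, , at + seq_len(cp), , drop = FALSE])
          at <- at + cp
        }
      },
      sigmoid = {
        y <- cache[[ly$name]]$y
        addg(ly$input, g * y * (1 - y))
      })
  }
  list(grads = grads, dinput = gr$input)
}

#' Segment an image with a network
#'
#' Runs a forward pass in evaluation mode and thresholds the probability
#' map. If the image size is not divisible by `2^depth` it is reflect-padded
#' on the bottom/right, segmented, and cropped back; the padding applied is
#' recorded in the `"padding"` attribute of the probability map.
#'
#' @param net A `"vessel_net"` (or a fitted `"vessel_model"`; see
#'   [train_segmenter()]).
#' @param image Numeric matrix in `[0, 1]` (a preprocessed gray image).
#' @param threshold Probability cutoff for the binary mask (default 0.5).
#' @return A list with `prob` (matrix of vessel probabilities in `[0, 1]`)
#'   and `mask` (0/1 matrix, `prob >= threshold`).
#' @export
predict_mask <- function(net, image, threshold = 0.5) {
  if (inherits(net, "vessel_model")) net <- net$net
  stopifnot(inherits(net, "vessel_net"), is.matrix(image))
  f <- 2L^net$spec$depth
  d <- dim(image)
  pad <- c((f - d[1] %% f) %% f, (f - d[2] %% f) %% f)
  img <- if (any(pad > 0)) pad_reflect(image, pad[1], pad[2]) else image
  out <- forward_net(net, array(img, c(dim(img), 1L, 1L)), train = FALSE)$out
  prob <- out[seq_len(d[1]), seq_len(d[2]), 1L, 1L]
  dim(prob) <- d
  attr(prob, "padding") <- pad
  list(prob = prob, mask = (prob >= threshold) * 1L)
}

## parameter count per layer, used by summaries
count_params <- function(p) sum(vapply(p, length, numeric(1)))

#' Per-layer summary of a network
#'
#' @param net A `"vessel_net"`.
#' @return A data frame with one row per layer: operation, input buffer(s),
#'   output channels and parameter count.
#' @export
net_summary <- function(net) {
  stopifnot(inherits(net, "vessel_net"))
  data.frame(
    layer = vapply(net$layers, `[[`, "", "name"),
    op = vapply(net$layers, `[[`, "", "op"),
    input = vapply(net$layers, function(l) paste(l$input, collapse = "+"),
                   ""),
    out_channels = vapply(net$layers, function(l) as.integer(l$cout),
                          integer(1)),
    n_params = vapply(net$layers, function(l) {
      p <- net$params[[l$name]]
      if (is.null(p)) 0 else count_params(p)
    }, numeric(1)),
    row.names = NULL)
}

#' @export
print.vessel_net <- function(x, ...) {
  s <- net_summary(x)
  cat(sprintf("<vessel_net> %s, depth %d, base %d: %d layers, %d parameters\n",
              x$spec$block, x$spec$depth, x$spec$base_channels,
              nrow(s), sum(s$n_params)))
  invisible(x)
}
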