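# The MD-Unet: a 3D encoder-decoder over the bin-stacked volume. Five scales
# by default, two 3x3x3 convolutions per block (each followed by batch
# normalization and ReLU), spatial-only 2x2 max pooling between encoder
# scales so the 3-bin depth axis survives to the output head, 2x2 spatial
# up-convolutions in the decoder, skip connections at every scale with
# learnable scalar gates on scales 1-2, and a bin-collapsing projection head
# (1x1 spatial kernel spanning the full depth) to the four material classes
# followed by a per-pixel softmax.

#' Network architecture configuration
#'
#' Defaults reproduce the full architecture: 5 scales, base width 64 doubling
#' to 1024 channels at the deepest scale, weighted skip connections on scales
#' 1 and 2, and 4 output classes (background, water, calcium, iodine).
#'
#' @param n_scales number of resolution scales.
#' @param base_channels channels at scale 1 (doubled per scale).
#' @param weighted_skip_scales scales carrying a learnable scalar skip gate.
#' @param n_materials output classes.
#' @param n_bins depth of the bin axis (3).
#' @return object of class `mdunet_config`.
#' @export
mdunet_config <- function(n_scales = 5, base_channels = 64,
                          weighted_skip_scales = c(1, 2), n_materials = 4,
                          n_bins = 3) {
  stopifnot(n_scales >= 2, base_channels >= 1, n_materials >= 2, n_bins >= 1)
  weighted_skip_scales <- intersect(weighted_skip_scales, seq_len(n_scales - 1))
  structure(list(n_scales = n_scales, base_channels = base_channels,
                 weighted_skip_scales = weighted_skip_scales,
                 n_materials = as.integer(n_materials),
                 n_bins = as.integer(n_bins)),
            class = "mdunet_config")
}

#' A desk-scale network configuration for fast CPU experiments
#' @param base_channels channels at scale 1.
#' @param n_scales number of scales.
#' @inheritParams mdunet_config
#' @export
mdunet_config_desk <- function(n_scales = 3, base_channels = 8,
                               weighted_skip_scales = c(1, 2)) {
  mdunet_config(n_scales = n_scales, base_channels = base_channels,
                weighted_skip_scales = weighted_skip_scales)
}

# channels at scale k
.ch <- function(config, k) as.integer(config$base_channels * 2^(k - 1))

#' Architecture table of an MD-Unet configuration
#'
#' One row per hidden layer under the documented counting convention:
#' convolutions, pooling layers, up-convolutions, weighted-skip gates and the
#' output projection. Batch-normalization and activation layers are bound to
#' their convolutions and not counted separately.
#'
#' @param config an [mdunet_config()].
#' @return data.frame with columns `name`, `type`, `scale`, `in_ch`, `out_ch`.
#' @export
mdunet_architecture <- function(config) {
  S <- config$n_scales
  rows <- list()
  add <- function(name, type, scale, in_ch, out_ch)
    rows[[length(rows) + 1]] <<- data.frame(name = name, type = type,
                                            scale = as.integer(scale),
                                            in_ch = as.integer(in_ch),
                                            out_ch = as.integer(out_ch))
  for (k in seq_len(S)) {
    cin <- if (k == 1) 1L else .ch(config, k - 1)
    add(sprintf("enc%d_conv1", k), "conv", k, cin, .ch(config, k))
    add(sprintf("enc%d_conv2", k), "conv", k, .ch(config, k), .ch(config, k))
    if (k < S) add(sprintf("pool%d", k), "pool", k, .ch(config, k), .ch(config, k))
  }
  for (k in rev(seq_len(S - 1))) {
    add(sprintf("dec%d_up", k), "upconv", k, .ch(config, k + 1), .ch(config, k))
    if (k %in% config$weighted_skip_scales)
      add(sprintf("gate%d", k), "gate", k, .ch(config, k), .ch(config, k))
    add(sprintf("dec%d_conv1", k), "conv", k, 2L * .ch(config, k), .ch(config, k))
    add(sprintf("dec%d_conv2", k), "conv", k, .ch(config, k), .ch(config, k))
  }
  add("head", "head", 1, config$n_bins * .ch(config, 1), config$n_materials)
  do.call(rbind, rows)
}

#' Count the hidden layers of a network or configuration
#'
#' Convention (documented, additive): all convolutions, pooling layers,
#' up-convolutions, weighted-skip gate layers, and the output projection.
#' Batch normalizations are excluded. The default configuration audits to 29.
#'
#' @param network an [build_network()] object or an [mdunet_config()].
#' @return integer layer count.
#' @export
count_hidden_layers <- function(network) {
  config <- if (inherits(network, "mdunet_config")) network else network$config
  nrow(mdunet_architecture(config))
}

#' Build an MD-Unet
#'
#' Allocates He-initialized weights for every layer of
#' [mdunet_architecture()]; skip gates start at 1.0 (plain skip connection).
#'
#' @param config an [mdunet_config()].
#' @param rng_seed seed for weight initialization.
#' @return object of class `mdunet`: `config`, `params` (named list),
#'   `bn_state` (running statistics per batch-norm layer).
#' @export
build_network <- function(config = mdunet_config(), rng_seed = 1) {
  set.seed(rng_seed)
  params <- list()
  bn_state <- list()
  he <- function(fanin, d) array(stats::rnorm(prod(d), 0, sqrt(2 / fanin)), d)
  add_conv <- function(name, cin, cout) {
    params[[paste0(name, "_w")]] <<- he(27 * cin, c(3, 3, 3, cin, cout))
    params[[paste0(name, "_b")]] <<- numeric(cout)
    params[[paste0(name, "_bn_gamma")]] <<- rep(1, cout)
    params[[paste0(name, "_bn_beta")]] <<- numeric(cout)
    bn_state[[name]] <<- list(mean = numeric(cout), var = rep(1, cout))
  }
  arch <- mdunet_architecture(config)
  for (i in seq_len(nrow(arch))) {
    r <- arch[i, ]
    if (r$type == "conv") add_conv(r$name, r$in_ch, r$out_ch)
    if (r$type == "upconv") {
      params[[paste0(r$name, "_w")]] <- he(4 * r$in_ch, c(2, 2, r$in_ch, r$out_ch))
      params[[paste0(r$name, "_b")]] <- numeric(r$out_ch)
    }
    if (r$type == "gate") params[[r$name]] <- 1.0
    if (r$type == "head") {
      params$head_w <- he(r$in_ch, c(r$in_ch, r$out_ch))
      params$head_b <- numeric(r$out_ch)
    }
  }
  structure(list(config = config, params = params, bn_state = bn_state),
            class = "mdunet")
}

#' @export
print.mdunet <- function(x, ...) {
  arch <- mdunet_architecture(x$config)
  np <- sum(vapply(x$params, length, integer(1)))
  cat("MD-Unet: ", x$config$n_scales, " scales, base ", x$config$base_channels,
      " channels (deepest ", .ch(x$config, x$config$n_scales), "), ",
      nrow(arch), " hidden layers, ", format(np, big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

# conv -> bn -> relu block; returns output plus caches, updates bn state
.block_forward <- function(net, name, x, train) {
  p <- net$params
  cv <- nn_conv3_forward(x, p[[paste0(name, "_w")]], p[[paste0(name, "_b")]])
  bn <- nn_bn_forward(cv$y, p[[paste0(name, "_bn_gamma")]],
                      p[[paste0(name, "_bn_beta")]], net$bn_state[[name]],
                      train)
  rl <- nn_relu_forward(bn$y)
  list(y = rl$y, state = bn$state,
       cache = list(conv = cv$cache, bn = bn$cache, relu = rl$cache))
}

.block_backward <- function(dy, name, cache, grads) {
  dy <- nn_relu_backward(dy, cache$relu)
  bn <- nn_bn_backward(dy, cache$bn)
  grads[[paste0(name, "_bn_gamma")]] <- bn$dgamma
  grads[[paste0(name, "_bn_beta")]] <- bn$dbeta
  cv <- nn_conv3_backward(bn$dx, cache$conv)
  grads[[paste0(name, "_w")]] <- cv$dw
  grads[[paste0(name, "_b")]] <- cv$db
  list(dx = cv$dx, grads = grads)
}

#' Forward pass of an MD-Unet
#'
#' @param net an [build_network()] object.
#' @param x input array `H x W x n_bins` (a [multibin_image()]'s data) or
#'   `H x W x n_bins x 1`.
#' @param train logical; batch statistics and caches for backprop when TRUE.
#' @return list with `probs` (`H x W x n_materials`, rows on the simplex),
#'   `net` (updated running statistics when training) and, when `train`,
#'   a `tape` for [mdunet_backward()].
#' @export
mdunet_forward <- function(net, x, train = FALSE) {
  cfg <- net$config
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[3] != cfg$n_bins) stop("input bin depth must be ", cfg$n_bins)
  div <- 2^(cfg$n_scales - 1)
  padH <- (div - d[1] %% div) %% div
  padW <- (div - d[2] %% div) %% div
  if (padH > 0 || padW > 0) {
    xp <- array(0, c(d[1] + padH, d[2] + padW, d[3], d[4]))
    xp[seq_len(d[1]), seq_len(d[2]), , ] <- x
    x <- xp
  }
  S <- cfg$n_scales
  tape <- list(pad = c(padH, padW), H = d[1], W = d[2])
  skips <- vector("list", S)
  feats <- x
  for (k in seq_len(S)) {
    for (j in 1:2) {
      nm <- sprintf("enc%d_conv%d", k, j)
      bl <- .block_forward(net, nm, feats, train)
      net$bn_state[[nm]] <- bl$state
      if (train) tape[[nm]] <- bl$cache
      feats <- bl$y
    }
    skips[[k]] <- feats
    if (k < S) {
      pl <- nn_pool_forward(feats)
      if (train) tape[[sprintf("pool%d", k)]] <- pl$cache
      feats <- pl$y
    }
  }
  for (k in rev(seq_len(S - 1))) {
    up <- nn_upconv_forward(feats, net$params[[sprintf("dec%d_up_w", k)]],
                            net$params[[sprintf("dec%d_up_b", k)]])
    if (train) tape[[sprintf("dec%d_up", k)]] <- up$cache
    sk <- skips[[k]]
    if (k %in% cfg$weighted_skip_scales) {
      g <- as.numeric(net$params[[sprintf("gate%d", k)]])
      if (train) tape[[sprintf("gate%d_x", k)]] <- sk
      sk <- g * sk
    }
    nc <- dim(sk)[4]
    feats <- array(c(sk, up$y), c(dim(sk)[1:3], 2L * nc))
    for (j in 1:2) {
      nm <- sprintf("dec%d_conv%d", k, j)
      bl <- .block_forward(net, nm, feats, train)
      net$bn_state[[nm]] <- bl$state
      if (train) tape[[nm]] <- bl$cache
      feats <- bl$y
    }
  }
  hd <- nn_head_forward(feats, net$params$head_w, net$params$head_b)
  if (train) tape$head <- hd$cache
  probs <- nn_softmax(hd$y)   # (Hp*Wp, K)
  Hp <- dim(feats)[1]; Wp <- dim(feats)[2]
  parr <- array(probs, c(Hp, Wp, cfg$n_materials))
  if (padH > 0 || padW > 0)
    parr <- parr[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  if (train) tape$probs_full <- probs
  list(probs = parr, net = net, tape = if (train) tape else NULL)
}

#' Backward pass of an MD-Unet
#'
#' @param net the network used in the forward pass.
#' @param tape the tape returned by [mdunet_forward()] with `train = TRUE`.
#' @param dprobs gradient of the loss w.r.t. the (cropped) probability array.
#' @return named list of parameter gradients.
#' @export
mdunet_backward <- function(net, tape, dprobs) {
  cfg <- net$config
  S <- cfg$n_scales
  padH <- tape$pad[1]; padW <- tape$pad[2]
  Hp <- tape$H + padH; Wp <- tape$W + padW
  K <- cfg$n_materials
  dp_full <- matrix(0, Hp * Wp, K)
  dparr <- array(0, c(Hp, Wp, K))
  dparr[seq_len(tape$H), seq_len(tape$W), ] <- dprobs
  dim(dparr) <- c(Hp * Wp, K)
  dz <- nn_softmax_backward(dparr, tape$probs_full)
  grads <- list()
  hd <- nn_head_backward(dz, tape$head)
  grads$head_w <- hd$dw
  grads$head_b <- hd$db
  dfeats <- hd$dx
  for (k in seq_len(S - 1)) {
    for (j in 2:1) {
      nm <- sprintf("dec%d_conv%d", k, j)
      bl <- .block_backward(dfeats, nm, tape[[nm]], grads)
      grads <- bl$grads
      dfeats <- bl$dx
    }
    nc <- dim(dfeats)[4] / 2L
    dsk <- dfeats[, , , seq_len(nc), drop = FALSE]
    dup <- dfeats[, , , nc + seq_len(nc), drop = FALSE]
    if (k %in% cfg$weighted_skip_scales) {
      g <- as.numeric(net$params[[sprintf("gate%d", k)]])
      xg <- tape[[sprintf("gate%d_x", k)]]
      grads[[sprintf("gate%d", k)]] <- sum(dsk * xg)
      dsk <- g * dsk
    }
    up <- nn_upconv_backward(dup, tape[[sprintf("dec%d_up", k)]])
    grads[[sprintf("dec%d_up_w", k)]] <- up$dw
    grads[[sprintf("dec%d_up_b", k)]] <- up$db
    # gradient flowing into the encoder skip at this scale
    dskip_total <- dsk
    # continue down the encoder path: pool backward then encoder blocks,
    # but the deeper decoder scales already consumed their inputs; we stack
    # the skip gradient with the pooled-path gradient below.
    tape[[sprintf("dskip%d", k)]] <- dskip_total
    dfeats <- up$dx
  }
  # bottom of the U: dfeats is the gradient w.r.t. skips[[S]]
  dacc <- dfeats
  for (k in rev(seq_len(S))) {
    if (k < S) {
      dacc <- nn_pool_backward(dacc, tape[[sprintf("pool%d", k)]])
      dacc <- dacc + tape[[sprintf("dskip%d", k)]]
    }
    for (j in 2:1) {
      nm <- sprintf("enc%d_conv%d", k, j)
      bl <- .block_backward(dacc, nm, tape[[nm]], grads)
      grads <- bl$grads
      dacc <- bl$dx
    }
  }
  grads
}

#' Predict material maps from a multi-bin image
#'
#' Evaluation-mode forward pass; the categorical map is the per-pixel argmax
#' with ties broken toward the lower class index.
#'
#' @param object an `mdunet`.
#' @param image a [multibin_image()] or a raw `H x W x n_bins` array.
#' @param ... unused.
#' @return list with `prob` (`H x W x K` probability array) and `labels`
#'   (integer matrix, classes 0..K-1).
#' @export
predict.mdunet <- function(object, image, ...) {
  x <- if (inherits(image, "multibin_image")) image$data else image
  fw <- mdunet_forward(object, x, train = FALSE)
  p <- fw$probs
  d <- dim(p)
  pm <- matrix(p, d[1] * d[2], d[3])
  lab <- matrix(max.col(pm, ties.method = "first") - 1L, d[1], d[2])
  list(prob = p, labels = lab)
}
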