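# Two-phase transfer learning: pre-train on (calibrated) simulated scans with
# flips / rotations / elastic deformation, then fine-tune on real-domain
# scans with encoder scale 1 frozen and elastic deformation disabled.
# Batch size is 1 throughout; the optimizer is Adam.

#' Training configuration
#'
#' Full-protocol values: 50 pre-training and 100 fine-tuning epochs,
#' batch size 1, Adam at learning rate 1e-5, encoder scale 1 frozen during
#' fine-tuning. The desk presets scale the epoch counts and learning rate to
#' the reduced network/data sizes.
#'
#' @param pretrain_epochs,finetune_epochs epochs per phase.
#' @param learning_rate Adam learning rate.
#' @param freeze_scales_finetune encoder scales frozen during fine-tuning.
#' @param seed RNG seed controlling shuffling, augmentation and noise.
#' @param augment logical; apply data augmentation.
#' @param elastic_strength,elastic_max control-point displacement sd and cap
#'   (pixels) for elastic deformation.
#' @return object of class `train_config` (batch size fixed at 1).
#' @export
train_config <- function(pretrain_epochs = 50, finetune_epochs = 100,
                         learning_rate = 1e-5, freeze_scales_finetune = 1,
                         seed = 1, augment = TRUE,
                         elastic_strength = 2, elastic_max = 8) {
  stopifnot(pretrain_epochs >= 1, finetune_epochs >= 1, learning_rate > 0)
  structure(list(pretrain_epochs = pretrain_epochs,
                 finetune_epochs = finetune_epochs, batch_size = 1L,
                 learning_rate = learning_rate,
                 freeze_scales_finetune = freeze_scales_finetune,
                 seed = seed, augment = augment,
                 elastic_strength = elastic_strength,
                 elastic_max = elastic_max),
            class = "train_config")
}

#' Desk-scale training configuration
#' @inheritParams train_config
#' @export
train_config_desk <- function(pretrain_epochs = 10, finetune_epochs = 20,
                              learning_rate = 1e-3, seed = 1, ...) {
  train_config(pretrain_epochs = pretrain_epochs,
               finetune_epochs = finetune_epochs,
               learning_rate = learning_rate, seed = seed, ...)
}

#' Build a dataset manifest
#'
#' @param samples list of `list(image =, labels =)` pairs, where `image` is a
#'   [multibin_image()] and `labels` an integer matrix.
#' @param phase `"pretrain"`, `"finetune"` or `"validation"`.
#' @return object of class `dataset_manifest`. Pre-training manifests must
#'   contain only simulated-or-calibrated entries mapped to the real LAC
#'   scale is fine; fine-tuning manifests only real-emulated entries.
#' @export
dataset_manifest <- function(samples, phase = c("pretrain", "finetune",
                                                "validation")) {
  phase <- match.arg(phase)
  for (s in samples) {
    if (!inherits(s$image, "multibin_image")) stop("samples need multibin images")
    if (!all(dim(s$image$data)[1:2] == dim(s$labels))) stop("image/label grids differ")
    if (phase == "pretrain" &&
        !s$image$domain %in% c("simulated", "simulated_calibrated"))
      stop("pre-training manifest must contain only simulated-domain entries")
    if (phase == "finetune" && s$image$domain != "real_emulated")
      stop("fine-tuning manifest must contain only real-emulated entries")
  }
  structure(list(samples = samples, phase = phase), class = "dataset_manifest")
}

# --- augmentations ---------------------------------------------------------

# bilinear sample of a matrix at fractional coordinates (outside -> fill)
.sample_bilinear <- function(m, ri, ci, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  val <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    out <- numeric(length(r))
    out[ok] <- m[cbind(r[ok], c[ok])]
    out
  }
  (1 - fr) * (1 - fc) * val(r0, c0) + (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) + fr * fc * val(r0 + 1, c0 + 1)
}

.sample_nearest <- function(m, ri, ci, fill = 0L) {
  H <- nrow(m); W <- ncol(m)
  r <- round(ri); c <- round(ci)
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  out <- rep(fill, length(r))
  out[ok] <- m[cbind(r[ok], c[ok])]
  out
}

# draw one geometric transform (flips + rotation [+ elastic]) and return the
# source-coordinate fields it induces; applied identically to all bins
.draw_transform <- function(H, W, elastic, strength, maxdisp) {
  flip_h <- stats::runif(1) < 0.5
  flip_v <- stats::runif(1) < 0.5
  angle <- stats::runif(1, 0, 360) * pi / 180
  rc <- (H + 1) / 2; cc <- (W + 1) / 2
  ri <- matrix(seq_len(H), H, W)
  ci <- matrix(seq_len(W), H, W, byrow = TRUE)
  y <- ri - rc; x <- ci - cc
  # inverse rotation of the output grid
  xs <- cos(angle) * x + sin(angle) * y
  ys <- -sin(angle) * x + cos(angle) * y
  if (flip_h) xs <- -xs
  if (flip_v) ys <- -ys
  ri <- ys + rc; ci <- xs + cc
  if (elastic) {
    ng <- 8
    smooth3 <- function(m) {
      k <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)
      .conv2_reflect(m, k)
    }
    dxc <- smooth3(matrix(stats::rnorm(ng * ng, 0, strength), ng, ng))
    dyc <- smooth3(matrix(stats::rnorm(ng * ng, 0, strength), ng, ng))
    upsample <- function(cm) {
      rr <- (seq_len(H) - 0.5) / H * (ng - 1) + 1
      cc2 <- (seq_len(W) - 0.5) / W * (ng - 1) + 1
      .sample_bilinear(cm, rep(rr, times = W), rep(cc2, each = H))
    }
    dx <- pmin(pmax(matrix(upsample(dxc), H, W), -maxdisp), maxdisp)
    dy <- pmin(pmax(matrix(upsample(dyc), H, W), -maxdisp), maxdisp)
    ri <- ri + dy; ci <- ci + dx
  }
  list(ri = as.vector(ri), ci = as.vector(ci))
}

.apply_transform <- function(image_arr, labels, tr) {
  d <- dim(image_arr)
  out <- image_arr
  for (b in seq_len(d[3]))
    out[, , b] <- matrix(.sample_bilinear(image_arr[, , b], tr$ri, tr$ci),
                         d[1], d[2])
  lab <- matrix(.sample_nearest(labels, tr$ri, tr$ci, fill = 0L), d[1], d[2])
  list(image = out, labels = lab)
}

#' Pre-training augmentation: flips, rotation and elastic deformation
#'
#' Random horizontal/vertical flips (p = 0.5 each), an in-plane rotation
#' uniform in \[0, 360) degrees (bilinear for the image, nearest for labels)
#' and an elastic deformation from a Gaussian-smoothed 8x8 random
#' displacement grid capped at `elastic_max` pixels — all applied identically
#' to the three bins. Uses the current RNG stream.
#'
#' @param image_arr `H x W x n_bins` array.
#' @param labels integer label matrix.
#' @param config a [train_config()]; `augment = FALSE` returns the inputs
#'   unchanged.
#' @return list with `image` and `labels`.
#' @export
augment_pretrain <- function(image_arr, labels, config = train_config()) {
  if (!config$augment) return(list(image = image_arr, labels = labels))
  tr <- .draw_transform(nrow(labels), ncol(labels), elastic = TRUE,
                        strength = config$elastic_strength,
                        maxdisp = config$elastic_max)
  .apply_transform(image_arr, labels, tr)
}

#' Fine-tuning augmentation: flips and rotation only
#'
#' Real-domain data carry artifacts and noise, so elastic deformation is
#' always disabled in this phase regardless of configuration.
#'
#' @inheritParams augment_pretrain
#' @export
augment_finetune <- function(image_arr, labels, config = train_config()) {
  if (!config$augment) return(list(image = image_arr, labels = labels))
  tr <- .draw_transform(nrow(labels), ncol(labels), elastic = FALSE,
                        strength = 0, maxdisp = 0)
  .apply_transform(image_arr, labels, tr)
}

# --- training loop ---------------------------------------------------------

.frozen_param_names <- function(net, scales) {
  if (length(scales) == 0) return(character(0))
  nms <- names(net$params)
  keep <- unlist(lapply(scales, function(k)
    nms[startsWith(nms, sprintf("enc%d_conv", k))]))
  keep
}

.run_phase <- function(net, manifest, config, losscfg, epochs, frozen_scales,
                       augment_fn, phase) {
  if (length(manifest$samples) == 0) stop("empty manifest")
  skip <- .frozen_param_names(net, frozen_scales)
  frozen_bn <- intersect(unique(sub("(_w|_b|_bn_gamma|_bn_beta)$", "", skip)),
                         names(net$bn_state))
  frozen_bn_state <- net$bn_state[frozen_bn]
  adam <- adam_init(net$params)
  set.seed(config$seed)
  history <- data.frame()
  for (ep in seq_len(epochs)) {
    ord <- sample(seq_along(manifest$samples))
    tot <- fl <- mg <- 0
    for (i in ord) {
      s <- manifest$samples[[i]]
      ag <- augment_fn(s$image$data, s$labels, config)
      fw <- mdunet_forward(net, ag$image, train = TRUE)
      net <- fw$net
      # frozen batch-norm layers keep their running statistics
      for (nm in frozen_bn) net$bn_state[[nm]] <- frozen_bn_state[[nm]]
      gt <- one_hot(ag$labels, net$config$n_materials)
      ls <- total_loss(fw$probs, gt, losscfg, gradient = TRUE)
      if (!is.finite(ls))
        stop("NaN/Inf loss in ", phase, " epoch ", ep, " sample ", i)
      grads <- mdunet_backward(net, fw$tape, attr(ls, "gradient"))
      upd <- adam_step(net$params, grads, adam, config$learning_rate,
                       skip = skip)
      net$params <- upd$params
      adam <- upd$state
      tot <- tot + as.numeric(ls)
      fl <- fl + attr(ls, "focal")
      mg <- mg + attr(ls, "mge")
    }
    n <- length(ord)
    history <- rbind(history, data.frame(phase = phase, epoch = ep,
                                         loss = tot / n, focal = fl / n,
                                         mge = mg / n))
  }
  list(network = net, history = history)
}

#' Pre-train an MD-Unet on simulated scans
#'
#' All parameters are trainable; samples are reshuffled every epoch (seeded)
#' and augmented with [augment_pretrain()].
#'
#' @param network an [build_network()] object.
#' @param manifest a `pretrain` [dataset_manifest()].
#' @param config a [train_config()].
#' @param losscfg a [loss_config()].
#' @return list with `network` (trained) and `history` (per-epoch mean
#'   total/focal/MGE losses).
#' @export
pretrain <- function(network, manifest, config = train_config(),
                     losscfg = loss_config()) {
  if (manifest$phase != "pretrain") stop("expected a pretrain manifest")
  .run_phase(network, manifest, config, losscfg, config$pretrain_epochs,
             frozen_scales = integer(0), augment_fn = augment_pretrain,
             phase = "pretrain")
}

#' Fine-tune a pre-trained MD-Unet on real-domain scans
#'
#' Every parameter of the frozen encoder scales (both convolution blocks and
#' their batch normalizations, running statistics included) is excluded from
#' optimization; elastic deformation is disabled.
#'
#' @inheritParams pretrain
#' @param manifest a `finetune` [dataset_manifest()] (real-emulated entries).
#' @export
finetune <- function(network, manifest, config = train_config(),
                     losscfg = loss_config()) {
  if (manifest$phase != "finetune") stop("expected a finetune manifest")
  .run_phase(network, manifest, config, losscfg, config$finetune_epochs,
             frozen_scales = config$freeze_scales_finetune,
             augment_fn = augment_finetune, phase = "finetune")
}
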