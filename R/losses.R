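# Customized training loss: class-weighted focal loss plus a Sobel-based
# mean gradient error (MGE) that penalizes differences between the gradient-
# magnitude-squared fields of prediction and ground truth, scaled by lambda.

#' Loss configuration
#'
#' @param gamma focusing exponent of the focal term (default 2).
#' @param w_b background-class weight; the default 0.25 down-weights the
#'   dominant background class.
#' @param lambda scale of the mean-gradient-error term (default 0.01).
#' @return object of class `loss_config` carrying `gamma`, `w_b`, `lambda`
#'   and the fixed 3x3 horizontal/vertical Sobel masks.
#' @export
loss_config <- function(gamma = 2, w_b = 0.25, lambda = 0.01) {
  stopifnot(gamma >= 0, lambda >= 0, w_b > 0)
  structure(list(gamma = gamma, w_b = w_b, lambda = lambda,
                 sobel_h = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3),
                 sobel_v = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)),
            class = "loss_config")
}

#' One-hot encode an integer label map
#' @param labels integer matrix with classes `0..K-1`.
#' @param n_classes number of classes K.
#' @return array `H x W x K` of 0/1 indicators.
#' @export
one_hot <- function(labels, n_classes = 4) {
  d <- dim(labels)
  out <- array(0, c(d, n_classes))
  for (k in seq_len(n_classes)) out[, , k] <- labels == (k - 1L)
  out
}

# reflect padding by 1 (mirror without edge repetition, scipy-style)
.reflect_pad1 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  m2 <- rbind(m[2, , drop = FALSE], m, m[n - 1, , drop = FALSE])
  cbind(m2[, 2, drop = FALSE], m2, m2[, p - 1, drop = FALSE])
}

# 2D correlation with a 3x3 kernel under reflect boundary, "same" output
.conv2_reflect <- function(m, k) {
  P <- .reflect_pad1(m)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in 1:3) for (j in 1:3)
    out <- out + k[i, j] * P[(i - 1) + seq_len(H), (j - 1) + seq_len(W)]
  out
}

# adjoint of .conv2_reflect: scatter through the kernel, then fold the
# reflect-padding contributions back onto their source rows/columns
.conv2_reflect_adjoint <- function(dy, k) {
  H <- nrow(dy); W <- ncol(dy)
  dP <- matrix(0, H + 2, W + 2)
  for (i in 1:3) for (j in 1:3)
    dP[(i - 1) + seq_len(H), (j - 1) + seq_len(W)] <-
      dP[(i - 1) + seq_len(H), (j - 1) + seq_len(W)] + k[i, j] * dy
  dx <- dP[2:(H + 1), 2:(W + 1)]
  dx[2, ] <- dx[2, ] + dP[1, 2:(W + 1)]
  dx[H - 1, ] <- dx[H - 1, ] + dP[H + 2, 2:(W + 1)]
  dx[, 2] <- dx[, 2] + dP[2:(H + 1), 1]
  dx[, W - 1] <- dx[, W - 1] + dP[2:(H + 1), W + 2]
  # corners of dP fold through both reflections
  dx[2, 2] <- dx[2, 2] + dP[1, 1]
  dx[2, W - 1] <- dx[2, W - 1] + dP[1, W + 2]
  dx[H - 1, 2] <- dx[H - 1, 2] + dP[H + 2, 1]
  dx[H - 1, W - 1] <- dx[H - 1, W - 1] + dP[H + 2, W + 2]
  dx
}

.check_prob_map <- function(f_P, f_GT) {
  if (!all(dim(f_P) == dim(f_GT))) stop("shape mismatch between f_P and f_GT")
  s <- apply(f_P, c(1, 2), sum)
  if (any(abs(s - 1) > 1e-5) || any(f_P < -1e-12))
    stop("f_P is not a valid per-pixel probability simplex")
}

#' Customized focal loss
#'
#' `(1/N) * sum over pixels and classes of
#' -w_i * (1 - f_Pi)^gamma * f_GTi * log(f_Pi)`, with `w_i = w_b` for the
#' background class (class index 1 of the array) and 1 otherwise; N is the
#' pixel count. Probabilities are clamped to `[1e-7, 1]` before the log.
#' With `gamma = 0, w_b = 1` this is exactly the mean cross-entropy.
#'
#' @param f_P probability array `H x W x K`.
#' @param f_GT_onehot one-hot ground truth of the same shape.
#' @param config a [loss_config()].
#' @param gradient also return the gradient w.r.t. `f_P`.
#' @return scalar loss (with attribute `gradient` when requested).
#' @export
focal_loss <- function(f_P, f_GT_onehot, config = loss_config(),
                       gradient = FALSE) {
  .check_prob_map(f_P, f_GT_onehot)
  K <- dim(f_P)[3]
  N <- prod(dim(f_P)[1:2])
  w <- c(config$w_b, rep(1, K - 1))
  p <- pmin(pmax(f_P, 1e-7), 1)
  wa <- array(rep(w, each = N), dim(f_P))
  term <- -wa * (1 - p)^config$gamma * f_GT_onehot * log(p)
  loss <- sum(term) / N
  if (gradient) {
    g <- config$gamma
    dp <- array(0, dim(f_P))
    active <- f_GT_onehot > 0 & f_P >= 1e-7 & f_P <= 1
    d_all <- wa * (g * (1 - p)^(pmax(g - 1, 0)) * log(p) - (1 - p)^g / p) / N
    dp[active] <- d_all[active]
    attr(loss, "gradient") <- dp
  }
  loss
}

#' Mean gradient error (MGE)
#'
#' Per material class, both maps are convolved with the horizontal and
#' vertical Sobel masks (reflect boundary); the loss is
#' `(1/N) * sum over classes and pixels of (g_GT - g_P)^2` where
#' `g = (map * M_h)^2 + (map * M_v)^2` is the gradient-magnitude-squared
#' field. Zero for identical maps and for spatially constant maps.
#'
#' @inheritParams focal_loss
#' @export
mge_loss <- function(f_P, f_GT_onehot, config = loss_config(),
                     gradient = FALSE) {
  if (!all(dim(f_P) == dim(f_GT_onehot))) stop("shape mismatch")
  K <- dim(f_P)[3]
  N <- prod(dim(f_P)[1:2])
  loss <- 0
  dp <- if (gradient) array(0, dim(f_P)) else NULL
  for (k in seq_len(K)) {
    gh_p <- .conv2_reflect(f_P[, , k], config$sobel_h)
    gv_p <- .conv2_reflect(f_P[, , k], config$sobel_v)
    gh_t <- .conv2_reflect(f_GT_onehot[, , k], config$sobel_h)
    gv_t <- .conv2_reflect(f_GT_onehot[, , k], config$sobel_v)
    g_p <- gh_p^2 + gv_p^2
    g_t <- gh_t^2 + gv_t^2
    diff <- g_t - g_p
    loss <- loss + sum(diff^2) / N
    if (gradient) {
      dgp <- -2 * diff / N
      dp[, , k] <- .conv2_reflect_adjoint(dgp * 2 * gh_p, config$sobel_h) +
        .conv2_reflect_adjoint(dgp * 2 * gv_p, config$sobel_v)
    }
  }
  if (gradient) attr(loss, "gradient") <- dp
  loss
}

#' Total training loss: focal + lambda * MGE
#'
#' @inheritParams focal_loss
#' @return scalar with attributes `focal`, `mge` (components) and, when
#'   `gradient = TRUE`, `gradient` (w.r.t. `f_P`).
#' @export
total_loss <- function(f_P, f_GT_onehot, config = loss_config(),
                       gradient = FALSE) {
  fl <- focal_loss(f_P, f_GT_onehot, config, gradient)
  mg <- mge_loss(f_P, f_GT_onehot, config, gradient)
  out <- as.numeric(fl) + config$lambda * as.numeric(mg)
  attr(out, "focal") <- as.numeric(fl)
  attr(out, "mge") <- as.numeric(mg)
  if (gradient)
    attr(out, "gradient") <- attr(fl, "gradient") +
      config$lambda * attr(mg, "gradient")
  out
}
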