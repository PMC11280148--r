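# Classical image-domain basis material decomposition baselines. Both solve,
# per pixel, the linear per-bin model B x = l (B from basis_matrix(), l the
# pixel's 3-bin LAC vector): MD-LS by unregularized least squares, MD-TV by
# adding an isotropic total-variation penalty per material map, minimized by
# monotone accelerated proximal gradient iterations (TV proximal operator via
# Chambolle's projection algorithm).

#' Per-pixel least-squares material decomposition (MD-LS)
#'
#' Solves `min ||B x - l||^2` per pixel via the normal equations; negative
#' solutions are clamped to zero with the clamp mask recorded.
#'
#' @param image a [multibin_image()] (or raw `H x W x bins` array).
#' @param basis a [basis_matrix()] (bins x materials, bins >= materials).
#' @return object of class `concentration_maps`: list `maps` of per-material
#'   matrices (water volume fraction; solutes in mg/mL), `materials`,
#'   `clamped` mask array, `basis_condition`.
#' @export
md_ls <- function(image, basis) {
  dat <- if (inherits(image, "multibin_image")) image$data else image
  d <- dim(dat)
  if (d[3] < ncol(basis)) stop("need at least as many bins as materials")
  kap <- attr(basis, "condition_number") %||% kappa(basis, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12) stop("singular basis matrix")
  L <- matrix(dat, d[1] * d[2], d[3])           # pixels x bins
  Xt <- t(solve(crossprod(basis), t(basis) %*% t(L)))  # pixels x materials
  clamped <- Xt < 0
  Xt[clamped] <- 0
  maps <- lapply(seq_len(ncol(basis)), function(m) matrix(Xt[, m], d[1], d[2]))
  names(maps) <- colnames(basis)
  structure(list(maps = maps, materials = colnames(basis),
                 clamped = array(clamped, c(d[1], d[2], ncol(basis))),
                 basis_condition = kap),
            class = "concentration_maps")
}

# isotropic total variation of a matrix (forward differences)
.tv <- function(m) {
  dx <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  dy <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
  gx <- matrix(0, nrow(m), ncol(m)); gx[, -ncol(m)] <- dx
  gy <- matrix(0, nrow(m), ncol(m)); gy[-nrow(m), ] <- dy
  sum(sqrt(gx^2 + gy^2))
}

# Chambolle's projection algorithm for the isotropic TV proximal operator:
# argmin_v ||v - y||^2 / 2 + lam * TV(v)
.tv_prox <- function(y, lam, iters = 40) {
  if (lam <= 0) return(y)
  H <- nrow(y); W <- ncol(y)
  px <- matrix(0, H, W); py <- matrix(0, H, W)
  tau <- 0.249
  for (it in seq_len(iters)) {
    # divergence of p
    div <- matrix(0, H, W)
    div[, 1:(W - 1)] <- div[, 1:(W - 1)] + px[, 1:(W - 1)]
    div[, 2:W] <- div[, 2:W] - px[, 1:(W - 1)]
    div[1:(H - 1), ] <- div[1:(H - 1), ] + py[1:(H - 1), ]
    div[2:H, ] <- div[2:H, ] - py[1:(H - 1), ]
    u <- div - y / lam
    gx <- matrix(0, H, W); gx[, -W] <- u[, -1] - u[, -W]
    gy <- matrix(0, H, W); gy[-H, ] <- u[-1, ] - u[-H, ]
    nrm <- sqrt(gx^2 + gy^2)
    px <- (px + tau * gx) / (1 + tau * nrm)
    py <- (py + tau * gy) / (1 + tau * nrm)
  }
  div <- matrix(0, H, W)
  div[, 1:(W - 1)] <- div[, 1:(W - 1)] + px[, 1:(W - 1)]
  div[, 2:W] <- div[, 2:W] - px[, 1:(W - 1)]
  div[1:(H - 1), ] <- div[1:(H - 1), ] + py[1:(H - 1), ]
  div[2:H, ] <- div[2:H, ] - py[1:(H - 1), ]
  y - lam * div
}

#' Total-variation regularized material decomposition (MD-TV)
#'
#' Minimizes `sum_pixels ||B x - l||^2 + beta * sum_materials TV(x_m)`
#' (isotropic TV) by monotone accelerated proximal-gradient iterations with
#' fixed step `1 / L`, `L` from the basis spectral norm. Material columns are
#' rescaled to unit norm internally (with the TV weights adjusted so the
#' stated objective is unchanged) to decouple the very different water and
#' solute scales. The `beta = 0` limit reproduces [md_ls()].
#'
#' @inheritParams md_ls
#' @param beta TV regularization weight (>= 0).
#' @param iters maximum iterations.
#' @param tol stop when the relative objective change drops below `tol`.
#' @return a `concentration_maps` object with fields `objective` (per
#'   iteration), `converged`.
#' @export
md_tv <- function(image, basis, beta = 1e-4, iters = 200, tol = 1e-9) {
  if (beta < 0) stop("beta must be >= 0")
  dat <- if (inherits(image, "multibin_image")) image$data else image
  d <- dim(dat)
  nm <- ncol(basis)
  L <- matrix(dat, d[1] * d[2], d[3])
  sc <- sqrt(colSums(basis^2))
  Bs <- sweep(basis, 2, sc, "/")
  Lip <- 2 * svd(Bs)$d[1]^2
  step <- 1 / Lip
  BtB <- crossprod(Bs); BtL <- t(Bs) %*% t(L)       # materials x pixels
  # objective in original variables x_m = y_m / sc_m
  obj <- function(Y) {
    R <- Bs %*% Y - t(L)
    v <- sum(R * R)
    if (beta > 0) for (m in seq_len(nm))
      v <- v + beta * .tv(matrix(Y[m, ] / sc[m], d[1], d[2]))
    v
  }
  # warm start at the unclamped least-squares solution: the exact fixed
  # point of the beta = 0 iteration
  Y <- solve(BtB, BtL)
  Z <- Y
  tprev <- 1
  objs <- obj(Y)
  converged <- FALSE
  prox_step <- function(W) {
    G <- W - step * 2 * (BtB %*% W - BtL)
    if (beta > 0) for (m in seq_len(nm)) {
      lam <- step * beta / sc[m]   # prox weight in scaled variables
      G[m, ] <- as.vector(.tv_prox(matrix(G[m, ], d[1], d[2]), lam))
    }
    G
  }
  for (it in seq_len(iters)) {
    Ynew <- prox_step(Z)
    onew <- obj(Ynew)
    if (onew > objs[length(objs)]) {
      # accelerated step overshot: restart momentum and take a plain
      # (monotone) proximal-gradient step from the best iterate
      tprev <- 1
      Ynew <- prox_step(Y)
      onew <- obj(Ynew)
      if (onew > objs[length(objs)]) { Ynew <- Y; onew <- objs[length(objs)] }
    }
    tnew <- (1 + sqrt(1 + 4 * tprev^2)) / 2
    Z <- Ynew + ((tprev - 1) / tnew) * (Ynew - Y)
    relchg <- abs(objs[length(objs)] - onew) / max(objs[length(objs)], 1e-300)
    Y <- Ynew; tprev <- tnew
    objs <- c(objs, onew)
    if (relchg < tol && it > 1) { converged <- TRUE; break }
  }
  if (!converged && beta > 0)
    warning("MD-TV did not converge in ", iters,
            " iterations (final objective ", signif(objs[length(objs)], 6), ")")
  X <- Y / sc
  clamped <- X < 0
  X[clamped] <- 0
  maps <- lapply(seq_len(nm), function(m) matrix(X[m, ], d[1], d[2]))
  names(maps) <- colnames(basis)
  structure(list(maps = maps, materials = colnames(basis),
                 clamped = array(t(clamped), c(d[1], d[2], nm)),
                 basis_condition = attr(basis, "condition_number"),
                 objective = objs, converged = converged || beta == 0),
            class = "concentration_maps")
}

#' Convert concentration maps to a categorical label map
#'
#' A pixel is background when every material map lies below its threshold.
#' Otherwise, solutes whose estimated concentration reaches their detection
#' threshold compete by normalized score (map / reference concentration),
#' ties broken toward the lower class index; a pixel with no detected solute
#' is water (the water volume fraction is close to 1 throughout an aqueous
#' object, so water is the in-object fallback rather than an argmax
#' competitor). Class codes match [phantom_labels()]: 0 background, 1 water,
#' 2 calcium, 3 iodine.
#'
#' @param maps a `concentration_maps` object.
#' @param thresholds named detection thresholds: water volume fraction below
#'   which (absent solutes) a pixel is background, and minimum solute
#'   concentrations (mg/mL).
#' @param references named normalization constants (typical full-scale
#'   concentrations, mg/mL) per solute; must be positive.
#' @return integer label matrix.
#' @export
to_categorical <- function(maps,
                           thresholds = c(water = 0.5, calcium = 50, iodine = 1),
                           references = c(water = 1, calcium = 300, iodine = 10)) {
  if (any(references <= 0)) stop("reference concentrations must be positive")
  mats <- maps$materials
  solutes <- setdiff(mats, "water")
  d <- dim(maps$maps[[1]])
  below <- vapply(mats, function(m) maps$maps[[m]] < thresholds[[m]],
                  matrix(TRUE, d[1], d[2]))
  bg <- apply(below, c(1, 2), all)
  score <- vapply(solutes, function(m) {
    s <- maps$maps[[m]] / references[[m]]
    s[maps$maps[[m]] < thresholds[[m]]] <- -Inf   # not detected
    s
  }, matrix(0, d[1], d[2]))
  sm <- matrix(score, d[1] * d[2], length(solutes))
  cls <- c(calcium = 2L, iodine = 3L)[solutes]
  best <- max.col(sm, ties.method = "first")
  lab <- matrix(cls[best], d[1], d[2])
  lab[matrix(!is.finite(sm[cbind(seq_len(nrow(sm)), best)]), d[1], d[2])] <- 1L
  lab[bg] <- 0L
  lab
}
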