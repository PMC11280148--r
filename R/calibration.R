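# Empirical simulation-to-real LAC calibration: ROI pairs from concentration
# inserts, a 3-parameter exponential (default) or 4-parameter logistic curve
# fitted by iterative nonlinear least squares, applied pixelwise to simulated
# images before pre-training.

#' Extract per-insert, per-bin calibration ROI pairs
#'
#' For every insert and energy bin, the mean over a disk ROI centered on the
#' insert is measured in both the simulated and the real(-emulated) image.
#'
#' @param sim,real co-registered [multibin_image()]s on the same grid.
#' @param spec the [phantom_spec()] both images were scanned from.
#' @param roi_radius ROI radius in mm; ROIs crossing an insert boundary are
#'   shrunk to fit with a warning (error if below one pixel).
#' @return data.frame with columns `material`, `concentration`, `bin`,
#'   `lac_sim`, `lac_real`.
#' @export
extract_pairs <- function(sim, real, spec, roi_radius = NULL) {
  if (!all(dim(sim$data) == dim(real$data)))
    stop("simulated and real images must share the grid")
  n <- dim(sim$data)[1]
  nb <- dim(sim$data)[3]
  ax <- (seq_len(n) - (n + 1) / 2) * sim$pitch
  X <- matrix(ax, n, n, byrow = TRUE); Y <- matrix(ax, n, n, byrow = FALSE)
  rows <- list()
  for (ins in spec$inserts) {
    r <- if (is.null(roi_radius)) 0.6 * ins$radius else roi_radius
    if (r > 0.9 * ins$radius) {
      r <- 0.9 * ins$radius
      warning("ROI shrunk to fit inside the ", ins$material, " insert")
    }
    if (r < sim$pitch) stop("ROI radius below one pixel")
    m <- ((X - ins$center[1])^2 + (Y - ins$center[2])^2) <= r^2
    for (b in seq_len(nb)) {
      rows[[length(rows) + 1]] <- data.frame(
        material = ins$material, concentration = ins$concentration, bin = b,
        lac_sim = mean(sim$data[, , b][m]), lac_real = mean(real$data[, , b][m]))
    }
  }
  do.call(rbind, rows)
}

# model functions and their parameter gradients
.cal_model <- function(variant) {
  switch(variant,
    exp3 = list(
      f = function(p, x) p[1] * exp(-p[2] * x) + p[3],
      grad = function(p, x) {
        e <- exp(-p[2] * x)
        cbind(e, -p[1] * x * e, 1)
      },
      npar = 3L),
    logistic4 = list(
      f = function(p, x) p[1] / (1 + exp(-p[2] * (x - p[3]))) + p[4],
      grad = function(p, x) {
        s <- 1 / (1 + exp(-p[2] * (x - p[3])))
        cbind(s, p[1] * s * (1 - s) * (x - p[3]), -p[1] * s * (1 - s) * p[2], 1)
      },
      npar = 4L),
    stop("unknown variant"))
}

#' Fit the sim-to-real LAC calibration curve
#'
#' Default variant `exp3` is `lac_real = a * exp(-b * lac_sim) + c`,
#' minimized by iterative nonlinear least squares with multi-start
#' initialization: for each start, the linear parameters are profiled out
#' (for fixed `b`, `(a, c)` solve a linear system) and the fit is polished by
#' quasi-Newton iterations with analytic gradients until the gradient norm
#' falls below 1e-10 or 500 iterations. The best residual over starts is
#' kept. Variant `logistic4` adds a fourth parameter
#' (`a / (1 + exp(-b (x - c))) + d`).
#'
#' @param pairs data.frame from [extract_pairs()] (needs `lac_sim`,
#'   `lac_real`), or any data.frame with those columns.
#' @param variant `"exp3"` or `"logistic4"`.
#' @return object of class `lac_fit` with elements `par` (named), `variant`,
#'   `residual_rms`, `fitted`, `residuals`, `converged`, `pairs`.
#' @export
fit_lac_curve <- function(pairs, variant = c("exp3", "logistic4")) {
  variant <- match.arg(variant)
  x <- pairs$lac_sim; y <- pairs$lac_real
  mod <- .cal_model(variant)
  if (length(x) < mod$npar)
    stop("need at least ", mod$npar, " pairs to fit the ", variant, " model")
  if (stats::sd(x) == 0) stop("degenerate pairs: lac_sim values all identical")
  # constant-data shortcut: the a -> 0 branch, model == c
  if (stats::sd(y) == 0) {
    par <- if (variant == "exp3") c(a = 0, b = 0, c = y[1]) else
      c(a = 0, b = 0, c = mean(x), d = y[1])
    return(structure(list(par = par, variant = variant, residual_rms = 0,
                          fitted = rep(y[1], length(y)),
                          residuals = rep(0, length(y)),
                          converged = TRUE, pairs = pairs),
                     class = "lac_fit"))
  }
  sse <- function(p) sum((y - mod$f(p, x))^2)
  gr  <- function(p) as.vector(-2 * t(mod$grad(p, x)) %*% (y - mod$f(p, x)))
  starts <- list()
  if (variant == "exp3") {
    # profile (a, c) for b on a multi-start grid spanning the spec'd
    # {0.1, 1, 10} and beyond, both signs of the decay rate
    for (b0 in c(0.01, 0.1, 0.3, 1, 3, 10, 30, -0.1, -1, -10)) {
      e <- exp(-b0 * x)
      if (any(!is.finite(e)) || stats::sd(e) == 0) next
      co <- tryCatch(stats::lm.fit(cbind(e, 1), y)$coefficients,
                     error = function(e2) NULL)
      if (is.null(co) || any(!is.finite(co))) next
      starts[[length(starts) + 1]] <- c(co[1], b0, co[2])
    }
  } else {
    rngx <- range(x)
    for (b0 in c(0.5, 1, 5, 20, -1, -5)) for (c0 in stats::quantile(x, c(.25, .5, .75))) {
      s <- 1 / (1 + exp(-b0 * (x - c0)))
      if (stats::sd(s) == 0) next
      co <- tryCatch(stats::lm.fit(cbind(s, 1), y)$coefficients,
                     error = function(e2) NULL)
      if (is.null(co) || any(!is.finite(co))) next
      starts[[length(starts) + 1]] <- c(co[1], b0, c0, co[2])
    }
  }
  if (length(starts) == 0) stop("conditioning error: no admissible start found")
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::nlminb(p0, sse, gradient = gr,
                    control = list(iter.max = 500, eval.max = 1000,
                                   abs.tol = 0, rel.tol = 1e-15, x.tol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best))
    stop("fit failure: no start converged")
  converged <- sqrt(sum(gr(best$par)^2)) < 1e-10 || best$objective < 1e-24
  # a genuinely flat optimum with tiny relative gradient also counts
  if (!converged)
    converged <- sqrt(sum(gr(best$par)^2)) < 1e-6 * max(1, best$objective)
  par <- best$par
  # the 4-parameter logistic is only identified up to a sign symmetry
  # (a, b, c, d) ~ (-a, -b, c, a + d); canonicalize to b >= 0
  if (variant == "logistic4" && par[2] < 0)
    par <- c(-par[1], -par[2], par[3], par[1] + par[4])
  names(par) <- if (variant == "exp3") c("a", "b", "c") else c("a", "b", "c", "d")
  fitted <- mod$f(par, x)
  structure(list(par = par, variant = variant,
                 residual_rms = sqrt(mean((y - fitted)^2)),
                 fitted = fitted, residuals = y - fitted,
                 converged = converged, pairs = pairs),
            class = "lac_fit")
}

#' Evaluate a calibration fit at new simulated LAC values
#' @param object a `lac_fit`.
#' @param newdata numeric vector of simulated LACs (1/cm), or a data.frame
#'   with a `lac_sim` column; defaults to the training pairs.
#' @param ... unused.
#' @export
predict.lac_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$pairs$lac_sim
       else if (is.data.frame(newdata)) newdata$lac_sim else newdata
  .cal_model(object$variant)$f(object$par, x)
}

#' @export
coef.lac_fit <- function(object, ...) object$par

#' @export
residuals.lac_fit <- function(object, ...) object$residuals

#' @export
print.lac_fit <- function(x, ...) {
  cat("LAC calibration fit (", x$variant, ")\n", sep = "")
  print(signif(x$par, 6))
  cat("residual RMS:", signif(x$residual_rms, 4),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

#' Fit one calibration curve per energy bin
#'
#' LAC scales differ strongly across bins, so three independent fits are the
#' default calibration.
#'
#' @param pairs data.frame from [extract_pairs()].
#' @param variant forwarded to [fit_lac_curve()].
#' @return list of `lac_fit`, one per bin index present in `pairs`.
#' @export
fit_lac_curves_by_bin <- function(pairs, variant = "exp3") {
  lapply(split(pairs, pairs$bin), fit_lac_curve, variant = variant)
}

#' Apply a calibration fit pixelwise to a multi-bin image
#'
#' Maps a simulated image into the real-emulated LAC scale. Accepts a single
#' `lac_fit` (applied to every bin) or a per-bin list from
#' [fit_lac_curves_by_bin()].
#'
#' @param image a [multibin_image()].
#' @param fit a `lac_fit` or list of them (one per bin).
#' @return a `multibin_image` tagged `simulated_calibrated` (simulated data
#'   mapped onto the real LAC scale).
#' @export
apply_calibration <- function(image, fit) {
  dat <- image$data
  nb <- dim(dat)[3]
  fits <- if (inherits(fit, "lac_fit")) rep(list(fit), nb) else fit
  if (length(fits) != nb) stop("need one fit per bin")
  for (i in seq_len(nb)) {
    fi <- fits[[i]]
    if (!fi$converged) stop("calibration fit for bin ", i, " did not converge")
    dat[, , i] <- .cal_model(fi$variant)$f(fi$par, dat[, , i])
  }
  out <- image
  out$data <- dat
  out$domain <- "simulated_calibrated"
  out
}

#' Serialize calibration fits to JSON
#' @param fits a `lac_fit` or list of them.
#' @param path output path.
#' @export
write_calibration_json <- function(fits, path) {
  if (inherits(fits, "lac_fit")) fits <- list(fits)
  obj <- lapply(fits, function(f)
    list(variant = f$variant, par = as.list(f$par),
         residual_rms = f$residual_rms, converged = f$converged))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
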