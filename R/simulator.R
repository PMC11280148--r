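# Three-bin CT simulation: polychromatic forward projection with analytic
# disk chord lengths (no rasterization error), Poisson counting noise, log
# transform, and filtered back-projection; plus an emulator that manufactures
# a controlled simulation-to-real domain gap.

#' CT acquisition geometry
#'
#' Desk default is parallel-beam (clean analytic oracles); the prototype's
#' fan-beam geometry (source-to-isocenter 227.5 mm, 1440 views, 48 detector
#' modules of 80 row pixels = 3840 detector pixels) is available via
#' [full_protocol_geometry()].
#'
#' @param mode `"parallel"` or `"fan"`.
#' @param fov field of view in mm.
#' @param n_views projections per rotation (parallel: over 180 degrees;
#'   fan: over 360 degrees).
#' @param detector_bins detector pixel count across the fov.
#' @param source_to_isocenter mm, fan mode only.
#' @param detector_modules,pixels_per_module optional physical detector
#'   descriptor; when given, `detector_bins` defaults to their product.
#' @return object of class `ct_geometry`.
#' @export
ct_geometry <- function(mode = c("parallel", "fan"), fov = 250, n_views = 360,
                        detector_bins = 256, source_to_isocenter = 227.5,
                        detector_modules = NULL, pixels_per_module = NULL) {
  mode <- match.arg(mode)
  if (!is.null(detector_modules) && !is.null(pixels_per_module))
    detector_bins <- detector_modules * pixels_per_module
  if (fov <= 0) stop("fov must be > 0")
  if (n_views < 2) stop("need at least 2 views")
  if (mode == "fan" && source_to_isocenter <= fov / 2)
    stop("fan geometry requires source_to_isocenter > fov/2")
  structure(list(mode = mode, fov = fov, n_views = as.integer(n_views),
                 detector_bins = as.integer(detector_bins),
                 source_to_isocenter = source_to_isocenter,
                 detector_modules = detector_modules,
                 pixels_per_module = pixels_per_module),
            class = "ct_geometry")
}

#' The prototype scanner's full-protocol geometry
#' @export
full_protocol_geometry <- function() {
  ct_geometry("fan", fov = 250, n_views = 1440, source_to_isocenter = 227.5,
              detector_modules = 48, pixels_per_module = 80)
}

#' Detector descriptor of a geometry
#' @param geometry a [ct_geometry()].
#' @return list with `row_pixels` and `modules`.
#' @export
detector_descriptor <- function(geometry) {
  list(row_pixels = as.integer(geometry$detector_bins),
       modules = if (is.null(geometry$detector_modules)) 1L
                 else as.integer(geometry$detector_modules))
}

# ray set of a geometry: origin points p and unit directions u, plus the
# perpendicular-offset representation used for fast chord evaluation.
# Returns, for n_rays = detector_bins * n_views, matrices p (n x 2), u (n x 2).
.rays <- function(geometry) {
  nd <- geometry$detector_bins
  nv <- geometry$n_views
  tau <- geometry$fov / nd
  s <- (seq_len(nd) - 0.5 - nd / 2) * tau
  if (geometry$mode == "parallel") {
    th <- (seq_len(nv) - 1) * pi / nv
    # ray through s * (cos th, sin th), direction (-sin th, cos th)
    px <- as.vector(outer(s, cos(th)))
    py <- as.vector(outer(s, sin(th)))
    ux <- rep(-sin(th), each = nd)
    uy <- rep(cos(th), each = nd)
  } else {
    D <- geometry$source_to_isocenter
    be <- (seq_len(nv) - 1) * 2 * pi / nv
    # source at D * a, virtual detector line through origin along t
    ax <- cos(be); ay <- sin(be)
    tx <- -sin(be); ty <- cos(be)
    px <- rep(D * ax, each = nd)
    py <- rep(D * ay, each = nd)
    qx <- as.vector(outer(s, tx)); qy <- as.vector(outer(s, ty))
    dx <- qx - px; dy <- qy - py
    nr <- sqrt(dx^2 + dy^2)
    ux <- dx / nr; uy <- dy / nr
  }
  list(px = px, py = py, ux = ux, uy = uy, tau = tau)
}

# chord lengths (mm) of every ray through one disk
.chords <- function(rays, center, radius) {
  # distance from disk center to the infinite ray line: |cross(c - p, u)|
  d <- abs((center[1] - rays$px) * rays$uy - (center[2] - rays$py) * rays$ux)
  ch <- numeric(length(d))
  hit <- d < radius
  ch[hit] <- 2 * sqrt(radius^2 - d[hit]^2)
  ch
}

#' Polychromatic forward projection of a phantom
#'
#' For each ray and bin, expected counts are the in-bin fluence-weighted sum
#' of `exp(-integral of lac(E) dl)`, with line integrals computed analytically
#' from disk chord lengths. Poisson noise is applied when `flux` is finite
#' (transmitted counts below 1 are clamped to 1 with a warning: photon
#' starvation); `flux = Inf` gives the noiseless expectation.
#'
#' @param spec a [phantom_spec()].
#' @param spectrum a [build_spectrum()] object.
#' @param bin_set a [default_bins()]-style bin set.
#' @param geometry a [ct_geometry()].
#' @param flux total incident photons per ray summed over all bins
#'   (`Inf` = noiseless).
#' @param rng_seed seed for the Poisson draw (required when flux is finite).
#' @return object of class `binned_sinogram`: list `p` of detector x view
#'   matrices of line integrals per bin, plus acquisition metadata.
#' @export
forward_project <- function(spec, spectrum, bin_set = default_bins(),
                            geometry = ct_geometry(), flux = Inf,
                            rng_seed = NULL) {
  if (!is.infinite(flux) && flux <= 0) stop("flux must be > 0")
  rays <- .rays(geometry)
  E <- spectrum$grid$energies
  in_any <- Reduce(`|`, lapply(seq_along(bin_set), function(i) .bin_mask(E, bin_set, i)))
  Eb <- E[in_any]
  w_all <- spectrum$fluence[in_any]
  # disks: water base + inserts as additive LAC differences on top of water
  disks <- c(list(list(center = c(0, 0), radius = spec$base_radius,
                       mu = lac("water", energy = Eb))),
             lapply(spec$inserts, function(ins)
               list(center = ins$center, radius = ins$radius,
                    mu = lac(ins$material, ins$concentration, Eb) -
                         lac("water", energy = Eb))))
  A <- vapply(disks, function(d) .chords(rays, d$center, d$radius),
              numeric(length(rays$px)))                      # rays x disks (mm)
  M <- do.call(rbind, lapply(disks, function(d) d$mu))       # disks x E (1/cm)
  L <- (A %*% M) / 10                                        # line integrals
  Tr <- exp(-L)
  nd <- geometry$detector_bins; nv <- geometry$n_views
  noisy <- is.finite(flux)
  if (noisy) {
    if (is.null(rng_seed)) stop("rng_seed required for a noisy scan")
    set.seed(rng_seed)
  }
  p <- vector("list", length(bin_set))
  flux_per_bin <- numeric(length(bin_set))
  starved <- 0L
  for (i in seq_along(bin_set)) {
    sel <- .bin_mask(Eb, bin_set, i)
    w <- w_all[sel]
    frac <- Tr[, sel, drop = FALSE] %*% w / sum(w)   # transmitted fraction
    if (noisy) {
      N0 <- flux * sum(w) / sum(w_all)
      flux_per_bin[i] <- N0
      N <- stats::rpois(length(frac), N0 * frac)
      nlow <- sum(N < 1)
      if (nlow > 0) { starved <- starved + nlow; N <- pmax(N, 1) }
      pi_ <- -log(N / N0)
    } else {
      flux_per_bin[i] <- Inf
      pi_ <- -log(frac)
    }
    p[[i]] <- matrix(pi_, nd, nv)
  }
  if (starved > 0)
    warning("photon starvation: ", starved, " ray measurements clamped to 1 count")
  structure(list(p = p, flux_per_bin = flux_per_bin, geometry = geometry,
                 bin_set = bin_set), class = "binned_sinogram")
}

# spatial-domain Ram-Lak filter kernel (Kak & Slaney), offsets -(n-1)..(n-1)
.ramp_kernel <- function(n, tau) {
  k <- -(n - 1):(n - 1)
  h <- numeric(length(k))
  h[k == 0] <- 1 / (4 * tau^2)
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi * k[odd] * tau)^2
  h
}

# filter one sinogram (detector x views) with the ramp (optionally Hann-
# apodized); returns filtered projections in 1/mm units after * tau.
.filter_projections <- function(P, tau, filter) {
  nd <- nrow(P)
  L <- 2^ceiling(log2(4 * nd))
  h <- .ramp_kernel(nd, tau)
  hpad <- numeric(L)
  hpad[1:(2 * nd - 1)] <- h
  H <- stats::fft(hpad)
  if (filter == "hann") {
    f <- c(seq(0, L / 2), seq(-L / 2 + 1, -1)) / L  # cycles per sample
    H <- H * (0.5 + 0.5 * cos(2 * pi * f))
  }
  Ppad <- rbind(P, matrix(0, L - nd, ncol(P)))
  Q <- Re(stats::mvfft(stats::mvfft(Ppad) * H, inverse = TRUE)) / L
  # convolution offset: kernel center sits at index nd
  Q[nd:(2 * nd - 1), , drop = FALSE] * tau
}

#' Filtered back-projection reconstruction of a binned sinogram
#'
#' Standard FBP: frequency-domain Ram-Lak ramp (optional Hann apodization)
#' and linear-interpolation backprojection; fan-beam data use the flat
#' equidistant-detector weighting. Output pixel values are effective LACs in
#' 1/cm on an `n_pixels` grid spanning the field of view.
#'
#' @param sinogram a [forward_project()] result.
#' @param geometry a [ct_geometry()]; defaults to the sinogram's own.
#' @param filter `"ramp"` or `"hann"`.
#' @param n_pixels reconstruction grid size (default: detector bin count).
#' @return object of class `multibin_image`.
#' @export
fbp_reconstruct <- function(sinogram, geometry = sinogram$geometry,
                            filter = c("ramp", "hann"), n_pixels = NULL) {
  filter <- match.arg(filter)
  nd <- geometry$detector_bins; nv <- geometry$n_views
  for (P in sinogram$p)
    if (!all(dim(P) == c(nd, nv))) stop("sinogram shape does not match geometry")
  if (is.null(n_pixels)) n_pixels <- nd
  n <- n_pixels
  pitch <- geometry$fov / n
  tau <- geometry$fov / nd
  ax <- (seq_len(n) - (n + 1) / 2) * pitch
  X <- matrix(ax, n, n, byrow = TRUE)   # x by column
  Y <- matrix(ax, n, n, byrow = FALSE)  # y by row (downward)
  slices <- vector("list", length(sinogram$p))
  for (b in seq_along(sinogram$p)) {
    P <- sinogram$p[[b]]
    if (geometry$mode == "fan") {
      D <- geometry$source_to_isocenter
      s <- (seq_len(nd) - 0.5 - nd / 2) * tau
      P <- P * (D / sqrt(D^2 + s^2))
    }
    Q <- .filter_projections(P, tau, filter)
    acc <- matrix(0, n, n)
    if (geometry$mode == "parallel") {
      th <- (seq_len(nv) - 1) * pi / nv
      for (v in seq_len(nv)) {
        s <- X * cos(th[v]) + Y * sin(th[v])
        u <- s / tau + nd / 2 + 0.5
        i0 <- floor(u); fr <- u - i0
        i0 <- pmin(pmax(i0, 1), nd); i1 <- pmin(i0 + 1, nd)
        qv <- Q[, v]
        acc <- acc + (1 - fr) * qv[i0] + fr * qv[i1]
      }
      img <- acc * pi / nv
    } else {
      D <- geometry$source_to_isocenter
      be <- (seq_len(nv) - 1) * 2 * pi / nv
      for (v in seq_len(nv)) {
        ra <- X * cos(be[v]) + Y * sin(be[v])
        rt <- -X * sin(be[v]) + Y * cos(be[v])
        U <- (D - ra) / D
        sp <- rt / U
        u <- sp / tau + nd / 2 + 0.5
        i0 <- floor(u); fr <- u - i0
        i0 <- pmin(pmax(i0, 1), nd); i1 <- pmin(i0 + 1, nd)
        qv <- Q[, v]
        acc <- acc + ((1 - fr) * qv[i0] + fr * qv[i1]) / U^2
      }
      img <- acc * pi / nv
    }
    slices[[b]] <- img * 10  # 1/mm -> 1/cm
  }
  multibin_image(array(unlist(slices), dim = c(n, n, length(slices))),
                 pitch = pitch, fov = geometry$fov, domain = "simulated",
                 geometry = geometry, filter = filter)
}

#' Construct a multi-bin image container
#'
#' @param data array `n x n x n_bins` of effective LACs (1/cm), bins ordered
#'   bin 1 (lowest energies) to bin 3.
#' @param pitch pixel pitch in mm.
#' @param fov field of view in mm.
#' @param domain `"simulated"` or `"real_emulated"`.
#' @param geometry,filter optional acquisition metadata.
#' @export
multibin_image <- function(data, pitch, fov, domain = "simulated",
                           geometry = NULL, filter = NULL) {
  stopifnot(length(dim(data)) == 3)
  structure(list(data = data, pitch = pitch, fov = fov, domain = domain,
                 geometry = geometry, filter = filter),
            class = "multibin_image")
}

#' @export
print.multibin_image <- function(x, ...) {
  d <- dim(x$data)
  cat("multibin_image: ", d[1], "x", d[2], " pixels, ", d[3], " bins, ",
      "pitch ", signif(x$pitch, 4), " mm, domain ", x$domain, "\n", sep = "")
  invisible(x)
}

#' Simulate a full three-bin scan of a phantom
#'
#' Forward projection followed by FBP, paired with the ground-truth label
#' map: the unit of a training sample.
#'
#' @inheritParams forward_project
#' @param filter FBP apodization (default Hann for noisy scans, ramp
#'   otherwise).
#' @param n_pixels reconstruction grid (default: the phantom's own grid).
#' @return list with `image` ([multibin_image()]) and `labels` (int matrix).
#' @export
simulate_scan <- function(spec, spectrum, bin_set = default_bins(),
                          geometry = ct_geometry(), flux = Inf,
                          rng_seed = NULL, filter = NULL, n_pixels = NULL) {
  if (is.null(filter)) filter <- if (is.finite(flux)) "hann" else "ramp"
  if (is.null(n_pixels)) n_pixels <- spec$n_pixels
  sg <- forward_project(spec, spectrum, bin_set, geometry, flux, rng_seed)
  img <- fbp_reconstruct(sg, geometry, filter, n_pixels)
  list(image = img, labels = phantom_labels(spec))
}

#' Exact per-bin linear-model image of a phantom
#'
#' Rasterizes the phantom directly in effective-bin-LAC space: every pixel
#' carries the basis-linear prediction `B x` of its material (no projection,
#' reconstruction blur or beam hardening). Useful as the exact forward model
#' for decomposition oracles.
#'
#' @param spec a [phantom_spec()].
#' @param spectrum a [build_spectrum()] object.
#' @param bin_set a [default_bins()]-style bin set.
#' @return a [multibin_image()] (domain `"simulated"`).
#' @export
effective_bin_image <- function(spec, spectrum, bin_set = default_bins()) {
  n <- spec$n_pixels
  lab <- phantom_labels(spec)
  dat <- array(0, c(n, n, length(bin_set)))
  for (b in seq_along(bin_set)) {
    img <- matrix(0, n, n)
    img[lab == 1L] <- effective_bin_lac(spectrum, b, "water", bin_set = bin_set)
    for (ins in spec$inserts) {
      v <- effective_bin_lac(spectrum, b, ins$material, ins$concentration,
                             bin_set = bin_set)
      cls <- if (ins$material == "calcium") 2L else 3L
      co <- .pixel_coords(spec)
      m <- ((co$x - ins$center[1])^2 + (co$y - ins$center[2])^2) <= ins$radius^2
      img[m] <- v
    }
    dat[, , b] <- img
  }
  multibin_image(dat, pitch = spec$pitch, fov = spec$fov, domain = "simulated")
}

#' Configure the simulation-to-real domain gap
#'
#' The emulator applies, in order: a pointwise monotone nonlinearity of the
#' calibration model's own exponential form (`a * exp(-b * LAC) + c`),
#' additive Gaussian noise, and an optional radius-dependent sinusoidal ring
#' gain. Defaults give a mild saturating compression that vanishes at LAC 0.
#'
#' @param a,b,c nonlinearity parameters (scalars, or length-3 per bin);
#'   `NULL` for `a` disables the nonlinearity.
#' @param noise_sd additive Gaussian noise sd in 1/cm.
#' @param ring_amplitude,ring_period_mm optional ring-artifact gain.
#' @export
gap_config <- function(a = -0.9, b = 1.1, c = 0.9, noise_sd = 0.01,
                       ring_amplitude = 0, ring_period_mm = 20) {
  structure(list(a = a, b = b, c = c, noise_sd = noise_sd,
                 ring_amplitude = ring_amplitude,
                 ring_period_mm = ring_period_mm), class = "gap_config")
}

#' An identity (no-op) domain gap
#' @export
identity_gap <- function() gap_config(a = NULL, noise_sd = 0, ring_amplitude = 0)

#' Emulate the real scanner domain from a simulated image
#'
#' Stands in for the prototype scanner: re-tags the image as
#' `"real_emulated"` after applying the configured gap.
#'
#' @param image a simulated-domain [multibin_image()].
#' @param gap a [gap_config()].
#' @param rng_seed seed for the noise draw.
#' @return a `multibin_image` tagged `real_emulated`.
#' @export
emulate_real_domain <- function(image, gap = gap_config(), rng_seed = 1) {
  if (image$domain != "simulated")
    stop("emulate_real_domain expects a simulated-domain image")
  dat <- image$data
  nb <- dim(dat)[3]
  if (!is.null(gap$a)) {
    a <- rep_len(gap$a, nb); b <- rep_len(gap$b, nb); cc <- rep_len(gap$c, nb)
    for (i in seq_len(nb)) dat[, , i] <- a[i] * exp(-b[i] * dat[, , i]) + cc[i]
  }
  set.seed(rng_seed)
  if (gap$noise_sd > 0)
    dat <- dat + stats::rnorm(length(dat), 0, gap$noise_sd)
  if (gap$ring_amplitude > 0) {
    n <- dim(dat)[1]
    ax <- (seq_len(n) - (n + 1) / 2) * image$pitch
    r <- sqrt(outer(ax^2, ax^2, `+`))
    gain <- 1 + gap$ring_amplitude * sin(2 * pi * r / gap$ring_period_mm)
    for (i in seq_len(nb)) dat[, , i] <- dat[, , i] * gain
  }
  out <- image
  out$data <- dat
  out$domain <- "real_emulated"
  out
}
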