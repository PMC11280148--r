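# Digital multi-energy phantoms: circular water base plus calcium / iodine
# inserts with known concentrations. Coordinates: physical origin at
# isocenter, x to the right, y increasing downward; image arrays are
# [row, col] with row 1 at the top. Pixel membership is decided by the pixel
# center point; inserts are innermost and override the base.

#' Concentration sets of the multi-energy phantom inserts
#'
#' The real phantom carries Ca at 100/300 mg/mL and I at 2/5/10/15 mg/mL;
#' the simulated pool augments these to 8 calcium and 9 iodine levels.
#'
#' @return list with `real_ca`, `sim_ca`, `real_i`, `sim_i` (mg/mL).
#' @export
concentration_sets <- function() {
  sets <- list(real_ca = c(100, 300),
               sim_ca  = c(100, 200, 300, 400, 500, 600, 900, 1000),
               real_i  = c(2, 5, 10, 15),
               sim_i   = c(2, 4, 5, 8, 10, 15, 20, 25, 30))
  stopifnot(all(sets$real_ca %in% sets$sim_ca), all(sets$real_i %in% sets$sim_i),
            all(unlist(sets) > 0))
  sets
}

#' Count the augmentation-only simulated concentrations
#'
#' @param sets a [concentration_sets()] list.
#' @return integer vector `c(extra_ca, extra_i)`: sizes of the simulated
#'   minus real concentration sets.
#' @export
augmentation_counts <- function(sets = concentration_sets()) {
  c(extra_ca = length(setdiff(sets$sim_ca, sets$real_ca)),
    extra_i  = length(setdiff(sets$sim_i, sets$real_i)))
}

#' Specify a cylindrical insert
#'
#' @param material `"calcium"` or `"iodine"`.
#' @param concentration mg/mL (> 0).
#' @param center `c(x, y)` in mm from isocenter (y downward).
#' @param radius mm (> 0).
#' @export
insert_spec <- function(material, concentration, center, radius) {
  material <- match.arg(material, c("calcium", "iodine"))
  if (radius <= 0) stop("insert radius must be > 0")
  if (concentration <= 0) stop("insert concentration must be > 0")
  structure(list(material = material, concentration = concentration,
                 center = as.numeric(center), radius = radius),
            class = "insert_spec")
}

#' Specify a digital multi-energy phantom
#'
#' @param base_radius mm; water base disk radius.
#' @param inserts list of [insert_spec()] objects; pairwise non-overlapping
#'   and strictly inside the base.
#' @param n_pixels image size (square).
#' @param fov field of view in mm (default 250, the system maximum).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(base_radius = 100, inserts = list(),
                         n_pixels = 256, fov = 250) {
  if (2 * base_radius > fov) stop("base disk does not fit in the field of view")
  for (ins in inserts) {
    d <- sqrt(sum(ins$center^2))
    if (d + ins$radius >= base_radius)
      stop("insert at (", ins$center[1], ", ", ins$center[2],
           ") does not lie strictly inside the base disk")
  }
  if (length(inserts) > 1) {
    for (i in seq_len(length(inserts) - 1)) for (j in (i + 1):length(inserts)) {
      d <- sqrt(sum((inserts[[i]]$center - inserts[[j]]$center)^2))
      if (d <= inserts[[i]]$radius + inserts[[j]]$radius)
        stop("inserts ", i, " and ", j, " overlap")
    }
  }
  structure(list(base_radius = base_radius, inserts = inserts,
                 n_pixels = as.integer(n_pixels), fov = fov,
                 pitch = fov / n_pixels),
            class = "phantom_spec")
}

# pixel-center coordinate grids (mm); row-major [row, col] arrays
.pixel_coords <- function(spec) {
  n <- spec$n_pixels
  ax <- (seq_len(n) - (n + 1) / 2) * spec$pitch
  list(x = matrix(ax, n, n, byrow = TRUE),   # column -> x
       y = matrix(ax, n, n, byrow = FALSE))  # row -> y (downward)
}

#' Rasterize a phantom at a single photon energy
#'
#' Pixel value is the LAC (1/cm) of the material whose shape contains the
#' pixel center (innermost shape wins); background pixels are 0.
#'
#' @param spec a [phantom_spec()].
#' @param energy photon energy in keV.
#' @return `n_pixels` x `n_pixels` numeric matrix (1/cm).
#' @export
rasterize <- function(spec, energy) {
  co <- .pixel_coords(spec)
  img <- matrix(0, spec$n_pixels, spec$n_pixels)
  base <- (co$x^2 + co$y^2) <= spec$base_radius^2
  img[base] <- lac("water", energy = energy)
  for (ins in spec$inserts) {
    m <- ((co$x - ins$center[1])^2 + (co$y - ins$center[2])^2) <= ins$radius^2
    img[m] <- lac(ins$material, ins$concentration, energy)
  }
  img
}

#' Ground-truth material label map of a phantom
#'
#' Classes: 0 background, 1 water, 2 calcium, 3 iodine. Uses the same
#' pixel-center membership rule as [rasterize()], so labels and LAC images
#' agree on support at every energy.
#'
#' @param spec a [phantom_spec()].
#' @return integer matrix of class labels.
#' @export
phantom_labels <- function(spec) {
  co <- .pixel_coords(spec)
  lab <- matrix(0L, spec$n_pixels, spec$n_pixels)
  base <- (co$x^2 + co$y^2) <= spec$base_radius^2
  lab[base] <- 1L
  cls <- c(calcium = 2L, iodine = 3L)
  for (ins in spec$inserts) {
    m <- ((co$x - ins$center[1])^2 + (co$y - ins$center[2])^2) <= ins$radius^2
    lab[m] <- cls[[ins$material]]
  }
  lab
}

#' Randomly sample a phantom specification
#'
#' Inserts are drawn by rejection sampling: concentrations uniformly from the
#' simulated sets, radii uniform in `size_range`, centers uniform inside the
#' base with a full-insert margin; placements overlapping an existing insert
#' are rejected. Reproducible for a given seed.
#'
#' @param rng_seed integer seed.
#' @param sets a [concentration_sets()] list.
#' @param size_range insert radius range in mm.
#' @param count_range integer range for the number of inserts.
#' @param base_radius,n_pixels,fov forwarded to [phantom_spec()].
#' @param budget rejection-sampling attempt budget per phantom.
#' @return a [phantom_spec()].
#' @export
sample_phantom <- function(rng_seed, sets = concentration_sets(),
                           size_range = c(8, 18), count_range = c(2, 6),
                           base_radius = 100, n_pixels = 256, fov = 250,
                           budget = 1000) {
  if (length(size_range) != 2 || size_range[1] > size_range[2])
    stop("invalid size_range")
  set.seed(rng_seed)
  n_ins <- if (count_range[1] == count_range[2]) count_range[1] else
    sample(count_range[1]:count_range[2], 1)
  inserts <- list()
  tries <- 0
  while (length(inserts) < n_ins) {
    tries <- tries + 1
    if (tries > budget)
      stop("could not place ", n_ins, " inserts within the sampling budget")
    material <- sample(c("calcium", "iodine"), 1)
    conc <- if (material == "calcium") sample(sets$sim_ca, 1) else sample(sets$sim_i, 1)
    r <- stats::runif(1, size_range[1], size_range[2])
    # uniform in the admissible disk of centers
    rr <- (base_radius - r - 1) * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    ctr <- c(rr * cos(th), rr * sin(th))
    ok <- TRUE
    for (ins in inserts)
      if (sqrt(sum((ins$center - ctr)^2)) <= ins$radius + r + 1) { ok <- FALSE; break }
    if (ok) inserts[[length(inserts) + 1]] <- insert_spec(material, conc, ctr, r)
  }
  phantom_spec(base_radius, inserts, n_pixels, fov)
}

#' The Fig-4-style calibration phantom layout
#'
#' Two calcium inserts (100, 300 mg/mL) and four iodine inserts
#' (2, 5, 10, 15 mg/mL), 15 mm radius, evenly placed on a ring.
#'
#' @param base_radius,n_pixels,fov forwarded to [phantom_spec()].
#' @param insert_radius insert radius in mm.
#' @export
calibration_phantom <- function(base_radius = 100, n_pixels = 256, fov = 250,
                                insert_radius = 15) {
  sets <- concentration_sets()
  conc <- c(sets$real_ca, sets$real_i)
  mat <- c(rep("calcium", 2), rep("iodine", 4))
  ring <- base_radius * 0.55
  th <- 2 * pi * (seq_along(conc) - 1) / length(conc)
  inserts <- lapply(seq_along(conc), function(i)
    insert_spec(mat[i], conc[i], ring * c(cos(th[i]), sin(th[i])), insert_radius))
  phantom_spec(base_radius, inserts, n_pixels, fov)
}
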