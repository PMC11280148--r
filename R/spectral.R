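# Material registry: density (g/cm^3) and K-edge (keV) handled as a split
# interpolation branch. Only iodine's K-edge falls inside the imaging range;
# the low-keV edges of Ca/Al are smoothed over by the coarse shipped tables.
.material_registry <- list(
  water    = list(density = 1.000, kedge = NA_real_),
  calcium  = list(density = 1.550, kedge = NA_real_),
  iodine   = list(density = 4.930, kedge = 33.2),
  aluminum = list(density = 2.699, kedge = NA_real_)
)

.pcdmd_cache <- new.env(parent = emptyenv())

#' Energy grid for spectral computations
#'
#' @param from,to grid limits in keV (must lie within \[1, 140\]).
#' @param step grid spacing in keV (> 0).
#' @return object of class `energy_grid` with fields `energies` and `step`.
#' @export
energy_grid <- function(from = 1, to = 140, step = 1) {
  if (step <= 0) stop("energy grid step must be > 0")
  if (from < 1 || to > 140 || from >= to)
    stop("energy grid must be strictly increasing and bounded within [1, 140] keV")
  structure(list(energies = seq(from, to, by = step), step = step),
            class = "energy_grid")
}

#' Mass attenuation table for a basis material
#'
#' Loads the packaged NIST-style mass attenuation samples (cm^2/g). Tables are
#' approximate transcriptions sufficient for simulation; the iodine table
#' carries the 33.2 keV K-edge as a discontinuity.
#'
#' @param material one of `"water"`, `"calcium"`, `"iodine"`, `"aluminum"`.
#' @return list with `material`, `energies`, `mass_atten`, `density`, `kedge`.
#' @export
material_table <- function(material) {
  material <- match.arg(material, names(.material_registry))
  key <- paste0("table_", material)
  if (!is.null(.pcdmd_cache[[key]])) return(.pcdmd_cache[[key]])
  path <- system.file("extdata", paste0("mass_atten_", material, ".csv"),
                      package = "pcdmd", mustWork = TRUE)
  tab <- utils::read.csv(path)
  out <- list(material = material,
              energies = tab$energy_keV,
              mass_atten = tab$mass_atten_cm2_g,
              density = .material_registry[[material]]$density,
              kedge = .material_registry[[material]]$kedge)
  .pcdmd_cache[[key]] <- out
  out
}

# log-log interpolation of a mass-attenuation table, split at the K-edge so no
# interpolation bridges the discontinuity.
.interp_mass_atten <- function(tab, energy) {
  if (any(energy < min(tab$energies) | energy > max(tab$energies)))
    stop("energy outside the ", tab$material, " table range [",
         min(tab$energies), ", ", max(tab$energies), "] keV")
  out <- numeric(length(energy))
  branch_of <- function(e) if (is.na(tab$kedge)) rep(1L, length(e)) else 1L + (e >= tab$kedge)
  eb <- branch_of(energy)
  tb <- branch_of(tab$energies)
  for (b in unique(eb)) {
    rows <- tb == b
    sel <- eb == b
    # clamp queries inside the branch's sample range (only reachable within
    # a hair of the edge itself)
    e <- pmin(pmax(energy[sel], min(tab$energies[rows])), max(tab$energies[rows]))
    out[sel] <- exp(stats::approx(log(tab$energies[rows]), log(tab$mass_atten[rows]),
                                  xout = log(e), rule = 1)$y)
  }
  out
}

#' Linear attenuation coefficient of a basis material or aqueous solute
#'
#' Water is evaluated as a pure material at 1.0 g/cm^3. Calcium and iodine are
#' treated as dilute aqueous solutes: the solute adds
#' `mass_atten(E) * concentration / 1000` (concentration in mg/mL) on top of
#' water's attenuation, neglecting water displacement. Aluminum is evaluated
#' as the pure filter metal.
#'
#' @param material material name.
#' @param concentration solute concentration in mg/mL (ignored for water and
#'   aluminum).
#' @param energy photon energy (keV), vectorized.
#' @return linear attenuation coefficient(s) in 1/cm.
#' @export
lac <- function(material, concentration = 0, energy) {
  material <- match.arg(material, names(.material_registry))
  if (any(concentration < 0)) stop("concentration must be >= 0")
  if (material == "water")
    return(.interp_mass_atten(material_table("water"), energy) * 1.0)
  if (material == "aluminum")
    return(.interp_mass_atten(material_table("aluminum"), energy) *
             .material_registry$aluminum$density)
  mu_w <- .interp_mass_atten(material_table("water"), energy)
  mu_s <- .interp_mass_atten(material_table(material), energy)
  mu_w + mu_s * concentration / 1000
}

#' Build the system X-ray spectrum
#'
#' Analytic Kramers bremsstrahlung (photon fluence proportional to
#' `(kvp - E) / E` for `E <= kvp`) hardened by an aluminum filter whose
#' thickness is solved by
#' bisection so that a further `hvl_target` mm of aluminum halves the total
#' fluence (the half-value-layer definition), to relative tolerance 1e-6.
#'
#' @param kvp tube voltage in kV (40-140).
#' @param hvl_target half-value layer in mm aluminum (> 0).
#' @param grid an [energy_grid()]; must span up to `kvp`.
#' @return object of class `spectrum`: `grid`, `fluence` (sums to 1), `kvp`,
#'   `hvl_mm_al`, `filter_mm_al`.
#' @export
build_spectrum <- function(kvp = 140, hvl_target = 5.0, grid = energy_grid(1, kvp)) {
  if (kvp < 40 || kvp > 140) stop("kvp must lie in [40, 140]")
  if (hvl_target <= 0) stop("hvl_target must be > 0")
  E <- grid$energies
  if (max(E) > kvp + 1e-9) E <- E[E <= kvp]
  raw <- pmax((kvp - E) / E, 0)
  mu_al <- lac("aluminum", energy = E)          # 1/cm
  trans <- function(mm) exp(-mu_al * mm / 10)
  frac_after <- function(filter_mm) {
    s <- raw * trans(filter_mm)
    sum(s * trans(hvl_target)) / sum(s)
  }
  lo <- 0; hi <- 100
  if (frac_after(hi) < 0.5)
    stop("no aluminum filter thickness in [0, 100] mm achieves HVL = ",
         hvl_target, " mm at ", kvp, " kV")
  if (frac_after(lo) >= 0.5) {
    filter_mm <- 0
  } else {
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (frac_after(mid) < 0.5) lo <- mid else hi <- mid
      if (abs(frac_after(mid) - 0.5) < 1e-9) break
    }
    filter_mm <- (lo + hi) / 2
  }
  fl <- raw * trans(filter_mm)
  fl_full <- numeric(length(grid$energies))
  fl_full[grid$energies <= kvp] <- fl
  fl_full <- fl_full / sum(fl_full)
  structure(list(grid = grid, fluence = fl_full, kvp = kvp,
                 hvl_mm_al = hvl_target, filter_mm_al = filter_mm),
            class = "spectrum")
}

#' Measure the half-value layer of a spectrum
#'
#' Solves for the aluminum thickness that halves total fluence.
#' @param spectrum a [build_spectrum()] object.
#' @return HVL in mm aluminum.
#' @export
measure_hvl <- function(spectrum) {
  E <- spectrum$grid$energies
  mu_al <- lac("aluminum", energy = E)
  f <- function(mm) sum(spectrum$fluence * exp(-mu_al * mm / 10)) /
    sum(spectrum$fluence) - 0.5
  stats::uniroot(f, c(1e-6, 200), tol = 1e-10)$root
}

#' Mean energy of a spectrum (keV)
#' @param spectrum a [build_spectrum()] object.
#' @export
mean_energy <- function(spectrum) {
  sum(spectrum$grid$energies * spectrum$fluence) / sum(spectrum$fluence)
}

#' Default three-bin energy thresholds
#'
#' Bins 30-50, 50-65 and 65-140 keV (half-open, last bin closed at the top);
#' photons below 30 keV are simulated but excluded from every bin.
#'
#' @return object of class `energy_bins`: list of `c(low, high)` intervals.
#' @export
default_bins <- function() {
  structure(list(c(30, 50), c(50, 65), c(65, 140)), class = "energy_bins")
}

# indices of grid energies falling in bin i of a bin set (last bin closed top)
.bin_mask <- function(energies, bin_set, i) {
  b <- bin_set[[i]]
  m <- energies >= b[1] & energies < b[2]
  if (i == length(bin_set)) m <- m | energies == b[2]
  m
}

#' Fluence-weighted effective linear attenuation coefficient in a bin
#'
#' @param spectrum a [build_spectrum()] object.
#' @param bin numeric `c(low, high)` in keV, or an index into `bin_set`.
#' @param material,concentration as in [lac()].
#' @param bin_set optional [default_bins()]-style set when `bin` is an index.
#' @return effective LAC in 1/cm.
#' @export
effective_bin_lac <- function(spectrum, bin, material, concentration = 0,
                              bin_set = NULL) {
  E <- spectrum$grid$energies
  if (length(bin) == 1 && !is.null(bin_set)) {
    m <- .bin_mask(E, bin_set, bin)
  } else {
    m <- E >= bin[1] & E < bin[2]
    if (!any(E >= bin[2])) m <- m | E == bin[2]
  }
  w <- spectrum$fluence[m]
  if (sum(w) <= 0) stop("empty bin: no fluence inside [", bin[1], ", ", bin[2], ") keV")
  w <- w / sum(w)
  sum(w * lac(material, concentration, E[m]))
}

#' Per-bin basis matrix for linear material decomposition
#'
#' Entry (b, m) is the effective bin-b LAC per unit concentration for solutes
#' (1/cm per mg/mL) and the absolute effective water LAC (1/cm) for water.
#' Within a bin the fluence weights are fixed, so the per-bin model is exactly
#' affine in concentration; beam hardening enters downstream as model mismatch.
#'
#' @param spectrum a [build_spectrum()] object.
#' @param bin_set a [default_bins()]-style bin set.
#' @param materials ordered material names (default water, calcium, iodine).
#' @return matrix (bins x materials) with a `condition_number` attribute.
#' @export
basis_matrix <- function(spectrum, bin_set = default_bins(),
                         materials = c("water", "calcium", "iodine")) {
  B <- matrix(0, length(bin_set), length(materials),
              dimnames = list(paste0("bin", seq_along(bin_set)), materials))
  for (b in seq_along(bin_set)) {
    for (m in seq_along(materials)) {
      mat <- materials[m]
      if (mat == "water") {
        B[b, m] <- effective_bin_lac(spectrum, b, "water", bin_set = bin_set)
      } else {
        # per-unit-concentration solute term (affine in c, so slope at c = 1)
        B[b, m] <- effective_bin_lac(spectrum, b, mat, 1, bin_set = bin_set) -
          effective_bin_lac(spectrum, b, "water", bin_set = bin_set)
      }
    }
  }
  kap <- kappa(B, exact = TRUE)
  if (!is.finite(kap) || kap > 1e8)
    warning("basis matrix is ill-conditioned (condition number ", signif(kap, 3), ")")
  attr(B, "condition_number") <- kap
  B
}

#' Export a spectrum as a two-column CSV (energy_keV, fluence)
#' @param spectrum a [build_spectrum()] object.
#' @param path output file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(energy_keV = spectrum$grid$energies,
                              fluence = spectrum$fluence),
                   path, row.names = FALSE)
  invisible(path)
}
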