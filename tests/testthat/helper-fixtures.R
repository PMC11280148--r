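# Shared, lazily-built fixtures. Everything is generated in code at test
# time; expensive objects are cached for the duration of the test run.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_spectrum <- function() fx_get("spectrum", function() build_spectrum(140, 5))

fx_basis <- function() fx_get("basis", function() basis_matrix(fx_spectrum()))

# a single-energy "spectrum" for monochromatic oracles
mono_spectrum <- function(E0 = 60) {
  structure(list(grid = energy_grid(1, 140),
                 fluence = as.numeric(seq(1, 140) == E0),
                 kvp = 140, hvl_mm_al = NA, filter_mm_al = 0),
            class = "spectrum")
}

mono_bin <- function(E0 = 60) {
  structure(list(c(E0 - 0.5, E0 + 0.5)), class = "energy_bins")
}

fx_geom64 <- function() ct_geometry("parallel", n_views = 60, detector_bins = 64)

# noiseless 64-px scan of the Gammex-layout phantom (22 mm inserts)
fx_gammex_scan <- function() fx_get("gammex_scan", function() {
  spec <- calibration_phantom(n_pixels = 64, insert_radius = 22)
  sc <- simulate_scan(spec, fx_spectrum(), geometry = fx_geom64(), flux = Inf)
  c(sc, list(spec = spec))
})

# pixel-center circular mask on an n x n grid
circle_mask <- function(n, pitch, center = c(0, 0), radius) {
  ax <- (seq_len(n) - (n + 1) / 2) * pitch
  X <- matrix(ax, n, n, byrow = TRUE); Y <- matrix(ax, n, n)
  (X - center[1])^2 + (Y - center[2])^2 <= radius^2
}

# tiny network + random input used by several nn tests
fx_tiny_net <- function() fx_get("tiny_net", function() {
  build_network(mdunet_config(n_scales = 2, base_channels = 3), rng_seed = 7)
})
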