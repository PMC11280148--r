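# Forward projection (analytic chords), FBP reconstruction, and the
# real-domain emulator.

test_that("monochromatic projections obey the Beer-Lambert chord law", {
  g <- ct_geometry("parallel", n_views = 4, detector_bins = 64)
  spec <- phantom_spec(80, list(insert_spec("iodine", 10, c(20, 10), 15)),
                       n_pixels = 64)
  E0 <- 60
  sg <- forward_project(spec, mono_spectrum(E0), mono_bin(E0), g, flux = Inf)
  tau <- g$fov / g$detector_bins
  s <- (seq_len(64) - 0.5 - 32) * tau
  th <- (seq_len(4) - 1) * pi / 4
  chord <- function(s0, c0, r) {
    d2 <- r^2 - s0^2
    ifelse(d2 > 0, 2 * sqrt(pmax(d2, 0)), 0)
  }
  for (v in 1:4) {
    # signed perpendicular offsets of the two disks for this view
    off_base <- s - 0
    off_ins <- s - (20 * cos(th[v]) + 10 * sin(th[v]))
    p_ref <- (lac("water", energy = E0) * chord(off_base, 0, 80) +
              (lac("iodine", 10, E0) - lac("water", energy = E0)) *
                chord(off_ins, 0, 15)) / 10
    expect_lt(max(abs(sg$p[[1]][, v] - p_ref)), 1e-9)
  }
  # open-beam contract: rays missing every disk carry zero line integral
  sg0 <- forward_project(phantom_spec(80, list(), n_pixels = 64),
                         fx_spectrum(), default_bins(), g, flux = Inf)
  miss <- abs(s) > 80
  for (b in 1:3) expect_lt(max(abs(sg0$p[[b]][miss, ])), 1e-12)
})

test_that("polychromatic projections show beam hardening", {
  g <- ct_geometry("parallel", n_views = 2, detector_bins = 65)
  spec <- phantom_spec(80, list(), n_pixels = 64)
  sp <- fx_spectrum()
  sg <- forward_project(spec, sp, default_bins(), g, flux = Inf)
  central <- 33  # offset 0 ray
  for (b in 1:3) {
    eff <- effective_bin_lac(sp, b, "water", bin_set = default_bins())
    linear <- eff * 2 * 80 / 10
    expect_lt(sg$p[[b]][central, 1], linear)
    # and the deficit is the hardening, largest in bin 1
  }
  d <- vapply(1:3, function(b) {
    eff <- effective_bin_lac(sp, b, "water", bin_set = default_bins())
    1 - sg$p[[b]][central, 1] / (eff * 16)
  }, numeric(1))
  expect_gt(d[1], d[3])
})

test_that("FBP recovers effective LACs, is linear, and respects seeds", {
  sp <- fx_spectrum()
  g <- ct_geometry("parallel", n_views = 180, detector_bins = 128)
  spec <- phantom_spec(40, list(), n_pixels = 128)
  sc <- simulate_scan(spec, sp, geometry = g, flux = Inf)
  roi <- circle_mask(128, sc$image$pitch, radius = 20)
  for (b in 1:3) {
    eff <- effective_bin_lac(sp, b, "water", bin_set = default_bins())
    expect_lt(abs(mean(sc$image$data[, , b][roi]) - eff) / eff, 0.03)
  }
  # zero sinogram -> zero image
  sg0 <- forward_project(phantom_spec(60, list(), n_pixels = 64), sp,
                         default_bins(), fx_geom64(), flux = Inf)
  for (b in 1:3) sg0$p[[b]][] <- 0
  img0 <- fbp_reconstruct(sg0, fx_geom64())
  expect_true(all(img0$data == 0))
  # linearity: reconstruction of a sum equals the sum of reconstructions
  specA <- phantom_spec(50, list(), n_pixels = 64)
  specB <- phantom_spec(70, list(insert_spec("calcium", 300, c(0, 30), 12)),
                        n_pixels = 64)
  sgA <- forward_project(specA, sp, default_bins(), fx_geom64(), flux = Inf)
  sgB <- forward_project(specB, sp, default_bins(), fx_geom64(), flux = Inf)
  sgS <- sgA
  for (b in 1:3) sgS$p[[b]] <- sgA$p[[b]] + sgB$p[[b]]
  imS <- fbp_reconstruct(sgS, fx_geom64())
  imA <- fbp_reconstruct(sgA, fx_geom64())
  imB <- fbp_reconstruct(sgB, fx_geom64())
  expect_lt(max(abs(imS$data - (imA$data + imB$data))), 1e-9)
  # determinism of a noisy scan under a fixed seed
  s1 <- simulate_scan(specB, sp, geometry = fx_geom64(), flux = 1e6, rng_seed = 3)
  s2 <- simulate_scan(specB, sp, geometry = fx_geom64(), flux = 1e6, rng_seed = 3)
  expect_identical(s1$image$data, s2$image$data)
})

test_that("fan-beam reconstruction matches the parallel result on a disk", {
  E0 <- 60
  gf <- ct_geometry("fan", n_views = 360, detector_bins = 128)
  spec <- phantom_spec(60, list(), n_pixels = 128)
  sg <- forward_project(spec, mono_spectrum(E0), mono_bin(E0), gf, flux = Inf)
  img <- fbp_reconstruct(sg, gf)
  roi <- circle_mask(128, img$pitch, radius = 30)
  expect_lt(abs(mean(img$data[, , 1][roi]) / lac("water", energy = E0) - 1),
            0.05)
  expect_error(ct_geometry("fan", source_to_isocenter = 100, fov = 250),
               "source_to_isocenter")
})

test_that("reconstruction noise falls with flux", {
  sp <- fx_spectrum()
  spec <- phantom_spec(60, list(), n_pixels = 64)
  roi <- circle_mask(64, 250 / 64, radius = 25)
  sds <- vapply(seq_along(fluxes <- c(1e4, 1e5, 1e6, 1e7)), function(i) {
    sc <- simulate_scan(spec, sp, geometry = fx_geom64(), flux = fluxes[i],
                        rng_seed = 11)
    stats::sd(sc$image$data[, , 1][roi])
  }, numeric(1))
  expect_identical(order(sds, decreasing = TRUE), seq_along(fluxes))
})

test_that("scanned insert contrasts rank with concentration and peak in bin 1", {
  sp <- fx_spectrum()
  spec <- phantom_spec(90, list(
    insert_spec("calcium", 300, c(-45, 0), 20),
    insert_spec("calcium", 100, c(45, 0), 20),
    insert_spec("iodine", 10, c(0, 45), 20)), n_pixels = 64)
  sc <- simulate_scan(spec, sp, geometry = fx_geom64(), flux = 1e6,
                      rng_seed = 5)
  p <- sc$image$pitch
  roi_of <- function(ctr) circle_mask(64, p, ctr, 12)
  for (b in 1:3)
    expect_gt(mean(sc$image$data[, , b][roi_of(c(-45, 0))]),
              mean(sc$image$data[, , b][roi_of(c(45, 0))]))
  # iodine contrast over water largest in the K-edge bin
  w <- roi_of(c(0, -45))
  contr <- vapply(1:3, function(b)
    mean(sc$image$data[, , b][roi_of(c(0, 45))]) -
      mean(sc$image$data[, , b][w]), numeric(1))
  expect_identical(which.max(contr), 1L)
  # full determinism of the scan pair
  sc2 <- simulate_scan(spec, sp, geometry = fx_geom64(), flux = 1e6,
                       rng_seed = 5)
  expect_identical(sc$image$data, sc2$image$data)
  expect_identical(sc$labels, sc2$labels)
})

test_that("the real-domain emulator applies the configured gap and re-tags", {
  sc <- fx_gammex_scan()
  out <- emulate_real_domain(sc$image, identity_gap(), rng_seed = 1)
  expect_equal(out$data, sc$image$data)
  expect_identical(out$domain, "real_emulated")
  expect_error(emulate_real_domain(out, gap_config()), "simulated-domain")
  # with the default gap, insert ROI means still rank with concentration
  real <- emulate_real_domain(sc$image, gap_config(), rng_seed = 2)
  p <- real$pitch
  ins <- sc$spec$inserts
  ca <- order(vapply(ins, function(i) i$concentration, numeric(1)))
  for (b in 1:3) {
    m_ca <- vapply(ins[ins_is <- vapply(ins, function(i)
      i$material == "calcium", logical(1))], function(i)
        mean(real$data[, , b][circle_mask(64, p, i$center, 12)]), numeric(1))
    conc <- vapply(ins[ins_is], function(i) i$concentration, numeric(1))
    expect_identical(order(m_ca), order(conc))
  }
  # determinism
  real2 <- emulate_real_domain(sc$image, gap_config(), rng_seed = 2)
  expect_identical(real$data, real2$data)
})

test_that("the full-protocol detector descriptor matches the scanner", {
  g <- full_protocol_geometry()
  d <- detector_descriptor(g)
  expect_identical(d$row_pixels, 3840L)
  expect_identical(d$modules, 48L)
  expect_identical(g$n_views, 1440L)
  expect_identical(g$source_to_isocenter, 227.5)
  expect_identical(g$mode, "fan")
})
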