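# Spectrum generation, attenuation tables and the per-bin basis model.

test_that("built spectra close on their half-value layer and harden monotonically", {
  sp <- fx_spectrum()
  expect_equal(measure_hvl(sp), 5.0, tolerance = 1e-6)
  # transmission through hvl_target mm Al is half the total fluence
  E <- sp$grid$energies
  mu <- lac("aluminum", energy = E)
  frac <- sum(sp$fluence * exp(-mu * 5 / 10)) / sum(sp$fluence)
  expect_equal(frac, 0.5, tolerance = 1e-6)
  expect_true(all(sp$fluence >= 0))
  expect_true(all(sp$fluence[E > sp$kvp] == 0))
  # mean energy non-decreasing in hvl_target
  me <- vapply(c(3, 5, 7), function(h) mean_energy(build_spectrum(140, h)),
               numeric(1))
  expect_true(all(diff(me) > 0))
  # HVL closure across targets
  for (h in c(3, 7)) expect_equal(measure_hvl(build_spectrum(140, h)), h,
                                  tolerance = 1e-6)
})

test_that("unreachable or invalid HVL targets raise errors", {
  expect_error(build_spectrum(140, -1), "hvl_target")
  expect_error(build_spectrum(140, 0), "hvl_target")
  # aluminum cannot push the HVL of a 140 kV beam beyond ~17.6 mm
  expect_error(build_spectrum(140, 30), "achieves HVL")
  expect_error(build_spectrum(20, 5), "kvp")
  expect_error(energy_grid(1, 140, step = 0), "step")
  expect_error(energy_grid(0.5, 140), "bounded")
})

test_that("lac follows the dilute additive-mixture rule with a log-log table", {
  E <- c(35, 47.5, 60, 80.2)
  expect_equal(lac("iodine", 0, E), lac("water", energy = E))
  expect_equal(lac("calcium", 0, E), lac("water", energy = E))
  # K-edge discontinuity at 33.2 keV, for any positive concentration
  eps <- 0.005
  expect_gt(lac("iodine", 5, 33.2 + eps), lac("iodine", 5, 33.2 - eps))
  expect_gt(lac("iodine", 5, 33.2 + eps) - lac("water", energy = 33.2 + eps),
            4 * (lac("iodine", 5, 33.2 - eps) - lac("water", energy = 33.2 - eps)))
  # hand log-log interpolation of the shipped calcium table at 57 keV
  tab <- utils::read.csv(system.file("extdata", "mass_atten_calcium.csv",
                                     package = "pcdmd"))
  i <- max(which(tab$energy_keV <= 57))
  lg <- (log(57) - log(tab$energy_keV[i])) /
    (log(tab$energy_keV[i + 1]) - log(tab$energy_keV[i]))
  mu_ca <- exp((1 - lg) * log(tab$mass_atten_cm2_g[i]) +
                 lg * log(tab$mass_atten_cm2_g[i + 1]))
  expect_equal(lac("calcium", 300, 57),
               lac("water", energy = 57) + mu_ca * 300 / 1000,
               tolerance = 1e-10)
  # at a table sample the interpolation is exact
  expect_equal(lac("calcium", 300, 60),
               lac("water", energy = 60) + 0.6578 * 0.3, tolerance = 1e-10)
  expect_error(lac("water", energy = 0.2), "range")
  expect_error(lac("iodine", -1, 60), "concentration")
})

test_that("default bins tile 30-140 keV and weight effective LACs correctly", {
  bins <- default_bins()
  expect_identical(bins[[1]][1], 30)
  expect_identical(bins[[3]][2], 140)
  for (i in 1:2) expect_identical(bins[[i]][2], bins[[i + 1]][1])
  sp <- fx_spectrum()
  # water effective LAC decreases from bin 1 to bin 3 (spectrum hardening)
  effw <- vapply(1:3, function(b)
    effective_bin_lac(sp, b, "water", bin_set = bins), numeric(1))
  expect_true(all(diff(effw) < 0))
  # direct integration oracle for bin 2
  E <- sp$grid$energies
  m <- E >= 50 & E < 65
  w <- sp$fluence[m] / sum(sp$fluence[m])
  expect_equal(effw[2], sum(w * lac("water", energy = E[m])), tolerance = 1e-12)
  # affine in concentration: solute term doubles with concentration
  e1 <- effective_bin_lac(sp, 1, "iodine", 5, bin_set = bins) - effw[1]
  e2 <- effective_bin_lac(sp, 1, "iodine", 10, bin_set = bins) - effw[1]
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  expect_error(effective_bin_lac(sp, c(141, 150), "water"), "empty bin")
})

test_that("the basis matrix is well-formed, invertible and K-edge ordered", {
  B <- fx_basis()
  expect_identical(dim(B), c(3L, 3L))
  expect_true(all(B >= 0))
  expect_gt(abs(det(B)), 0)
  expect_true(is.finite(attr(B, "condition_number")))
  # iodine per-unit-concentration entry larger in bin 1 (contains the K-edge)
  # than in bin 3
  expect_gt(B["bin1", "iodine"], B["bin3", "iodine"])
  # single-material basis: 3 x 1 column of water bin LACs
  Bw <- basis_matrix(fx_spectrum(), materials = "water")
  expect_identical(dim(Bw), c(3L, 1L))
  expect_equal(unname(Bw[, 1]), unname(B[, "water"]))
  # permuting materials permutes columns
  Bp <- basis_matrix(fx_spectrum(), materials = c("iodine", "water", "calcium"))
  expect_equal(unname(Bp[, "iodine"]), unname(B[, "iodine"]))
  expect_equal(unname(Bp[, "water"]), unname(B[, "water"]))
})
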