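# Sim-to-real LAC calibration: ROI pair extraction, the exponential /
# logistic curve fits, and pixelwise application.

test_that("extract_pairs measures one ROI pair per insert and bin", {
  sc <- fx_gammex_scan()
  pairs <- extract_pairs(sc$image, sc$image, sc$spec)
  # 2 Ca + 4 I inserts x 3 bins
  expect_identical(nrow(pairs), 18L)
  expect_equal(pairs$lac_sim, pairs$lac_real)
  # ROI mean of a constant image is the constant
  cimg <- sc$image; cimg$data[] <- 0.42
  p2 <- extract_pairs(cimg, cimg, sc$spec)
  expect_true(all(abs(p2$lac_sim - 0.42) < 1e-12))
  expect_error(extract_pairs(sc$image, sc$image, sc$spec, roi_radius = 0.1),
               "below one pixel")
})

test_that("the exponential fit recovers parameters and bounds its residual", {
  x <- seq(0.05, 1.2, length.out = 20)
  y <- 0.5 * exp(-2 * x) + 0.1
  f <- fit_lac_curve(data.frame(lac_sim = x, lac_real = y))
  expect_lt(max(abs(coef(f) - c(0.5, 2, 0.1))), 1e-6)
  expect_true(f$converged)
  expect_lt(f$residual_rms, 1e-8)
  expect_equal(predict(f, x), y, tolerance = 1e-6)
  # negative-amplitude (monotone increasing) branch
  y2 <- -0.9 * exp(-1.1 * x) + 0.9
  f2 <- fit_lac_curve(data.frame(lac_sim = x, lac_real = y2))
  expect_lt(max(abs(coef(f2) - c(-0.9, 1.1, 0.9))), 1e-6)
  # degenerate constant data: the a -> 0 branch
  f3 <- fit_lac_curve(data.frame(lac_sim = x, lac_real = rep(0.3, 20)))
  expect_identical(unname(coef(f3)[["c"]]), 0.3)
  expect_identical(f3$residual_rms, 0)
  # residual never exceeds the best constant model
  set.seed(8)
  yr <- y + stats::rnorm(20, 0, 0.05)
  fr <- fit_lac_curve(data.frame(lac_sim = x, lac_real = yr))
  expect_lte(fr$residual_rms, sqrt(mean((yr - mean(yr))^2)) + 1e-12)
  # error contracts
  expect_error(fit_lac_curve(data.frame(lac_sim = x[1:2], lac_real = y[1:2])),
               "at least")
  expect_error(fit_lac_curve(data.frame(lac_sim = rep(1, 5),
                                        lac_real = y[1:5])), "identical")
})

test_that("noisy fits have calibrated residuals and small bias", {
  x <- seq(0.05, 1.2, length.out = 20)
  y <- 0.5 * exp(-2 * x) + 0.1
  sigma <- 1e-3
  set.seed(99)
  pars <- matrix(0, 100, 3)
  rms <- numeric(100)
  for (r in 1:100) {
    f <- fit_lac_curve(data.frame(lac_sim = x,
                                  lac_real = y + stats::rnorm(20, 0, sigma)))
    pars[r, ] <- coef(f)
    rms[r] <- f$residual_rms
  }
  expect_true(all(rms >= 0.5 * sigma & rms <= 2 * sigma))
  bias <- abs(colMeans(pars) - c(0.5, 2, 0.1)) / c(0.5, 2, 0.1)
  expect_true(all(bias < 0.05))
  # independent oracle: stats::nls on one replicate agrees
  set.seed(123)
  yy <- y + stats::rnorm(20, 0, sigma)
  f <- fit_lac_curve(data.frame(lac_sim = x, lac_real = yy))
  nf <- stats::nls(yy ~ a * exp(-b * x) + c,
                   start = list(a = 0.4, b = 1.5, c = 0.05))
  expect_lt(max(abs(coef(f) - coef(nf))), 1e-4)
})

test_that("the 4-parameter logistic variant round-trips", {
  x <- seq(0.05, 1.2, length.out = 25)
  y <- 0.8 / (1 + exp(-3 * (x - 0.5))) + 0.05
  f <- fit_lac_curve(data.frame(lac_sim = x, lac_real = y),
                     variant = "logistic4")
  # parameters are canonicalized to the b >= 0 representation
  expect_lt(max(abs(coef(f) - c(0.8, 3, 0.5, 0.05))), 1e-5)
  expect_lt(max(abs(predict(f, x) - y)), 1e-7)
})

test_that("calibration application is pixelwise, monotone and closes on ROIs", {
  sc <- fx_gammex_scan()
  real <- emulate_real_domain(sc$image, gap_config(), rng_seed = 21)
  pairs <- extract_pairs(sc$image, real, sc$spec)
  fits <- fit_lac_curves_by_bin(pairs)
  expect_length(fits, 3L)
  cal <- apply_calibration(sc$image, fits)
  expect_identical(cal$domain, "simulated_calibrated")
  # closure: calibrated simulated ROI means match emulated-real ROI means
  # within twice the fit residual (plus the emulator's noise floor)
  chk <- extract_pairs(cal, real, sc$spec)
  for (b in 1:3) {
    sel <- chk$bin == b
    tol <- 2 * fits[[b]]$residual_rms + 2 * gap_config()$noise_sd / 5
    expect_lt(max(abs(chk$lac_sim[sel] - chk$lac_real[sel])), tol)
  }
  # fitted curves with b > 0 and a < 0 are increasing: rank order preserved
  for (b in 1:3) {
    pr <- coef(fits[[b]])
    xs <- sort(unique(pairs$lac_sim[pairs$bin == b]))
    expect_true(all(diff(predict(fits[[b]], xs)) > 0) ||
                  all(diff(predict(fits[[b]], xs)) < 0))
  }
  # degenerate fit application: a = 0 maps everything to the constant c
  f0 <- fit_lac_curve(data.frame(lac_sim = seq(0, 1, length.out = 10),
                                 lac_real = rep(0.25, 10)))
  out <- apply_calibration(sc$image, f0)
  expect_true(all(out$data == 0.25))
})
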