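# MD-Unet architecture conformance and the customized loss.

test_that("the default architecture audits to its documented shape", {
  cfg <- mdunet_config()
  expect_identical(count_hidden_layers(cfg), 29L)
  arch <- mdunet_architecture(cfg)
  expect_identical(max(arch$out_ch), 1024L)             # deepest scale
  expect_identical(arch$out_ch[arch$name == "enc5_conv2"], 1024L)
  # counting convention is additive: dropping both gates removes exactly 2
  cfg0 <- mdunet_config(weighted_skip_scales = integer(0))
  expect_identical(count_hidden_layers(cfg0), 27L)
  # hand count of a reduced net: 2 scales, no gates ->
  # 4 enc convs + 1 pool + 1 upconv + 2 dec convs + 1 head = 9
  expect_identical(count_hidden_layers(
    mdunet_config(n_scales = 2, weighted_skip_scales = integer(0))), 9L)
  # channels double per scale from the base width
  expect_identical(arch$out_ch[arch$name == "enc2_conv1"], 128L)
  # the audit also runs on a constructed network object
  # (2 scales, gate on scale 1: 4 + 1 + 1 + 1 + 2 + 1 = 10)
  expect_identical(count_hidden_layers(fx_tiny_net()), 10L)
})

test_that("forward passes produce per-pixel probability simplices", {
  net <- fx_tiny_net()
  fw <- mdunet_forward(net, array(stats::rnorm(16 * 16 * 3), c(16, 16, 3)))
  expect_identical(dim(fw$probs), c(16L, 16L, 4L))
  expect_lt(max(abs(apply(fw$probs, c(1, 2), sum) - 1)), 1e-5)
  expect_true(all(fw$probs >= 0))
  # property: many random inputs keep the simplex invariant
  set.seed(10)
  small <- build_network(mdunet_config(n_scales = 2, base_channels = 2),
                         rng_seed = 2)
  for (i in 1:200) {
    p <- mdunet_forward(small,
                        array(stats::rnorm(4 * 4 * 3, sd = runif(1, 0.1, 5)),
                              c(4, 4, 3)))$probs
    expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-5)
  }
  # non-divisible input sizes are padded and cropped back
  fw2 <- mdunet_forward(net, array(stats::rnorm(10 * 14 * 3), c(10, 14, 3)))
  expect_identical(dim(fw2$probs), c(10L, 14L, 4L))
  expect_error(mdunet_forward(net, array(0, c(8, 8, 2))), "bin depth")
})

test_that("focal loss reduces to cross-entropy and matches hand arithmetic", {
  set.seed(2)
  lab <- matrix(sample(0:3, 36, TRUE), 6, 6)
  gt <- one_hot(lab, 4)
  p <- array(stats::runif(36 * 4, 0.05, 1), c(6, 6, 4))
  p <- p / array(rep(apply(p, c(1, 2), sum), 4), dim(p))
  # independent mean cross-entropy implementation
  ce <- -mean(log(vapply(seq_len(36), function(i) {
    r <- (i - 1) %% 6 + 1; cc <- (i - 1) %/% 6 + 1
    p[r, cc, lab[r, cc] + 1]
  }, numeric(1))))
  expect_equal(as.numeric(focal_loss(p, gt, loss_config(gamma = 0, w_b = 1))),
               ce, tolerance = 1e-6)
  # perfect prediction: loss at the clamping floor
  expect_lt(as.numeric(focal_loss(gt, gt, loss_config())), 1e-10)
  # single pixel, two active classes of four, hand arithmetic
  p1 <- array(c(0.9, 0.1, 0, 0), c(1, 1, 4))
  g1 <- array(c(1, 0, 0, 0), c(1, 1, 4))
  expect_equal(as.numeric(focal_loss(p1, g1, loss_config(gamma = 2, w_b = 1))),
               -(0.1)^2 * log(0.9), tolerance = 1e-12)
  # background weighting scales the background class only
  g0 <- array(c(1, 0, 0, 0), c(1, 1, 4))   # class 0 = background
  expect_equal(as.numeric(focal_loss(p1, g0, loss_config(gamma = 2, w_b = 0.25))),
               0.25 * -(0.1)^2 * log(0.9), tolerance = 1e-12)
  expect_error(focal_loss(p[, , 1:3], gt, loss_config()), "shape")
  expect_error(focal_loss(gt * 2, gt, loss_config()), "simplex")
})

test_that("the Sobel mean gradient error matches a literal transcription", {
  lc <- loss_config()
  set.seed(5)
  lab <- matrix(sample(0:3, 25, TRUE), 5, 5)
  gt <- one_hot(lab, 4)
  expect_identical(as.numeric(mge_loss(gt, gt, lc)), 0)
  # spatially constant maps have zero Sobel response under reflect padding
  cst <- array(rep(c(0.2, 0.3, 0.4, 0.1), each = 25), c(5, 5, 4))
  expect_equal(as.numeric(mge_loss(cst, gt * 0 + 0.25, lc)), 0, tolerance = 1e-20)
  # 5x5 single-class step edge vs a flat prediction: loop-based oracle
  step <- matrix(0, 5, 5); step[, 4:5] <- 1
  gt1 <- array(0, c(5, 5, 2)); gt1[, , 1] <- step; gt1[, , 2] <- 1 - step
  flat <- array(0.5, c(5, 5, 2))
  conv_ref <- function(m, k) {
    P <- rbind(m[2, ], m, m[4, ]); P <- cbind(P[, 2], P, P[, 4])
    out <- matrix(0, 5, 5)
    for (h in 1:5) for (w in 1:5) {
      a <- 0
      for (i in 1:3) for (j in 1:3) a <- a + k[i, j] * P[h + i - 1, w + j - 1]
      out[h, w] <- a
    }
    out
  }
  ref <- 0
  for (cl in 1:2) {
    gT <- conv_ref(gt1[, , cl], lc$sobel_h)^2 + conv_ref(gt1[, , cl], lc$sobel_v)^2
    gP <- conv_ref(flat[, , cl], lc$sobel_h)^2 + conv_ref(flat[, , cl], lc$sobel_v)^2
    ref <- ref + sum((gT - gP)^2) / 25
  }
  expect_equal(as.numeric(mge_loss(flat, gt1, lc)), ref, tolerance = 1e-12)
})

test_that("the total loss composes focal and MGE with the lambda scale", {
  set.seed(6)
  lab <- matrix(sample(0:3, 64, TRUE), 8, 8)
  gt <- one_hot(lab, 4)
  p <- array(stats::runif(64 * 4, 0.01, 1), c(8, 8, 4))
  p <- p / array(rep(apply(p, c(1, 2), sum), 4), dim(p))
  lc <- loss_config()
  tot <- total_loss(p, gt, lc)
  expect_equal(as.numeric(tot),
               as.numeric(focal_loss(p, gt, lc)) +
                 0.01 * as.numeric(mge_loss(p, gt, lc)), tolerance = 1e-15)
  lc0 <- loss_config(lambda = 0)
  expect_equal(as.numeric(total_loss(p, gt, lc0)),
               as.numeric(focal_loss(p, gt, lc0)), tolerance = 1e-15)
  expect_lt(as.numeric(total_loss(gt, gt, lc)), 1e-9)
  # focal loss decreases monotonically along the mixing path toward truth
  vals <- vapply(seq(0, 1, length.out = 11), function(a) {
    q <- (1 - a) * p + a * gt
    as.numeric(focal_loss(q, gt, lc))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals >= 0))
})
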