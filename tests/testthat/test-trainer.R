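# Augmentations, the two-phase training protocol, freezing, determinism.

test_that("augmentations preserve label values and honor their contracts", {
  spec <- phantom_spec(90, list(insert_spec("iodine", 10, c(30, 0), 20)),
                       n_pixels = 64)
  lab <- phantom_labels(spec)
  img <- array(rep(rasterize(spec, 60), 3), c(64, 64, 3))
  tc <- train_config()
  # disabled augmentation is the identity
  tc0 <- train_config(augment = FALSE)
  a0 <- augment_pretrain(img, lab, tc0)
  expect_identical(a0$image, img)
  expect_identical(a0$labels, lab)
  set.seed(31)
  for (i in 1:20) {
    a <- augment_pretrain(img, lab, tc)
    expect_true(all(a$labels %in% 0:3))
    expect_identical(dim(a$image), dim(img))
    # the same geometric transform is applied to every bin: bins stay equal
    expect_equal(a$image[, , 1], a$image[, , 2], tolerance = 1e-12)
  }
  # identity transform (no flips, zero angle, no elastic) reproduces inputs
  idt <- list(ri = as.vector(matrix(seq_len(64), 64, 64)),
              ci = as.vector(matrix(seq_len(64), 64, 64, byrow = TRUE)))
  ai <- pcdmd:::.apply_transform(img, lab, idt)
  expect_equal(ai$image, img, tolerance = 1e-12)
  expect_identical(ai$labels, lab)
  # flips compose to the identity
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  expect_identical(flip(flip(lab)), lab)
})

test_that("elastic deformation approximately preserves region areas", {
  spec <- phantom_spec(100, list(), n_pixels = 128)
  lab <- phantom_labels(spec)
  img <- array(rep(rasterize(spec, 60), 3), c(128, 128, 3))
  tc <- train_config()
  set.seed(99)
  chg <- replicate(100, {
    a <- augment_pretrain(img, lab, tc)
    abs(sum(a$labels == 1L) - sum(lab == 1L)) / sum(lab == 1L)
  })
  expect_lt(max(chg), 0.05)
})

test_that("fine-tuning augmentation never applies elastic deformation", {
  # a centered disk is invariant under rotations and flips up to
  # nearest-neighbor resampling at the rim; elastic deformation (disabled in
  # this phase) would shift hundreds of pixels at default strength
  spec <- phantom_spec(100, list(), n_pixels = 64)
  lab <- phantom_labels(spec)
  img <- array(rep(rasterize(spec, 60), 3), c(64, 64, 3))
  set.seed(5)
  for (i in 1:20) {
    a <- augment_finetune(img, lab, train_config())
    expect_true(all(a$labels %in% c(0L, 1L)))
    # only rim pixels may flip under nearest-neighbor resampling
    expect_lt(sum(a$labels != lab) / sum(lab == 1L), 0.06)
    expect_identical(a$labels[32, 32], 1L)
  }
})

test_that("manifests validate domain tags per phase", {
  sc <- fx_gammex_scan()
  sim_sample <- list(image = sc$image, labels = sc$labels)
  real_sample <- list(image = emulate_real_domain(sc$image, gap_config(), 1),
                      labels = sc$labels)
  expect_error(dataset_manifest(list(sim_sample), "finetune"), "real-emulated")
  expect_error(dataset_manifest(list(real_sample), "pretrain"), "simulated")
  expect_s3_class(dataset_manifest(list(sim_sample), "pretrain"),
                  "dataset_manifest")
  expect_s3_class(dataset_manifest(list(real_sample), "finetune"),
                  "dataset_manifest")
})

test_that("smoke training reduces the loss deterministically and updates all
           parameters, while fine-tuning freezes encoder scale 1", {
  set.seed(1)
  sp <- fx_spectrum()
  mk <- function(s, emulate = FALSE) {
    ps <- sample_phantom(s, size_range = c(18, 30), count_range = c(1, 2),
                         n_pixels = 32)
    sc <- suppressWarnings(
      simulate_scan(ps, sp,
                    geometry = ct_geometry("parallel", n_views = 30,
                                           detector_bins = 32),
                    flux = 1e6, rng_seed = s + 1))
    img <- if (emulate) emulate_real_domain(sc$image, gap_config(), s + 2)
           else sc$image
    list(image = img, labels = sc$labels)
  }
  pre <- dataset_manifest(suppressWarnings(lapply(1:6, function(i)
    mk(400 + i))), "pretrain")
  fin <- dataset_manifest(suppressWarnings(lapply(1:3, function(i)
    mk(500 + i, TRUE))), "finetune")
  cfg <- mdunet_config(n_scales = 2, base_channels = 4)
  tc <- train_config_desk(pretrain_epochs = 6, finetune_epochs = 4, seed = 3)
  net <- build_network(cfg, rng_seed = 3)
  pt <- pretrain(net, pre, tc)
  expect_lt(tail(pt$history$loss, 1), pt$history$loss[1])
  # every parameter tensor moved during unfrozen training
  for (nm in names(net$params))
    expect_false(identical(net$params[[nm]], pt$network$params[[nm]]))
  # determinism: identical seeds give bit-identical training
  pt2 <- pretrain(net, pre, tc)
  expect_identical(pt$network$params, pt2$network$params)
  expect_identical(pt$history, pt2$history)
  # fine-tuning freezes encoder scale 1 (convolutions + normalizations)
  ft <- finetune(pt$network, fin, tc)
  frozen <- grep("^enc1_conv", names(net$params), value = TRUE)
  for (nm in frozen)
    expect_identical(ft$network$params[[nm]], pt$network$params[[nm]])
  for (nm in grep("^enc2_conv", names(net$params), value = TRUE))
    expect_false(identical(ft$network$params[[nm]], pt$network$params[[nm]]))
  # frozen batch-norm running statistics are preserved too
  expect_identical(ft$network$bn_state[["enc1_conv1"]],
                   pt$network$bn_state[["enc1_conv1"]])
  # prediction is deterministic and argmax picks a single class
  v <- mk(600, TRUE)
  p1 <- predict(ft$network, v$image)
  p2 <- predict(ft$network, v$image)
  expect_identical(p1$labels, p2$labels)
  expect_true(all(p1$labels %in% 0:3))
  expect_error(predict(ft$network, array(0, c(32, 32, 2))), "bin depth")
})

test_that("pre-training transfer beats from-scratch training when real data
           and fine-tuning budget are scarce", {
  res <- do.call(rbind, lapply(1:3, function(s) {
    cfg <- experiment_config("desk", seed = s, n_pretrain = 12, n_finetune = 4,
                             train = train_config_desk(pretrain_epochs = 6,
                                                       finetune_epochs = 6,
                                                       seed = s))
    suppressWarnings(transfer_benchmark(s, cfg, include_scratch = TRUE))
  }))
  expect_gte(stats::median(res$miou_transfer), stats::median(res$miou_scratch))
  expect_true(all(res$frozen_identical))
})
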