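# End-to-end experiment driver reproducing the pipeline shape:
# simulate -> calibrate -> pretrain -> finetune -> decompose -> evaluate.
# The "full" preset documents the scanner protocol (1440 views, 3840-pixel
# detector, 5-scale/64-channel network, 87/16 images, 50/100 epochs at
# lr 1e-5); the desk presets scale every knob to minutes on one CPU.

#' Experiment configuration
#'
#' @param preset `"desk"` (default benchmark scale), `"tiny"` (smoke scale)
#'   or `"full"` (the documented full protocol; hours of compute).
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @param ... named overrides of any configuration field.
#' @return object of class `experiment_config` (a nested list).
#' @export
experiment_config <- function(preset = c("desk", "tiny", "full"), seed = 1,
                              ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    desk = list(
      n_pixels = 64, n_views = 60, detector_bins = 64,
      base_radius = 100, fov = 250, size_range = c(18, 30),
      count_range = c(1, 3), flux = 1e6, insert_radius = 22,
      n_pretrain = 30, n_finetune = 8, n_validation = 2,
      net = mdunet_config_desk(),
      train = train_config_desk(),
      loss = loss_config(),
      gap = gap_config(),
      tv_beta = 1e-4, tv_iters = 60,
      kvp = 140, hvl = 5.0),
    tiny = list(
      n_pixels = 32, n_views = 30, detector_bins = 32,
      base_radius = 100, fov = 250, size_range = c(20, 30),
      count_range = c(1, 2), flux = 1e6, insert_radius = 22,
      n_pretrain = 2, n_finetune = 2, n_validation = 1,
      net = mdunet_config(n_scales = 2, base_channels = 4),
      train = train_config_desk(pretrain_epochs = 1, finetune_epochs = 2),
      loss = loss_config(),
      gap = gap_config(),
      tv_beta = 1e-4, tv_iters = 30,
      kvp = 140, hvl = 5.0),
    full = list(
      n_pixels = 256, n_views = 1440, detector_bins = 3840,
      base_radius = 100, fov = 250, size_range = c(8, 18),
      count_range = c(2, 6), flux = 1e6, insert_radius = 15,
      n_pretrain = 87, n_finetune = 16, n_validation = 4,
      net = mdunet_config(),
      train = train_config(),
      loss = loss_config(),
      gap = gap_config(),
      tv_beta = 1e-4, tv_iters = 200,
      kvp = 140, hvl = 5.0))
  cfg$preset <- preset
  cfg$seed <- seed
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg$train$seed <- seed
  structure(cfg, class = "experiment_config")
}

# derived sub-seed streams (kept below 2^31)
.subseed <- function(seed, stage, i = 0) (seed * 10007L + stage * 101L + i) %% 2000000000L

# a water-region background ROI that avoids every insert
.find_water_roi <- function(spec, radius = 8) {
  for (frac in c(0, 0.3, 0.5, 0.7)) for (th in seq(0, 2 * pi, length.out = 13)) {
    ctr <- spec$base_radius * frac * c(cos(th), sin(th))
    if (sqrt(sum(ctr^2)) + radius >= spec$base_radius) next
    ok <- TRUE
    for (ins in spec$inserts)
      if (sqrt(sum((ins$center - ctr)^2)) <= ins$radius + radius + 2) {
        ok <- FALSE; break
      }
    if (ok) return(roi(ctr, radius, label = 1L))
  }
  stop("no insert-free water region found for the background ROI")
}

# simulate one sampled phantom into a training sample
.make_sample <- function(seed, cfg, spectrum, geometry, emulate = FALSE,
                         fits = NULL) {
  spec <- sample_phantom(seed, size_range = cfg$size_range,
                         count_range = cfg$count_range,
                         base_radius = cfg$base_radius,
                         n_pixels = cfg$n_pixels, fov = cfg$fov)
  sc <- simulate_scan(spec, spectrum, geometry = geometry, flux = cfg$flux,
                      rng_seed = seed + 1L)
  img <- sc$image
  if (emulate) img <- emulate_real_domain(img, cfg$gap, rng_seed = seed + 2L)
  else if (!is.null(fits)) img <- apply_calibration(img, fits)
  list(image = img, labels = sc$labels, spec = spec)
}

#' Run the end-to-end material decomposition experiment
#'
#' Executes the six pipeline stages in order and evaluates MD-LS, MD-TV, a
#' plain Unet (no weighted skips, cross-entropy-only loss, no transfer) and
#' MD-Unet on held-out real-emulated phantoms. Every stage draws from
#' seeds derived from `config$seed`, so identical configurations reproduce
#' identical reports.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, intermediates (calibration
#'   fits, label maps, images, histories, report, provenance) are persisted.
#' @return list with `report` ([evaluate_methods()] result), `fits`,
#'   `histories`, `networks`, `validation` (the held-out samples).
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  cfg <- config
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  # 1: physics + calibration pair ------------------------------------------
  spectrum <- stage("simulate", build_spectrum(cfg$kvp, cfg$hvl))
  geometry <- ct_geometry("parallel", fov = cfg$fov, n_views = cfg$n_views,
                          detector_bins = cfg$detector_bins)
  basis <- basis_matrix(spectrum)
  gammex <- calibration_phantom(base_radius = cfg$base_radius,
                                n_pixels = cfg$n_pixels, fov = cfg$fov,
                                insert_radius = cfg$insert_radius)
  scan_gammex <- function(s) {
    sc <- simulate_scan(gammex, spectrum, geometry = geometry,
                        flux = cfg$flux, rng_seed = s)
    list(image = emulate_real_domain(sc$image, cfg$gap, rng_seed = s + 1L),
         labels = sc$labels, spec = gammex)
  }
  cal_sim <- stage("simulate",
                   simulate_scan(gammex, spectrum, geometry = geometry,
                                 flux = cfg$flux,
                                 rng_seed = .subseed(cfg$seed, 1)))
  cal_real <- emulate_real_domain(cal_sim$image, cfg$gap,
                                  rng_seed = .subseed(cfg$seed, 2))
  # 2: calibrate ------------------------------------------------------------
  pairs <- stage("calibrate", extract_pairs(cal_sim$image, cal_real, gammex))
  fits <- stage("calibrate", fit_lac_curves_by_bin(pairs))
  # 3/4: datasets + two-phase training --------------------------------------
  # pre-training: diverse simulated phantoms mapped onto the real LAC scale;
  # fine-tuning/validation: repeated real-emulated scans of the fixed
  # multi-energy phantom, mirroring the scanner protocol
  pre <- lapply(seq_len(cfg$n_pretrain), function(i)
    .make_sample(.subseed(cfg$seed, 3, i), cfg, spectrum, geometry,
                 fits = fits))
  fin <- lapply(seq_len(cfg$n_finetune), function(i)
    scan_gammex(.subseed(cfg$seed, 4, i)))
  val <- lapply(seq_len(cfg$n_validation), function(i)
    scan_gammex(.subseed(cfg$seed, 5, i)))
  man_pre <- dataset_manifest(pre, "pretrain")
  man_fin <- dataset_manifest(fin, "finetune")
  net <- build_network(cfg$net, rng_seed = .subseed(cfg$seed, 6))
  pt <- stage("pretrain", pretrain(net, man_pre, cfg$train, cfg$loss))
  ft <- stage("finetune", finetune(pt$network, man_fin, cfg$train, cfg$loss))
  # plain Unet: no weighted skips, cross-entropy loss, no transfer
  unet_cfg <- cfg$net
  unet_cfg$weighted_skip_scales <- integer(0)
  ce_loss <- loss_config(gamma = 0, w_b = 1, lambda = 0)
  unet0 <- build_network(unet_cfg, rng_seed = .subseed(cfg$seed, 7))
  scratch_cfg <- cfg$train
  scratch_cfg$freeze_scales_finetune <- integer(0)
  scratch_cfg$finetune_epochs <- cfg$train$pretrain_epochs +
    cfg$train$finetune_epochs
  un <- stage("finetune", finetune(unet0, man_fin, scratch_cfg, ce_loss))
  # 5/6: decompose + evaluate ----------------------------------------------
  v <- val[[1]]
  cnr_src <- function(cm) {
    d <- dim(cm$maps[[1]])
    array(c(matrix(0, d[1], d[2]), cm$maps$water, cm$maps$calcium,
            cm$maps$iodine), c(d, 4))
  }
  preds <- stage("decompose", list(
    md_ls = {
      cm <- md_ls(v$image, basis)
      list(labels = to_categorical(cm), maps = cm, cnr_source = cnr_src(cm))
    },
    md_tv = {
      cm <- md_tv(v$image, basis, beta = cfg$tv_beta, iters = cfg$tv_iters)
      list(labels = to_categorical(cm), maps = cm, cnr_source = cnr_src(cm))
    },
    unet = predict(un$network, v$image),
    md_unet = predict(ft$network, v$image)))
  roi_set <- list(background = .find_water_roi(v$spec),
                  rois = lapply(v$spec$inserts, function(ins)
                    roi(ins$center, 0.6 * ins$radius,
                        label = c(calcium = 2L, iodine = 3L)[[ins$material]])))
  fingerprint <- list(seed = cfg$seed, preset = cfg$preset,
                      n_pixels = cfg$n_pixels, n_views = cfg$n_views,
                      net = unclass(cfg$net), train = unclass(cfg$train),
                      loss = unclass(cfg$loss)[c("gamma", "w_b", "lambda")],
                      gap = unclass(cfg$gap),
                      package_version = as.character(utils::packageVersion("pcdmd")))
  report <- stage("evaluate",
                  evaluate_methods(preds, v$labels, roi_set,
                                   pitch = v$image$pitch,
                                   fingerprint = fingerprint))
  if (!is.null(out_dir)) {
    write_calibration_json(fits, file.path(out_dir, "calibration.json"))
    utils::write.csv(pairs, file.path(out_dir, "calibration_pairs.csv"),
                     row.names = FALSE)
    write_multibin(v$image, file.path(out_dir, "validation1"))
    write_labels(v$labels, file.path(out_dir, "validation1_labels.csv"))
    utils::write.csv(rbind(pt$history, ft$history),
                     file.path(out_dir, "training_history.csv"),
                     row.names = FALSE)
    write_report_json(report, file.path(out_dir, "report.json"))
    jsonlite::write_json(fingerprint, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, fits = fits, basis = basis,
       histories = list(pretrain = pt$history, finetune = ft$history,
                        unet = un$history),
       networks = list(md_unet = ft$network, unet = un$network),
       validation = val, predictions = preds)
}

#' Seeded transfer-learning benchmark at desk scale
#'
#' Runs the reduced end-to-end benchmark for one seed: pre-train on
#' `n_pretrain` calibrated simulated phantoms, fine-tune (encoder scale 1
#' frozen) on `n_finetune` real-emulated scans of the fixed multi-energy
#' phantom, and score the held-out scan. Optionally adds a from-scratch arm
#' (same fine-tuning without pre-training) and the MD-LS baseline for
#' comparison.
#'
#' @param seed benchmark seed (controls data, initialization and training).
#' @param config an [experiment_config()]; the `desk` preset is the CI
#'   benchmark scale.
#' @param include_scratch also train the no-pretraining arm (doubles the
#'   fine-tuning cost; off by default).
#' @return one-row data.frame with `seed`, `miou_transfer`, `miou_scratch`
#'   (NA when skipped), `miou_ls`, and a `frozen_identical` flag verifying
#'   that encoder scale 1 was bit-identical across fine-tuning.
#' @export
transfer_benchmark <- function(seed = 1, config = experiment_config(seed = seed),
                               include_scratch = FALSE) {
  cfg <- config
  cfg$seed <- seed
  cfg$train$seed <- seed
  spectrum <- build_spectrum(cfg$kvp, cfg$hvl)
  geometry <- ct_geometry("parallel", fov = cfg$fov, n_views = cfg$n_views,
                          detector_bins = cfg$detector_bins)
  basis <- basis_matrix(spectrum)
  gammex <- calibration_phantom(base_radius = cfg$base_radius,
                                n_pixels = cfg$n_pixels, fov = cfg$fov,
                                insert_radius = cfg$insert_radius)
  scan_gammex <- function(s) {
    sc <- simulate_scan(gammex, spectrum, geometry = geometry,
                        flux = cfg$flux, rng_seed = s)
    list(image = emulate_real_domain(sc$image, cfg$gap, rng_seed = s + 1L),
         labels = sc$labels, spec = gammex)
  }
  cal_sim <- simulate_scan(gammex, spectrum, geometry = geometry,
                           flux = cfg$flux, rng_seed = .subseed(seed, 1))
  cal_real <- emulate_real_domain(cal_sim$image, cfg$gap,
                                  rng_seed = .subseed(seed, 2))
  fits <- fit_lac_curves_by_bin(extract_pairs(cal_sim$image, cal_real, gammex))
  pre <- lapply(seq_len(cfg$n_pretrain), function(i)
    .make_sample(.subseed(seed, 3, i), cfg, spectrum, geometry, fits = fits))
  fin <- lapply(seq_len(cfg$n_finetune), function(i)
    scan_gammex(.subseed(seed, 4, i)))
  vals <- lapply(seq_len(max(1, cfg$n_validation)), function(i)
    scan_gammex(.subseed(seed, 5, i)))
  man_pre <- dataset_manifest(pre, "pretrain")
  man_fin <- dataset_manifest(fin, "finetune")
  net <- build_network(cfg$net, rng_seed = .subseed(seed, 6))
  pt <- pretrain(net, man_pre, cfg$train, cfg$loss)
  ft <- finetune(pt$network, man_fin, cfg$train, cfg$loss)
  frozen <- .frozen_param_names(pt$network, cfg$train$freeze_scales_finetune)
  frozen_identical <- all(vapply(frozen, function(nm)
    identical(pt$network$params[[nm]], ft$network$params[[nm]]), logical(1)))
  score <- function(network) mean(vapply(vals, function(v)
    miou(predict(network, v$image)$labels, v$labels), numeric(1)))
  miou_transfer <- score(ft$network)
  miou_scratch <- NA_real_
  if (include_scratch) {
    scratch_cfg <- cfg$train
    scratch_cfg$freeze_scales_finetune <- integer(0)
    sc0 <- build_network(cfg$net, rng_seed = .subseed(seed, 6))
    sct <- finetune(sc0, man_fin, scratch_cfg, cfg$loss)
    miou_scratch <- score(sct$network)
  }
  miou_ls <- mean(vapply(vals, function(v)
    miou(to_categorical(md_ls(v$image, basis)), v$labels), numeric(1)))
  data.frame(seed = seed, miou_transfer = miou_transfer,
             miou_scratch = miou_scratch, miou_ls = miou_ls,
             frozen_identical = frozen_identical)
}

#' Generate the small fixture dataset used by the test-suite
#'
#' One phantom per insert-material combination (water-only, calcium-only,
#' iodine-only, calcium+iodine) scanned at 64 pixels / 60 views; regenerating
#' with the same seed is bit-identical.
#'
#' @param seed RNG seed.
#' @param dir optional output directory for persisted copies.
#' @return list of samples (`image`, `labels`, `spec`) plus the spectrum.
#' @export
make_fixtures <- function(seed = 1, dir = NULL) {
  spectrum <- build_spectrum(140, 5)
  geometry <- ct_geometry("parallel", n_views = 60, detector_bins = 64)
  specs <- list(
    water = phantom_spec(100, list(), n_pixels = 64),
    calcium = phantom_spec(100, list(
      insert_spec("calcium", 300, c(-35, 0), 18),
      insert_spec("calcium", 100, c(35, 0), 18)), n_pixels = 64),
    iodine = phantom_spec(100, list(
      insert_spec("iodine", 15, c(0, -35), 18),
      insert_spec("iodine", 5, c(0, 35), 18)), n_pixels = 64),
    mixed = phantom_spec(100, list(
      insert_spec("calcium", 300, c(-40, 0), 16),
      insert_spec("iodine", 10, c(40, 0), 16)), n_pixels = 64))
  out <- lapply(seq_along(specs), function(i) {
    sc <- simulate_scan(specs[[i]], spectrum, geometry = geometry,
                        flux = 2e5, rng_seed = seed + i)
    list(image = sc$image, labels = sc$labels, spec = specs[[i]])
  })
  names(out) <- names(specs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      write_multibin(out[[nm]]$image, file.path(dir, nm))
      write_labels(out[[nm]]$labels, file.path(dir, paste0(nm, "_labels.csv")))
    }
  }
  c(out, list(spectrum = spectrum, geometry = geometry))
}
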