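# Evaluation suite: contrast-to-noise ratio on circular ROIs, mean
# intersection-over-union and mean Dice over material classes, and the
# pooled R^2 score on per-class maps.

#' Circular region of interest
#' @param center `c(x, y)` mm from isocenter.
#' @param radius mm.
#' @param label optional name.
#' @export
roi <- function(center, radius, label = NULL) {
  structure(list(center = as.numeric(center), radius = radius, label = label),
            class = "roi")
}

# logical pixel mask of a circular ROI on an n x n grid with given pitch
.roi_mask <- function(r, n, pitch) {
  ax <- (seq_len(n) - (n + 1) / 2) * pitch
  X <- matrix(ax, n, n, byrow = TRUE); Y <- matrix(ax, n, n, byrow = FALSE)
  (X - r$center[1])^2 + (Y - r$center[2])^2 <= r$radius^2
}

#' Contrast-to-noise ratio
#'
#' `|mean(ROI) - mean(background)| / sd(background)` with the population
#' (denominator n) standard deviation. Scale-invariant.
#'
#' @param image matrix, or [multibin_image()] with `bin` selecting a slice.
#' @param roi,background_roi [roi()] objects, or logical masks.
#' @param pitch pixel pitch in mm (taken from the image when available).
#' @param bin bin index for multi-bin input.
#' @return scalar CNR.
#' @export
cnr <- function(image, roi, background_roi, pitch = NULL, bin = 1) {
  if (inherits(image, "multibin_image")) {
    pitch <- image$pitch
    image <- image$data[, , bin]
  }
  n <- nrow(image)
  m_roi <- if (is.logical(roi)) roi else .roi_mask(roi, n, pitch %||% 1)
  m_bg <- if (is.logical(background_roi)) background_roi else
    .roi_mask(background_roi, n, pitch %||% 1)
  bg <- image[m_bg]
  sd_bg <- sqrt(mean((bg - mean(bg))^2))
  if (sd_bg == 0) stop("undefined CNR: background standard deviation is zero")
  abs(mean(image[m_roi]) - mean(bg)) / sd_bg
}

# per-class intersection/union/sizes; empty-set convention handled by caller
.class_counts <- function(pred, gt, cls) {
  p <- pred == cls; g <- gt == cls
  c(inter = sum(p & g), union = sum(p | g), np = sum(p), ng = sum(g))
}

#' Mean intersection-over-union across classes
#'
#' Mean over the configured classes of `|pred_i & gt_i| / |pred_i | gt_i|`.
#' A class absent from both maps contributes 1 (empty-set convention, so a
#' water-only phantom is not penalized for having no iodine to find).
#'
#' @param pred,gt integer label matrices on the same grid.
#' @param classes class codes to average over (default 0:3, i.e. background
#'   plus the three materials).
#' @return scalar in \[0, 1\].
#' @export
miou <- function(pred, gt, classes = 0:3) {
  if (!all(dim(pred) == dim(gt))) stop("label maps must share the grid")
  ious <- vapply(classes, function(k) {
    ct <- .class_counts(pred, gt, k)
    if (ct["union"] == 0) 1 else ct[["inter"]] / ct[["union"]]
  }, numeric(1))
  mean(ious)
}

#' Mean Dice similarity coefficient across classes
#'
#' Mean of `2 |pred_i & gt_i| / (|pred_i| + |gt_i|)`; same empty-set
#' convention as [miou()]. Per class, `DSC = 2 IoU / (1 + IoU)`.
#'
#' @inheritParams miou
#' @export
mdsc <- function(pred, gt, classes = 0:3) {
  if (!all(dim(pred) == dim(gt))) stop("label maps must share the grid")
  ds <- vapply(classes, function(k) {
    ct <- .class_counts(pred, gt, k)
    if (ct["np"] + ct["ng"] == 0) 1 else 2 * ct[["inter"]] / (ct[["np"]] + ct[["ng"]])
  }, numeric(1))
  mean(ds)
}

#' Pooled R-squared score over material channels
#'
#' `1 - sum((gt - pred)^2) / sum((gt - mean(gt))^2)`, with the sums pooled
#' over all material channels and pixels. When only categorical maps are
#' available both are one-hot encoded first.
#'
#' @param pred_maps,gt_maps arrays `H x W x K`, or integer label matrices
#'   (one-hot encoded with `n_classes`).
#' @param n_classes classes used when encoding label matrices.
#' @return scalar (at most 1).
#' @export
r2_score <- function(pred_maps, gt_maps, n_classes = 4) {
  if (is.matrix(pred_maps)) pred_maps <- one_hot(pred_maps, n_classes)
  if (is.matrix(gt_maps)) gt_maps <- one_hot(gt_maps, n_classes)
  if (!all(dim(pred_maps) == dim(gt_maps))) stop("shape mismatch")
  ss_tot <- sum((gt_maps - mean(gt_maps))^2)
  if (ss_tot == 0) stop("undefined R^2: ground truth is constant")
  1 - sum((gt_maps - pred_maps)^2) / ss_tot
}

#' Assemble a metrics report over decomposition methods
#'
#' Computes CNR (per ROI, on the indicated material's predicted map), mIoU,
#' mDSC and the R^2 score for each method against the ground truth, with a
#' configuration fingerprint for provenance.
#'
#' @param predictions named list; each element a list with `labels` (integer
#'   matrix) and optionally `prob` (`H x W x K` array used for CNR/R^2;
#'   falls back to one-hot labels) and `cnr_source` (`H x W x K` continuous
#'   maps used for CNR only; an undefined CNR — zero background spread, as
#'   happens on exact one-hot maps — is reported as NA).
#' @param gt_labels ground-truth integer label matrix.
#' @param roi_set optional list of [roi()]s with a `background` roi and
#'   insert rois labelled by class index; CNR skipped when `NULL`.
#' @param pitch pixel pitch in mm (for ROI masks).
#' @param classes class codes for the categorical metrics.
#' @param fingerprint list recorded verbatim (seeds, configs, versions).
#' @return object of class `metrics_report`: data.frame `table` plus
#'   `cnr` (per method x ROI), `fingerprint`, `empty_class_convention`.
#' @export
evaluate_methods <- function(predictions, gt_labels, roi_set = NULL,
                             pitch = 1, classes = 0:3, fingerprint = list()) {
  rows <- list()
  cnr_tab <- list()
  for (nm in names(predictions)) {
    pr <- predictions[[nm]]
    pm <- if (!is.null(pr$prob)) pr$prob else one_hot(pr$labels, length(classes))
    rows[[nm]] <- data.frame(method = nm,
                             miou = miou(pr$labels, gt_labels, classes),
                             mdsc = mdsc(pr$labels, gt_labels, classes),
                             r2 = r2_score(pm, one_hot(gt_labels, length(classes))))
    if (!is.null(roi_set)) {
      bg <- roi_set$background
      cm_src <- if (!is.null(pr$cnr_source)) pr$cnr_source else pm
      vals <- vapply(roi_set$rois, function(rr) {
        ch <- rr$label %||% 2L   # channel = class index + 1
        tryCatch(cnr(cm_src[, , ch + 1L], rr, bg, pitch = pitch),
                 error = function(e) NA_real_)
      }, numeric(1))
      cnr_tab[[nm]] <- vals
    }
  }
  structure(list(table = do.call(rbind, rows),
                 cnr = cnr_tab,
                 fingerprint = fingerprint,
                 empty_class_convention = "absent-from-both scores 1"),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Material decomposition metrics\n")
  print(x$table, row.names = FALSE)
  if (length(x$cnr)) {
    cat("CNR per ROI:\n")
    print(do.call(rbind, x$cnr))
  }
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param report a `metrics_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  obj <- list(table = report$table, cnr = report$cnr,
              fingerprint = report$fingerprint,
              empty_class_convention = report$empty_class_convention)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read back a JSON metrics report
#' @param path path written by [write_report_json()].
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(table = obj$table, cnr = obj$cnr,
                 fingerprint = obj$fingerprint,
                 empty_class_convention = obj$empty_class_convention),
            class = "metrics_report")
}
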