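# Plain-text persistence: multi-bin volumes and label maps as one CSV per
# slice with a JSON metadata sidecar (no binary imaging format is assumed to
# be available). Paths are used as prefixes: <prefix>.json, <prefix>_bin1.csv
# (or <prefix>_labels.csv).

#' Write a multi-bin image to CSV slices + JSON metadata
#' @param image a [multibin_image()].
#' @param prefix output path prefix.
#' @export
write_multibin <- function(image, prefix) {
  nb <- dim(image$data)[3]
  meta <- list(format = "pcdmd-multibin-v1", n_pixels = dim(image$data)[1],
               n_bins = nb, pitch_mm = image$pitch, fov_mm = image$fov,
               domain = image$domain, units = "1/cm")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  for (b in seq_len(nb))
    data.table::fwrite(data.table::as.data.table(image$data[, , b]),
                       paste0(prefix, "_bin", b, ".csv"), col.names = FALSE)
  invisible(prefix)
}

#' Read a multi-bin image written by [write_multibin()]
#' @param prefix path prefix.
#' @export
read_multibin <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dat <- array(0, c(meta$n_pixels, meta$n_pixels, meta$n_bins))
  for (b in seq_len(meta$n_bins))
    dat[, , b] <- as.matrix(data.table::fread(
      paste0(prefix, "_bin", b, ".csv"), header = FALSE))
  multibin_image(dat, pitch = meta$pitch_mm, fov = meta$fov_mm,
                 domain = meta$domain)
}

#' Write a label map to CSV
#' @param labels integer matrix.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(data.table::as.data.table(labels), path,
                     col.names = FALSE)
  invisible(path)
}

#' Read a label map written by [write_labels()]
#' @param path CSV path.
#' @export
read_labels <- function(path) {
  m <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}
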