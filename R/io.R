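# TIFF / CSV / JSON input-output. TIFF pages are channel-major (all frames of
# channel 1, then channel 2, ...); calibration and intensity scaling travel in
# a JSON sidecar next to the TIFF.

#' Write a FollicleStack as a multi-page TIFF with JSON sidecar
#'
#' @param stack a [FollicleStack-class].
#' @param path output TIFF path; the sidecar is \code{<path>.json}.
#' @param spec optional generation spec echoed into the sidecar.
#' @return \code{path}, invisibly.
#' @export
writeImageStack <- function(stack, path, spec = NULL) {
  d <- dim(stack@pixels)
  scale <- max(stack@pixels, 1e-12)
  pages <- list()
  for (ch in seq_len(d[3])) for (t in seq_len(d[4]))
    pages[[length(pages) + 1L]] <- t(stack@pixels[, , ch, t]) / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(channel_names = channelNames(stack),
               n_frames = d[4], pixel_size_um = pixelSize(stack),
               frame_interval_s = frameInterval(stack),
               intensity_scale = scale, page_order = "channel-major")
  if (!is.null(spec)) meta$spec <- unclass(spec)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a FollicleStack written by [writeImageStack()]
#'
#' @param path TIFF path with a \code{<path>.json} sidecar.
#' @return a [FollicleStack-class].
#' @export
readImageStack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- length(meta$channel_names)
  nf <- meta$n_frames
  d <- dim(pages[[1]])
  pix <- array(0, dim = c(d[2], d[1], nch, nf))
  k <- 1L
  for (ch in seq_len(nch)) for (t in seq_len(nf)) {
    pix[, , ch, t] <- t(pages[[k]]) * meta$intensity_scale
    k <- k + 1L
  }
  FollicleStack(pix, pixelSize = meta$pixel_size_um,
                frameInterval = meta$frame_interval_s,
                channelNames = meta$channel_names)
}

#' Write a label stack as a 16-bit multi-page TIFF
#'
#' @param labels integer \code{[x, y, frame]} array (values < 65536).
#' @param path output path.
#' @export
writeLabelStack <- function(labels, path) {
  if (max(labels) > 65535L) stopf("labels exceed 16-bit range")
  pages <- lapply(seq_len(dim(labels)[3]),
                  function(t) t(labels[, , t]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label stack written by [writeLabelStack()]
#' @param path TIFF path.
#' @return integer \code{[x, y, frame]} array.
#' @export
readLabelStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- as.integer(round(t(pages[[t]]) * 65535))
  arr
}

#' Write a data.frame as CSV with a provenance comment header
#'
#' Header lines start with \code{#} and carry column units, the configuration
#' hash and the package version, so every numeric output documents its
#' provenance; [readMetricsCsv()] skips them.
#'
#' @param df data.frame.
#' @param path output path.
#' @param units optional named character vector (column -> unit).
#' @param provenance optional named list echoed as \code{# key: value} lines.
#' @export
writeMetricsCsv <- function(df, path, units = NULL, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# follipulse %s",
                     as.character(utils::packageVersion("follipulse"))), con)
  if (!is.null(units))
    writeLines(sprintf("# units: %s",
                       paste(names(units), units, sep = "=", collapse = "; ")),
               con)
  for (k in names(provenance))
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [writeMetricsCsv()]
#' @param path CSV path.
#' @return data.frame (comment header skipped).
#' @export
readMetricsCsv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write ground truth as CSV + JSON sidecar
#'
#' @param truth a [GroundTruth-class].
#' @param dir output directory (created if needed).
#' @param spec optional spec echoed into the JSON.
#' @return the directory, invisibly.
#' @export
writeGroundTruth <- function(truth, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeMetricsCsv(perCellTruth(truth), file.path(dir, "truth_per_cell.csv"),
                  units = c(dist_um = "um", mean_area_um2 = "um^2"))
  writeLabelStack(labelStack(truth), file.path(dir, "truth_labels.tif"))
  g <- truthGlobal(truth)
  if (!is.null(spec)) g$spec <- unclass(spec)
  jsonlite::write_json(g, file.path(dir, "truth_global.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
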