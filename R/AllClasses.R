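#' Multi-channel calibrated time-lapse image stack
#'
#' Container for the raw observation of a pulsing follicular epithelium: one
#' 2D image per channel per frame (maximum projections), with spatial and
#' temporal calibration. Images are stored as a 4D numeric array indexed
#' \code{[x, y, channel, frame]}; the image x axis is the anterior-posterior
#' (AP) axis by convention and pixel coordinates are 0-based pixel centres.
#'
#' @slot pixels numeric 4D array \code{[x, y, channel, frame]}, intensities >= 0.
#' @slot pixelSize numeric, micrometres per pixel (> 0).
#' @slot frameInterval numeric, seconds between frames (> 0).
#' @slot channelNames character, one name per channel (e.g. "membrane",
#'   "myosin").
#'
#' @seealso [genPulsingTissue()], [readImageStack()], [maxProject()]
#' @export
setClass("FollicleStack",
  representation(pixels = "array", pixelSize = "numeric",
                 frameInterval = "numeric", channelNames = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@pixels)
    if (length(d) != 4L)
      msg <- c(msg, "pixels must be a 4D [x, y, channel, frame] array")
    else if (length(object@channelNames) != d[3L])
      msg <- c(msg, "channelNames length must equal the number of channels")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number")
    if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
      msg <- c(msg, "frameInterval must be a single positive number")
    if (anyNA(object@pixels) || min(object@pixels) < 0)
      msg <- c(msg, "intensities must be finite and >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a FollicleStack
#'
#' @param pixels 4D numeric array \code{[x, y, channel, frame]}.
#' @param pixelSize micrometres per pixel.
#' @param frameInterval seconds per frame.
#' @param channelNames character vector naming the channels.
#' @return A [FollicleStack-class] object.
#' @export
FollicleStack <- function(pixels, pixelSize, frameInterval, channelNames) {
  methods::new("FollicleStack", pixels = pixels, pixelSize = pixelSize,
               frameInterval = frameInterval, channelNames = channelNames)
}

#' Ground truth for a synthetic pulsing tissue
#'
#' Truth tables produced alongside a synthetic movie: the per-frame true label
#' masks, the per-cell table (seed position, distance to the pole, imposed
#' fractional pulse amplitudes, rendered mean area) and the global generator
#' parameters every downstream estimator is validated against.
#'
#' @slot labelStack integer 3D array \code{[x, y, frame]} of true cell labels
#'   (every pixel assigned; no background).
#' @slot perCell data.frame with columns \code{cell_id, x_px, y_px, dist_um,
#'   amplitude, amplitude_ap, amplitude_ml, mean_area_um2}.
#' @slot series list of cells-by-frames matrices: \code{area_px} (rendered
#'   areas), \code{drive} (contraction drive in [0,1]) and \code{myosin_drive}
#'   (drive advanced by the myosin lag).
#' @slot global list: \code{myosin_lag_frames}, \code{decay_length},
#'   \code{anisotropy_ratio}, \code{bond_enrichment}, \code{enrichment_band},
#'   \code{pole_um}.
#'
#' @export
setClass("GroundTruth",
  representation(labelStack = "array", perCell = "data.frame",
                 series = "list", global = "list"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labelStack)) != 3L)
      msg <- c(msg, "labelStack must be a 3D [x, y, frame] array")
    need <- c("cell_id", "dist_um", "amplitude", "mean_area_um2")
    if (!all(need %in% names(object@perCell)))
      msg <- c(msg, paste("perCell must contain columns:",
                          paste(need, collapse = ", ")))
    else {
      if (any(object@perCell$amplitude < 0))
        msg <- c(msg, "amplitudes must be >= 0")
      ids <- sort(object@perCell$cell_id)
      for (t in seq_len(dim(object@labelStack)[3L])) {
        if (!all(ids %in% object@labelStack[, , t])) {
          msg <- c(msg, "every cell_id must appear in every frame's label mask")
          break
        }
      }
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname GroundTruth-class
#' @param labelStack,perCell,series,global see slots.
#' @export
GroundTruth <- function(labelStack, perCell, series = list(), global = list()) {
  methods::new("GroundTruth", labelStack = labelStack, perCell = perCell,
               series = series, global = global)
}
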