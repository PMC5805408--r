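# Accessor generics and methods for the core containers.

#' @rdname FollicleStack-class
#' @param object a \code{FollicleStack} or \code{GroundTruth}.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname FollicleStack-class
#' @export
setMethod("pixelSize", "FollicleStack", function(object) object@pixelSize)

#' @rdname FollicleStack-class
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname FollicleStack-class
#' @export
setMethod("frameInterval", "FollicleStack", function(object) object@frameInterval)

#' @rdname FollicleStack-class
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname FollicleStack-class
#' @export
setMethod("channelNames", "FollicleStack", function(object) object@channelNames)

#' @rdname FollicleStack-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname FollicleStack-class
#' @export
setMethod("nFrames", "FollicleStack", function(object) dim(object@pixels)[4L])
#' @rdname GroundTruth-class
#' @export
setMethod("nFrames", "GroundTruth", function(object) dim(object@labelStack)[3L])

#' Extract one channel image
#'
#' @param object a \code{FollicleStack}.
#' @param channel channel name or index.
#' @param frame frame index (1-based); \code{NULL} returns the
#'   \code{[x, y, frame]} array for the channel.
#' @return a 2D matrix (one frame) or 3D array (all frames), indexed
#'   \code{[x, y]} with AP along x.
#' @export
setGeneric("getChannel", function(object, channel, frame = NULL)
  standardGeneric("getChannel"))
#' @rdname getChannel
#' @export
setMethod("getChannel", "FollicleStack", function(object, channel, frame = NULL) {
  if (is.character(channel)) {
    channel <- match(channel, object@channelNames)
    if (is.na(channel)) stopf("unknown channel; available: %s",
                              paste(object@channelNames, collapse = ", "))
  }
  if (is.null(frame)) object@pixels[, , channel, , drop = FALSE][, , 1L, ]
  else object@pixels[, , channel, frame]
})

#' @rdname GroundTruth-class
#' @export
setGeneric("labelStack", function(object) standardGeneric("labelStack"))
#' @rdname GroundTruth-class
#' @export
setMethod("labelStack", "GroundTruth", function(object) object@labelStack)

#' @rdname GroundTruth-class
#' @export
setGeneric("perCellTruth", function(object) standardGeneric("perCellTruth"))
#' @rdname GroundTruth-class
#' @export
setMethod("perCellTruth", "GroundTruth", function(object) object@perCell)

#' @rdname GroundTruth-class
#' @export
setGeneric("truthGlobal", function(object) standardGeneric("truthGlobal"))
#' @rdname GroundTruth-class
#' @export
setMethod("truthGlobal", "GroundTruth", function(object) object@global)

#' @rdname GroundTruth-class
#' @export
setGeneric("truthSeries", function(object) standardGeneric("truthSeries"))
#' @rdname GroundTruth-class
#' @export
setMethod("truthSeries", "GroundTruth", function(object) object@series)

setMethod("show", "FollicleStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "FollicleStack: %d x %d px, %d channel(s) [%s], %d frame(s)\n",
    d[1L], d[2L], d[3L], paste(object@channelNames, collapse = ", "), d[4L]))
  cat(sprintf("  calibration: %.4g um/px, %.4g s/frame\n",
              object@pixelSize, object@frameInterval))
})

setMethod("show", "GroundTruth", function(object) {
  d <- dim(object@labelStack)
  cat(sprintf("GroundTruth: %d cells over %d frame(s) (%d x %d px)\n",
              nrow(object@perCell), d[3L], d[1L], d[2L]))
  g <- object@global
  if (length(g))
    cat(sprintf("  lag %s frames, decay %s um, anisotropy %s, bond enrichment %s\n",
                g$myosin_lag_frames, g$decay_length, g$anisotropy_ratio,
                g$bond_enrichment))
})
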