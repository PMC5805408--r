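# Segmentation of membrane-channel projections, overlap tracking, per-cell
# measurement and bond extraction.

#' Maximum-intensity projection of a z-stack
#'
#' @param zstack 3D numeric array \code{[x, y, z]} (or a 2D matrix, returned
#'   unchanged).
#' @return 2D matrix of per-pixel maxima across z.
#' @export
maxProject <- function(zstack) {
  if (is.matrix(zstack)) return(zstack)
  d <- dim(zstack)
  if (is.null(d) || length(d) != 3L || d[3L] < 1L)
    stopf("maxProject expects a [x, y, z] array with >= 1 plane")
  Reduce(pmax, lapply(seq_len(d[3L]), function(k) zstack[, , k]))
}

#' Segment one membrane-channel frame by marker-controlled watershed
#'
#' Standard junctional-marker segmentation: Gaussian blur, inversion (cells
#' become bright basins of the membrane ridge landscape), then a watershed in
#' which minima shallower than \code{h_minima_depth} are suppressed — the
#' marker-controlled watershed with h-minima markers. Regions outside
#' \code{[min_area, max_area]} (um^2) are removed, and border-touching cells
#' optionally cleared.
#'
#' @param image 2D matrix \code{[x, y]}, membrane channel.
#' @param pixel_size um per pixel.
#' @param blur_sigma Gaussian blur sigma in px.
#' @param h_minima_depth watershed tolerance: minima shallower than this
#'   (intensity units) do not seed a cell.
#' @param min_area,max_area area gates in um^2.
#' @param clear_border drop cells touching the image border.
#' @return integer label matrix (0 = removed/background); labels are
#'   sequential from 1.
#' @export
segmentFrame <- function(image, pixel_size = 1, blur_sigma = 1.5,
                         h_minima_depth = 0.08, min_area = 5,
                         max_area = 2000, clear_border = TRUE) {
  if (!is.matrix(image)) stopf("segmentFrame expects a 2D matrix")
  sm <- EBImage::gblur(image, sigma = blur_sigma)
  inv <- max(sm) - sm
  lab <- EBImage::imageData(EBImage::watershed(inv, tolerance = h_minima_depth,
                                               ext = 1))
  storage.mode(lab) <- "integer"
  if (max(lab) == 0L)
    stopf("segmentation found no seeds (h_minima_depth %.3g too high?)", h_minima_depth)
  areas <- tabulate(lab, nbins = max(lab)) * pixel_size^2
  drop <- which(areas < min_area | areas > max_area)
  if (clear_border) {
    nx <- nrow(lab); ny <- ncol(lab)
    border <- unique(c(lab[1, ], lab[nx, ], lab[, 1], lab[, ny]))
    drop <- union(drop, border[border > 0])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  # relabel sequentially
  keep <- sort(unique(as.vector(lab)))
  keep <- keep[keep > 0]
  remap <- integer(max(lab) + 1L)
  remap[keep + 1L] <- seq_along(keep)
  matrix(remap[lab + 1L], nrow(lab), ncol(lab))
}

#' Segment every frame of a stack
#'
#' @param stack a [FollicleStack-class].
#' @param channel membrane channel name or index.
#' @param ... passed to [segmentFrame()] (pixel_size is taken from the stack).
#' @return integer 3D array \code{[x, y, frame]} of per-frame labels (labels
#'   are not consistent across frames; see [trackCells()]).
#' @export
segmentStack <- function(stack, channel = "membrane", ...) {
  nf <- nFrames(stack)
  out <- NULL
  for (t in seq_len(nf)) {
    lab <- segmentFrame(getChannel(stack, channel, t),
                        pixel_size = pixelSize(stack), ...)
    if (is.null(out)) out <- array(0L, dim = c(dim(lab), nf))
    out[, , t] <- lab
  }
  out
}

# Overlap table between two label images: data.frame(a, b, inter, iou).
#' @noRd
.overlapTable <- function(labA, labB) {
  sel <- labA > 0L & labB > 0L
  if (!any(sel)) return(data.frame(a = integer(), b = integer(),
                                   inter = integer(), iou = numeric()))
  a <- labA[sel]; b <- labB[sel]
  ka <- max(a)
  key <- (b - 1) * ka + a
  cnt <- tabulate(key)
  nz <- which(cnt > 0)
  ai <- ((nz - 1) %% ka) + 1L
  bi <- ((nz - 1) %/% ka) + 1L
  areaA <- tabulate(labA[labA > 0L], nbins = max(labA))
  areaB <- tabulate(labB[labB > 0L], nbins = max(labB))
  inter <- cnt[nz]
  data.frame(a = ai, b = bi, inter = inter,
             iou = inter / (areaA[ai] + areaB[bi] - inter))
}

#' Track cells across frames by greedy maximal overlap
#'
#' Frame-to-frame greedy assignment on intersection-over-union (IoU): label
#' pairs are matched in decreasing IoU order; a track ends when its best IoU
#' falls below \code{min_iou}. Adequate when displacement per frame is much
#' smaller than a cell diameter, as at 15 s sampling.
#'
#' @param labels integer 3D array \code{[x, y, frame]} of per-frame labels.
#' @param min_iou minimum IoU to continue a track.
#' @return integer 3D array of the same shape with stable cell ids.
#' @export
trackCells <- function(labels, min_iou = 0.3) {
  d <- dim(labels)
  if (length(d) != 3L || d[3L] < 2L)
    stopf("trackCells expects a [x, y, frame] array with >= 2 frames")
  out <- array(0L, dim = d)
  # frame 1: stable ids = sequential relabel
  first <- labels[, , 1L]
  ids <- sort(unique(as.vector(first))); ids <- ids[ids > 0]
  remap <- integer(max(first, 1L) + 1L)
  remap[ids + 1L] <- seq_along(ids)
  out[, , 1L] <- remap[first + 1L]
  nextId <- length(ids)
  for (t in 2:d[3L]) {
    prev <- out[, , t - 1L]
    cur <- labels[, , t]
    ov <- .overlapTable(prev, cur)
    ov <- ov[order(-ov$iou), , drop = FALSE]
    assignTo <- integer(max(cur, 1L))
    usedPrev <- logical(max(prev, 1L))
    for (k in seq_len(nrow(ov))) {
      if (ov$iou[k] < min_iou) break
      a <- ov$a[k]; b <- ov$b[k]
      if (!usedPrev[a] && assignTo[b] == 0L) {
        assignTo[b] <- a
        usedPrev[a] <- TRUE
      }
    }
    newb <- which(assignTo == 0L)
    newb <- newb[newb %in% cur]
    if (length(newb)) {
      assignTo[newb] <- nextId + seq_along(newb)
      nextId <- nextId + length(newb)
    }
    out[, , t] <- matrix(c(0L, assignTo)[cur + 1L], d[1L], d[2L])
  }
  out
}

# Per-frame measurements for every label in a 2D mask.
#' @noRd
.measureFrame <- function(lab, channels, pixel_size) {
  sel <- lab > 0L
  if (!any(sel)) return(NULL)
  nx <- nrow(lab)
  px <- which(sel)
  l <- lab[px]
  xs <- (px - 1L) %% nx
  ys <- (px - 1L) %/% nx
  ids <- sort(unique(l))
  cnt <- tabulate(l, nbins = max(l))[ids]
  sx <- rowsum(xs, l)[, 1]
  sy <- rowsum(ys, l)[, 1]
  minx <- tapply(xs, l, min); maxx <- tapply(xs, l, max)
  miny <- tapply(ys, l, min); maxy <- tapply(ys, l, max)
  # moment-based extents (4 sd): sub-pixel measures of the axis lengths
  vx <- rowsum(xs^2, l)[, 1] / cnt - (sx / cnt)^2 + 1 / 12
  vy <- rowsum(ys^2, l)[, 1] / cnt - (sy / cnt)^2 + 1 / 12
  out <- data.frame(cell_id = ids,
                    area_um2 = cnt * pixel_size^2,
                    cx_um = (sx / cnt) * pixel_size,
                    cy_um = (sy / cnt) * pixel_size,
                    bbox_ap_um = (maxx - minx + 1) * pixel_size,
                    bbox_ml_um = (maxy - miny + 1) * pixel_size,
                    ext_ap_um = 4 * sqrt(vx) * pixel_size,
                    ext_ml_um = 4 * sqrt(vy) * pixel_size)
  for (ch in names(channels)) {
    v <- channels[[ch]][px]
    out[[paste0("mean_", ch)]] <- rowsum(v, l)[, 1] / cnt
  }
  rownames(out) <- NULL
  out
}

#' Per-frame measurements of one cell
#'
#' Area (pixel count times the squared calibration), centroid, AP/ML
#' bounding-box extents (AP = image x) and mean intensity per channel.
#'
#' @param lab integer label matrix.
#' @param channels named list of intensity matrices (may be empty).
#' @param cell_id label to measure.
#' @param pixel_size um per pixel.
#' @return one-row data.frame.
#' @export
measureCell <- function(lab, channels = list(), cell_id, pixel_size = 1) {
  if (!any(lab == cell_id))
    stopf("cell_id %s not present in the label mask", cell_id)
  m <- .measureFrame(lab, channels, pixel_size)
  m[m$cell_id == cell_id, , drop = FALSE]
}

#' Build per-cell tracks from a stable-id label stack
#'
#' @param stableLabels integer \code{[x, y, frame]} array of stable ids (from
#'   [trackCells()] or a ground-truth label stack).
#' @param stack optional [FollicleStack-class] supplying intensity channels.
#' @param pixel_size,frame_interval calibration; taken from \code{stack} when
#'   given.
#' @return data.frame with one row per (cell, frame): \code{cell_id, frame,
#'   area_um2, cx_um, cy_um, bbox_ap_um, bbox_ml_um} plus one
#'   \code{mean_<channel>} column per channel.
#' @export
cellTracks <- function(stableLabels, stack = NULL, pixel_size = 1,
                       frame_interval = 1) {
  d <- dim(stableLabels)
  if (!is.null(stack)) {
    stopifnot(all(d[1:2] == dim(stack@pixels)[1:2]), d[3] == nFrames(stack))
    pixel_size <- pixelSize(stack)
  }
  rows <- vector("list", d[3L])
  for (t in seq_len(d[3L])) {
    channels <- list()
    if (!is.null(stack))
      channels <- stats::setNames(
        lapply(channelNames(stack), function(ch) getChannel(stack, ch, t)),
        channelNames(stack))
    m <- .measureFrame(stableLabels[, , t], channels, pixel_size)
    if (!is.null(m)) m$frame <- t
    rows[[t]] <- m
  }
  out <- do.call(rbind, rows)
  out[order(out$cell_id, out$frame), , drop = FALSE]
}

#' Tracks spanning every frame
#'
#' Only cells observed in every frame enter pulse statistics (the analysis
#' window is fixed); this filters a track table down to those.
#'
#' @param tracks a track data.frame from [cellTracks()].
#' @param n_frames total number of frames in the movie.
#' @return the filtered track data.frame.
#' @export
fullLengthTracks <- function(tracks, n_frames) {
  cnt <- table(tracks$cell_id)
  keep <- as.integer(names(cnt)[cnt == n_frames])
  tracks[tracks$cell_id %in% keep, , drop = FALSE]
}

# Bond pixel table for a tiled label mask: for every adjacent label pair, the
# boundary pixels on both sides of the interface, its axial angle to the AP
# (x) axis and its length in interface steps.
#' @noRd
.bondPixelTable <- function(lab) {
  nx <- nrow(lab); ny <- ncol(lab)
  # horizontal neighbours (along x)
  ih <- which(lab[-nx, ] != lab[-1, ])
  i1 <- ((ih - 1L) %% (nx - 1L)) + 1L
  j1 <- ((ih - 1L) %/% (nx - 1L)) + 1L
  ph1 <- i1 + (j1 - 1L) * nx
  ph2 <- ph1 + 1L
  # vertical neighbours (along y)
  iv <- which(lab[, -ny] != lab[, -1])
  i2 <- ((iv - 1L) %% nx) + 1L
  j2 <- ((iv - 1L) %/% nx) + 1L
  pv1 <- i2 + (j2 - 1L) * nx
  pv2 <- pv1 + nx
  p1 <- c(ph1, pv1); p2 <- c(ph2, pv2)
  la <- lab[p1]; lb <- lab[p2]
  ok <- la > 0L & lb > 0L
  p1 <- p1[ok]; p2 <- p2[ok]; la <- la[ok]; lb <- lb[ok]
  if (!length(p1))
    return(list(pairs = data.frame(a = integer(), b = integer(),
                                   angle = numeric(), n_steps = integer()),
                pixels = list()))
  lo <- pmin(la, lb); hi <- pmax(la, lb)
  key <- paste(lo, hi)
  ord <- order(key)
  grp <- split(seq_along(key)[ord], key[ord])
  pairs <- data.frame(a = integer(length(grp)), b = integer(length(grp)),
                      angle = numeric(length(grp)),
                      n_steps = integer(length(grp)))
  pixels <- vector("list", length(grp))
  for (g in seq_along(grp)) {
    idx <- grp[[g]]
    px <- unique(c(p1[idx], p2[idx]))
    # angle from interface-step midpoints: using the full two-pixel band
    # would contaminate the principal direction with the band thickness
    xm <- ((p1[idx] - 1L) %% nx + (p2[idx] - 1L) %% nx) / 2
    ym <- ((p1[idx] - 1L) %/% nx + (p2[idx] - 1L) %/% nx) / 2
    ang <- if (length(idx) >= 2) {
      ax <- momentAxes(pixelMoments(xm, ym))$orientation
      axialAngle90(ax)
    } else {
      # single step: the interface normal is the pixel-pair direction
      if (abs(p2[idx[1]] - p1[idx[1]]) == 1L) 90 else 0
    }
    pairs$a[g] <- lo[idx[1]]; pairs$b[g] <- hi[idx[1]]
    pairs$angle[g] <- ang
    pairs$n_steps[g] <- length(idx)
    pixels[[g]] <- px
  }
  list(pairs = pairs, pixels = pixels)
}

#' Extract cell-cell bonds from a label mask
#'
#' For each pair of adjacent labels, the bond is the set of boundary pixels on
#' both sides of their interface. The bond angle is the axial orientation of
#' the principal direction of those pixels relative to the AP (x) axis, in
#' [0, 90] degrees; intensity is the mean of each channel over the bond
#' pixels dilated by one pixel.
#'
#' @param lab integer label matrix (cells tile the mask; 0 = background).
#' @param channels named list of intensity matrices.
#' @param pixel_size um per pixel.
#' @param min_bond_px minimum number of interface steps for a bond to be kept.
#' @param dilate_px dilation radius (px) of the bond pixel set for intensity
#'   sampling; 0 samples the two-pixel interface band only.
#' @param trim_vertices exclude bond pixels adjacent to a third cell from
#'   intensity sampling (vertex regions mix signal from other bonds).
#' @return data.frame \code{cell_a, cell_b, angle_deg, length_um} plus one
#'   \code{mean_<channel>} column per channel; zero rows when the mask has
#'   fewer than two cells.
#' @export
extractBonds <- function(lab, channels = list(), pixel_size = 1,
                         min_bond_px = 3, dilate_px = 0, trim_vertices = TRUE) {
  if (length(unique(lab[lab > 0])) < 2)
    return(data.frame(cell_a = integer(), cell_b = integer(),
                      angle_deg = numeric(), length_um = numeric()))
  bt <- .bondPixelTable(lab)
  keep <- which(bt$pairs$n_steps >= min_bond_px)
  out <- data.frame(cell_a = bt$pairs$a[keep], cell_b = bt$pairs$b[keep],
                    angle_deg = bt$pairs$angle[keep],
                    length_um = bt$pairs$n_steps[keep] * pixel_size)
  nx <- nrow(lab); npx <- length(lab)
  sample_px <- lapply(keep, function(k) {
    px <- bt$pixels[[k]]
    if (trim_vertices && length(px) > 3) {
      a <- bt$pairs$a[k]; b <- bt$pairs$b[k]
      okp <- rep(TRUE, length(px))
      for (off in c(-1L, 1L, -nx, nx)) {
        nb <- px + off
        inb <- nb >= 1L & nb <= npx
        third <- inb
        third[inb] <- !(lab[nb[inb]] %in% c(a, b, 0L))
        okp <- okp & !third
      }
      if (sum(okp) >= 2) px <- px[okp]
    }
    if (dilate_px > 0) for (r in seq_len(dilate_px)) {
      px <- unique(c(px, px - 1L, px + 1L, px - nx, px + nx))
      px <- px[px >= 1L & px <= npx]
    }
    px
  })
  for (ch in names(channels)) {
    out[[paste0("mean_", ch)]] <-
      vapply(sample_px, function(px) mean(channels[[ch]][px]), numeric(1))
  }
  out
}
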