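# Spatial mapping of per-cell metrics against the distance from a pole
# landmark; line profiles; AP-line cell counting; volumes; heatmap export.

#' Bin a per-cell metric by distance from the pole
#'
#' Euclidean distance (in the projection plane) from each cell centroid to
#' the pole landmark, fixed-width bins from 0 (the last partial bin is kept
#' when it holds >= 3 cells), and an optional least-squares exponential fit
#' \code{metric(d) = baseline + A exp(-d / lambda)} on the bin means.
#'
#' @param metric numeric per-cell metric.
#' @param centroids n x 2 matrix of cell centroids (um).
#' @param pole length-2 pole position (um).
#' @param bin_width_um bin width (um).
#' @param fit attempt the exponential fit.
#' @param weighted weight the fit by the number of cells per bin (default:
#'   bin means with more cells constrain the fit more).
#' @return list of class \code{"GradientProfile"}: \code{profile} (data.frame
#'   \code{bin_center, metric_mean, metric_sd, n_cells}), \code{fit} (list
#'   \code{amplitude_at_pole, baseline, decay_length} or NULL), \code{dist}
#'   (per-cell distances).
#' @export
metricVsDistance <- function(metric, centroids, pole, bin_width_um = 5,
                             fit = TRUE, weighted = TRUE) {
  centroids <- as.matrix(centroids)
  if (length(metric) < 1 || nrow(centroids) != length(metric))
    stopf("metric and centroids must have one entry per cell")
  d <- sqrt((centroids[, 1] - pole[1])^2 + (centroids[, 2] - pole[2])^2)
  bin <- floor(d / bin_width_um)
  full_max <- max(bin)
  tab <- tapply(metric, bin, length)
  keep <- as.integer(names(tab))[tab >= 3 | as.integer(names(tab)) < full_max]
  sel <- bin %in% keep
  bm <- tapply(metric[sel], bin[sel], mean)
  bs <- tapply(metric[sel], bin[sel], stats::sd)
  bn <- tapply(metric[sel], bin[sel], length)
  bd <- tapply(d[sel], bin[sel], mean)
  prof <- data.frame(bin_center = (as.integer(names(bm)) + 0.5) * bin_width_um,
                     mean_dist = as.numeric(bd),
                     metric_mean = as.numeric(bm),
                     metric_sd = as.numeric(bs),
                     n_cells = as.integer(bn))
  prof <- prof[order(prof$bin_center), , drop = FALSE]
  fitres <- NULL
  if (fit) {
    if (nrow(prof) < 3) {
      warnf("fewer than 3 occupied bins: exponential fit skipped")
    } else if (diff(range(prof$metric_mean)) < 1e-12) {
      # flat profile: no gradient to fit
      fitres <- list(amplitude_at_pole = prof$metric_mean[1],
                     baseline = prof$metric_mean[1], amplitude = 0,
                     decay_length = NA_real_)
    } else {
      a0 <- max(prof$metric_mean) - min(prof$metric_mean)
      fitres <- tryCatch({
        # abscissa: mean cell distance per bin (the geometric bin centre
        # misplaces sparse near-pole bins and biases the decay length)
        nl <- minpack.lm::nlsLM(
          metric_mean ~ b + A * exp(-mean_dist / l), data = prof,
          weights = if (weighted) prof$n_cells else rep(1, nrow(prof)),
          start = list(b = min(prof$metric_mean), A = max(a0, 1e-6),
                       l = max(prof$mean_dist) / 3),
          lower = c(-abs(min(prof$metric_mean)) - 1e-6, 0, 1e-3),
          upper = c(Inf, Inf, 10 * max(prof$mean_dist)),
          control = minpack.lm::nls.lm.control(maxiter = 200))
        co <- stats::coef(nl)
        list(amplitude_at_pole = unname(co["b"] + co["A"]),
             baseline = unname(co["b"]), amplitude = unname(co["A"]),
             decay_length = unname(co["l"]))
      }, error = function(e) {
        warnf("exponential fit failed: %s", conditionMessage(e))
        NULL
      })
    }
  }
  structure(list(profile = prof, fit = fitres, dist = d),
            class = "GradientProfile")
}

#' @export
print.GradientProfile <- function(x, ...) {
  cat(sprintf("Gradient profile: %d bins, %d cells\n", nrow(x$profile),
              sum(x$profile$n_cells)))
  if (!is.null(x$fit))
    cat(sprintf("  fit: baseline %.3g + %.3g exp(-d/%.3g um)\n",
                x$fit$baseline, x$fit$amplitude, x$fit$decay_length))
  invisible(x)
}

#' Relative apical surface profile (smallest cell = 1)
#'
#' Areas are normalized to the smallest cell before distance binning, so the
#' profile reads as fold-change of apical surface over the most constricted
#' cell.
#'
#' @param areas per-cell apical areas (um^2), all > 0.
#' @inheritParams metricVsDistance
#' @param ... passed to [metricVsDistance()].
#' @return a \code{"GradientProfile"} (of relative areas).
#' @export
relativeApicalSurface <- function(areas, centroids, pole, ...) {
  if (length(areas) < 1) stopf("empty input")
  if (any(areas <= 0)) stopf("areas must be > 0")
  metricVsDistance(areas / min(areas), centroids, pole, ...)
}

#' Relative intensity profile along a wide line
#'
#' Emulates a wide freehand line: the path is resampled to unit pixel
#' spacing, and at each position the intensity is averaged across a
#' perpendicular band of \code{width_px} nearest pixels. The profile is
#' divided by its own mean (relative intensity = intensity at a position /
#' mean intensity of the measured signal).
#'
#' @param image 2D matrix \code{[x, y]}.
#' @param path k x 2 matrix of waypoints (0-based px coordinates).
#' @param width_px band width in pixels (odd values centre the band).
#' @return data.frame \code{position_px, relative_intensity} (mean = 1).
#' @export
lineProfile <- function(image, path, width_px = 15) {
  path <- as.matrix(path)
  if (nrow(path) < 2) stopf("path needs >= 2 points")
  if (width_px < 1) stopf("width_px must be >= 1")
  # resample to ~unit spacing
  seglen <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(seglen))
  n <- max(2L, ceiling(cum[length(cum)]) + 1L)
  s <- seq(0, cum[length(cum)], length.out = n)
  xi <- stats::approx(cum, path[, 1], xout = s)$y
  yi <- stats::approx(cum, path[, 2], xout = s)$y
  # tangents by central differences -> unit normals
  tx <- numeric(n); ty <- numeric(n)
  tx[2:(n - 1)] <- xi[3:n] - xi[1:(n - 2)]
  ty[2:(n - 1)] <- yi[3:n] - yi[1:(n - 2)]
  tx[1] <- xi[2] - xi[1]; ty[1] <- yi[2] - yi[1]
  tx[n] <- xi[n] - xi[n - 1]; ty[n] <- yi[n] - yi[n - 1]
  tl <- sqrt(tx^2 + ty^2)
  nxv <- -ty / tl; nyv <- tx / tl
  offs <- seq_len(width_px) - (width_px + 1) / 2
  nx <- nrow(image); ny <- ncol(image)
  vals <- matrix(NA_real_, n, width_px)
  clipped <- FALSE
  for (k in seq_along(offs)) {
    px <- round(xi + offs[k] * nxv)
    py <- round(yi + offs[k] * nyv)
    ok <- px >= 0 & px < nx & py >= 0 & py < ny
    if (!all(ok)) clipped <- TRUE
    vals[ok, k] <- image[cbind(px[ok] + 1L, py[ok] + 1L)]
  }
  if (clipped) warnf("line band exits the image: outside samples clipped")
  prof <- rowMeans(vals, na.rm = TRUE)
  data.frame(position_px = s, relative_intensity = prof / mean(prof))
}

#' Count cells intersected by the AP pole-to-pole line
#'
#' Rasterizes the segment between the two pole landmarks and counts the
#' distinct non-background labels under it, minus any excluded labels (e.g.
#' the polar cells themselves).
#'
#' @param lab integer label matrix.
#' @param pole_a,pole_b length-2 pole positions (0-based px).
#' @param exclude_labels labels to exclude from the count.
#' @return integer cell count (0 with a warning when the segment only crosses
#'   background).
#' @export
countCellsOnApLine <- function(lab, pole_a, pole_b, exclude_labels = integer()) {
  nx <- nrow(lab); ny <- ncol(lab)
  for (p in list(pole_a, pole_b))
    if (p[1] < 0 || p[1] >= nx || p[2] < 0 || p[2] >= ny)
      stopf("pole (%g, %g) outside mask bounds", p[1], p[2])
  n <- max(abs(pole_b[1] - pole_a[1]), abs(pole_b[2] - pole_a[2])) + 1
  xs <- round(seq(pole_a[1], pole_b[1], length.out = n))
  ys <- round(seq(pole_a[2], pole_b[2], length.out = n))
  hit <- unique(lab[cbind(xs + 1L, ys + 1L)])
  hit <- setdiff(hit[hit > 0], exclude_labels)
  if (!length(hit)) warnf("AP segment crosses only background")
  length(hit)
}

#' Cell volume from mean apical surface and mean height
#'
#' @param mean_apical_surface um^2 (> 0); vectorized.
#' @param mean_height um (> 0); vectorized.
#' @return volume(s) in um^3.
#' @export
cellVolume <- function(mean_apical_surface, mean_height) {
  if (any(mean_apical_surface <= 0) || any(mean_height <= 0))
    stopf("surface and height must be > 0")
  mean_apical_surface * mean_height
}

#' Color-code a per-cell metric onto the label mask
#'
#' Paints each cell's pixels with a colour mapped from its metric; background
#' is black and labels without a metric are grey. Optionally writes an RGB
#' TIFF.
#'
#' @param lab integer label matrix.
#' @param metric named numeric vector (names = labels) or plain vector
#'   indexed by label.
#' @param palette a palette name for [grDevices::hcl.colors()].
#' @param file optional output TIFF path.
#' @return invisibly, a list with \code{rgb} (\code{[x, y, 3]} array in
#'   [0, 1]) and \code{range} (metric range of the colour scale).
#' @export
heatmapExport <- function(lab, metric, palette = "viridis", file = NULL) {
  ids <- sort(unique(lab[lab > 0]))
  vals <- if (!is.null(names(metric))) metric[as.character(ids)]
          else metric[ids]
  missing <- !is.finite(vals)
  if (any(missing)) warnf("%d label(s) have no metric: painted grey",
                          sum(missing))
  rng <- range(vals[!missing])
  cols <- grDevices::hcl.colors(256, palette)
  idx <- pmin(256L, pmax(1L, 1L + floor(255 *
    (vals - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps))))
  cellcol <- grDevices::col2rgb(cols[idx]) / 255
  cellcol[, missing] <- 0.5
  out <- array(0, dim = c(nrow(lab), ncol(lab), 3L))
  map <- matrix(0, max(ids), 3)
  map[ids, ] <- t(cellcol)
  sel <- lab > 0
  for (k in 1:3) {
    plane <- matrix(0, nrow(lab), ncol(lab))
    plane[sel] <- map[lab[sel], k]
    out[, , k] <- plane
  }
  if (!is.null(file))
    tiff::writeTIFF(aperm(out, c(2, 1, 3)), file)
  invisible(list(rgb = out, range = rng))
}
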