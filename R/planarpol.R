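# Planar-polarity quantification: bond intensity vs angle, rose-diagram
# binning, division-orientation statistics, and the cell elongation tensor.

#' Relative bond intensity by angle
#'
#' Bonds are binned by their axial angle to the AP axis (0 deg = AP-parallel)
#' and each bin's mean intensity is divided by the global mean bond intensity,
#' so an unpolarized tissue gives a flat profile at 1.
#'
#' @param bonds bond data.frame from [extractBonds()].
#' @param channel channel name (expects column \code{mean_<channel>}).
#' @param bin_width_deg bin width in degrees (bins partition [0, 90]).
#' @return data.frame \code{bin_lo, bin_hi, bin_mid, relative_intensity,
#'   n_bonds}; empty bins carry NA intensity.
#' @export
bondAngleProfile <- function(bonds, channel, bin_width_deg = 10) {
  col <- paste0("mean_", channel)
  if (!col %in% names(bonds) || nrow(bonds) < 1)
    stopf("no bond intensities for channel '%s'", channel)
  v <- bonds[[col]]
  gmean <- mean(v)
  edges <- seq(0, 90, by = bin_width_deg)
  if (edges[length(edges)] < 90) edges <- c(edges, 90)
  bin <- findInterval(bonds$angle_deg, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  bm <- tapply(v, factor(bin, levels = seq_len(nb)), mean)
  bn <- tabulate(bin, nbins = nb)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
             relative_intensity = as.numeric(bm) / gmean,
             n_bonds = bn)
}

#' Rose-diagram binning of angles
#'
#' Axial angles are folded to [0, 180) and counted in fixed-width bins
#' (default 10 deg); in a rose plot the bin size is proportional to the
#' number of data points in it.
#'
#' @param angles_deg numeric angles in degrees.
#' @param bin_width_deg bin width.
#' @param axial fold angles to the undirected [0, 180) range (default);
#'   \code{FALSE} uses the full circle.
#' @return data.frame of class \code{"RoseHistogram"}: \code{bin_lo, bin_hi,
#'   bin_mid, count}.
#' @export
roseHistogram <- function(angles_deg, bin_width_deg = 10, axial = TRUE) {
  if (any(!is.finite(angles_deg))) stopf("angles must be finite")
  top <- if (axial) 180 else 360
  a <- angles_deg %% top
  edges <- seq(0, top, by = bin_width_deg)
  bin <- findInterval(a, edges, rightmost.closed = FALSE)
  nb <- length(edges) - 1L
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
                    count = tabulate(bin, nbins = nb))
  class(out) <- c("RoseHistogram", "data.frame")
  out
}

#' Test division (or any axial) orientations for a directional bias
#'
#' Rayleigh test of circular uniformity applied to the doubled angles (the
#' standard treatment of undirected axes): p > alpha means no detectable
#' orientation bias, e.g. of cytokinesis figures towards the AP axis.
#'
#' @param angles_deg axial angles in degrees (n >= 5).
#' @param axial double the angles before testing (default, for undirected
#'   axes).
#' @return list with \code{p_value}, \code{statistic} (Rayleigh Z),
#'   \code{r_bar} (mean resultant length), \code{mean_axis_deg},
#'   \code{rose} (a [roseHistogram()]), \code{n}.
#' @export
divisionOrientationTest <- function(angles_deg, axial = TRUE) {
  n <- length(angles_deg)
  if (n < 5) stopf("insufficient data: need >= 5 angles (got %d)", n)
  th <- angles_deg * pi / 180 * (if (axial) 2 else 1)
  C <- mean(cos(th)); S <- mean(sin(th))
  rbar <- sqrt(C^2 + S^2)
  Z <- n * rbar^2
  # Rayleigh p with the standard finite-n correction
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  mu <- atan2(S, C) * 180 / pi / (if (axial) 2 else 1)
  list(p_value = p, statistic = Z, r_bar = rbar,
       mean_axis_deg = axialAngle180(mu),
       rose = roseHistogram(angles_deg, axial = axial), n = n)
}

#' Cell elongation tensor of a segmented tissue
#'
#' Per cell, the principal axes of the pixel second moments give an axis
#' ratio r and an axial orientation theta; the elongation magnitude is the
#' log-nematic norm \code{0.5 log(r)} (alternative \code{(r-1)/(r+1)} via
#' \code{convention}). The tissue tensor averages the nematic components
#' \code{(m cos 2 theta, m sin 2 theta)} over cells, so opposite orientations
#' cancel, and is reported as a mean magnitude and mean orientation.
#'
#' @param lab integer label matrix.
#' @param convention \code{"log"} (default) or \code{"ratio"}.
#' @return list of class \code{"ElongationTensor"}: \code{per_cell}
#'   (data.frame \code{cell_id, magnitude, orientation_deg}), \code{tissue}
#'   (list \code{mean_magnitude, mean_orientation_deg, n_cells}).
#' @export
cellElongationTensor <- function(lab, convention = c("log", "ratio")) {
  convention <- match.arg(convention)
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) stopf("no cells in the label mask")
  nx <- nrow(lab)
  px <- which(lab > 0)
  l <- lab[px]
  xs <- (px - 1L) %% nx
  ys <- (px - 1L) %/% nx
  rows <- lapply(ids, function(id) {
    sel <- l == id
    if (sum(sel) < 2) return(NULL)  # single-pixel cells skipped
    ax <- momentAxes(pixelMoments(xs[sel], ys[sel]))
    r <- ax$major / ax$minor
    m <- if (convention == "log") 0.5 * log(r) else (r - 1) / (r + 1)
    data.frame(cell_id = id, magnitude = m, orientation_deg = ax$orientation)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) warnf("%d single-pixel cell(s) skipped", skipped)
  per <- do.call(rbind, rows)
  if (is.null(per)) stopf("no measurable cells (all single-pixel)")
  th2 <- per$orientation_deg * pi / 90  # 2 theta in radians
  qx <- mean(per$magnitude * cos(th2))
  qy <- mean(per$magnitude * sin(th2))
  structure(list(per_cell = per,
                 tissue = list(mean_magnitude = sqrt(qx^2 + qy^2),
                               mean_orientation_deg =
                                 axialAngle180(atan2(qy, qx) * 90 / pi),
                               n_cells = nrow(per))),
            class = "ElongationTensor")
}

#' @export
print.ElongationTensor <- function(x, ...) {
  cat(sprintf(
    "Cell elongation tensor (%d cells): mean magnitude %.3f, mean orientation %.1f deg\n",
    x$tissue$n_cells, x$tissue$mean_magnitude, x$tissue$mean_orientation_deg))
  invisible(x)
}
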