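# Per-cell pulse statistics, myosin-area cross-correlation and group
# comparison with normality-gated test routing.

#' Pulse intensity of an apical-area time series
#'
#' The intensity of one cell's pulsation: (maximum surface - minimum surface)
#' / mean surface, a dimensionless fractional amplitude.
#'
#' @param area_series numeric vector of per-frame apical areas (um^2), all > 0.
#' @return dimensionless pulse intensity >= 0.
#' @examples
#' pulseIntensity(c(4, 5, 6))  # 0.4
#' @export
pulseIntensity <- function(area_series) {
  if (length(area_series) < 2) stopf("pulse intensity needs >= 2 frames")
  if (any(!is.finite(area_series)) || any(area_series <= 0))
    stopf("areas must be finite and > 0")
  (max(area_series) - min(area_series)) / mean(area_series)
}

#' Pulse isotropy of one tracked cell
#'
#' Ratio of the AP (and ML) bounding-box extent at the frame of maximal area
#' to the extent at the frame of minimal area. An isotropy index
#' (ML ratio / AP ratio) of 1 means the pulse contracts both axes equally.
#'
#' @param track data.frame for one cell with columns \code{area_um2,
#'   bbox_ap_um, bbox_ml_um} (one row per frame).
#' @return list with \code{isotropy_ap}, \code{isotropy_ml},
#'   \code{isotropy_index}.
#' @export
pulseIsotropy <- function(track) {
  if (nrow(track) < 2) stopf("pulse isotropy needs >= 2 frames")
  imax <- which.max(track$area_um2)
  imin <- which.min(track$area_um2)
  if (imax == imin) stopf("max-area and min-area frames must be distinct")
  if (track$bbox_ap_um[imin] <= 0 || track$bbox_ml_um[imin] <= 0)
    stopf("degenerate bounding box (zero extent)")
  ap <- track$bbox_ap_um[imax] / track$bbox_ap_um[imin]
  ml <- track$bbox_ml_um[imax] / track$bbox_ml_um[imin]
  list(isotropy_ap = ap, isotropy_ml = ml, isotropy_index = ml / ap)
}

#' Per-cell pulse metrics for a track table
#'
#' @param tracks track data.frame ([cellTracks()]).
#' @return data.frame with one row per cell: \code{cell_id, n_frames,
#'   pulse_intensity, isotropy_ap, isotropy_ml, isotropy_index}.
#' @export
pulseMetrics <- function(tracks) {
  ids <- sort(unique(tracks$cell_id))
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$cell_id == id, , drop = FALSE]
    iso <- tryCatch(pulseIsotropy(tr), error = function(e)
      list(isotropy_ap = NA_real_, isotropy_ml = NA_real_,
           isotropy_index = NA_real_))
    data.frame(cell_id = id, n_frames = nrow(tr),
               pulse_intensity = pulseIntensity(tr$area_um2),
               isotropy_ap = iso$isotropy_ap, isotropy_ml = iso$isotropy_ml,
               isotropy_index = iso$isotropy_index)
  })
  do.call(rbind, rows)
}

#' Mean percentage of apical surface variation for one follicle
#'
#' Mean over cells of 100 x pulse intensity. A follicle enters the statistic
#' only when at least \code{min_cells} full-length tracks are available;
#' otherwise an insufficient-cells error is raised so the follicle can be
#' excluded and logged.
#'
#' @param tracks track data.frame; only cells present in every frame count.
#' @param min_cells minimum number of analyzable cells (default 10).
#' @param n_frames total frames; default the maximum frame index present.
#' @return mean percent surface variation (a single number).
#' @export
folliclePulseAmplitude <- function(tracks, min_cells = 10,
                                   n_frames = max(tracks$frame)) {
  full <- fullLengthTracks(tracks, n_frames)
  ids <- unique(full$cell_id)
  if (length(ids) < min_cells)
    stopf("insufficient cells: %d full-length tracks < min_cells = %d",
          length(ids), min_cells)
  pm <- pulseMetrics(full)
  mean(100 * pm$pulse_intensity)
}

#' Cross-correlation of myosin intensity and apical area
#'
#' Per cell, the area and myosin series are linearly detrended and z-scored,
#' then correlated at integer lags: the value at lag tau pairs myosin(t) with
#' area(t + tau), each lag normalized by its (T - |tau|) overlapping samples.
#' The population curve is the mean over cells; the lead-lag is the lag of
#' the most negative correlation. A positive lead-lag means myosin
#' accumulation precedes the reduction of the apical surface.
#'
#' @param tracks track data.frame with an intensity column for \code{channel}.
#' @param channel channel name (expects column \code{mean_<channel>}).
#' @param max_lag_frames maximum |lag| in frames.
#' @param detrend linearly detrend + z-score (default); \code{FALSE} only
#'   centres and scales.
#' @param frame_interval seconds per frame, for the lag axis in seconds.
#' @return list of class \code{"XCorrResult"}: \code{lags_frames, lags_s,
#'   correlation, lead_lag_frames, lead_lag_s, n_cells, per_cell}.
#' @export
crossCorrelate <- function(tracks, channel = "myosin", max_lag_frames = 8,
                           detrend = TRUE, frame_interval = 1) {
  col <- paste0("mean_", channel)
  if (!col %in% names(tracks)) stopf("tracks lack an intensity column '%s'", col)
  nf <- max(tracks$frame)
  full <- fullLengthTracks(tracks, nf)
  ids <- unique(full$cell_id)
  if (nf <= 2 * max_lag_frames)
    stopf("series length %d must exceed 2 x max_lag_frames", nf)
  lags <- -max_lag_frames:max_lag_frames
  prep <- function(v) {
    s0 <- stats::sd(v)
    if (s0 < 1e-10 * max(1, abs(mean(v)))) return(NULL)
    if (detrend) v <- stats::residuals(stats::lm(v ~ seq_along(v)))
    s <- stats::sd(v)
    if (s < 1e-8 * s0) return(NULL)
    (v - mean(v)) / s
  }
  percell <- matrix(NA_real_, length(ids), length(lags),
                    dimnames = list(ids, lags))
  nskip <- 0L
  for (k in seq_along(ids)) {
    tr <- full[full$cell_id == ids[k], ]
    tr <- tr[order(tr$frame), ]
    a <- prep(tr$area_um2)
    m <- prep(tr[[col]])
    if (is.null(a) || is.null(m)) {
      nskip <- nskip + 1L
      next
    }
    for (j in seq_along(lags)) {
      tau <- lags[j]
      t1 <- max(1, 1 - tau):min(nf, nf - tau)  # myosin indices
      percell[k, j] <- sum(m[t1] * a[t1 + tau]) / length(t1)
    }
  }
  if (nskip > 0) warnf("%d zero-variance cell(s) skipped", nskip)
  ok <- rowSums(is.na(percell)) == 0
  if (!any(ok)) stopf("all cells had zero-variance series")
  curve <- colMeans(percell[ok, , drop = FALSE])
  curve <- pmin(pmax(curve, -1), 1)
  ll <- lags[which.min(curve)]
  structure(list(lags_frames = lags, lags_s = lags * frame_interval,
                 correlation = unname(curve), lead_lag_frames = ll,
                 lead_lag_s = ll * frame_interval, n_cells = sum(ok),
                 per_cell = percell[ok, , drop = FALSE]),
            class = "XCorrResult")
}

#' @export
print.XCorrResult <- function(x, ...) {
  cat(sprintf(
    "Myosin-area cross-correlation (%d cells): lead-lag %+d frame(s) (%+.0f s), min r = %.3f\n",
    x$n_cells, x$lead_lag_frames, x$lead_lag_s, min(x$correlation)))
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness and kurtosis z-statistics (D'Agostino 1970;
#' Anscombe & Glynn 1983) into K^2 = Z_skew^2 + Z_kurt^2, referred to a
#' chi-squared distribution with 2 degrees of freedom. Requires n >= 8.
#'
#' @param x numeric sample.
#' @return list with \code{statistic} (K^2), \code{p_value}, \code{z_skew},
#'   \code{z_kurt}, \code{n}.
#' @export
dagostinoPearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stopf("D'Agostino-Pearson test requires n >= 8 (got %d)", n)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  # skewness transform (D'Agostino)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zs <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis transform (Anscombe-Glynn)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Zs^2 + Zk^2
  list(statistic = K2, p_value = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       z_skew = Zs, z_kurt = Zk, n = n)
}

#' Compare two samples with normality-gated test routing
#'
#' Routing follows standard practice for these data: normality of each group
#' is assessed with the D'Agostino-Pearson omnibus test; when both groups
#' pass at \code{alpha_normality}, an unpaired t-test is used, otherwise an
#' unpaired Mann-Whitney (Wilcoxon rank-sum) test. Groups smaller than 8
#' (the test's minimum) fall back to the rank test.
#'
#' @param a,b numeric samples (each n >= 3).
#' @param alpha_normality significance level of the normality gate.
#' @param var_equal use the Student (equal-variance) t-test (default);
#'   \code{FALSE} gives Welch.
#' @return list with \code{test_used} ("t-test" or "mann-whitney"),
#'   \code{statistic}, \code{p_value}, \code{normality_p} (per group or NA),
#'   \code{n}.
#' @export
compareGroups <- function(a, b, alpha_normality = 0.05, var_equal = TRUE) {
  if (length(a) < 3 || length(b) < 3)
    stopf("both groups need n >= 3 (got %d, %d)", length(a), length(b))
  norm_p <- c(NA_real_, NA_real_)
  normal <- FALSE
  if (length(a) >= 8 && length(b) >= 8) {
    norm_p <- c(dagostinoPearson(a)$p_value, dagostinoPearson(b)$p_value)
    normal <- all(norm_p > alpha_normality)
  }
  if (normal) {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    list(test_used = "t-test", statistic = unname(tt$statistic),
         p_value = tt$p.value, normality_p = norm_p,
         n = c(length(a), length(b)))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    list(test_used = "mann-whitney", statistic = unname(wt$statistic),
         p_value = wt$p.value, normality_p = norm_p,
         n = c(length(a), length(b)))
  }
}

#' Estimate the ML/AP pulse-anisotropy ratio from tracked cells
#'
#' The fluctuation amplitude of a cell's ML extent relative to its AP extent.
#' Per cell, the log of each (sub-pixel, moment-based) extent series is
#' linearly detrended; the ratio of the pooled ML to pooled AP standard
#' deviation estimates the imposed ML/AP pulse-amplitude ratio (1 =
#' isotropic pulses). Pooling across cells weights strongly pulsing cells
#' more, where the extent signal dominates discretization noise.
#'
#' @param tracks track data.frame with \code{ext_ap_um}, \code{ext_ml_um}
#'   columns; only full-length tracks are used.
#' @param n_frames total frames (default max frame index).
#' @return list with \code{ratio}, \code{mean_isotropy_index} (mean
#'   bounding-box isotropy index over cells) and the \code{per_cell} metric
#'   table.
#' @export
anisotropyRatio <- function(tracks, n_frames = max(tracks$frame)) {
  full <- fullLengthTracks(tracks, n_frames)
  pm <- pulseMetrics(full)
  pm <- pm[is.finite(pm$isotropy_index), , drop = FALSE]
  dvar <- function(v) {
    r <- stats::residuals(stats::lm(log(v) ~ seq_along(v)))
    sum(r^2)
  }
  ids <- unique(full$cell_id)
  v_ap <- v_ml <- 0
  for (id in ids) {
    tr <- full[full$cell_id == id, ]
    tr <- tr[order(tr$frame), ]
    v_ap <- v_ap + dvar(tr$ext_ap_um)
    v_ml <- v_ml + dvar(tr$ext_ml_um)
  }
  list(ratio = sqrt(v_ml / v_ap),
       mean_isotropy_index = mean(pm$isotropy_index),
       per_cell = pm)
}
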