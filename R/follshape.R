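# Follicle-level shape statistics: equivalent-ellipse axes, aspect ratio,
# elongation coefficient with ANCOVA group comparison, and the per-pole
# extrapolated aspect ratio (eAR).

#' Fit follicle axes from a binary mask
#'
#' Equivalent-ellipse axes from the second central moments of the mask pixels:
#' each axis length is 4 sqrt(eigenvalue) of the normalized covariance matrix
#' (exact for a filled ellipse), with the major-axis orientation in degrees.
#'
#' @param mask logical or 0/1 matrix \code{[x, y]}; a single connected region
#'   of >= 100 px.
#' @param pixel_size um per pixel.
#' @return list with \code{long_axis_um}, \code{short_axis_um},
#'   \code{orientation_deg} (axial, [0, 180)), \code{centroid_px}.
#' @export
fitFollicleAxes <- function(mask, pixel_size = 1) {
  m <- mask > 0
  npx <- sum(m)
  if (npx < 100) stopf("mask too small: %d px < 100", npx)
  cc <- EBImage::bwlabel(m)
  if (max(cc) != 1) stopf("mask must be a single connected region (found %d)",
                          max(cc))
  px <- which(m)
  nx <- nrow(m)
  xs <- (px - 1L) %% nx
  ys <- (px - 1L) %/% nx
  mom <- pixelMoments(xs, ys)
  ax <- momentAxes(mom)
  list(long_axis_um = ax$major * pixel_size,
       short_axis_um = ax$minor * pixel_size,
       orientation_deg = ax$orientation,
       centroid_px = c(mom$mx, mom$my))
}

#' Follicle aspect ratio
#'
#' @param long_axis,short_axis um, with \code{long_axis >= short_axis > 0};
#'   or pass a follicle record (data.frame row / list with
#'   \code{long_axis_um}, \code{short_axis_um}) as \code{long_axis}.
#' @return long axis / short axis (>= 1).
#' @export
aspectRatio <- function(long_axis, short_axis = NULL) {
  if (is.null(short_axis)) {
    short_axis <- long_axis$short_axis_um
    long_axis <- long_axis$long_axis_um
  }
  if (any(short_axis <= 0) || any(long_axis < short_axis))
    stopf("invalid record: need long_axis >= short_axis > 0")
  long_axis / short_axis
}

#' Elongation coefficient of a follicle cohort
#'
#' Ordinary least-squares regression of the long axis on the short axis
#' across a cohort of previtellogenic follicles. The slope is the elongation
#' coefficient: a value of 1 means no elongation (spherical growth).
#'
#' @param records follicle data.frame with \code{long_axis_um,
#'   short_axis_um} and optionally \code{stage, genotype}.
#' @param stage_max follicles with \code{stage >= stage_max} are excluded
#'   (default 8, restricting to previtellogenic stages); records with unknown
#'   stage are kept.
#' @param through_origin constrain the fit through the origin.
#' @param conf_level confidence level for the slope CI.
#' @return list of class \code{"ElongationFit"}: \code{genotype, slope,
#'   intercept, n, slope_ci, residual_sd, model}.
#' @export
elongationCoefficient <- function(records, stage_max = 8,
                                  through_origin = FALSE, conf_level = 0.95) {
  if (!is.null(records$stage))
    records <- records[is.na(records$stage) | records$stage < stage_max, ,
                       drop = FALSE]
  if (nrow(records) < 3)
    stopf("insufficient data: %d records after stage filtering (< 3)",
          nrow(records))
  fit <- if (through_origin)
    stats::lm(long_axis_um ~ 0 + short_axis_um, data = records)
  else stats::lm(long_axis_um ~ short_axis_um, data = records)
  co <- stats::coef(fit)
  ci <- stats::confint(fit, "short_axis_um", level = conf_level)
  structure(list(genotype = if (!is.null(records$genotype))
                   paste(unique(records$genotype), collapse = "+") else NA,
                 slope = unname(co[["short_axis_um"]]),
                 intercept = if (through_origin) 0 else unname(co[[1]]),
                 n = nrow(records),
                 slope_ci = unname(ci[1, ]),
                 residual_sd = stats::sigma(fit),
                 model = fit),
            class = "ElongationFit")
}

#' @export
print.ElongationFit <- function(x, ...) {
  cat(sprintf(
    "Elongation coefficient (%s, n = %d): slope %.3f [%.3f, %.3f], intercept %.2f um, residual sd %.2f um\n",
    x$genotype, x$n, x$slope, x$slope_ci[1], x$slope_ci[2], x$intercept,
    x$residual_sd))
  invisible(x)
}

#' Compare elongation coefficients across genotypes by ANCOVA
#'
#' Separate-slopes analysis of covariance: \code{long ~ short * genotype}.
#' The interaction term tests whether slopes (elongation coefficients)
#' differ; pairwise slope contrasts are Bonferroni-adjusted by default.
#'
#' @param records follicle data.frame covering >= 2 genotypes.
#' @param stage_max previtellogenic stage cut-off, as in
#'   [elongationCoefficient()].
#' @param adjust p-adjustment for the pairwise slope contrasts.
#' @return list of class \code{"AncovaReport"}: \code{slopes} (per-genotype
#'   trend estimates), \code{interaction_p}, \code{contrasts} (pairwise
#'   slope differences with adjusted p), \code{model}.
#' @export
compareElongation <- function(records, stage_max = 8, adjust = "bonferroni") {
  if (!is.null(records$stage))
    records <- records[is.na(records$stage) | records$stage < stage_max, ,
                       drop = FALSE]
  records$genotype <- factor(records$genotype)
  if (nlevels(records$genotype) < 2)
    stopf("ANCOVA needs >= 2 genotypes (got %d)", nlevels(records$genotype))
  cnt <- table(records$genotype)
  if (any(cnt < 3)) stopf("every genotype needs >= 3 records")
  fit <- stats::lm(long_axis_um ~ short_axis_um * genotype, data = records)
  an <- stats::anova(fit)
  ip <- an["short_axis_um:genotype", "Pr(>F)"]
  tr <- emmeans::emtrends(fit, pairwise ~ genotype, var = "short_axis_um",
                          adjust = adjust)
  slopes <- as.data.frame(tr$emtrends)
  contrasts <- as.data.frame(tr$contrasts)
  structure(list(slopes = slopes, interaction_p = ip, contrasts = contrasts,
                 adjust = adjust, model = fit),
            class = "AncovaReport")
}

#' @export
print.AncovaReport <- function(x, ...) {
  cat("ANCOVA of long ~ short x genotype\n")
  cat(sprintf("  slope heterogeneity (interaction) p = %.3g\n", x$interaction_p))
  s <- x$slopes
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: slope %.3f [%.3f, %.3f]\n", s$genotype[i],
                s$short_axis_um.trend[i], s$lower.CL[i], s$upper.CL[i]))
  cat(sprintf("  pairwise slope contrasts (%s-adjusted):\n", x$adjust))
  cstat <- x$contrasts
  for (i in seq_len(nrow(cstat)))
    cat(sprintf("    %s: diff %.3f, p = %.3g\n", cstat$contrast[i],
                cstat$estimate[i], cstat$p.value[i]))
  invisible(x)
}

#' Extrapolated per-pole aspect ratio (eAR)
#'
#' The width of the follicle is measured at 25\% of its total AP length from
#' the given pole's tip. For an ellipse that chord is sqrt(3)/2 of the full
#' width, so the full width the pole "predicts" is \code{w25 * 2/sqrt(3)} and
#' eAR = length / extrapolated width. Agreement of anterior and posterior
#' eAR with the global aspect ratio is exact for a symmetric ellipse; an
#' under-elongated pole lowers its eAR.
#'
#' @param mask binary matrix \code{[x, y]} of the follicle (or semi-follicle
#'   completed by mirroring upstream).
#' @param pole \code{"anterior"} (tip at minimal AP coordinate) or
#'   \code{"posterior"}.
#' @param pixel_size um per pixel.
#' @param orientation_deg AP-axis orientation; \code{NULL} resolves it with
#'   [fitFollicleAxes()].
#' @return one-row data.frame: \code{pole, length_um, width_at_25_um,
#'   extrapolated_width_um, eAR}.
#' @export
extrapolatedAR <- function(mask, pole = c("anterior", "posterior"),
                           pixel_size = 1, orientation_deg = NULL) {
  pole <- match.arg(pole)
  m <- mask > 0
  if (is.null(orientation_deg))
    orientation_deg <- fitFollicleAxes(m, pixel_size)$orientation_deg
  px <- which(m)
  nx <- nrow(m)
  xs <- (px - 1L) %% nx
  ys <- (px - 1L) %/% nx
  th <- orientation_deg * pi / 180
  u <- xs * cos(th) + ys * sin(th)    # AP coordinate (px)
  # All lengths below come from the cumulative pixel-count function
  # N(u) = #\{pixels with AP coordinate <= u\}, whose derivative is the local
  # width. Working with N avoids both the half-pixel bias of bounding-box
  # extents and the lattice aliasing of binned row counts at degenerate
  # orientations (0, 45, 90 degrees).
  us <- sort(u)
  nPix <- length(us)
  span <- us[nPix] - us[1]
  # tip: near a smooth convex pole the width grows like sqrt(u - tip), so the
  # cumulative count grows like (u - tip)^(3/2); N^(2/3) is linear in u and
  # its root locates the tip at sub-pixel precision
  tipAt <- function(side) {
    edge <- if (side < 0) us[1] - 0.5 else us[nPix] + 0.5
    h <- max(4, 0.3 * span)
    if (side < 0) {
      sel <- us <= us[1] + h
      uu <- us[sel]
    } else {
      sel <- us >= us[nPix] - h
      uu <- sort(-us[sel])
    }
    M <- (seq_len(sum(sel)) - 0.5)^(2 / 3)
    co <- stats::coef(stats::lm(M ~ uu + I(uu^2)))
    disc <- co[[2]]^2 - 4 * co[[3]] * co[[1]]
    root <- if (is.finite(disc) && disc >= 0) {
      roots <- (-co[[2]] + c(-1, 1) * sqrt(disc)) / (2 * co[[3]])
      suppressWarnings(max(roots[roots <= min(uu) + 0.5]))
    } else -co[[1]] / co[[2]]
    root <- if (side < 0) root else -root
    if (is.finite(root) && abs(root - edge) <= 2.5) root else edge
  }
  tipA <- tipAt(-1)
  tipP <- tipAt(1)
  L <- tipP - tipA
  tip <- if (pole == "anterior") tipA else tipP
  station <- if (pole == "anterior") tip + 0.25 * L else tip - 0.25 * L
  # width at the station: derivative of a local quartic fit to N(u)
  h <- max(5, 0.3 * L)
  sel <- abs(us - station) <= h
  if (sum(sel) < 8)
    stopf("no mask pixels at the 25%% station for the %s pole", pole)
  x0 <- us[sel] - station
  N <- which(sel) - 0.5
  co <- stats::coef(stats::lm(N ~ x0 + I(x0^2) + I(x0^3) + I(x0^4)))
  w25 <- co[[2]] * pixel_size
  extw <- w25 * 2 / sqrt(3)
  data.frame(pole = pole, length_um = L * pixel_size, width_at_25_um = w25,
             extrapolated_width_um = extw, eAR = L * pixel_size / extw,
             stringsAsFactors = FALSE)
}

#' eAR at both poles of a mask
#'
#' @inheritParams extrapolatedAR
#' @param follicle_id id attached to the output rows.
#' @return two-row data.frame (anterior and posterior).
#' @export
poleEARs <- function(mask, pixel_size = 1, follicle_id = NA,
                     orientation_deg = NULL) {
  if (is.null(orientation_deg))
    orientation_deg <- fitFollicleAxes(mask, pixel_size)$orientation_deg
  out <- rbind(
    extrapolatedAR(mask, "anterior", pixel_size, orientation_deg),
    extrapolatedAR(mask, "posterior", pixel_size, orientation_deg))
  cbind(follicle_id = follicle_id, out)
}

#' Two-way repeated-measures comparison of pole eARs
#'
#' Two-way ANOVA with repeated measures on pole (within-subject factor) and
#' genotype (between-subject factor), followed by the two Bonferroni-adjusted
#' anterior-vs-posterior paired contrasts, one per genotype. Follicles
#' missing either pole are excluded with a warning.
#'
#' @param ear data.frame with columns \code{follicle_id, genotype, pole, eAR}
#'   (pole in \code{anterior}/\code{posterior}).
#' @return list of class \code{"PoleAnovaReport"}: \code{anova_table},
#'   \code{pole_p, genotype_p, interaction_p}, \code{pairwise} (per-genotype
#'   paired contrasts, Bonferroni-adjusted), \code{n_follicles}.
#' @export
comparePoles <- function(ear) {
  ear$pole <- factor(ear$pole, levels = c("anterior", "posterior"))
  ear$genotype <- factor(ear$genotype)
  cnt <- table(ear$follicle_id)
  bad <- names(cnt)[cnt != 2]
  if (length(bad)) {
    warnf("excluding %d follicle(s) missing a pole measurement", length(bad))
    ear <- ear[!ear$follicle_id %in% bad, , drop = FALSE]
  }
  ear$follicle_id <- factor(ear$follicle_id)
  fit <- stats::aov(eAR ~ genotype * pole + Error(follicle_id),
                    data = ear)
  sm <- summary(fit)
  between <- sm[["Error: follicle_id"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  gp <- between["genotype", "Pr(>F)"]
  pp <- within["pole", "Pr(>F)"]
  ipp <- within["genotype:pole", "Pr(>F)"]
  pw <- lapply(levels(ear$genotype), function(g) {
    sub <- ear[ear$genotype == g, ]
    wide <- merge(sub[sub$pole == "anterior", c("follicle_id", "eAR")],
                  sub[sub$pole == "posterior", c("follicle_id", "eAR")],
                  by = "follicle_id", suffixes = c("_ant", "_post"))
    diffs <- wide$eAR_ant - wide$eAR_post
    if (stats::sd(diffs) == 0) {
      # constant difference: the paired t-test is undefined; p = 1 for a
      # zero difference, otherwise the contrast is degenerate-certain
      praw <- if (all(diffs == 0)) 1 else 0
    } else praw <- stats::t.test(diffs)$p.value
    data.frame(genotype = g, mean_diff = mean(diffs),
               p_raw = praw,
               p_adjusted = min(1, praw * nlevels(ear$genotype)),
               n = nrow(wide))
  })
  structure(list(anova_table = sm, pole_p = pp, genotype_p = gp,
                 interaction_p = ipp, pairwise = do.call(rbind, pw),
                 n_follicles = nlevels(droplevels(ear$follicle_id))),
            class = "PoleAnovaReport")
}

#' @export
print.PoleAnovaReport <- function(x, ...) {
  cat(sprintf(
    "Two-way RM-ANOVA on eAR (%d follicles): pole p = %.3g, genotype p = %.3g, interaction p = %.3g\n",
    x$n_follicles, x$pole_p, x$genotype_p, x$interaction_p))
  pw <- x$pairwise
  for (i in seq_len(nrow(pw)))
    cat(sprintf("  %s anterior - posterior: %.3f (Bonferroni p = %.3g, n = %d)\n",
                pw$genotype[i], pw$mean_diff[i], pw$p_adjusted[i], pw$n[i]))
  invisible(x)
}
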