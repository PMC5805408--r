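# Synthetic-data generator: follicle cohorts with a known elongation
# coefficient, and pulsing-epithelium movies with known per-cell amplitudes,
# amplitude gradient, myosin lag, pulse anisotropy and bond enrichment.

#' Specification of a synthetic follicle cohort
#'
#' A cohort of follicles whose long axis is a linear function of the short
#' axis: \code{long = slope * short + intercept + N(0, noise_sd)}, clipped so
#' that \code{long >= short}. The slope is the cohort's true elongation
#' coefficient (1 = spheres, no elongation).
#'
#' @param n_follicles number of follicles (>= 2).
#' @param short_axis_range numeric length-2, min/max short axis in um.
#' @param slope dimensionless long-vs-short slope.
#' @param intercept um.
#' @param noise_sd additive Gaussian noise on the long axis, um (>= 0).
#' @param genotype_label text label attached to every record.
#' @param stages integer vector of developmental stages to cycle through
#'   (default 3:7, the early elongation window).
#' @param spacing \code{"even"} (default) places short axes on a regular grid
#'   over the range; \code{"random"} draws them uniformly.
#' @param seed integer RNG seed; \code{NULL} leaves the RNG state alone.
#' @return a validated list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(n_follicles = 30L, short_axis_range = c(20, 80),
                       slope = 1.6, intercept = 0, noise_sd = 0,
                       genotype_label = "WT", stages = 3:7,
                       spacing = c("even", "random"), seed = 1L) {
  spacing <- match.arg(spacing)
  checkField(is.numeric(n_follicles) && n_follicles >= 2, "n_follicles", ">= 2 required")
  checkField(length(short_axis_range) == 2 && short_axis_range[1] > 0 &&
             short_axis_range[1] <= short_axis_range[2],
             "short_axis_range", "need 0 < min <= max")
  checkField(is.numeric(slope) && length(slope) == 1, "slope", "single number")
  checkField(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", ">= 0 required")
  structure(list(n_follicles = as.integer(n_follicles),
                 short_axis_range = as.numeric(short_axis_range),
                 slope = slope, intercept = intercept, noise_sd = noise_sd,
                 genotype_label = genotype_label, stages = as.integer(stages),
                 spacing = spacing, seed = seed),
            class = "CohortSpec")
}

#' Generate a synthetic follicle cohort
#'
#' @param spec a [cohortSpec()].
#' @return data.frame of follicle records: \code{follicle_id, genotype, stage,
#'   long_axis_um, short_axis_um, source}.
#' @examples
#' coh <- genFollicleCohort(cohortSpec(slope = 1.6, noise_sd = 0))
#' all.equal(coh$long_axis_um / coh$short_axis_um, rep(1.6, 30))
#' @export
genFollicleCohort <- function(spec) {
  if (!inherits(spec, "CohortSpec")) spec <- do.call(cohortSpec, spec)
  withSeed(spec$seed, {
    n <- spec$n_follicles
    r <- spec$short_axis_range
    short <- if (spec$spacing == "even") seq(r[1], r[2], length.out = n)
             else stats::runif(n, r[1], r[2])
    long <- spec$slope * short + spec$intercept +
      if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else 0
    long <- pmax(long, short)
    data.frame(follicle_id = sprintf("%s_%03d", spec$genotype_label, seq_len(n)),
               genotype = spec$genotype_label,
               stage = rep_len(spec$stages, n),
               long_axis_um = long, short_axis_um = short,
               source = "synthetic", stringsAsFactors = FALSE)
  })
}

#' Specification of a synthetic pulsing epithelium movie
#'
#' Defines a flat 2D sheet of Voronoi-like cells whose apical areas oscillate
#' asynchronously. Each cell's fractional area amplitude follows an
#' exponential gradient from the pole,
#' \code{A(d) = baseline + (amplitude_at_pole - baseline) * exp(-d / decay_length)}.
#' Contraction episodes are raised-cosine pulses (duration
#' \code{pulse_period_s}) separated by exponentially distributed pauses; the
#' per-cell myosin signal is the same contraction drive advanced by
#' \code{myosin_lag_frames} frames. Defaults mirror the imaging regime the
#' pipeline targets: 40 frames at 15 s, ~3 min pulses, ~40% fractional area
#' variation near the pole.
#'
#' @param n_cells number of cells.
#' @param field_size image side in pixels (square field).
#' @param pixel_size um per pixel.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval_s seconds between frames.
#' @param pulse_period_s duration of one contraction episode, seconds.
#' @param pause_mean_s mean of the exponential inter-pulse pause, seconds.
#' @param amplitude_at_pole fractional area amplitude at the pole.
#' @param baseline_amplitude fractional area amplitude far from the pole.
#' @param decay_length amplitude gradient length scale, um.
#' @param myosin_lag_frames integer frames by which myosin leads contraction.
#' @param myosin_gain myosin intensity per unit contraction drive.
#' @param anisotropy_ratio ML/AP pulse amplitude ratio (1 = isotropic pulses).
#' @param bond_enrichment intensity factor applied to membrane-channel bonds
#'   whose axial angle falls in \code{enrichment_band} (1 = unpolarized).
#' @param enrichment_band degrees, angle band (relative to AP) receiving the
#'   enrichment factor.
#' @param pole_size_drop fractional reduction of cell target area at the pole
#'   (0 = uniform cell sizes), decaying with \code{decay_length}.
#' @param seed_jitter uniform jitter of the seed points as a fraction of the
#'   grid spacing (0 = regular lattice).
#' @param pole_xy pixel coordinates (0-based) of the pole landmark; default
#'   mid-left edge so AP runs along x.
#' @param noise_model list with \code{gaussian_sd} (read noise, intensity
#'   units) and \code{photon_scale} (photons per intensity unit for Poisson
#'   shot noise; \code{Inf} disables it).
#' @param psf_sigma_px Gaussian blur sigma (px) emulating the optical point
#'   spread function (default 0.8 px, i.e. 0.2 um at the default
#'   calibration).
#' @param seed integer RNG seed.
#' @return a validated list of class \code{"TissueSpec"}.
#' @export
tissueSpec <- function(n_cells = 50L, field_size = 200L, pixel_size = 0.25,
                       n_frames = 40L, frame_interval_s = 15,
                       pulse_period_s = 180, pause_mean_s = 120,
                       amplitude_at_pole = 0.4, baseline_amplitude = 0.1,
                       decay_length = 30, myosin_lag_frames = 2L,
                       myosin_gain = 1, anisotropy_ratio = 1,
                       bond_enrichment = 1, enrichment_band = c(70, 90),
                       pole_size_drop = 0, seed_jitter = 0.3, pole_xy = NULL,
                       noise_model = list(gaussian_sd = 0.05, photon_scale = 200),
                       psf_sigma_px = 0.8, seed = 1L) {
  checkField(n_cells >= 1, "n_cells", ">= 1 required")
  checkField(field_size >= 8, "field_size", "too small")
  checkField(pixel_size > 0, "pixel_size", "> 0 required")
  checkField(n_frames >= 2, "n_frames", ">= 2 required")
  checkField(frame_interval_s > 0, "frame_interval_s", "> 0 required")
  checkField(amplitude_at_pole >= baseline_amplitude && baseline_amplitude >= 0,
             "amplitude_at_pole", "need amplitude_at_pole >= baseline_amplitude >= 0")
  checkField(amplitude_at_pole < 1, "amplitude_at_pole", "< 1 required")
  checkField(decay_length > 0, "decay_length", "> 0 required")
  checkField(anisotropy_ratio > 0, "anisotropy_ratio", "> 0 required")
  checkField(bond_enrichment > 0, "bond_enrichment", "> 0 required")
  checkField(pole_size_drop >= 0 && pole_size_drop < 1, "pole_size_drop",
             "in [0, 1) required")
  checkField(seed_jitter >= 0 && seed_jitter <= 0.45, "seed_jitter",
             "in [0, 0.45] required")
  if (is.null(pole_xy)) pole_xy <- c(0, (field_size - 1) / 2)
  # geometry: mean cell diameter must stay resolvable
  diam_px <- field_size / sqrt(n_cells)
  if (diam_px < 3)
    stopf("field too small for n_cells: mean cell diameter %.2f px < 3 px", diam_px)
  structure(list(n_cells = as.integer(n_cells), field_size = as.integer(field_size),
                 pixel_size = pixel_size, n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 pulse_period_s = pulse_period_s, pause_mean_s = pause_mean_s,
                 amplitude_at_pole = amplitude_at_pole,
                 baseline_amplitude = baseline_amplitude,
                 decay_length = decay_length,
                 myosin_lag_frames = as.integer(myosin_lag_frames),
                 myosin_gain = myosin_gain, anisotropy_ratio = anisotropy_ratio,
                 bond_enrichment = bond_enrichment,
                 enrichment_band = enrichment_band,
                 pole_size_drop = pole_size_drop,
                 seed_jitter = seed_jitter,
                 pole_xy = as.numeric(pole_xy), noise_model = noise_model,
                 psf_sigma_px = psf_sigma_px, seed = seed),
            class = "TissueSpec")
}

# Raised-cosine pulse train: returns a function of time (seconds) in [0, 1].
# Pulse starts are drawn as t0, t0 + P + Exp(pause), ...; t0 < 0 randomizes
# the phase so cells pulse asynchronously.
#' @noRd
makePulseTrain <- function(period_s, pause_mean_s, t_max) {
  t0 <- -period_s - stats::rexp(1, 1 / max(pause_mean_s, 1e-9)) * stats::runif(1)
  starts <- t0
  while (starts[length(starts)] < t_max) {
    starts <- c(starts,
                starts[length(starts)] + period_s +
                  stats::rexp(1, 1 / max(pause_mean_s, 1e-9)))
  }
  function(times) {
    v <- numeric(length(times))
    for (s in starts) {
      inpulse <- times >= s & times < s + period_s
      if (any(inpulse))
        v[inpulse] <- 0.5 * (1 - cos(2 * pi * (times[inpulse] - s) / period_s))
    }
    v
  }
}

#' Generate a synthetic pulsing tissue movie with ground truth
#'
#' Renders an \code{n_frames}-frame, two-channel movie of a pulsing cell
#' sheet. Cell territories are an anisotropically weighted Voronoi
#' tessellation of jittered grid seeds: during a contraction episode a cell's
#' AP and ML length scales shrink by its per-axis amplitudes (split from the
#' total area amplitude by \code{anisotropy_ratio}), so its area drops and its
#' neighbours expand to fill the field. The membrane channel draws the
#' boundaries between territories (optionally enriched on bonds in a given
#' angle band), blurred and corrupted by shot plus read noise; the myosin
#' channel fills each cell with \code{base + myosin_gain * amplitude * drive}
#' evaluated \code{myosin_lag_frames} frames ahead of the area drive.
#'
#' @param spec a [tissueSpec()].
#' @return list with elements \code{stack} (a [FollicleStack-class] with
#'   channels \code{membrane}, \code{myosin}) and \code{truth}
#'   (a [GroundTruth-class]).
#' @export
genPulsingTissue <- function(spec) {
  if (!inherits(spec, "TissueSpec")) spec <- do.call(tissueSpec, spec)
  withSeed(spec$seed, .renderTissue(spec))
}

#' @noRd
.renderTissue <- function(spec) {
  n <- spec$n_cells
  fs <- spec$field_size
  ps <- spec$pixel_size
  nf <- spec$n_frames
  dt <- spec$frame_interval_s

  # --- seed points: jittered grid, n cells kept
  gx <- ceiling(sqrt(n))
  gy <- ceiling(n / gx)
  spx <- fs / gx
  spy <- fs / gy
  cx <- as.vector(outer((seq_len(gx) - 0.5) * spx, rep(1, gy)))
  cy <- as.vector(outer(rep(1, gx), (seq_len(gy) - 0.5) * spy))
  keep <- if (gx * gy > n) sort(sample.int(gx * gy, n)) else seq_len(n)
  jit <- spec$seed_jitter
  cx <- cx[keep] + stats::runif(n, -jit, jit) * spx
  cy <- cy[keep] + stats::runif(n, -jit, jit) * spy
  if (spec$pole_size_drop > 0) {
    # cells near the pole must be smaller: raise the seed density there by
    # compressing seed positions radially towards the pole (local competition
    # alone cannot impose a smooth global size field)
    k <- 1 - sqrt(1 - spec$pole_size_drop)
    rx <- cx - spec$pole_xy[1]
    ry <- cy - spec$pole_xy[2]
    r <- sqrt(rx^2 + ry^2)
    lam_px <- spec$decay_length / spec$pixel_size
    shrink <- 1 - k * exp(-r / lam_px)
    cx <- spec$pole_xy[1] + rx * shrink
    cy <- spec$pole_xy[2] + ry * shrink
    cx <- pmin(pmax(cx, 1), fs - 2)
    cy <- pmin(pmax(cy, 1), fs - 2)
  }

  # --- per-cell amplitudes from the pole gradient
  d_um <- sqrt((cx - spec$pole_xy[1])^2 + (cy - spec$pole_xy[2])^2) * ps
  amp <- spec$baseline_amplitude +
    (spec$amplitude_at_pole - spec$baseline_amplitude) *
    exp(-d_um / spec$decay_length)
  r <- spec$anisotropy_ratio
  amp_ap <- amp / (1 + r)      # fractional AP length amplitude
  amp_ml <- amp * r / (1 + r)  # fractional ML length amplitude

  # cell-size gradient (smaller cells near the pole when pole_size_drop > 0)
  wsize <- sqrt(1 - spec$pole_size_drop * exp(-d_um / spec$decay_length))

  # --- per-cell drive at frame times and myosin (advanced) times
  t_frames <- (seq_len(nf) - 1) * dt
  t_myo <- t_frames + spec$myosin_lag_frames * dt
  drive <- matrix(0, n, nf)
  mdrive <- matrix(0, n, nf)
  for (i in seq_len(n)) {
    f <- makePulseTrain(spec$pulse_period_s, spec$pause_mean_s,
                        max(t_frames, t_myo) + spec$pulse_period_s)
    drive[i, ] <- f(t_frames)
    mdrive[i, ] <- f(t_myo)
  }

  # --- static tessellation (anisotropically weighted Voronoi of the seeds)
  xs <- rep(0:(fs - 1), times = fs)  # [x, y] column-major over matrix
  ys <- rep(0:(fs - 1), each = fs)
  best <- rep(Inf, fs * fs)
  lab0 <- integer(fs * fs)
  for (i in seq_len(n)) {
    di <- ((xs - cx[i])^2 + (ys - cy[i])^2) / wsize[i]^2
    upd <- di < best
    best[upd] <- di[upd]
    lab0[upd] <- i
  }
  L0 <- matrix(lab0, fs, fs)
  region <- split(seq_len(fs * fs), lab0)  # static pixel sets per cell

  # static junction lines (always rendered) and per-bond pixels for enrichment
  iface <- .staticInterface(L0, spec$bond_enrichment, spec$enrichment_band)

  # candidate neighbours per cell (itself first, then static adjacency),
  # for the analytic point-in-territory test below
  bt0 <- .bondPixelTable(L0)
  adj <- lapply(seq_len(n), function(i)
    c(i, sort(unique(c(bt0$pairs$b[bt0$pairs$a == i],
                       bt0$pairs$a[bt0$pairs$b == i])))))

  # --- per-frame labels: each cell's territory is its static polygon scaled
  # about its seed by the per-axis contraction factors (kinematic pulses:
  # cells contract independently; the widening inter-outline band becomes
  # the junctional membrane belt)
  labels <- array(0L, dim = c(fs, fs, nf))
  area_px <- matrix(0, n, nf)
  for (t in seq_len(nf)) {
    sx <- 1 - amp_ap * drive[, t]
    sy <- 1 - amp_ml * drive[, t]
    lab <- integer(fs * fs)
    for (i in seq_len(n)) {
      p <- region[[i]]
      # continuous back-map: p is in the contracted territory iff the
      # expanded point q still lies in cell i's static Voronoi territory
      qx <- cx[i] + (xs[p] - cx[i]) / sx[i]
      qy <- cy[i] + (ys[p] - cy[i]) / sy[i]
      keep <- qx >= -0.5 & qx <= fs - 0.5 & qy >= -0.5 & qy <= fs - 0.5
      cand <- adj[[i]]
      dmat <- vapply(cand, function(j)
        ((qx - cx[j])^2 + (qy - cy[j])^2) / wsize[j]^2,
        numeric(length(p)))
      keep <- keep & (max.col(-dmat, ties.method = "first") == 1L)
      lab[p[keep]] <- i
    }
    labels[, , t] <- lab
    area_px[, t] <- tabulate(lab, nbins = n)
  }
  if (any(area_px == 0))
    stopf("field too small for n_cells: a cell vanished during rendering")

  # --- membrane + myosin channels
  gsd <- spec$noise_model$gaussian_sd %||% 0
  phs <- spec$noise_model$photon_scale %||% Inf
  pix <- array(0, dim = c(fs, fs, 2L, nf))
  myo_base <- 0.2
  for (t in seq_len(nf)) {
    lab <- labels[, , t]
    mem <- matrix(0, fs, fs)
    mem[lab == 0L] <- 1          # inter-outline band (junctions + moat)
    mem[iface$pixels] <- 1       # static junction lines
    if (spec$bond_enrichment != 1) {
      fac <- .floodFactors(iface$pixels, iface$factor, which(mem > 0),
                           fs, fs * fs)
      scale <- fac > 0
      mem[scale] <- mem[scale] * fac[scale]
    }
    myo_val <- c(myo_base, myo_base + spec$myosin_gain * amp * mdrive[, t])
    myo <- matrix(myo_val[lab + 1L], fs, fs)
    mem <- EBImage::gblur(mem, sigma = spec$psf_sigma_px) + 0.05
    myo <- EBImage::gblur(myo, sigma = max(spec$psf_sigma_px, 1))
    pix[, , 1L, t] <- .addNoise(mem, gsd, phs)
    pix[, , 2L, t] <- .addNoise(myo, gsd, phs)
  }
  border_ids <- unique(c(L0[1, ], L0[fs, ], L0[, 1], L0[, fs]))

  stack <- FollicleStack(pix, pixelSize = ps, frameInterval = dt,
                         channelNames = c("membrane", "myosin"))
  # realized fractional area amplitude of the isolated-cell area model
  # (1 - A_ap d)(1 - A_ml d): what a pulse-intensity estimator can recover
  # from the frames actually rendered, given the drive each cell executed.
  a_model <- (1 - amp_ap * drive) * (1 - amp_ml * drive)
  amp_real <- apply(a_model, 1, function(a) (max(a) - min(a)) / mean(a))
  perCell <- data.frame(cell_id = seq_len(n), x_px = cx, y_px = cy,
                        dist_um = d_um, amplitude = amp,
                        amplitude_ap = amp_ap, amplitude_ml = amp_ml,
                        amplitude_realized = amp_real,
                        mean_area_um2 = rowMeans(area_px) * ps^2,
                        is_border = seq_len(n) %in% border_ids)
  truth <- GroundTruth(labelStack = labels, perCell = perCell,
                       series = list(area_px = area_px, drive = drive,
                                     myosin_drive = mdrive,
                                     static_labels = L0),
                       global = list(myosin_lag_frames = spec$myosin_lag_frames,
                                     decay_length = spec$decay_length,
                                     anisotropy_ratio = spec$anisotropy_ratio,
                                     bond_enrichment = spec$bond_enrichment,
                                     enrichment_band = spec$enrichment_band,
                                     pole_um = spec$pole_xy * ps,
                                     pole_px = spec$pole_xy))
  list(stack = stack, truth = truth, spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Static junction lines of the tessellation, plus a per-pixel intensity
# factor (the bond enrichment for bonds whose axial angle lies in the band,
# 1 elsewhere) seeded on the interface pixels.
#' @noRd
.staticInterface <- function(L0, enrichment = 1, band = c(70, 90)) {
  bonds <- .bondPixelTable(L0)
  pixels <- unlist(bonds$pixels, use.names = FALSE)
  fac <- rep(1, length(pixels))
  if (enrichment != 1 && nrow(bonds$pairs)) {
    nper <- lengths(bonds$pixels)
    enr <- bonds$pairs$angle >= band[1] & bonds$pairs$angle <= band[2]
    fac <- rep(ifelse(enr, enrichment, 1), nper)
  }
  list(pixels = pixels, factor = fac)
}

# Propagate per-bond intensity factors from the static interface pixels into
# the widened junction band by first-arrival 4-neighbour flooding, so each
# band pixel inherits the factor of its own bond (no cross-bond bleeding).
#' @noRd
.floodFactors <- function(seedpix, seedfac, band, nx, npx, rounds = 6L) {
  fac <- rep(0, npx)
  fac[seedpix] <- seedfac
  inband <- rep(FALSE, npx)
  inband[band] <- TRUE
  front <- seedpix
  for (r in seq_len(rounds)) {
    cand <- unique(c(front - 1L, front + 1L, front - nx, front + nx))
    cand <- cand[cand >= 1L & cand <= npx]
    cand <- cand[inband[cand] & fac[cand] == 0]
    if (!length(cand)) break
    # inherit from an already-set 4-neighbour (first non-zero found)
    for (off in c(-1L, 1L, -nx, nx)) {
      src <- cand + off
      ok <- src >= 1L & src <= npx
      ok[ok] <- fac[src[ok]] > 0
      todo <- ok & fac[cand] == 0
      fac[cand[todo]] <- fac[src[todo]]
    }
    front <- cand
  }
  fac
}

#' @noRd
.addNoise <- function(img, gaussian_sd, photon_scale) {
  img[img < 0] <- 0
  if (is.finite(photon_scale) && photon_scale > 0)
    img <- matrix(stats::rpois(length(img), img * photon_scale) / photon_scale,
                  nrow(img), ncol(img))
  if (gaussian_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, gaussian_sd),
                        nrow(img), ncol(img))
  img[img < 0] <- 0
  img
}

#' Generate a discrete filled-ellipse mask with known aspect ratio
#'
#' Fixture generator for the shape statistics: a binary mask sampling a filled
#' ellipse of semi-axes \code{semi_major}, \code{semi_minor} (um), rotated by
#' \code{orientation} degrees (major axis relative to the image x axis).
#'
#' @param semi_major,semi_minor semi-axes in um, \code{semi_major >= semi_minor > 0}.
#' @param orientation degrees.
#' @param pixel_size um per pixel; the minor semi-axis must span >= 5 px.
#' @return list with \code{mask} (logical matrix \code{[x, y]}), \code{trueAR}
#'   (\code{semi_major / semi_minor}), \code{pixelSize}, \code{center} (px).
#' @export
genEllipseMask <- function(semi_major, semi_minor, orientation = 0,
                           pixel_size = 0.5) {
  checkField(semi_major >= semi_minor && semi_minor > 0, "semi_minor",
             "need semi_major >= semi_minor > 0")
  if (semi_minor / pixel_size < 5)
    stopf("sub-resolution ellipse: semi_minor spans %.2f px < 5 px",
          semi_minor / pixel_size)
  a <- semi_major / pixel_size
  b <- semi_minor / pixel_size
  half <- ceiling(a) + 2
  nside <- 2 * half + 1
  ctr <- half + 0.25  # 0-based centre; quarter-pixel offset avoids the
                      # degenerate lattice alignment of an integer centre
  x <- 0:(nside - 1) - ctr
  th <- orientation * pi / 180
  X <- matrix(rep(x, times = nside), nside, nside)
  Y <- matrix(rep(x, each = nside), nside, nside)
  U <- X * cos(th) + Y * sin(th)
  V <- -X * sin(th) + Y * cos(th)
  # strict inequality: midpoint sampling without the degenerate inclusive
  # boundary when axes align with the pixel grid
  mask <- (U / a)^2 + (V / b)^2 < 1
  list(mask = mask, trueAR = semi_major / semi_minor, pixelSize = pixel_size,
       center = c(ctr, ctr))
}
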