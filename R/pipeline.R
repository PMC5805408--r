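# Pipeline orchestration: a validated configuration, stage subcommands and a
# summary report. This is the programmatic entry point; inst/scripts ships a
# thin Rscript wrapper around it.

#' Build and validate a pipeline configuration
#'
#' Fills defaults and validates a configuration list (or YAML file). All
#' failures are reported together in one validation error.
#'
#' @param config a named list or path to a YAML file.
#' @return the validated config (class \code{"PipelineConfig"}).
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    out_dir = "follipulse_out",
    seed = 1L,
    channels = list(membrane = "membrane", myosin = "myosin"),
    tissue = list(),          # tissueSpec() overrides
    cohort = list(),          # cohortSpec() overrides
    segmentation = list(blur_sigma = 1.5, h_minima_depth = 0.08,
                        min_area = 5, max_area = 2000, clear_border = TRUE),
    tracking = list(min_iou = 0.3),
    pulses = list(min_cells = 10),
    xcorr = list(max_lag_frames = 8, detrend = TRUE),
    gradient = list(bin_width_um = 5),
    polarity = list(bin_width_deg = 10),
    inputs = list()           # stack/tracks/follicles/mask paths
  )
  cfg <- utils::modifyList(defaults, config)
  errs <- character()
  if (!is.numeric(cfg$seed)) errs <- c(errs, "seed must be numeric")
  if (!is.character(cfg$out_dir)) errs <- c(errs, "out_dir must be a path")
  for (f in c("membrane", "myosin"))
    if (is.null(cfg$channels[[f]]))
      errs <- c(errs, sprintf("channels$%s must be mapped", f))
  num01 <- function(x) is.numeric(x) && length(x) == 1 && x > 0
  if (!num01(cfg$tracking$min_iou) || cfg$tracking$min_iou > 1)
    errs <- c(errs, "tracking$min_iou must be in (0, 1]")
  if (!num01(cfg$segmentation$blur_sigma))
    errs <- c(errs, "segmentation$blur_sigma must be > 0")
  if (length(errs))
    stopf("invalid pipeline config:\n  - %s", paste(errs, collapse = "\n  - "))
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Run one pipeline stage
#'
#' Subcommands: \code{simulate} (synthetic movie + ground truth),
#' \code{segment}, \code{track}, \code{pulses} (per-cell metrics +
#' per-follicle amplitude), \code{xcorr}, \code{shape} (elongation
#' coefficients and, with >= 2 genotypes, ANCOVA), \code{ear},
#' \code{gradient}, \code{polarity}, \code{count-ap} and \code{report}
#' (aggregates the stage CSVs present in \code{out_dir}). Every CSV carries
#' the package version and the config hash; outputs are deterministic for a
#' fixed config and seed.
#'
#' @param config a [pipelineConfig()] (list or YAML path accepted).
#' @param subcommand stage to run.
#' @return stage-dependent result, invisibly (paths of the written outputs in
#'   \code{$outputs}).
#' @export
runPipeline <- function(config, subcommand = c("simulate", "segment", "track",
                                               "pulses", "xcorr", "shape",
                                               "ear", "gradient", "polarity",
                                               "count-ap", "report")) {
  subcommand <- match.arg(subcommand)
  cfg <- if (inherits(config, "PipelineConfig")) config else pipelineConfig(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = configHash(unclass(cfg)), stage = subcommand)
  p <- function(...) file.path(cfg$out_dir, ...)
  res <- switch(subcommand,
    "simulate" = {
      spec <- do.call(tissueSpec, utils::modifyList(list(seed = cfg$seed),
                                                    cfg$tissue))
      sim <- genPulsingTissue(spec)
      writeImageStack(sim$stack, p("stack.tif"), spec = spec)
      writeGroundTruth(sim$truth, p("truth"), spec = spec)
      message(sprintf("[simulate] %d cells, %d frames -> %s",
                      spec$n_cells, spec$n_frames, p("stack.tif")))
      list(stack = sim$stack, truth = sim$truth,
           outputs = c(p("stack.tif"), p("truth")))
    },
    "segment" = {
      stack <- readImageStack(cfg$inputs$stack %||% p("stack.tif"))
      seg <- do.call(segmentStack,
                     c(list(stack = stack, channel = cfg$channels$membrane),
                       cfg$segmentation))
      writeLabelStack(seg, p("segmented.tif"))
      jsonlite::write_json(cfg$segmentation, p("segmentation_params.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      message(sprintf("[segment] %d frames -> %s", dim(seg)[3], p("segmented.tif")))
      list(labels = seg, outputs = p("segmented.tif"))
    },
    "track" = {
      labels <- readLabelStack(cfg$inputs$labels %||% p("segmented.tif"))
      stack <- readImageStack(cfg$inputs$stack %||% p("stack.tif"))
      stable <- trackCells(labels, min_iou = cfg$tracking$min_iou)
      tracks <- cellTracks(stable, stack)
      writeLabelStack(stable, p("tracked.tif"))
      writeMetricsCsv(tracks, p("tracks.csv"),
                      units = c(area_um2 = "um^2", cx_um = "um", cy_um = "um",
                                bbox_ap_um = "um", bbox_ml_um = "um"),
                      provenance = prov)
      message(sprintf("[track] %d tracks -> %s",
                      length(unique(tracks$cell_id)), p("tracks.csv")))
      list(tracks = tracks, outputs = c(p("tracked.tif"), p("tracks.csv")))
    },
    "pulses" = {
      tracks <- readMetricsCsv(cfg$inputs$tracks %||% p("tracks.csv"))
      nf <- max(tracks$frame)
      pm <- pulseMetrics(fullLengthTracks(tracks, nf))
      writeMetricsCsv(pm, p("pulse_metrics.csv"),
                      units = c(pulse_intensity = "dimensionless"),
                      provenance = prov)
      amp <- tryCatch(folliclePulseAmplitude(tracks,
                                             min_cells = cfg$pulses$min_cells),
                      error = function(e) {
                        message("[pulses] follicle excluded: ",
                                conditionMessage(e))
                        NA_real_
                      })
      writeMetricsCsv(data.frame(n_cells = sum(!is.na(pm$pulse_intensity)),
                                 mean_surface_variation_pct = amp),
                      p("follicle_amplitude.csv"),
                      units = c(mean_surface_variation_pct = "percent"),
                      provenance = prov)
      message(sprintf("[pulses] %d cells, mean variation %.1f%%", nrow(pm), amp))
      list(metrics = pm, amplitude = amp,
           outputs = c(p("pulse_metrics.csv"), p("follicle_amplitude.csv")))
    },
    "xcorr" = {
      tracks <- readMetricsCsv(cfg$inputs$tracks %||% p("tracks.csv"))
      xc <- crossCorrelate(tracks, channel = cfg$channels$myosin,
                           max_lag_frames = cfg$xcorr$max_lag_frames,
                           detrend = cfg$xcorr$detrend)
      writeMetricsCsv(data.frame(lag_frames = xc$lags_frames,
                                 correlation = xc$correlation),
                      p("xcorr.csv"), provenance = prov)
      message(sprintf("[xcorr] lead-lag %+d frames over %d cells",
                      xc$lead_lag_frames, xc$n_cells))
      list(xcorr = xc, outputs = p("xcorr.csv"))
    },
    "shape" = {
      foll <- if (!is.null(cfg$inputs$follicles))
        readMetricsCsv(cfg$inputs$follicles)
      else genFollicleCohort(do.call(cohortSpec,
                                     utils::modifyList(list(seed = cfg$seed),
                                                       cfg$cohort)))
      fits <- lapply(split(foll, foll$genotype), elongationCoefficient)
      fitdf <- do.call(rbind, lapply(fits, function(f)
        data.frame(genotype = f$genotype, slope = f$slope,
                   intercept = f$intercept, n = f$n,
                   slope_lo = f$slope_ci[1], slope_hi = f$slope_ci[2])))
      writeMetricsCsv(fitdf, p("elongation_fits.csv"),
                      units = c(intercept = "um"), provenance = prov)
      anc <- NULL
      if (length(unique(foll$genotype)) >= 2) {
        anc <- compareElongation(foll)
        writeMetricsCsv(anc$contrasts, p("elongation_ancova.csv"),
                        provenance = prov)
      }
      message(sprintf("[shape] %d genotype(s) fitted", nrow(fitdf)))
      list(fits = fits, ancova = anc, outputs = p("elongation_fits.csv"))
    },
    "ear" = {
      mask <- readLabelStack(cfg$inputs$mask)[, , 1] > 0
      ears <- poleEARs(mask, pixel_size = cfg$inputs$mask_pixel_size %||% 1,
                       follicle_id = cfg$inputs$follicle_id %||% 1)
      writeMetricsCsv(ears, p("ear.csv"),
                      units = c(length_um = "um", width_at_25_um = "um",
                                extrapolated_width_um = "um"),
                      provenance = prov)
      message(sprintf("[ear] anterior %.2f / posterior %.2f",
                      ears$eAR[1], ears$eAR[2]))
      list(ears = ears, outputs = p("ear.csv"))
    },
    "gradient" = {
      tracks <- readMetricsCsv(cfg$inputs$tracks %||% p("tracks.csv"))
      nf <- max(tracks$frame)
      full <- fullLengthTracks(tracks, nf)
      pm <- pulseMetrics(full)
      agg <- stats::aggregate(full[, c("cx_um", "cy_um")],
                              by = list(cell_id = full$cell_id), mean)
      pole <- unlist(cfg$inputs$pole_um %||% c(0, 0))
      gp <- metricVsDistance(pm$pulse_intensity,
                             agg[match(pm$cell_id, agg$cell_id),
                                 c("cx_um", "cy_um")],
                             pole, bin_width_um = cfg$gradient$bin_width_um)
      writeMetricsCsv(gp$profile, p("gradient.csv"),
                      units = c(bin_center = "um"), provenance = prov)
      if (!is.null(gp$fit))
        jsonlite::write_json(gp$fit, p("gradient_fit.json"),
                             auto_unbox = TRUE, digits = NA)
      message(sprintf("[gradient] %d bins%s", nrow(gp$profile),
                      if (!is.null(gp$fit))
                        sprintf(", decay %.1f um", gp$fit$decay_length) else ""))
      list(profile = gp, outputs = p("gradient.csv"))
    },
    "polarity" = {
      labels <- readLabelStack(cfg$inputs$labels %||% p("segmented.tif"))
      stack <- readImageStack(cfg$inputs$stack %||% p("stack.tif"))
      lab <- labels[, , 1]
      chs <- stats::setNames(lapply(channelNames(stack),
                                    function(ch) getChannel(stack, ch, 1)),
                             channelNames(stack))
      bonds <- extractBonds(lab, chs, pixel_size = pixelSize(stack))
      writeMetricsCsv(bonds, p("bonds.csv"),
                      units = c(angle_deg = "deg", length_um = "um"),
                      provenance = prov)
      prof <- bondAngleProfile(bonds, cfg$channels$membrane,
                               bin_width_deg = cfg$polarity$bin_width_deg)
      writeMetricsCsv(prof, p("bond_profile.csv"),
                      units = c(bin_mid = "deg"), provenance = prov)
      message(sprintf("[polarity] %d bonds in %d bins", nrow(bonds), nrow(prof)))
      list(bonds = bonds, profile = prof,
           outputs = c(p("bonds.csv"), p("bond_profile.csv")))
    },
    "count-ap" = {
      labels <- readLabelStack(cfg$inputs$labels %||% p("segmented.tif"))
      lab <- labels[, , 1]
      cnt <- countCellsOnApLine(lab, unlist(cfg$inputs$pole_a_px),
                                unlist(cfg$inputs$pole_b_px),
                                exclude_labels =
                                  unlist(cfg$inputs$exclude_labels %||% integer()))
      jsonlite::write_json(list(ap_line_cell_count = cnt), p("count_ap.json"),
                           auto_unbox = TRUE)
      message(sprintf("[count-ap] %d cells on the AP line", cnt))
      list(count = cnt, outputs = p("count_ap.json"))
    },
    "report" = {
      files <- list.files(cfg$out_dir, pattern = "\\.csv$", full.names = TRUE)
      rows <- lapply(files, function(f) {
        df <- readMetricsCsv(f)
        data.frame(file = basename(f), n_rows = nrow(df),
                   n_cols = ncol(df))
      })
      rep <- do.call(rbind, rows)
      writeMetricsCsv(rep, p("report.csv"), provenance = prov)
      message(sprintf("[report] %d stage file(s) aggregated", nrow(rep)))
      list(report = rep, outputs = p("report.csv"))
    })
  invisible(res)
}
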