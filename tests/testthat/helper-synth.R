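# Shared fixtures: expensive synthetic movies are generated once per test run
# and cached; everything is built in code (no stored binary fixtures).

.simCache <- new.env(parent = emptyenv())

# default-condition pulsing tissue (50 cells, 40 frames, default noise)
defaultSim <- function(seed = 7, ...) {
  key <- paste0("sim_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.simCache[[key]]))
    .simCache[[key]] <- genPulsingTissue(tissueSpec(seed = seed, ...))
  .simCache[[key]]
}

# tracks measured on the ground-truth label stack (isolates the estimators
# from segmentation accuracy, which is tested separately)
truthTracks <- function(sim) {
  cellTracks(labelStack(sim$truth), sim$stack)
}

# per-cell mean centroids from a track table, as a cells x 2 matrix
trackCentroids <- function(tracks) {
  agg <- stats::aggregate(tracks[, c("cx_um", "cy_um")],
                          by = list(cell_id = tracks$cell_id), mean)
  m <- as.matrix(agg[, c("cx_um", "cy_um")])
  rownames(m) <- agg$cell_id
  m
}

# IoU of each true interior cell against its best-overlap segmented label
interiorIoU <- function(truthFrame, segFrame, ids) {
  vapply(ids, function(i) {
    sel <- truthFrame == i
    hit <- segFrame[sel]
    hit <- hit[hit > 0]
    if (!length(hit)) return(0)
    b <- as.integer(names(which.max(table(hit))))
    inter <- sum(sel & segFrame == b)
    inter / (sum(sel) + sum(segFrame == b) - inter)
  }, numeric(1))
}
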