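test_that("distance binning reports self-consistent profiles", {
  set.seed(51)
  n <- 200
  cent <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  pole <- c(0, 50)
  d <- sqrt((cent[, 1] - pole[1])^2 + (cent[, 2] - pole[2])^2)
  # metric = distance itself: bin means equal bin mean distances
  gp <- metricVsDistance(d, cent, pole, bin_width_um = 10, fit = FALSE)
  expect_equal(gp$profile$metric_mean, gp$profile$mean_dist)
  expect_true(all(abs(gp$profile$metric_mean - gp$profile$bin_center) <= 5))
  # constant metric: flat profile, fitted amplitude ~ 0
  gpc <- metricVsDistance(rep(2.5, n), cent, pole, bin_width_um = 10)
  expect_true(all(gpc$profile$metric_mean == 2.5))
  expect_lt(gpc$fit$amplitude, 1e-6)
  # invariance to cell input order
  ord <- sample(n)
  gp2 <- metricVsDistance(d[ord], cent[ord, ], pole, bin_width_um = 10,
                          fit = FALSE)
  expect_equal(gp2$profile, gp$profile)
})

test_that("exponential fits recover known decay parameters from clean samples", {
  set.seed(52)
  cent <- cbind(runif(600, 0, 150), runif(600, 0, 150))
  pole <- c(75, 75)
  d <- sqrt((cent[, 1] - pole[1])^2 + (cent[, 2] - pole[2])^2)
  for (lam in c(15, 30, 60)) {
    y <- 0.1 + 0.3 * exp(-d / lam)
    gp <- metricVsDistance(y, cent, pole, bin_width_um = 5)
    expect_lt(abs(gp$fit$decay_length - lam) / lam, 0.05)
    expect_lt(abs(gp$fit$amplitude_at_pole - 0.4), 0.02)
  }
})

test_that("relative apical surface normalizes to the smallest cell", {
  cent <- cbind(rep(c(0.5, 1.5, 2.5), each = 3), rep(0, 9))
  gp <- relativeApicalSurface(rep(c(2, 4, 8), each = 3), cent, c(0, 0),
                              bin_width_um = 1, fit = FALSE)
  expect_equal(sort(gp$profile$metric_mean), c(1, 2, 4))
  gpe <- relativeApicalSurface(rep(5, 9), cent, c(0, 0), fit = FALSE)
  expect_true(all(gpe$profile$metric_mean == 1))
  expect_error(relativeApicalSurface(numeric(), cent[0, ], c(0, 0)), "empty")
  expect_error(relativeApicalSurface(c(1, -1, 2), cent[1:3, ], c(0, 0)), "> 0")
})

test_that("apical surfaces increase away from the pole when polar cells are smaller", {
  sim <- genPulsingTissue(tissueSpec(seed = 6, pole_size_drop = 0.5,
                                     seed_jitter = 0.1, n_cells = 100L,
                                     n_frames = 2L))
  tk <- cellTracks(labelStack(sim$truth), pixel_size = 0.25)
  pc <- perCellTruth(sim$truth)
  interior <- pc$cell_id[!pc$is_border]
  tk <- tk[tk$cell_id %in% interior, ]
  areas <- tapply(tk$area_um2, tk$cell_id, mean)
  cent <- trackCentroids(tk)
  gp <- relativeApicalSurface(as.numeric(areas), cent,
                              truthGlobal(sim$truth)$pole_um,
                              bin_width_um = 10, fit = FALSE)
  prof <- gp$profile$metric_mean
  expect_gt(prof[length(prof)], prof[1])
  expect_gt(stats::cor(gp$profile$mean_dist, prof), 0.8)
})

test_that("wide-line profiles are relative to their own mean", {
  img <- matrix(5, 60, 60)
  lp <- lineProfile(img, rbind(c(5, 30), c(55, 30)))
  expect_true(all(abs(lp$relative_intensity - 1) < 1e-12))
  # normalization identity on an arbitrary image and diagonal path
  set.seed(53)
  img2 <- matrix(runif(3600, 1, 3), 60, 60)
  lp2 <- lineProfile(img2, rbind(c(8, 10), c(50, 45)))
  expect_equal(mean(lp2$relative_intensity), 1, tolerance = 1e-6)
  # two-pole exponential field: maxima at the ends, minimum mid-path
  x <- 0:99
  field <- outer(exp(-x / 15) + exp(-(99 - x) / 15), rep(1, 40)) + 0.1
  lp3 <- lineProfile(field, rbind(c(0, 20), c(99, 20)), width_px = 9)
  n <- nrow(lp3)
  mid <- lp3$relative_intensity[floor(n / 2)]
  expect_gt(lp3$relative_intensity[1], mid)
  expect_gt(lp3$relative_intensity[n], mid)
  expect_warning(lineProfile(img, rbind(c(-10, 30), c(55, 30))), "clipped")
})

test_that("AP-line cell counts match a rasterization oracle", {
  lab <- matrix(0L, 70, 10)
  for (i in 0:6) lab[(i * 10 + 1):((i + 1) * 10), ] <- i + 1L
  expect_equal(countCellsOnApLine(lab, c(0, 5), c(69, 5)), 7)
  expect_equal(countCellsOnApLine(lab, c(0, 5), c(69, 5),
                                  exclude_labels = c(1L, 7L)), 5)
  # symmetry in the two poles
  expect_equal(countCellsOnApLine(lab, c(69, 5), c(0, 5)), 7)
  # oracle on a synthetic tessellation: labels under the rasterized segment
  sim <- defaultSim(7)
  lab2 <- truthSeries(sim$truth)$static_labels
  pa <- c(0, 100); pb <- c(199, 100)
  n <- max(abs(pb - pa)) + 1
  xs <- round(seq(pa[1], pb[1], length.out = n))
  ys <- round(seq(pa[2], pb[2], length.out = n))
  brute <- length(setdiff(unique(lab2[cbind(xs + 1, ys + 1)]), 0L))
  expect_equal(countCellsOnApLine(lab2, pa, pb), brute)
  expect_warning(cnt <- countCellsOnApLine(matrix(0L, 5, 5), c(0, 0), c(4, 4)),
                 "background")
  expect_equal(cnt, 0)
  expect_error(countCellsOnApLine(lab, c(-1, 0), c(5, 5)), "outside")
})

test_that("cell volume is surface times height", {
  expect_equal(cellVolume(10, 5), 50)
  expect_equal(cellVolume(20, 5), 2 * cellVolume(10, 5))
  set.seed(54)
  s <- runif(50, 5, 40); h <- runif(50, 2, 12)
  expect_equal(cellVolume(s, h), s * h)
  expect_error(cellVolume(-1, 5), "> 0")
})

test_that("heatmaps paint cells by metric rank with black background", {
  lab <- matrix(0L, 20, 20)
  lab[2:8, 2:8] <- 1L; lab[12:18, 12:18] <- 2L
  hm <- heatmapExport(lab, c("1" = 0, "2" = 10))
  expect_equal(dim(hm$rgb), c(20, 20, 3))
  expect_true(all(hm$rgb[1, 1, ] == 0))
  c1 <- hm$rgb[5, 5, ]; c2 <- hm$rgb[15, 15, ]
  expect_false(all(c1 == c2))
  # constant metric: one colour
  hm2 <- heatmapExport(lab, c("1" = 3, "2" = 3))
  expect_equal(hm2$rgb[5, 5, ], hm2$rgb[15, 15, ])
  # rank order check on a gradient tissue
  sim <- defaultSim(7)
  slab <- truthSeries(sim$truth)$static_labels
  pc <- perCellTruth(sim$truth)
  met <- stats::setNames(pc$amplitude, pc$cell_id)
  hm3 <- heatmapExport(slab, met)
  # the per-cell painted colour index must be monotone in the metric
  idx <- vapply(pc$cell_id, function(i) {
    px <- which(slab == i)[1]
    sum(hm3$rgb[cbind((px - 1) %% 200 + 1, (px - 1) %/% 200 + 1, 1:3)] * c(1, 256, 65536))
  }, numeric(1))
  expect_equal(length(unique(idx[order(pc$amplitude)])) > 5, TRUE)
  expect_warning(heatmapExport(lab, c("1" = 1)), "no metric")
})
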