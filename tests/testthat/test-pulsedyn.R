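test_that("pulse intensity is (max - min) / mean and behaves accordingly", {
  expect_equal(pulseIntensity(c(4, 5, 6)), 0.4)
  expect_equal(pulseIntensity(rep(7, 10)), 0)
  # exhaustive-scan oracle on 1000 random positive series
  set.seed(21)
  for (k in 1:1000) {
    x <- runif(sample(3:30, 1), 0.5, 50)
    brute <- (max(x) - min(x)) / (sum(x) / length(x))
    expect_identical(pulseIntensity(x), brute)
  }
  # scale invariance and permutation invariance
  set.seed(22)
  x <- runif(20, 1, 10)
  expect_equal(pulseIntensity(3.7 * x), pulseIntensity(x))
  expect_equal(pulseIntensity(sample(x)), pulseIntensity(x))
  expect_error(pulseIntensity(c(5)), ">= 2 frames")
  expect_error(pulseIntensity(c(1, -2)), "> 0")
})

test_that("pulse isotropy compares bounding boxes at area extrema", {
  # uniform scaling pulse: both extents shrink by 0.8 at minimum
  tr <- data.frame(area_um2 = c(100, 64, 100), bbox_ap_um = c(10, 8, 10),
                   bbox_ml_um = c(10, 8, 10))
  iso <- pulseIsotropy(tr)
  expect_equal(iso$isotropy_ap, 1.25)
  expect_equal(iso$isotropy_ml, 1.25)
  expect_equal(iso$isotropy_index, 1)
  # ML-only pulse: ML halves, AP constant
  tr2 <- data.frame(area_um2 = c(100, 50, 100), bbox_ap_um = c(10, 10, 10),
                    bbox_ml_um = c(10, 5, 10))
  expect_equal(pulseIsotropy(tr2)$isotropy_index, 2)
  expect_error(pulseIsotropy(data.frame(area_um2 = c(1, 1),
                                        bbox_ap_um = c(1, 1),
                                        bbox_ml_um = c(1, 1))), "distinct")
})

test_that("follicle pulse amplitude averages per-cell percent variation", {
  tr <- do.call(rbind, lapply(1:10, function(i)
    data.frame(cell_id = i, frame = 1:3, area_um2 = c(4, 5, 6),
               bbox_ap_um = 1, bbox_ml_um = 1)))
  expect_equal(folliclePulseAmplitude(tr, min_cells = 10, n_frames = 3), 40)
  flat <- transform(tr, area_um2 = 5)
  expect_equal(folliclePulseAmplitude(flat, min_cells = 10, n_frames = 3), 0)
  nine <- tr[tr$cell_id <= 9, ]
  expect_error(folliclePulseAmplitude(nine, min_cells = 10, n_frames = 3),
               "insufficient cells")
  # mixture property: amplitude of a pooled set is the weighted subgroup mean
  tr2 <- do.call(rbind, lapply(11:15, function(i)
    data.frame(cell_id = i, frame = 1:3, area_um2 = c(8, 10, 12),
               bbox_ap_um = 1, bbox_ml_um = 1)))
  pool <- folliclePulseAmplitude(rbind(tr, tr2), min_cells = 10, n_frames = 3)
  expect_equal(pool, (10 * 40 + 5 * 40) / 15)
})

test_that("cross-correlation finds the imposed lead-lag on constructed series", {
  set.seed(31)
  base <- as.numeric(stats::filter(rnorm(60), rep(1/5, 5), sides = 2))
  base[is.na(base)] <- 0
  mk <- function(id, myo, area) data.frame(cell_id = id, frame = seq_along(area),
                                           area_um2 = area + 50,
                                           mean_myosin = myo)
  # area = -myosin at the same frames: minimum at lag 0, correlation -1
  tr <- mk(1, base, -base)
  xc <- crossCorrelate(tr, max_lag_frames = 6)
  expect_equal(xc$lead_lag_frames, 0)
  expect_lt(min(xc$correlation), -0.95)
  # myosin advanced by 2 frames: brute-force oracle over all integer lags
  n <- 40
  myo <- base[3:(n + 2)]
  area <- -base[1:n]
  xc2 <- crossCorrelate(mk(1, myo, area), max_lag_frames = 6)
  brute <- vapply(-6:6, function(tau) {
    t1 <- max(1, 1 - tau):min(n, n - tau)
    stats::cor(myo[t1], area[t1 + tau])
  }, numeric(1))
  expect_equal(xc2$lead_lag_frames, (-6:6)[which.min(brute)])
  expect_equal(xc2$lead_lag_frames, 2)
})

test_that("lead-lag is equivariant under shifting the myosin series", {
  set.seed(32)
  base <- as.numeric(stats::filter(rnorm(80), rep(1/7, 7), sides = 2))
  base[is.na(base)] <- 0
  n <- 50
  for (k in 0:3) {
    tr <- data.frame(cell_id = 1, frame = 1:n,
                     area_um2 = 50 - base[1:n],
                     mean_myosin = base[(1 + k):(n + k)])
    expect_equal(crossCorrelate(tr, max_lag_frames = 8)$lead_lag_frames, k)
  }
})

test_that("zero-variance cells are skipped with a warning", {
  tr <- rbind(data.frame(cell_id = 1, frame = 1:20,
                         area_um2 = 50 + sin(1:20), mean_myosin = -sin(1:20)),
              data.frame(cell_id = 2, frame = 1:20, area_um2 = 50,
                         mean_myosin = 1))
  expect_warning(xc <- crossCorrelate(tr, max_lag_frames = 4), "skipped")
  expect_equal(xc$n_cells, 1)
})

test_that("the normality test matches an independent reference implementation", {
  # frozen oracle values from scipy.stats.normaltest on the same inputs
  r1 <- dagostinoPearson(sin(1:20) * 2 + (0:19) * 0.1)
  expect_equal(r1$statistic, 1.744949, tolerance = 1e-5)
  expect_equal(r1$p_value, 0.417916, tolerance = 1e-4)
  r2 <- dagostinoPearson(exp(seq(-2, 2, length.out = 30))^2)
  expect_equal(r2$statistic, 27.058097, tolerance = 1e-5)
  r3 <- dagostinoPearson(seq(0, 1, length.out = 12))
  expect_equal(r3$statistic, 1.310727, tolerance = 1e-5)
  expect_equal(r3$p_value, 0.519253, tolerance = 1e-4)
  expect_error(dagostinoPearson(1:5), "n >= 8")
})

test_that("group comparison routes through normality gating", {
  set.seed(41)
  a <- rnorm(20, 40, 5); b <- rnorm(20, 15, 5)
  r <- compareGroups(a, b)
  expect_equal(r$test_used, "t-test")
  expect_lt(r$p_value, 0.001)
  # heavy-tailed samples fail the gate and fall to the rank test
  set.seed(42)
  h1 <- exp(rnorm(30, 0, 1.5)); h2 <- exp(rnorm(30, 0.1, 1.5))
  rh <- compareGroups(h1, h2)
  expect_equal(rh$test_used, "mann-whitney")
  # identical groups: no difference detected
  ri <- compareGroups(a, a)
  expect_gt(ri$p_value, 0.9)
  # small samples cannot be gated: rank test
  expect_equal(compareGroups(rnorm(5), rnorm(5))$test_used, "mann-whitney")
  expect_error(compareGroups(1:2, 1:10), "n >= 3")
})

test_that("per-cell amplitude estimates track the imposed gradient", {
  sim <- defaultSim(7)
  tk <- truthTracks(sim)
  pm <- pulseMetrics(fullLengthTracks(tk, 40))
  pc <- perCellTruth(sim$truth)
  m <- merge(pm, pc, by = "cell_id")
  expect_gte(stats::cor(m$pulse_intensity, m$amplitude), 0.9)
})
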