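test_that("moment-based axes reproduce analytic ellipses", {
  ell <- genEllipseMask(40, 20, 0, 0.5)
  ax <- fitFollicleAxes(ell$mask, ell$pixelSize)
  expect_lt(abs(ax$long_axis_um - 80) / 80, 0.02)
  expect_lt(abs(ax$short_axis_um - 40) / 40, 0.02)
  circ <- genEllipseMask(20, 20, 0, 0.5)
  axc <- fitFollicleAxes(circ$mask, 0.5)
  expect_lt(abs(axc$long_axis_um / axc$short_axis_um - 1), 0.01)
  rot <- genEllipseMask(40, 20, 30, 0.5)
  axr <- fitFollicleAxes(rot$mask, 0.5)
  expect_lt(abs(axr$long_axis_um - 80) / 80, 0.02)
  expect_lt(abs(axr$orientation_deg - 30), 2)
  expect_error(fitFollicleAxes(matrix(FALSE, 10, 10)), "too small")
  two <- matrix(FALSE, 40, 40); two[1:10, 1:20] <- TRUE; two[30:39, 25:39] <- TRUE
  expect_error(fitFollicleAxes(two), "connected")
})

test_that("aspect ratio is long over short with validation", {
  expect_equal(aspectRatio(50, 20), 2.5)
  expect_equal(aspectRatio(7, 7), 1)
  coh <- genFollicleCohort(cohortSpec(slope = 1.6, intercept = 0, noise_sd = 0))
  expect_equal(aspectRatio(coh), rep(1.6, nrow(coh)))
  expect_error(aspectRatio(3, 5), "long_axis >= short_axis")
})

test_that("the elongation coefficient is the long-vs-short OLS slope", {
  sph <- genFollicleCohort(cohortSpec(slope = 1, intercept = 0, noise_sd = 0,
                                      n_follicles = 30L))
  fit <- suppressWarnings(elongationCoefficient(sph))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  coh <- genFollicleCohort(cohortSpec(slope = 1.6, intercept = 0, noise_sd = 0))
  expect_equal(suppressWarnings(elongationCoefficient(coh))$slope, 1.6)
  noisy <- genFollicleCohort(cohortSpec(n_follicles = 200L, slope = 1.6,
                                        noise_sd = 2, seed = 5L))
  nf <- elongationCoefficient(noisy)
  expect_true(nf$slope_ci[1] <= 1.6 && 1.6 <= nf$slope_ci[2])
  expect_error(elongationCoefficient(sph[1:2, ]), "insufficient")
})

test_that("stage filtering keeps previtellogenic follicles only", {
  coh <- genFollicleCohort(cohortSpec(slope = 1.6, noise_sd = 0))
  coh$stage <- rep(c(3, 8), length.out = nrow(coh))
  fit <- suppressWarnings(elongationCoefficient(coh))
  expect_equal(fit$n, sum(coh$stage < 8))
})

test_that("ANCOVA separates genotype slopes and controls identical cohorts", {
  a <- genFollicleCohort(cohortSpec(n_follicles = 100L, slope = 1.6,
                                    noise_sd = 2, genotype_label = "A", seed = 7L))
  b <- genFollicleCohort(cohortSpec(n_follicles = 100L, slope = 1.0,
                                    noise_sd = 2, genotype_label = "B", seed = 8L))
  r <- compareElongation(rbind(a, b))
  expect_lt(r$contrasts$p.value[1], 0.001)
  expect_lt(abs(r$slopes$short_axis_um.trend[r$slopes$genotype == "A"] - 1.6), 0.1)
  # same-slope cohorts: no slope difference detected
  b2 <- genFollicleCohort(cohortSpec(n_follicles = 100L, slope = 1.6,
                                     noise_sd = 2, genotype_label = "B", seed = 9L))
  r2 <- compareElongation(rbind(a, b2))
  expect_gt(r2$contrasts$p.value[1], 0.05)
  # three genotypes: exactly 3 pairwise contrasts
  c3 <- genFollicleCohort(cohortSpec(n_follicles = 50L, slope = 1.3,
                                     noise_sd = 2, genotype_label = "C", seed = 10L))
  r3 <- compareElongation(rbind(a, b2, c3))
  expect_equal(nrow(r3$contrasts), 3)
  expect_error(compareElongation(a), ">= 2 genotypes")
})

test_that("eAR equals the axis ratio on discrete ellipses at both poles", {
  ell <- genEllipseMask(40, 20, 0, 0.5)
  ea <- poleEARs(ell$mask, ell$pixelSize)
  expect_lt(max(abs(ea$eAR - 2)) / 2, 0.02)
  circ <- genEllipseMask(20, 20, 0, 0.5)
  expect_lt(max(abs(poleEARs(circ$mask, 0.5)$eAR - 1)), 0.02)
  # rotation invariance
  rot <- genEllipseMask(40, 20, 30, 0.5)
  expect_lt(max(abs(poleEARs(rot$mask, 0.5)$eAR - 2)) / 2, 0.02)
  # scale invariance (coarser calibration, same shape)
  big <- genEllipseMask(40, 20, 0, 1)
  expect_lt(max(abs(poleEARs(big$mask, 1)$eAR - 2)) / 2, 0.02)
})

test_that("an elongated anterior half raises the anterior eAR", {
  # composite half-ellipses sharing the equator: anterior semi-axis 48 um,
  # posterior 40 um, common half-width 20 um, 0.5 um/px
  px <- 0.5
  half <- 110
  x <- ((0:(2 * half)) - half) * px
  y <- ((0:99) - 49.5) * px
  X <- matrix(rep(x, times = 100), ncol = 100)
  Y <- matrix(rep(y, each = 2 * half + 1), ncol = 100)
  a_loc <- ifelse(X < 0, 48, 40)
  m <- (X / a_loc)^2 + (Y / 20)^2 <= 1
  ant <- extrapolatedAR(m, "anterior", px, orientation_deg = 0)
  post <- extrapolatedAR(m, "posterior", px, orientation_deg = 0)
  expect_gt(ant$eAR, post$eAR)
  # closed-form chord widths of the composite at the two 25% stations
  w_ant <- 40 * sqrt(1 - (26 / 48)^2) * 2 / sqrt(3)
  w_post <- 40 * sqrt(1 - (18 / 40)^2) * 2 / sqrt(3)
  expect_lt(abs(ant$eAR - 88 / w_ant), 0.05)
  expect_lt(abs(post$eAR - 88 / w_post), 0.05)
})

test_that("pole comparison detects imposed pole differences and crossovers", {
  set.seed(13)
  mk <- function(ids, genotype, delta, sd = 0.1)
    do.call(rbind, lapply(ids, function(i) {
      post <- 2 + rnorm(1, 0, sd)
      data.frame(follicle_id = i, genotype = genotype,
                 pole = c("anterior", "posterior"),
                 eAR = c(post + delta + rnorm(1, 0, sd), post))
    }))
  ear <- rbind(mk(1:15, "WT", 0.3), mk(16:30, "mut", 0))
  r <- comparePoles(ear)
  expect_lt(r$pole_p, 0.001)
  expect_lt(r$pairwise$p_adjusted[r$pairwise$genotype == "WT"], 0.001)
  expect_gt(r$pairwise$p_adjusted[r$pairwise$genotype == "mut"], 0.05)
  # equal poles: no pole effect
  eq <- rbind(mk(1:15, "WT", 0, sd = 0.05), mk(16:30, "mut", 0, sd = 0.05))
  expect_gt(comparePoles(eq)$pole_p, 0.3)
  # opposite ordering in the two genotypes: significant interaction
  cross <- rbind(mk(1:15, "WT", 0.3), mk(16:30, "mut", -0.3))
  expect_lt(comparePoles(cross)$interaction_p, 0.001)
  # missing pole excluded with a warning
  miss <- rbind(mk(1:15, "WT", 0.3), mk(16:30, "mut", 0))[-1, ]
  expect_warning(comparePoles(miss), "missing")
})
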