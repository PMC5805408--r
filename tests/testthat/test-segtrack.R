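test_that("maximum projection equals the elementwise maximum", {
  one <- matrix(runif(25), 5, 5)
  expect_identical(maxProject(array(one, c(5, 5, 1))), one)
  expect_identical(maxProject(array(c(one, one), c(5, 5, 2))), one)
  set.seed(1)
  z <- array(runif(75), c(5, 5, 3))
  brute <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) brute[i, j] <- max(z[i, j, ])
  expect_equal(maxProject(z), brute)
  expect_error(maxProject(array(0, c(5, 5, 0))), "plane")
})

test_that("watershed segmentation recovers noise-free cells at high overlap", {
  # noise-free static tissue (no pulses): pure segmentation geometry
  sim <- genPulsingTissue(tissueSpec(
    seed = 5, n_cells = 36L, field_size = 256L, n_frames = 2L,
    amplitude_at_pole = 0, baseline_amplitude = 0,
    noise_model = list(gaussian_sd = 0, photon_scale = Inf)))
  img <- getChannel(sim$stack, "membrane", 1)
  lab <- segmentFrame(img, pixel_size = 0.25, clear_border = FALSE,
                      max_area = 5000)
  pc <- perCellTruth(sim$truth)
  expect_equal(max(lab), nrow(pc))
  iou <- interiorIoU(labelStack(sim$truth)[, , 1], lab, pc$cell_id)
  expect_true(all(iou >= 0.9))
})

test_that("segmentation is deterministic and conserves pixels", {
  sim <- defaultSim(7)
  img <- getChannel(sim$stack, "membrane", 1)
  a <- segmentFrame(img, pixel_size = 0.25)
  b <- segmentFrame(img, pixel_size = 0.25)
  expect_identical(a, b)
  areas <- tabulate(a[a > 0])
  expect_equal(sum(areas) + sum(a == 0), length(img))
})

test_that("a blank image yields a segmentation error", {
  expect_error(segmentFrame(matrix(0, 50, 50), pixel_size = 0.25),
               "no seeds")
})

test_that("static labels are tracked unchanged and deletions end tracks", {
  lab <- matrix(0L, 40, 40)
  lab[5:15, 5:15] <- 1L; lab[20:35, 10:25] <- 2L
  stack <- array(lab, c(40, 40, 6))
  st <- trackCells(stack)
  tr <- cellTracks(st, pixel_size = 1)
  expect_equal(length(unique(tr$cell_id)), 2)
  expect_true(all(table(tr$cell_id) == 6))
  expect_equal(stats::sd(tr$area_um2[tr$cell_id == tr$cell_id[1]]), 0)
  # delete cell 2 from frame 4 on: its track length is 3
  stack2 <- stack
  for (t in 4:6) { f <- stack2[, , t]; f[f == 2L] <- 0L; stack2[, , t] <- f }
  tr2 <- cellTracks(trackCells(stack2), pixel_size = 1)
  lens <- table(tr2$cell_id)
  expect_setequal(as.integer(lens), c(6L, 3L))
})

test_that("track geometry is invariant to a permutation of input labels", {
  sim <- genPulsingTissue(tissueSpec(seed = 9, n_cells = 12L, field_size = 80L,
                                     n_frames = 6L))
  labs <- labelStack(sim$truth)
  perm <- sample(12L)
  labs2 <- labs
  labs2[labs > 0] <- perm[labs[labs > 0]]
  t1 <- cellTracks(trackCells(labs), pixel_size = 0.25)
  t2 <- cellTracks(trackCells(labs2), pixel_size = 0.25)
  k1 <- t1[order(t1$frame, t1$area_um2, t1$cx_um), c("frame", "area_um2", "cx_um", "cy_um")]
  k2 <- t2[order(t2$frame, t2$area_um2, t2$cx_um), c("frame", "area_um2", "cx_um", "cy_um")]
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
})

test_that("tracking keeps identities on the full default movie", {
  sim <- defaultSim(7)
  truth <- labelStack(sim$truth)
  st <- trackCells(truth)
  # stable ids must be a consistent relabeling of the true ids
  for (t in c(1, 20, 40)) {
    tab <- table(truth[, , t], st[, , t])
    expect_true(all(rowSums(tab > 0) == 1))
  }
})

test_that("cell measurements match a pixel-count oracle", {
  lab <- matrix(0L, 30, 30)
  lab[3:12, 5:14] <- 1L              # 10 x 10 square
  lab[15:26, 20:24] <- 2L            # 12 x 5 rectangle
  m1 <- measureCell(lab, cell_id = 1, pixel_size = 0.5)
  expect_equal(m1$area_um2, 25)
  expect_equal(m1$bbox_ap_um, 5)
  expect_equal(m1$bbox_ml_um, 5)
  m2 <- measureCell(lab, cell_id = 2, pixel_size = 0.5)
  expect_equal(m2$bbox_ap_um, 6)
  expect_equal(m2$bbox_ml_um, 2.5)
  # random blob oracle
  set.seed(4)
  blob <- matrix(0L, 30, 30)
  blob[sample(900, 200)] <- 3L
  mb <- measureCell(blob, cell_id = 3, pixel_size = 0.7)
  expect_equal(mb$area_um2, sum(blob == 3L) * 0.49)
  expect_error(measureCell(lab, cell_id = 9), "not present")
})

test_that("bonds are symmetric, unique and match the adjacency graph", {
  sim <- defaultSim(7)
  lab <- truthSeries(sim$truth)$static_labels
  bonds <- extractBonds(lab, pixel_size = 0.25, min_bond_px = 1)
  expect_true(all(bonds$cell_a < bonds$cell_b))
  expect_equal(nrow(bonds), nrow(unique(bonds[, c("cell_a", "cell_b")])))
  # adjacency count oracle: unordered label pairs sharing an edge
  nx <- nrow(lab)
  pairs <- rbind(cbind(as.vector(lab[-nx, ]), as.vector(lab[-1, ])),
                 cbind(as.vector(lab[, -ncol(lab)]), as.vector(lab[, -1])))
  pairs <- pairs[pairs[, 1] != pairs[, 2] & pairs[, 1] > 0 & pairs[, 2] > 0, ]
  adj <- unique(data.frame(a = pmin(pairs[, 1], pairs[, 2]),
                           b = pmax(pairs[, 1], pairs[, 2])))
  expect_equal(nrow(bonds), nrow(adj))
})

test_that("bond angles follow the axial AP convention", {
  lab <- matrix(0L, 20, 20)
  lab[1:10, 5:15] <- 1L; lab[11:20, 5:15] <- 2L   # shared edge runs along y
  b <- extractBonds(lab, list(ch = matrix(2, 20, 20)))
  expect_equal(nrow(b), 1)
  expect_equal(b$angle_deg, 90)
  expect_equal(b$mean_ch, 2)
  lab2 <- matrix(0L, 20, 20)
  lab2[5:15, 1:10] <- 1L; lab2[5:15, 11:20] <- 2L # shared edge runs along x
  expect_equal(extractBonds(lab2)$angle_deg, 0)
  expect_equal(nrow(extractBonds(matrix(1L, 10, 10))), 0)
})
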