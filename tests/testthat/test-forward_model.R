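coil0 <- coil_field()

test_that("pose transform places, translates and rotates rigidly", {
  rp <- random_phantom(12, n_tissues = 2, seed = 9)
  ph <- rp$phantom
  # identity placement: the alignment plane maps exactly to the coil centre
  pos0 <- pose_transform(ph, pose(0, 0), coil0, table_offset = 0)
  # the alignment plane maps to the coil midplane: some voxel-centre layer
  # lies within half a voxel of z = centre
  expect_lte(min(abs(pos0[, 3] - coil0$centre)), ph$voxel_size[3] / 2 + 1e-12)
  # translation: Pose(dz, 0) shifts every transformed z by exactly dz
  pos_dz <- pose_transform(ph, pose(0.037, 0), coil0, table_offset = 0)
  expect_equal(pos_dz[, 3], pos0[, 3] + 0.037, tolerance = 1e-12)
  expect_equal(pos_dz[, 1:2], pos0[, 1:2], tolerance = 1e-12)
  # rotation about the long axis preserves distance to the body's own axis
  # and all pairwise distances
  off <- 0.05
  pos_t <- pose_transform(ph, pose(0, 3.7), coil0, table_offset = off)
  pos_r <- pose_transform(ph, pose(0, 0), coil0, table_offset = off)
  d_axis0 <- sqrt(pos_r[, 1]^2 + (pos_r[, 2] + off)^2)
  d_axis1 <- sqrt(pos_t[, 1]^2 + (pos_t[, 2] + off)^2)
  expect_equal(d_axis1, d_axis0, tolerance = 1e-12)
  set.seed(1)
  i <- sample(nrow(pos_r), 30); j <- sample(nrow(pos_r), 30)
  expect_equal(sqrt(rowSums((pos_t[i, ] - pos_t[j, ])^2)),
               sqrt(rowSums((pos_r[i, ] - pos_r[j, ])^2)), tolerance = 1e-10)
  # pitch mode is also rigid
  pos_p <- pose_transform(ph, pose(0, 2.5), coil0, table_offset = off,
                          tilt_axis = "pitch")
  expect_equal(sqrt(rowSums((pos_p[i, ] - pos_p[j, ])^2)),
               sqrt(rowSums((pos_r[i, ] - pos_r[j, ])^2)), tolerance = 1e-10)
})

test_that("the quasi-static SAR field follows its closed form", {
  # lossless body: sigma = 0 everywhere -> SAR identically 0
  lab <- array(1L, c(4, 4, 4))
  props0 <- tissue_table(c("Background", "T"), 0:1, c(0, 0), c(1, 50),
                         c(0, 1000))
  ph <- voxel_phantom(lab, 0.002, alignment_z = 0.004)
  expect_true(all(sar_field(ph, props0, coil0, pose(0, 0)) == 0))

  # single voxel at a known off-axis distance: independent hand evaluation
  # E = (2 pi f * B1 / 2) * d * w, SAR = sigma E^2 / (2 rho)
  lab1 <- array(0L, c(1, 1, 1)); lab1[1, 1, 1] <- 1L
  props <- tissue_table(c("Background", "T"), 0:1, c(0, 0.5), c(1, 50),
                        c(0, 1000))
  ph1 <- voxel_phantom(lab1, 0.002, alignment_z = 0.001)
  coil <- coil_field(frequency = 64e6, b1 = 1e-6, length = 1, taper = 0)
  # place the voxel at d = 0.1 m from the coil axis via the table offset
  # (voxel centre sits on the body axis, so d = table_offset)
  sar <- sar_field(ph1, props, coil, pose(0, 0), table_offset = 0.1)
  E <- 2 * pi * 64e6 * 1e-6 / 2 * 0.1 * 1
  expect_equal(sar[1, 1, 1], 0.5 * E^2 / (2 * 1000), tolerance = 1e-12)
  # on the coil axis the field vanishes
  sar0 <- sar_field(ph1, props, coil, pose(0, 0), table_offset = 0)
  expect_equal(sar0[1, 1, 1], 0)
})

test_that("axial profile is flat inside, raised-cosine in the taper, 0 beyond", {
  coil <- coil_field(length = 0.2, taper = 0.1, centre = 0.05)
  expect_equal(axial_profile(c(0.05, 0.14, -0.05), coil), c(1, 1, 1))
  expect_equal(axial_profile(0.05 + 0.1 + 0.1, coil), 0)
  z <- 0.05 + 0.1 + 0.05  # mid-taper
  expect_equal(axial_profile(z, coil), cos(pi * 0.05 / 0.2)^2)
  expect_equal(axial_profile(0.05 - 0.25, coil), 0)
})

test_that("whole-body and head averages are mass-weighted means", {
  rp <- random_phantom(14, n_tissues = 3, seed = 21)
  ph <- rp$phantom
  ph$head_mask <- ph$labels != 0L & array(rep(c(TRUE, FALSE), length.out =
    length(ph$labels)), dim(ph$labels))
  set.seed(2)
  sar <- array(stats::runif(length(ph$labels)), dim(ph$labels))
  sar[ph$labels == 0L] <- 0
  # explicit summation oracle
  vol <- prod(ph$voxel_size)
  m <- array(0, dim(ph$labels))
  tis <- ph$labels != 0L
  m[tis] <- vol * rp$rho[ph$labels[tis]]
  expect_equal(wb_sar(sar, ph, rp$props), sum(sar * m) / sum(m),
               tolerance = 1e-12)
  expect_equal(hd_sar(sar, ph, rp$props),
               sum((sar * m)[ph$head_mask]) / sum(m[ph$head_mask]),
               tolerance = 1e-12)
  # uniform SAR over all tissue: wb = hd = s
  sar_u <- array(0, dim(ph$labels)); sar_u[tis] <- 3.25
  expect_equal(wb_sar(sar_u, ph, rp$props), 3.25, tolerance = 1e-12)
  expect_equal(hd_sar(sar_u, ph, rp$props), 3.25, tolerance = 1e-12)
  ph$head_mask[] <- FALSE
  expect_error(hd_sar(sar, ph, rp$props), "head mask")
})

test_that("peak 10 g SAR matches uniformity and scaling properties", {
  lab <- array(1L, c(20, 20, 20))
  props <- tissue_table(c("Background", "T"), 0:1, c(0, 0.5), c(1, 50),
                        c(0, 1200))
  ph <- voxel_phantom(lab, 0.004, alignment_z = 0.04)
  sar <- array(0.7, dim(lab))
  pk <- psar10g(sar, ph, props)
  expect_equal(pk$value, 0.7, tolerance = 1e-12)
  # homogeneity: scaling the field scales the peak, location unchanged
  set.seed(4)
  sar2 <- array(stats::runif(8000), dim(lab))
  pk1 <- psar10g(sar2, ph, props)
  pk3 <- psar10g(sar2 * 3, ph, props)
  expect_equal(pk3$value, 3 * pk1$value, tolerance = 1e-12)
  expect_equal(pk3$location, pk1$location)
})

test_that("peak 10 g SAR equals the exhaustive cube oracle", {
  for (seed in 1:4) {
    set.seed(seed + 100)
    n <- sample(16:20, 1)
    rp <- random_phantom(n, n_tissues = 3, seed = seed + 200)
    sar <- array(stats::runif(n^3), dim(rp$phantom$labels))
    sar[rp$phantom$labels == 0L] <- 0
    got <- psar10g(sar, rp$phantom, rp$props)
    want <- oracle_psar(sar, rp$phantom$labels, rp$rho,
                        rp$phantom$voxel_size[1])
    expect_equal(got$value, want$value, tolerance = 1e-12)
    expect_equal(got$location, want$location)
  }
})

test_that("normalization rescales to 1 W absorbed and preserves ratios", {
  rp <- random_phantom(18, n_tissues = 2, seed = 31)
  ph <- rp$phantom
  set.seed(3)
  sar <- array(stats::runif(length(ph$labels)), dim(ph$labels))
  sar[ph$labels == 0L] <- 0
  expect_identical(normalize_sar(sar, ph, rp$props, "raw_B1"), sar)
  sarn <- normalize_sar(sar, ph, rp$props, "absorbed_power_1W")
  vol <- prod(ph$voxel_size)
  m <- array(0, dim(ph$labels))
  tis <- ph$labels != 0L
  m[tis] <- vol * rp$rho[ph$labels[tis]]
  expect_equal(sum(sarn * m), 1, tolerance = 1e-12)
  # peak-to-whole-body ratio is invariant under normalization (a 5 g
  # averaging mass keeps the cube inside this small test grid)
  r_raw <- psar10g(sar, ph, rp$props, 0.005)$value / wb_sar(sar, ph, rp$props)
  r_nrm <- psar10g(sarn, ph, rp$props, 0.005)$value / wb_sar(sarn, ph, rp$props)
  expect_equal(r_nrm, r_raw, tolerance = 1e-10)
})

test_that("full metric extraction is consistent and ordered", {
  sp <- small_pair()
  res <- sar_metrics(sp$reference$phantom, sp$reference$props, coil0,
                     pose(0, 0))
  expect_gt(res$wbSAR, 0)
  expect_gt(res$hdSAR, 0)
  expect_gte(res$pSAR10g, res$wbSAR)  # peak average >= global average
  expect_equal(length(res$psar10g_location), 3L)
  expect_true(sp$reference$phantom$labels[res$psar10g_location[1],
                                          res$psar10g_location[2],
                                          res$psar10g_location[3]] != 0L)
})

test_that("wbSAR tail decay and tilt symmetry behave physically", {
  lab <- array(0L, c(10, 10, 30)); lab[4:7, 4:7, 5:26] <- 1L
  props <- tissue_table(c("Background", "T"), 0:1, c(0, 0.6), c(1, 60),
                        c(0, 1050))
  ph <- voxel_phantom(lab, 0.004, alignment_z = 0.06)
  coil <- coil_field(length = 0.02, taper = 0.06)
  wb <- function(dz) wb_sar(sar_field(ph, props, coil, pose(dz, 0)), ph, props)
  # once only the taper overlaps the body, pushing further out monotonically
  # reduces the absorbed power
  expect_gt(wb(0.05), wb(0.08))
  expect_gt(wb(0.08), wb(0.11))
  # mirror-symmetric body about the rotation plane: even in tilt
  w_p <- wb_sar(sar_field(ph, props, coil, pose(0, 4)), ph, props)
  w_m <- wb_sar(sar_field(ph, props, coil, pose(0, -4)), ph, props)
  expect_equal(w_p, w_m, tolerance = 1e-10)
})
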