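test_that("dice coefficient identities hold", {
  a <- array(FALSE, c(5, 5, 5)); a[1:3, 1:3, 1:3] <- TRUE
  b <- array(FALSE, c(5, 5, 5)); b[4:5, 4:5, 4:5] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0)
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))), 1)
  # |A| = |B| = 100 with overlap 50 gives 0.5
  x <- array(FALSE, c(10, 10, 2)); x[1:100] <- TRUE
  y <- array(FALSE, c(10, 10, 2)); y[51:150] <- TRUE
  expect_equal(dice(x, y), 0.5)
  expect_error(dice(a, array(FALSE, c(4, 4, 4))), "grid")
})

test_that("tissue segmentation keeps the seed component and drops specks", {
  fl <- array(0, c(30, 30, 30))
  X <- array(seq_len(30) - 15.5, c(30, 30, 30))
  Y <- array(rep(seq_len(30) - 15.5, each = 30), c(30, 30, 30))
  Z <- array(rep(seq_len(30) - 15.5, each = 900), c(30, 30, 30))
  ball <- sqrt(X^2 + Y^2 + Z^2) <= 9
  fl[ball] <- 100
  fl[2, 2, 2] <- 100  # disconnected speck
  vol <- volume3d(fl, 20, "fluorescence")
  sc <- volume3d(array(0, dim(fl)), 20, "scattering")
  lab <- segment_tissue(vol, sc, seeds = c(15, 15, 15))
  tmask <- lv_mask(lab, "T")
  expect_false(tmask[2, 2, 2])
  # interior untouched; the erode/dilate sequence nets at most a thin
  # outward shell (it ends on a dilation)
  expect_true(all(tmask[ball]))
  expect_true(all(fibromap:::dilate3(ball, 2)[tmask]))
  expect_gt(dice(tmask, ball), 0.75)
})

test_that("the morphological smoothing sequence moves a half-space boundary at most one voxel", {
  m <- array(FALSE, c(24, 24, 24)); m[, 1:12, ] <- TRUE
  sm <- fibromap:::dilate3(fibromap:::erode3(fibromap:::dilate3(
    fibromap:::erode3(m, 1L), 2L), 2L), 2L)
  # interior columns (away from array borders): boundary at y = 12 +/- 1
  core <- sm[6:18, , 6:18]
  ref1 <- array(FALSE, dim(core)); ref1[, 1:11, ] <- TRUE
  ref2 <- array(FALSE, dim(core)); ref2[, 1:13, ] <- TRUE
  expect_true(all(core[ref1]))      # at least up to y = 11
  expect_true(all(!core[, 14:24, ]))  # no farther than y = 13
})

test_that("the AVS slab obeys its Boolean identities", {
  tags <- array(0L, c(31, 31, 40)); tags[10:20, 10:20, ] <- 1L
  lab <- label_volume(tags, 20)
  out <- apply_avs(lab, c(15, 15, 30), c(25, 15, 30), c(15, 25, 30),
                   seeds = c(15, 15, 5))
  tis <- lv_mask(out, "T"); avs <- lv_mask(out, "AVS")
  v <- tis & !avs
  expect_true(all(tis == (v | avs)))          # T = V OR AVS
  expect_true(all(!(v & avs)))                # exclusive tags
  expect_equal(max(which(apply(v, 3, any))), 24)  # severed above the slab
  # slab not intersecting tissue: AVS empty, V = T
  out2 <- apply_avs(lab, c(2, 2, 50), c(4, 2, 50), c(2, 4, 50))
  expect_equal(sum(lv_mask(out2, "AVS")), 0)
  expect_equal(sum(lv_mask(out2, "T")), sum(tags == 1L))
  expect_error(apply_avs(lab, c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)), "collinear")
})

test_that("CF and NCF segmentation follow threshold and set-difference rules", {
  tags <- array(1L, c(10, 10, 10))
  lab <- label_volume(tags, 20)
  sc <- volume3d(array(5, c(10, 10, 10)), 20, "scattering")
  expect_equal(sum(segment_cf(sc, lab, threshold = 10)), 0)
  # EXC == CF leaves no NCF
  sc2 <- volume3d(array(c(20, 0), c(10, 10, 10)), 20, "scattering")
  cf <- segment_cf(sc2, lab, threshold = 10)
  ncf <- segment_ncf(sc2, 10, cf, lab)
  expect_equal(sum(ncf), 0)
})

test_that("threshold calibration hits a constructed quantile exactly", {
  # 2.5% of tissue voxels at >= 7, rest below
  vals <- c(rep(7, 25), rep(2, 975))
  sc <- volume3d(array(vals, c(10, 10, 10)), 20, "scattering")
  tm <- array(TRUE, c(10, 10, 10))
  cal <- calibrate_ncf_threshold(sc, tm, target_fraction = 0.025)
  expect_equal(cal$threshold, 7)
  expect_equal(cal$fractions, 0.025)
  expect_error(calibrate_ncf_threshold(
    volume3d(array(1, c(5, 5, 5)), 20, "scattering"),
    array(TRUE, c(5, 5, 5))), "constant")
})

test_that("morphometry converts voxel counts to volumes and percentages", {
  tags <- array(0L, c(20, 20, 20))
  tags[1:10, , 1:5] <- 1L     # MYO: 1000 voxels
  tags[1:10, 1:10, 6] <- 4L   # L_ch: 100
  lab <- label_volume(tags, 20)
  mo <- morphometry(lab)
  expect_equal(mo$volumes_mm3[["MYO"]], 1000 * 8e-6)
  expect_equal(mo$dilation_ratio, (100 * 8e-6) / mo$volumes_mm3[["T"]])
  # CF = T gives 100 percent
  tags2 <- array(0L, c(5, 5, 5)); tags2[1:2, , ] <- 2L
  expect_equal(morphometry(label_volume(tags2, 20))$pct_cf, 100)
  expect_error(morphometry(label_volume(array(0L, c(3, 3, 3)), 20)), "empty")
})

test_that("wall thickness casts the stated rays and matches annulus geometry", {
  n <- 61; nz <- 30
  X <- array(seq_len(n) - 31, c(n, n, nz))
  Y <- array(rep(seq_len(n) - 31, each = n), c(n, n, nz))
  R <- sqrt(X^2 + Y^2)
  tags <- array(0L, c(n, n, nz))
  tags[R >= 10 & R <= 20] <- 1L
  tags[R < 10] <- 4L
  lab <- label_volume(tags, 20)
  for (lv in c("basal", "mid")) {
    wt <- wall_thickness(lab, lv)
    expect_equal(nrow(wt), 6)
    expect_equal(diff(wt$angle_deg), rep(60, 5))
    expect_true(all(abs(wt$thickness_um - 200) <= 20))  # within one voxel
  }
  wa <- wall_thickness(lab, "apical")
  expect_equal(nrow(wa), 4)
  expect_equal(diff(wa$angle_deg), rep(90, 3))
})

test_that("sector maps conserve intensity and localize point sources", {
  p <- ring_seg()
  sm <- sector_map(p$scatt, p$fluo)
  expect_equal(dim(sm$sectors), c(16, 16))
  # conservation: sector sums equal the projected intensity in the annulus
  expect_equal(sum(sm$sectors_raw), sum(sm$projection[sm$annulus]),
               tolerance = 1e-9)
  # uniform annulus: nonzero sectors within a moderate spread (discretization)
  smu <- sector_map(p$truth$tissue + 0, p$fluo)
  nz <- smu$sectors_raw[smu$sectors_raw > 0]
  # single bright voxel: exactly one nonzero sector
  one <- array(0, dim(p$fluo$data))
  one[30, 46, 20] <- 50
  smo <- sector_map(one, p$fluo)
  expect_equal(sum(smo$sectors_raw > 0), 1)
})

test_that("group averaging uses arithmetic-mean radii", {
  m1 <- structure(list(sectors = matrix(1, 16, 16), sectors_raw = matrix(2, 16, 16),
                       r = 10, R = 30), class = "sector_map")
  m2 <- structure(list(sectors = matrix(3, 16, 16), sectors_raw = matrix(4, 16, 16),
                       r = 20, R = 40), class = "sector_map")
  avg <- average_sector_maps(list(m1, m2))
  expect_equal(avg$r, 15)
  expect_equal(avg$R, 35)
  expect_true(all(avg$sectors == 2))
})

test_that("EXC calibration on the control phantom hits the 2.5 percent target", {
  p <- ring_ctrl()
  lab <- segment_tissue(p$fluo, p$scatt)
  cal <- calibrate_ncf_threshold(p$scatt, lv_mask(lab, "T"),
                                 target_fraction = 0.025)
  expect_lt(abs(cal$fractions * 100 - 2.5), 0.2)
})
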