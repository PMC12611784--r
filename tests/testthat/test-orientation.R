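test_that("structure tensors are consistent with the gradient field", {
  # constant volume: all tensors zero
  st0 <- structure_tensor_field(array(5, c(8, 8, 8)), sigma = 0)
  expect_true(all(st0$sxx == 0) && all(st0$syz == 0))

  # variation only along y: only the yy component is nonzero (unsmoothed)
  a <- array(rep(rep(seq_len(10), each = 10), 10), c(10, 10, 10))
  st <- structure_tensor_field(a, sigma = 0)
  expect_true(all(st$sxx == 0) && all(st$szz == 0) && all(st$sxy == 0))
  expect_true(all(st$syy[, 2:9, ] > 0))

  # trace identity: trace(S) = smoothed |grad I|^2
  set.seed(3)
  b <- array(rnorm(12^3), c(12, 12, 12))
  stb <- structure_tensor_field(b, sigma = 1)
  g <- fibromap:::grad3(b)
  sm <- fibromap:::gauss_smooth3(g$gx^2 + g$gy^2 + g$gz^2, 1)
  expect_equal(stb$sxx + stb$syy + stb$szz, sm, tolerance = 1e-12)

  expect_error(structure_tensor_field(b, sigma = -1), "sigma")
})

test_that("fractional anisotropy matches its analytic values", {
  expect_equal(fractional_anisotropy(1, 1, 1), 0)
  expect_equal(fractional_anisotropy(1, 0, 0), 1)
  expect_equal(fractional_anisotropy(2, 1, 1), 1 / sqrt(6), tolerance = 1e-12)
  expect_error(fractional_anisotropy(0, 0, 0), "zero")
})

test_that("eigen decomposition reconstructs random PSD tensors", {
  set.seed(7)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3, 3)
    S <- crossprod(A)
    e <- eigen(S, symmetric = TRUE)
    rec <- e$vectors %*% diag(e$values) %*% t(e$vectors)
    expect_lt(max(abs(rec - S)) / max(abs(S)), 1e-10)
  }
})

test_that("block orientation recovers constant and rotated textures, gates noise", {
  n <- 48
  X <- array(seq_len(n), c(n, n, n))
  Y <- array(rep(seq_len(n), each = n), c(n, n, n))
  Z <- array(rep(seq_len(n), each = n * n), c(n, n, n))
  mk <- function(f) {
    w1 <- c(-f[2], f[1], 0); w2 <- c(0, 0, 1)
    100 + 30 * cos(2 * pi * (X * w1[1] + Y * w1[2]) / 8) +
      30 * cos(2 * pi * Z / 7)
  }
  # texture constant along +y
  ofy <- block_orientation(structure_tensor_field(mk(c(0, 1, 0)), 1))
  idx <- which(ofy$mask, arr.ind = TRUE)
  err <- apply(idx, 1, function(ii)
    fibromap:::axial_angle_deg(ofy$vectors[ii[1], ii[2], ii[3], ], c(0, 1, 0)))
  expect_lt(median(err), 3)

  # texture rotated 30 degrees in-plane
  f30 <- c(cos(pi / 6), sin(pi / 6), 0)
  of30 <- block_orientation(structure_tensor_field(mk(f30), 1))
  idx30 <- which(of30$mask, arr.ind = TRUE)
  err30 <- apply(idx30, 1, function(ii)
    fibromap:::axial_angle_deg(of30$vectors[ii[1], ii[2], ii[3], ], f30))
  expect_lt(median(err30), 3)

  # isotropic noise: FA below the 0.25 gate
  set.seed(5)
  noise <- fibromap:::gauss_smooth3(array(rnorm(n^3), c(n, n, n)), 1)
  ofn <- block_orientation(structure_tensor_field(noise, 1))
  expect_true(all(ofn$fa[is.finite(ofn$fa)] < 0.25) || sum(ofn$mask) == 0)
})

test_that("fiber recovery on ring phantoms meets the error budget", {
  expect_lt(orientation_median_error(ring_recovery()), 3)
  expect_lt(orientation_median_error(ring_small(noise_sd = 12)), 8)
})

test_that("orientation grid pitch is block size times voxel pitch", {
  p <- ring_small()
  of <- block_orientation(structure_tensor_field(p$fluo, 1), block = 16)
  expect_equal(of$pitch_um, 96)
})

test_that("helix angles follow the circumferential/apico-basal convention", {
  e_t <- c(1, 0, 0); e_n <- c(0, 0, 1); e_l <- c(0, 1, 0)
  expect_equal(helix_angle(e_l, e_t, e_n, e_l), 0)
  expect_equal(helix_angle(e_n, e_t, e_n, e_l), 90)
  expect_equal(helix_angle((e_l + e_n) / sqrt(2), e_t, e_n, e_l), 45)
  expect_true(is.nan(helix_angle(e_t, e_t, e_n, e_l)))
  # sign invariance: v and -v give the same angle mod 180
  v <- c(0.3, 0.8, 0.52); v <- v / sqrt(sum(v^2))
  h1 <- helix_angle(v, e_t, e_n, e_l)
  h2 <- helix_angle(-v, e_t, e_n, e_l)
  expect_equal((h1 - h2) %% 180, 0, tolerance = 1e-9)
})
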