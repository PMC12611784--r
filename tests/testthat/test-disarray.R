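test_that("Helmholtz smoothing has the right fixed points", {
  u <- matrix(0.7, 12, 12)
  expect_equal(laplacian_smooth(u, 300, 96), u, tolerance = 1e-10)
  set.seed(2)
  v <- matrix(rnorm(64), 8, 8)
  expect_equal(laplacian_smooth(v, 0, 96), v)
  expect_error(laplacian_smooth(v, 300, 96, mask = matrix(FALSE, 8, 8)),
               "empty")
})

test_that("sinusoid attenuation matches the operator's eigenvalue to 1e-3", {
  n <- 64; h <- 96; delta <- 2 * h
  x <- seq_len(n) - 0.5
  k <- 2 * pi / n        # wavenumber in voxel units (Neumann eigenfunction)
  u <- cos(k * x)
  ub <- laplacian_smooth(u, delta, h)
  att_obs <- sum(ub * u) / sum(u * u)
  att_cont <- 1 / (1 + delta^2 * (k / h)^2)
  expect_lt(abs(att_obs - att_cont), 1e-3)
})

test_that("grid solver agrees with a dense direct solve", {
  set.seed(4)
  d <- c(12, 12, 12)
  u <- array(rnorm(prod(d)), d)
  delta <- 250; h <- 96
  A <- as.matrix(fibromap:::helmholtz_operator(array(TRUE, d), delta, h))
  dense <- solve(A, as.vector(u))
  sp <- laplacian_smooth(u, delta, h)
  expect_lt(max(abs(as.vector(sp) - dense)), 1e-6)
})

test_that("disarray respects directional equivalence and equivariance", {
  set.seed(6)
  al <- matrix(runif(400, -pi / 2, pi / 2 - 1e-6), 20, 20)
  d1 <- disarray_map(al, pitch_um = 96, delta_um = 300)
  # mixing alpha and alpha + pi leaves disarray unchanged
  flip <- matrix(sample(c(0, pi), 400, TRUE), 20, 20)
  d2 <- disarray_map(al + flip, pitch_um = 96, delta_um = 300)
  expect_equal(d1$disarray_deg, d2$disarray_deg, tolerance = 1e-8)
  # rotating all angles by a constant leaves disarray unchanged
  d3 <- disarray_map(al + 0.3, pitch_um = 96, delta_um = 300)
  expect_equal(d3$disarray_deg, d1$disarray_deg, tolerance = 1e-6)
  # bounds
  expect_true(all(d1$disarray_deg >= 0 & d1$disarray_deg <= 90))
})

test_that("constant fields have zero disarray; split populations read their offset", {
  d0 <- disarray_map(matrix(0.4, 16, 16), pitch_um = 96)
  expect_lt(max(abs(d0$disarray_deg)), 1e-10)

  # two interleaved populations at +/-20 degrees about the mean
  al <- matrix(0, 32, 32)
  al[, seq(1, 32, 2)] <- 20 * pi / 180
  al[, seq(2, 32, 2)] <- -20 * pi / 180
  dm <- disarray_map(al, pitch_um = 96, delta_um = 3000)
  expect_equal(mean(dm$disarray_deg), 20, tolerance = 1)

  expect_error(disarray_map(matrix(NaN, 4, 4), pitch_um = 96), "non-finite")
})

test_that("region summaries aggregate the disarray map", {
  al <- matrix(0, 10, 10); al[1:5, ] <- 0.2
  dm <- disarray_map(al, pitch_um = 96, delta_um = 300)
  s <- summarize_disarray(dm, list(top = rbind(matrix(TRUE, 5, 10),
                                               matrix(FALSE, 5, 10))))
  expect_equal(s$n, 50)
  expect_true(is.finite(s$mean_deg))
})
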