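test_that("preprocessing yields inverted percent dF/F0 on the binned grid", {
  # constant movie: dF/F0 identically zero
  mv <- optical_movie(array(100, c(60, 8, 8)), stimulus_times_ms = 40)
  pp <- om_preprocess(mv)
  expect_true(all(pp$frames == 0))
  expect_equal(pp$pitch_um, 312)
  expect_equal(dim(pp$frames)[2:3], c(2, 2))

  # a 10% dip becomes +10 after inversion
  fr <- array(100, c(60, 8, 8)); fr[45:50, , ] <- 90
  pp2 <- om_preprocess(optical_movie(fr, stimulus_times_ms = 40))
  expect_equal(max(pp2$frames), 10, tolerance = 1e-12)

  # binning is the block mean: alternating 0/1 static pixels average to 0.5
  # (checked on the raw binning helper since dF/F0 of a static pattern is 0)
  blk <- array(rep(c(0, 1), length.out = 16), c(1, 4, 4))
  expect_equal(as.numeric(fibromap:::bin_frames(blk, 4)), 0.5)

  # block means conserve the frame mean for full blocks
  set.seed(1)
  fr3 <- array(rnorm(10 * 8 * 8), c(10, 8, 8))
  b3 <- fibromap:::bin_frames(fr3, 4)
  expect_equal(apply(b3, 1, mean), apply(fr3, 1, mean), tolerance = 1e-12)

  expect_error(om_preprocess(optical_movie(fr)), "stimulus")
})

test_that("AP kinetics recover TTP and APDs from synthetic traces", {
  # piecewise-linear AP: 5 ms rise, triangular 100 ms recovery
  n <- 160
  tr <- rep(0, n)
  tr[41:46] <- seq(0, 10, length.out = 6)            # onset 40, peak 45
  tr[47:146] <- 10 - 10 * (1:100) / 100              # back to 0 at 145
  mv <- optical_movie(array(rep(tr, each = 1), c(n, 1, 1)) * 1,
                      stimulus_times_ms = 40)
  mv$frames <- array(tr, c(n, 1, 1))
  k <- ap_kinetics(mv, windows = cbind(30, 160))
  expect_equal(unname(k$means["TTP"]), 5, tolerance = 1e-6)
  expect_equal(unname(k$means["APD50"]), 55, tolerance = 0.02)
  expect_equal(unname(k$means["APD90"]), 95, tolerance = 0.02)
})

test_that("kinetics of a phantom movie match the template within one frame", {
  m <- movie_planar()
  pp <- om_preprocess(m$movie)
  k <- ap_kinetics(pp)
  sp <- movie_spec()
  expect_lt(abs(k$means[["TTP"]] - sp$ap$ttp_ms), 1)
  expect_lt(abs(k$means[["APD50"]] - sp$ap$apd50_ms), 1)
  expect_lt(abs(k$means[["APD70"]] - sp$ap$apd70_ms), 1)
  expect_lt(abs(k$means[["APD90"]] - sp$ap$apd90_ms), 1)
})

test_that("cross-correlation activation maps recover shifts and planar slopes", {
  # identical traces: all delays zero
  tr <- c(rep(0, 30), seq(0, 10, length.out = 5), 10 * exp(-(1:45) / 15))
  fr <- array(rep(tr, 4 * 4), c(length(tr), 4, 4))
  mv <- optical_movie(fr, pitch_um = 312, stimulus_times_ms = 25)
  mv$preprocessed <- TRUE
  a0 <- activation_map(mv, c(1, 1))
  expect_equal(max(abs(a0$values)), 0, tolerance = 1e-9)

  # trace shifted by k frames reports k ms
  fr2 <- fr
  fr2[, 2, 2] <- c(rep(0, 3), tr[1:(length(tr) - 3)])
  mv2 <- mv; mv2$frames <- fr2
  a2 <- activation_map(mv2, c(1, 1), lag_max_ms = 10)
  expect_equal(a2$values[2, 2], 3, tolerance = 0.05)

  # planar phantom: 0.624 ms per binned pixel along propagation
  pp <- om_preprocess(movie_planar()$movie)
  am <- activation_map(pp, c(4, 4))
  slopes <- apply(am$values, 1, function(r) mean(diff(r)))
  expect_equal(mean(slopes), 0.624, tolerance = 0.02)
})

test_that("conduction fields recover planar speed, dispersion and radial geometry", {
  pp <- om_preprocess(movie_planar()$movie)
  am <- activation_map(pp, c(4, 4))
  cd <- conduction(am)
  expect_lt(abs(cd$mean_cv_m_s - 0.5) / 0.5, 0.02)
  expect_lt(cd$angular_dispersion_deg, 1)

  # radial wave: angles span the full circle
  mr <- make_movie(movie_spec(nx = 32, ny = 32, n_beats = 3, cycle_ms = 150,
                              wave = list(type = "radial", speed_m_s = 0.5,
                                          origin_px = c(16, 16))))
  ppr <- om_preprocess(mr$movie)
  amr <- activation_map(ppr, c(4, 4))
  cdr <- conduction(amr)
  ang <- cdr$angle$values[is.finite(cdr$angle$values)]
  expect_gt(diff(range(ang)), 270)
  expect_lt(abs(median(cdr$speed$values, na.rm = TRUE) - 0.5) / 0.5, 0.1)

  # constant activation map: no propagation anywhere
  flat <- scalar_map2d(matrix(5, 8, 8), 312, "activation")
  expect_true(all(!is.finite(conduction(flat)$speed$values)))
})

test_that("local conduction time flags delays against 4-neighbors", {
  pp <- om_preprocess(movie_planar()$movie)
  am <- activation_map(pp, c(4, 4))
  lct <- local_conduction_time(am)
  expect_equal(median(lct$values, na.rm = TRUE), 0.624, tolerance = 0.05)

  flat <- scalar_map2d(matrix(2, 5, 5), 312, "activation")
  expect_true(all(local_conduction_time(flat)$values == 0))

  one <- matrix(0, 5, 5); one[3, 3] <- 5
  l1 <- local_conduction_time(scalar_map2d(one, 312, "activation"))
  expect_equal(l1$values[3, 3], 5)
})

test_that("differential maps and heterogeneity follow their definitions", {
  a <- scalar_map2d(matrix(rnorm(64), 8, 8), 312, "APD90")
  d0 <- differential_map(a, a)
  expect_true(all(d0$values == 0))
  expect_equal(heterogeneity(d0), 0)

  # constant offset: zero heterogeneity; +/- c split: heterogeneity = c
  b <- scalar_map2d(a$values + 3, 312, "APD90")
  expect_equal(heterogeneity(differential_map(b, a)), 0)
  half <- matrix(c(2, -2), 8, 8)
  expect_equal(fibromap:::pop_sd(half), 2)
  # translation invariance
  expect_equal(heterogeneity(scalar_map2d(a$values + 100, 312, "APD90")),
               heterogeneity(a), tolerance = 1e-12)
  expect_error(differential_map(a, scalar_map2d(matrix(0, 4, 4), 312, "APD90")),
               "grid")
})

test_that("inducibility counts only premature stimuli inside the window", {
  s <- data.frame(coupling_interval_ms = c(50, 60), induced = c(TRUE, FALSE))
  expect_equal(inducibility(s)$fraction, 0.5)
  s2 <- data.frame(coupling_interval_ms = c(80, 90), induced = c(TRUE, TRUE))
  expect_true(is.nan(inducibility(s2)$fraction))
  expect_equal(inducibility(s2)$n, 0)
  s3 <- data.frame(coupling_interval_ms = 74, induced = TRUE)
  expect_equal(inducibility(s3)$fraction, 1)
})
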