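test_that("percolation follows its Bernoulli definition", {
  m <- tissue_model(100, 100, ncf = matrix(TRUE, 100, 100),
                    scatt = matrix(1, 100, 100))
  # zero scattering or k = 0 changes nothing
  m0 <- m; m0$scatt <- matrix(0, 100, 100)
  expect_equal(sum(percolate_ncf(m0, k = 0.5)$nonconducting), 0)
  expect_equal(sum(percolate_ncf(m, k = 0)$nonconducting), 0)
  # binomial mean within 3 standard errors on 10^4 elements
  hit <- sum(percolate_ncf(m, k = 0.3, seed = 123)$nonconducting)
  se <- sqrt(0.3 * 0.7 / 1e4)
  expect_lt(abs(hit / 1e4 - 0.3), 3 * se)
  expect_error(percolate_ncf(m, k = 1.5), "exceeds 1")
})

test_that("scenarios alter exactly the stated parameters inside NCF", {
  b <- sheet_phantom()
  sel <- b$ncf
  mc <- apply_scenario(b, "c")
  expect_true(all(mc$gna[sel] == 0.25) && all(mc$gna[!sel] == 1))
  ma <- apply_scenario(b, "a")
  expect_true(all(ma$D_l[sel] == 0.25 * b$D_t0))
  expect_true(all(ma$D_t[sel] == 0.0625 * b$D_t0))
  mb <- apply_scenario(b, "b")
  expect_true(all(mb$D_l[sel] == mb$D_t[sel]))
  md <- apply_scenario(b, "d")
  expect_true(all(md$nfib[sel] == 12L) && all(md$nfib[!sel] == 0L))
  # e is the parameter-by-parameter composition of b, c and d
  me <- apply_scenario(b, "e")
  comp <- apply_scenario(apply_scenario(apply_scenario(b, "b"), "c"), "d")
  expect_identical(me$D_l, comp$D_l)
  expect_identical(me$D_t, comp$D_t)
  expect_identical(me$gna, comp$gna)
  expect_identical(me$nfib, comp$nfib)
  expect_error(apply_scenario(b, "z"), "unknown scenario")
})

test_that("unstimulated tissue rests stably for a second", {
  m <- tissue_model(10, 10)
  s <- simulate_tissue(m, lf_hz = 1, hf_hz = 1, n_lf = 1, n_hf = 1,
                       stim_amp_per_ms = 0, probe = c(5, 5))
  expect_lt(max(abs(s$probe$V_mV + 84)), 0.5)
  expect_true(all(!is.finite(s$act_lf)))
})

test_that("planar CV scales as the square root of conductivity", {
  cv1 <- fm_cache("cv_base", planar_cv(along = TRUE))
  cv4 <- fm_cache("cv_4x", planar_cv(D_l = 4 * 0.145, D_t = 4 * 0.03625,
                                     along = TRUE, dt_ms = 0.0035))
  expect_lt(abs(cv4 / cv1 - 2), 0.06)  # within 3 percent of the factor 2
})

test_that("the anisotropy ratio of 4 in conductivity gives a CV ratio near 2", {
  cv_l <- fm_cache("cv_base", planar_cv(along = TRUE))
  cv_t <- fm_cache("cv_t", planar_cv(along = FALSE))
  expect_lt(abs(cv_l / cv_t - 2), 0.1)  # within 5 percent
})

test_that("waves funnel through a gap in a non-conducting barrier", {
  nx <- 20; ny <- 40
  cf <- matrix(FALSE, nx, ny)
  cf[, 20:21] <- TRUE
  cf[5:16, 20:21] <- FALSE   # 1.2 mm gap
  m <- tissue_model(nx, ny, fiber_angle_deg = 90, cf = cf)
  s <- simulate_tissue(m, lf_hz = 2, hf_hz = 2, n_lf = 1, n_hf = 1)
  act <- s$act_lf
  expect_true(is.finite(act[10, 30]))          # reached behind the barrier
  expect_gt(act[10, 30], act[10, 10])          # later than in front
  expect_gt(act[2, 25], act[10, 23])           # corners behind lag the gap exit
})

test_that("a fibrosis-free sheet shows minimal rate dependence of activation", {
  ctrl <- sheet_phantom(strip_mm = NULL)
  s <- fm_cache("ctrl_full", simulate_tissue(ctrl))
  expect_equal(s$n_unactivated_hf, 0)
  expect_lt(abs(s$prolongation_ms) / s$tat_lf_ms, 0.05)
})

test_that("the combined NCF alteration slows high-frequency conduction the most", {
  sres <- fm_cache("scenario_prol", {
    base <- sheet_phantom()
    lapply(setNames(nm = c("a", "b", "c", "d", "e")), function(sc) {
      m <- apply_scenario(base, sc)
      s <- simulate_tissue(m, n_lf = 5, n_hf = 5)
      cond <- !m$nonconducting
      list(prol = s$prolongation_ms,
           un_hf = sum(cond & !is.finite(s$act_hf)))
    })
  })
  prol <- vapply(sres, `[[`, 0, "prol")
  # every scenario must still conduct at HF for the comparison
  expect_true(all(vapply(sres, `[[`, 0, "un_hf") == 0))
  expect_gt(prol[["e"]], prol[["a"]])
  expect_gt(prol[["e"]], prol[["b"]])
  expect_gt(prol[["e"]], prol[["c"]])
  expect_gt(prol[["e"]], prol[["d"]])
})

test_that("depth averaging follows the epicardial surface", {
  vals <- array(rep(1:10, each = 4), c(2, 2, 10))
  tis <- array(TRUE, c(2, 2, 10))
  tis[1, 1, 9:10] <- FALSE   # lower surface in one column
  out <- depth_average(vals, tis, voxel_um = 200, depth_um = 1000)
  expect_equal(out[2, 2], mean(6:10))
  expect_equal(out[1, 1], mean(4:8))
})
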