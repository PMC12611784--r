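test_that("ring phantom renders exact labels and clean channels", {
  spec <- ring_phantom_spec(outer_radius_um = 300, inner_radius_um = 150,
                            height_um = 150, voxel_um = 10, noise_sd = 0)
  p <- make_ring_phantom(spec)
  tis <- p$truth$tissue
  # no blobs rendered: scattering identically zero inside tissue
  expect_true(all(p$scatt$data[tis] == 0))
  # labels exactly MYO inside, background outside
  expect_true(all(p$truth$labels$tags[tis] == lv_codes()[["MYO"]]))
  expect_true(all(p$truth$labels$tags[!tis] == lv_codes()[["B"]]))
})

test_that("truth helix varies linearly across the wall with the stated endpoints", {
  spec <- ring_phantom_spec(outer_radius_um = 400, inner_radius_um = 200,
                            height_um = 120, voxel_um = 10,
                            helix_endo_deg = 60, helix_epi_deg = -60)
  p <- make_ring_phantom(spec)
  d <- dim(p$truth$helix_deg)
  ctr <- (d[1:2] + 1) / 2
  xs <- (seq_len(d[1]) - ctr[1]) * 10
  # walk outward along +x at mid-height
  z <- round(d[3] / 2)
  iy <- round(ctr[2])
  for (ix in seq_len(d[1])) {
    h <- p$truth$helix_deg[ix, iy, z]
    if (!is.finite(h)) next
    r <- abs(xs[ix])
    expected <- 60 + (-60 - 60) * (r - 200) / 200
    expect_equal(h, expected, tolerance = 1e-10)
  }
})

test_that("identical specs and seeds give bit-identical volumes", {
  spec <- ring_phantom_spec(outer_radius_um = 250, inner_radius_um = 120,
                            height_um = 100, voxel_um = 10, noise_sd = 4,
                            cf_blobs = list(list(center_um = c(185, 0, 50),
                                                 radius_um = 30, intensity = 40)),
                            seed = 99)
  p1 <- make_ring_phantom(spec)
  p2 <- make_ring_phantom(spec)
  expect_identical(p1$fluo$data, p2$fluo$data)
  expect_identical(p1$scatt$data, p2$scatt$data)
})

test_that("blobs outside the annulus wall are rejected", {
  expect_error(make_ring_phantom(ring_phantom_spec(
    outer_radius_um = 300, inner_radius_um = 150, height_um = 150,
    voxel_um = 10,
    cf_blobs = list(list(center_um = c(0, 0, 75), radius_um = 30,
                         intensity = 40)))),
    "outside the annulus")
})

test_that("planar movie truth activation advances by pitch / speed per pixel", {
  m <- movie_planar()
  # 78 um at 0.5 m/s: 0.156 ms per pixel along +x
  expect_equal(diff(m$truth$activation_ms[1, ]),
               rep(0.156, 31), tolerance = 1e-9)
  # finite-difference gradient equals 1/speed along the direction (exact)
  gx <- diff(t(m$truth$activation_ms))  # along x
  expect_equal(max(abs(gx * 0.5 * 1000 / 78 - 1)), 0, tolerance = 1e-9)
})

test_that("movie AP dip matches the template amplitude and dye convention", {
  sp <- movie_spec(nx = 4, ny = 4, n_beats = 1, cycle_ms = 200, noise_sd = 0)
  m <- make_movie(sp)
  tr <- m$movie$frames[, 1, 1]
  # fluorescence decreases during the AP; dip = amplitude fraction
  expect_equal(max(tr), 100)
  expect_equal(min(tr), 100 * (1 - sp$ap$amplitude), tolerance = 1e-9)
})

test_that("radial movies have concentric-circle isochrones and validated origins", {
  sp <- movie_spec(nx = 21, ny = 21,
                   wave = list(type = "radial", speed_m_s = 0.4,
                               origin_px = c(11, 11)))
  m <- make_movie(sp)
  a <- m$truth$activation_ms
  rad <- sqrt(outer((1:21 - 11)^2, (1:21 - 11)^2, `+`))
  expect_equal(a, rad * 78 / 400, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(movie_spec(nx = 10, ny = 10,
                          wave = list(type = "radial", speed_m_s = 0.4,
                                      origin_px = c(50, 5))),
               "origin outside")
})

test_that("movie generation is seed-deterministic under noise", {
  sp <- movie_spec(nx = 8, ny = 8, noise_sd = 2, seed = 42)
  expect_identical(make_movie(sp)$movie$frames, make_movie(sp)$movie$frames)
})
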