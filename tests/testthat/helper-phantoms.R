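# Shared fixtures, built once per session and cached.

.fm_cache_env <- new.env(parent = emptyenv())

fm_cache <- function(key, expr) {
  if (!exists(key, envir = .fm_cache_env)) {
    assign(key, force(expr), envir = .fm_cache_env)
  }
  get(key, envir = .fm_cache_env)
}

# small orientation-scale ring phantom (6 um voxels)
ring_small <- function(noise_sd = 0) {
  fm_cache(paste0("ring_small_", noise_sd),
           make_ring_phantom(ring_phantom_spec(
             outer_radius_um = 600, inner_radius_um = 300, height_um = 400,
             voxel_um = 6, noise_sd = noise_sd)))
}

# proportionate wall (480 um) for the fiber-recovery property
ring_recovery <- function() {
  fm_cache("ring_recovery",
           make_ring_phantom(ring_phantom_spec(
             outer_radius_um = 780, inner_radius_um = 300, height_um = 400,
             voxel_um = 6)))
}

# segmentation-scale phantom with one CF blob (20 um voxels)
ring_seg <- function() {
  fm_cache("ring_seg", make_ring_phantom(ring_phantom_spec(
    outer_radius_um = 900, inner_radius_um = 420, height_um = 800,
    voxel_um = 20, noise_sd = 2,
    cf_blobs = list(list(center_um = c(660, 0, 400), radius_um = 120,
                         intensity = 40)))))
}

# control phantom (no fibrosis, noisy scattering) for threshold calibration
ring_ctrl <- function() {
  fm_cache("ring_ctrl", make_ring_phantom(ring_phantom_spec(
    outer_radius_um = 900, inner_radius_um = 420, height_um = 800,
    voxel_um = 20, noise_sd = 3)))
}

# planar optical-mapping movie at the acquisition defaults
movie_planar <- function() {
  fm_cache("movie_planar", make_movie(movie_spec(
    nx = 32, ny = 32, n_beats = 3, cycle_ms = 150)))
}

# median axial error between a recovered orientation field and phantom truth,
# over blocks fully inside the myocardium
orientation_median_error <- function(phantom, block = 16L) {
  st <- structure_tensor_field(phantom$fluo, sigma = 1)
  of <- block_orientation(st, block = block)
  d <- dim(phantom$truth$tissue)
  nb <- dim(of$fa)
  err <- c()
  for (i in seq_len(nb[1])) for (j in seq_len(nb[2])) for (k in seq_len(nb[3])) {
    if (!of$mask[i, j, k]) next
    if (i * block > d[1] || j * block > d[2] || k * block > d[3]) next
    ix <- ((i - 1) * block + 1):(i * block)
    iy <- ((j - 1) * block + 1):(j * block)
    iz <- ((k - 1) * block + 1):(k * block)
    if (mean(phantom$truth$tissue[ix, iy, iz]) < 1) next
    ctr <- round((c(i, j, k) - 0.5) * block)
    tv <- phantom$truth$fiber[ctr[1], ctr[2], ctr[3], ]
    err <- c(err, fibromap:::axial_angle_deg(of$vectors[i, j, k, ], tv))
  }
  median(err)
}

# reduced-protocol chain config used outside the acceptance tests
chain_quick <- function(n, rate, ...) {
  chain_config(n_fibroblasts = n, pacing_rate_hz = rate,
               n_precondition = 10, dt_ms = 0.01, ...)
}

# small asymmetric two-lobe volume used by the registration tests
reg_volume <- function(n = 32) {
  fm_cache("reg_volume", {
    X <- array(seq_len(n), c(n, n, n))
    Y <- array(rep(seq_len(n), each = n), c(n, n, n))
    Z <- array(rep(seq_len(n), each = n * n), c(n, n, n))
    exp(-((X - 13)^2 / 60 + (Y - 16)^2 / 30 + (Z - 14)^2 / 110)) +
      0.7 * exp(-((X - 21)^2 / 25 + (Y - 18)^2 / 45 + (Z - 22)^2 / 30))
  })
}
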