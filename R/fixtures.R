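# Seeded phantom generators. Every downstream module is testable against the
# exact ground truth these produce: ring-shaped ventricular phantoms with a
# known transmural helix field and fibrosis rendered into the two imaging
# channels, and optical-mapping movies with known activation geometry.

#' Specification of a ring (annular ventricle) phantom
#'
#' The phantom is a thick-walled annulus aligned with the z (long) axis.
#' Myocardial fluorescence carries a texture locally aligned with a linear
#' transmural helix field; compact-fibrosis (CF) blobs and their diffuse
#' non-compact (NCF) halos are rendered into the scattering channel.
#'
#' @param outer_radius_um,inner_radius_um annulus radii (inner < outer).
#' @param height_um phantom height along z.
#' @param voxel_um isotropic voxel pitch (default 6, the orientation-analysis
#'   grid; use 20 for segmentation-scale phantoms).
#' @param helix_endo_deg,helix_epi_deg helix angle at the endocardial /
#'   epicardial surface; the truth field interpolates linearly across the wall.
#' @param cf_blobs list of blobs, each \code{list(center_um = c(x, y, z),
#'   radius_um =, intensity =)}; x, y relative to the annulus axis, z from the
#'   phantom base. Blobs must lie inside the annulus wall.
#' @param ncf_halo_width_um width of the diffuse scattering halo around each
#'   CF blob (0 disables halos).
#' @param noise_sd additive Gaussian noise SD applied to both channels.
#' @param base_intensity,texture_amplitude fluorescence baseline and texture
#'   amplitude (arbitrary units).
#' @param seed integer RNG seed; identical specs and seeds give bit-identical
#'   volumes.
#' @return object of class \code{ring_phantom_spec}.
#' @export
ring_phantom_spec <- function(outer_radius_um = 900, inner_radius_um = 420,
                              height_um = 600, voxel_um = 6,
                              helix_endo_deg = 60, helix_epi_deg = -60,
                              cf_blobs = list(), ncf_halo_width_um = 150,
                              noise_sd = 0, base_intensity = 100,
                              texture_amplitude = 30, seed = 1L) {
  if (inner_radius_um >= outer_radius_um) stop("inner radius must be < outer radius")
  if (voxel_um <= 0) stop("voxel_um must be positive")
  for (b in cf_blobs) {
    if (b$intensity < 0) stop("blob intensities must be >= 0")
  }
  structure(list(outer_radius_um = outer_radius_um,
                 inner_radius_um = inner_radius_um,
                 height_um = height_um, voxel_um = voxel_um,
                 helix_endo_deg = helix_endo_deg, helix_epi_deg = helix_epi_deg,
                 cf_blobs = cf_blobs, ncf_halo_width_um = ncf_halo_width_um,
                 noise_sd = noise_sd, base_intensity = base_intensity,
                 texture_amplitude = texture_amplitude, seed = as.integer(seed)),
            class = "ring_phantom_spec")
}

#' Render a ring phantom into fluorescence and scattering channels
#'
#' The fluorescence texture combines a transmural cosine stripe (whose phase
#' is exactly the radius, so its gradient is exactly radial) with seeded
#' noise convolved along the local fiber direction, leaving image gradients
#' confined to the plane perpendicular to the fiber: the structure tensor's
#' smallest-eigenvalue direction is the ground-truth fiber. Scattering is
#' zero in healthy myocardium, equals the blob intensity inside CF, and is
#' drawn per-voxel from an exponential distribution whose mean tapers with
#' distance from the CF surface inside the NCF halo.
#'
#' @param spec a \code{\link{ring_phantom_spec}}.
#' @return list with elements \code{fluo}, \code{scatt} (both
#'   \code{\link{volume3d}}) and \code{truth}, a list holding the exact
#'   \code{labels} (\code{\link{label_volume}}), the \code{fiber} field
#'   (4D array, unit vectors, NA outside tissue), the \code{helix_deg} grid,
#'   and the analytic local axes \code{e_t}, \code{e_n}, \code{e_l}.
#' @export
make_ring_phantom <- function(spec) {
  stopifnot(inherits(spec, "ring_phantom_spec"))
  v <- spec$voxel_um
  half <- ceiling(spec$outer_radius_um / v) + 2L
  nx <- ny <- 2L * half + 1L
  nz <- max(3L, ceiling(spec$height_um / v))
  xs <- (seq_len(nx) - (nx + 1) / 2) * v
  ys <- (seq_len(ny) - (ny + 1) / 2) * v
  zs <- (seq_len(nz) - 0.5) * v

  # blob validity: entirely inside the annulus wall
  for (b in spec$cf_blobs) {
    rc <- sqrt(sum(b$center_um[1:2]^2))
    if (rc - b$radius_um < spec$inner_radius_um ||
        rc + b$radius_um > spec$outer_radius_um ||
        b$center_um[3] - b$radius_um < 0 ||
        b$center_um[3] + b$radius_um > spec$height_um)
      stop("CF blob extends outside the annulus wall")
  }

  X <- array(xs, c(nx, ny, nz))
  Y <- array(rep(ys, each = nx), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  R <- sqrt(X^2 + Y^2)
  tissue <- R >= spec$inner_radius_um & R <= spec$outer_radius_um

  phi <- atan2(Y, X)
  depth <- (R - spec$inner_radius_um) / (spec$outer_radius_um - spec$inner_radius_um)
  helix <- (spec$helix_endo_deg + (spec$helix_epi_deg - spec$helix_endo_deg) * depth)
  hrad <- helix * pi / 180

  # local axes: transmural (radial), apico-basal (z), circumferential
  et <- array(c(cos(phi), sin(phi), array(0, dim(phi))), c(dim(phi), 3))
  en <- array(c(array(0, dim(phi)), array(0, dim(phi)), array(1, dim(phi))), c(dim(phi), 3))
  el <- array(c(-sin(phi), cos(phi), array(0, dim(phi))), c(dim(phi), 3))

  # fiber f = cos(h) e_l + sin(h) e_n  (lies in the circumferential/long plane)
  fib <- array(NA_real_, c(dim(phi), 3))
  for (k in 1:3) fib[, , , k] <- cos(hrad) * el[, , , k] + sin(hrad) * en[, , , k]

  # Fluorescence texture with gradients confined to the plane perpendicular
  # to the fiber. Family 1 is an additive cosine stripe running
  # transmurally: its phase is exactly r, so its gradient is the radial
  # direction with no curvature contamination. Family 2 is seeded white
  # noise smeared along the local fiber direction (line-integral-convolution
  # style): after smearing, intensity varies much more steeply across the
  # fiber than along it, for any smoothly curving field. Together the two
  # families span the perpendicular plane, making the structure tensor's
  # smallest-eigenvalue direction the fiber axis.
  lam1 <- 8 * v   # stripe wavelength (upper end of the 4-8 voxel range:
  # short wavelengths bias central-difference gradients directionally)
  # fiber direction on the full grid (depth clamped outside the wall) so the
  # smear needs no boundary special-casing
  depc <- pmin(1, pmax(0, depth))
  hfull <- (spec$helix_endo_deg +
              (spec$helix_epi_deg - spec$helix_endo_deg) * depc) * pi / 180
  ffull <- array(0, c(dim(phi), 3))
  for (k in 1:3) ffull[, , , k] <- cos(hfull) * el[, , , k] + sin(hfull) * en[, , , k]

  # labels and scattering channel
  tags <- array(0L, dim(phi))
  tags[tissue] <- .lv_codes[["MYO"]]
  scatt <- array(0, dim(phi))

  dist_cf <- array(Inf, dim(phi))
  for (b in spec$cf_blobs) {
    d <- sqrt((X - b$center_um[1])^2 + (Y - b$center_um[2])^2 + (Z - b$center_um[3])^2)
    inblob <- d <= b$radius_um
    scatt[inblob] <- b$intensity
    tags[inblob & tissue] <- .lv_codes[["CF"]]
    dist_cf <- pmin(dist_cf, d - b$radius_um)
  }

  out <- with_seed(spec$seed, {
    # oriented-noise texture family (across-fiber contrast): smoothed white
    # noise convolved with a Gaussian along the local fiber direction in a
    # single pass (line-integral-convolution style; iterated resampling
    # would accumulate interpolation artifacts)
    noise <- gauss_smooth3(array(stats::rnorm(length(phi)), dim(phi)), 1.2)
    Xi <- array(seq_len(nx), dim(phi))
    Yi <- array(rep(seq_len(ny), each = nx), dim(phi))
    Zi <- array(rep(seq_len(nz), each = nx * ny), dim(phi))
    sig_along <- 5; K <- 12L
    wts <- exp(-(seq(-K, K))^2 / (2 * sig_along^2))
    wts <- wts / sum(wts)
    tex <- array(0, dim(phi))
    for (j in seq(-K, K)) {
      tex <- tex + wts[j + K + 1] *
        array(trilinear3(noise, Xi + j * ffull[, , , 1],
                         Yi + j * ffull[, , , 2], Zi + j * ffull[, , , 3]),
              dim(phi))
    }
    tex <- tex / stats::sd(tex)
    fluo <- array(0, dim(phi))
    fluo[tissue] <- spec$base_intensity +
      spec$texture_amplitude * (cos(2 * pi * R[tissue] / lam1) + tex[tissue])

    if (length(spec$cf_blobs) > 0 && spec$ncf_halo_width_um > 0) {
      halo <- tissue & tags != .lv_codes[["CF"]] &
        dist_cf > 0 & dist_cf <= spec$ncf_halo_width_um
      idx <- which(halo)
      if (length(idx) > 0) {
        mean_int <- mean(vapply(spec$cf_blobs, function(b) b$intensity, 0))
        taper <- 1 - dist_cf[idx] / spec$ncf_halo_width_um
        scatt[idx] <- stats::rexp(length(idx), rate = 1) * (0.12 * mean_int * taper)
        tags[idx] <- .lv_codes[["NCF"]]
      }
    }
    if (spec$noise_sd > 0) {
      fluo <- fluo + array(stats::rnorm(length(fluo), sd = spec$noise_sd), dim(fluo))
      scatt <- scatt + array(stats::rnorm(length(scatt), sd = spec$noise_sd), dim(scatt))
    }
    list(fluo = fluo, scatt = scatt, tags = tags)
  })

  fib[!array(rep(tissue, 3), c(dim(phi), 3))] <- NA_real_
  helix[!tissue] <- NA_real_

  list(fluo = volume3d(out$fluo, v, "fluorescence"),
       scatt = volume3d(out$scatt, v, "scattering"),
       truth = list(labels = label_volume(out$tags, v),
                    fiber = fib, helix_deg = helix,
                    e_t = et, e_n = en, e_l = el,
                    tissue = tissue))
}

#' Specification of a synthetic optical-mapping movie
#'
#' @param nx,ny frame size in pixels.
#' @param pitch_um pixel pitch (default 78, the acquisition value).
#' @param dt_ms frame interval (default 1, i.e. 1 kHz).
#' @param wave either \code{list(type = "planar", speed_m_s =, direction_deg =)}
#'   or \code{list(type = "radial", speed_m_s =, origin_px = c(x, y))}.
#' @param ap action-potential template:
#'   \code{list(ttp_ms =, apd50_ms =, apd70_ms =, apd90_ms =, amplitude =)}
#'   with \code{apd50 < apd70 < apd90}; \code{amplitude} is the fractional
#'   fluorescence dip (voltage-dye convention: fluorescence decreases during
#'   the AP).
#' @param n_beats,cycle_ms pacing burst description.
#' @param baseline resting fluorescence level.
#' @param pre_ms quiet lead-in before the first stimulus (supplies the
#'   diastolic window used for baseline estimation).
#' @param noise_sd additive Gaussian noise SD (fluorescence units).
#' @param seed RNG seed.
#' @return object of class \code{movie_spec}.
#' @export
movie_spec <- function(nx = 32, ny = 32, pitch_um = 78, dt_ms = 1,
                       wave = list(type = "planar", speed_m_s = 0.5, direction_deg = 0),
                       ap = list(ttp_ms = 4, apd50_ms = 25, apd70_ms = 35,
                                 apd90_ms = 50, amplitude = 0.1),
                       n_beats = 3, cycle_ms = 150, baseline = 100,
                       pre_ms = 40, noise_sd = 0, seed = 1L) {
  if (wave$speed_m_s <= 0) stop("wave speed must be positive")
  if (!(ap$apd50_ms < ap$apd70_ms && ap$apd70_ms < ap$apd90_ms))
    stop("need apd50 < apd70 < apd90")
  if (identical(wave$type, "radial")) {
    o <- wave$origin_px
    if (o[1] < 1 || o[1] > nx || o[2] < 1 || o[2] > ny)
      stop("radial wave origin outside frame")
  }
  structure(list(nx = nx, ny = ny, pitch_um = pitch_um, dt_ms = dt_ms,
                 wave = wave, ap = ap, n_beats = n_beats, cycle_ms = cycle_ms,
                 baseline = baseline, pre_ms = pre_ms, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "movie_spec")
}

# piecewise-linear AP shape s(tau) in [0,1]; onset at tau = 0, peak at ttp,
# recovery crosses 0.5/0.3/0.1 at apd50/70/90 measured from onset
ap_shape <- function(tau, ap) {
  tail_end <- ap$apd90_ms + 0.5 * (ap$apd90_ms - ap$apd70_ms)
  knots_t <- c(0, ap$ttp_ms, ap$apd50_ms, ap$apd70_ms, ap$apd90_ms, tail_end)
  knots_s <- c(0, 1, 0.5, 0.3, 0.1, 0)
  s <- stats::approx(knots_t, knots_s, xout = tau, yleft = 0, yright = 0)$y
  s
}

#' Render a synthetic optical-mapping movie with known activation geometry
#'
#' Fluorescence decreases during the action potential (voltage-sensitive-dye
#' convention); preprocessing later inverts the signal. For planar waves the
#' ground-truth activation time grows by \code{pitch / speed} per pixel along
#' the propagation direction; for radial waves isochrones are concentric
#' circles around the origin.
#'
#' @param spec a \code{\link{movie_spec}}.
#' @return list with \code{movie} (an \code{\link{optical_movie}}) and
#'   \code{truth}: \code{activation_ms} (y-x matrix of per-pixel activation
#'   offsets relative to the stimulus), \code{speed_m_s}, and
#'   \code{direction_deg} (planar waves only).
#' @export
make_movie <- function(spec) {
  stopifnot(inherits(spec, "movie_spec"))
  px_um <- spec$pitch_um
  speed_um_ms <- spec$wave$speed_m_s * 1000  # 1 m/s = 1000 um/ms
  xs <- seq_len(spec$nx); ys <- seq_len(spec$ny)
  if (identical(spec$wave$type, "planar")) {
    th <- spec$wave$direction_deg * pi / 180
    u <- c(cos(th), sin(th))
    proj <- outer(ys, xs, function(y, x) (x - 1) * u[1] + (y - 1) * u[2])
    act <- (proj - min(proj)) * px_um / speed_um_ms
  } else if (identical(spec$wave$type, "radial")) {
    o <- spec$wave$origin_px
    act <- outer(ys, xs, function(y, x) sqrt((x - o[1])^2 + (y - o[2])^2)) *
      px_um / speed_um_ms
  } else stop("unknown wave type: ", spec$wave$type)

  stim <- spec$pre_ms + (seq_len(spec$n_beats) - 1) * spec$cycle_ms
  total_ms <- spec$pre_ms + spec$n_beats * spec$cycle_ms
  nt <- ceiling(total_ms / spec$dt_ms)
  tt <- (seq_len(nt) - 1) * spec$dt_ms

  frames <- array(0, c(nt, spec$ny, spec$nx))
  s_total <- matrix(0, nt, spec$ny * spec$nx)
  act_v <- as.vector(act)  # column-major: (y fastest) matches frames[t, y, x]
  for (t0 in stim) {
    tau <- outer(tt, act_v, function(a, b) a - t0 - b)
    s_total <- s_total + ap_shape(tau, spec$ap)
  }
  f <- spec$baseline * (1 - spec$ap$amplitude * pmin(s_total, 1))
  frames <- array(f, c(nt, spec$ny, spec$nx))

  frames <- with_seed(spec$seed, {
    if (spec$noise_sd > 0)
      frames + array(stats::rnorm(length(frames), sd = spec$noise_sd), dim(frames))
    else frames
  })

  movie <- optical_movie(frames, dt_ms = spec$dt_ms, pitch_um = px_um,
                         stimulus_times_ms = stim,
                         pacing_rate_hz = 1000 / spec$cycle_ms)
  truth <- list(activation_ms = act, speed_m_s = spec$wave$speed_m_s,
                direction_deg = if (identical(spec$wave$type, "planar"))
                  spec$wave$direction_deg else NA_real_)
  list(movie = movie, truth = truth)
}
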