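# Reduced-scale monodomain tissue with image-informed percolation fibrosis
# and the five NCF electrophysiological-alteration scenarios.
#
# The tissue is a 2D sheet on a 100-um grid (the mesh scale of the
# organ-level models this substitutes for at desk scale). Compact fibrosis is
# non-conducting (no-flux interfaces); non-compact fibrosis starts as
# conducting myocardium whose elements can be percolated to non-conducting
# with probability proportional to the local scattering intensity.

# Baseline diffusivities (mm^2/ms on the dimensionless-u equation), sized so
# the control sheet conducts at ~0.35 / 0.175 m/s along / across fibers with
# the mouse myocyte parameters (anisotropy ratio sigma_l/sigma_t = 4).
.monodomain_defaults <- list(D_l = 0.145, D_t = 0.03625)

#' Build a 2D monodomain tissue model
#'
#' @param nx,ny grid size (elements).
#' @param h_mm grid spacing (default 0.1 mm).
#' @param fiber_angle_deg fiber direction (from +x), scalar or matrix.
#' @param D_l,D_t longitudinal/transverse diffusivities (mm^2/ms).
#' @param ncf logical matrix tagging non-compact-fibrosis elements (default
#'   none).
#' @param cf logical matrix of compact fibrosis (non-conducting; default
#'   none).
#' @param scatt numeric matrix of scattering intensity (drives percolation;
#'   default 0).
#' @param myo,fib cell-model parameters (\code{\link{myocyte_params}},
#'   \code{\link{fibroblast_params}}); the tissue default is the
#'   \code{"mouse_tissue"} set, which follows 15-Hz pacing 1:1.
#' @param G_mf myocyte-fibroblast coupling conductance for scenario d (nS);
#'   the tissue default (3 nS per fibroblast) is in the modest range of
#'   heterocellular coupling formulations used at organ scale.
#' @return object of class \code{tissue_model}.
#' @export
tissue_model <- function(nx, ny, h_mm = 0.1, fiber_angle_deg = 0,
                         D_l = .monodomain_defaults$D_l,
                         D_t = .monodomain_defaults$D_t,
                         ncf = NULL, cf = NULL, scatt = NULL,
                         myo = myocyte_params("mouse_tissue"),
                         fib = fibroblast_params(),
                         G_mf = 3) {
  mfull <- function(x, default) {
    if (is.null(x)) matrix(default, nx, ny)
    else if (is.matrix(x)) x else matrix(x, nx, ny)
  }
  structure(list(nx = nx, ny = ny, h_mm = h_mm,
                 angle_rad = mfull(fiber_angle_deg, 0) * pi / 180,
                 D_l = mfull(D_l, D_l), D_t = mfull(D_t, D_t),
                 D_l0 = D_l, D_t0 = D_t,
                 ncf = mfull(ncf, FALSE), cf = mfull(cf, FALSE),
                 nonconducting = mfull(cf, FALSE),
                 scatt = mfull(scatt, 0),
                 gna = matrix(1, nx, ny), nfib = matrix(0L, nx, ny),
                 myo = myo, fib = fib, G_mf = G_mf),
            class = "tissue_model")
}

#' Rectangular sheet phantom with an optional NCF strip
#'
#' A width x height sheet (fibers along +x by default) with a full-width NCF
#' strip perpendicular to propagation; the strip carries a uniform scattering
#' intensity used by \code{\link{percolate_ncf}}.
#'
#' @param width_mm,height_mm sheet dimensions.
#' @param strip_mm NULL, or c(y0, y1) in mm bounding the NCF band.
#' @param scatt_level scattering intensity inside NCF elements.
#' @param ncf_density fraction of band elements tagged NCF (default 0.2):
#'   non-compact fibrosis is collagen intermixed with surviving myocytes, so
#'   the band is patchy rather than solid.
#' @param seed seed for the patchy-band draw.
#' @param fiber_angle_deg fiber direction (from +x). The default 0 puts
#'   fibers across the propagation (y) axis: the wave crosses the strip
#'   transversally, as when an epicardial wave traverses a fibrotic band.
#' @param ... passed to \code{\link{tissue_model}}.
#' @return \code{tissue_model}.
#' @export
sheet_phantom <- function(width_mm = 2, height_mm = 4, strip_mm = c(1.8, 2.4),
                          scatt_level = 1, fiber_angle_deg = 0,
                          ncf_density = 0.2, seed = 11L, ...) {
  h <- 0.1
  nx <- round(width_mm / h); ny <- round(height_mm / h)
  ncf <- scatt <- NULL
  if (!is.null(strip_mm)) {
    yy <- matrix(rep((seq_len(ny) - 0.5) * h, each = nx), nx, ny)
    band <- yy >= strip_mm[1] & yy < strip_mm[2]
    draws <- with_seed(seed, matrix(stats::runif(nx * ny), nx, ny))
    ncf <- band & draws < ncf_density
    scatt <- ifelse(ncf, scatt_level, 0)
  }
  tissue_model(nx, ny, h_mm = h, fiber_angle_deg = fiber_angle_deg,
               ncf = ncf, scatt = scatt, ...)
}

#' Percolate NCF elements to non-conducting
#'
#' Each NCF element independently becomes non-conducting with probability
#' p = k * scattering intensity (denser fibrosis percolates more).
#'
#' @param model \code{\link{tissue_model}}.
#' @param k proportionality constant; \code{k * max(scatt)} must be <= 1.
#'   Default normalizes the maximum intensity to p = 0.5.
#' @param seed RNG seed.
#' @return updated model.
#' @export
percolate_ncf <- function(model, k = NULL, seed = 1L) {
  stopifnot(inherits(model, "tissue_model"))
  if (is.null(k)) {
    mx <- max(model$scatt[model$ncf])
    k <- if (mx > 0) 0.5 / mx else 0
  }
  p <- k * model$scatt
  if (any(p[model$ncf] > 1)) stop("percolation probability exceeds 1")
  draws <- with_seed(seed, matrix(stats::runif(model$nx * model$ny),
                                  model$nx, model$ny))
  hit <- model$ncf & draws < p
  model$nonconducting <- model$nonconducting | hit
  model
}

#' Apply an NCF electrophysiological-alteration scenario
#'
#' Alterations act only inside the NCF region: (a) conductivity reduced to
#' 25 percent of the control transverse value with the normal anisotropy
#' ratio preserved (transverse further reduced to 25 percent of the new
#' longitudinal value); (b) the same reduction but isotropic; (c) peak
#' fast-inward (sodium) conductance reduced to 25 percent; (d) each NCF
#' myocyte coupled to 12 passive fibroblasts; (e) the combined condition:
#' isotropic reduced conductivity + sodium reduction + fibroblast coupling.
#'
#' @param model \code{\link{tissue_model}}.
#' @param scenario one of "a", "b", "c", "d", "e".
#' @return updated model.
#' @export
apply_scenario <- function(model, scenario) {
  stopifnot(inherits(model, "tissue_model"))
  if (!scenario %in% c("a", "b", "c", "d", "e"))
    stop("unknown scenario: ", scenario)
  sel <- model$ncf
  if (scenario %in% c("a", "b", "e")) {
    dl_new <- 0.25 * model$D_t0
    model$D_l[sel] <- dl_new
    model$D_t[sel] <- if (scenario == "a") 0.25 * dl_new else dl_new
  }
  if (scenario %in% c("c", "e")) model$gna[sel] <- 0.25
  if (scenario %in% c("d", "e")) model$nfib[sel] <- 12L
  model
}

#' Simulate paced tissue and report activation maps
#'
#' Paces the model (default: a 0.5 x 0.5 mm patch at the apical y = 0 edge,
#' 2 ms suprathreshold pulses) for \code{n_lf} beats at the low frequency and
#' \code{n_hf} beats at the high frequency, recording per-element activation
#' times (upstroke crossing of -20 mV) during the final beat of each train.
#' The activation-time prolongation is the difference of total activation
#' times (HF minus LF) over elements activated in both.
#'
#' @param model \code{\link{tissue_model}}.
#' @param lf_hz,hf_hz pacing frequencies (defaults 5 and 15).
#' @param n_lf,n_hf beats per train (defaults 10 each).
#' @param dt_ms integration step (default 0.01, inside the diffusion
#'   stability bound at the default diffusivities).
#' @param stim_mask logical matrix of paced elements; default apical patch.
#' @param stim_amp_per_ms stimulus strength in du/dt units (default 3,
#'   suprathreshold for all scenario conditions).
#' @param probe optional c(i, j) element whose voltage trace is sampled.
#' @return list with \code{act_lf}, \code{act_hf} (ms activation maps of the
#'   final LF/HF beats), \code{tat_lf_ms}, \code{tat_hf_ms},
#'   \code{prolongation_ms}, \code{n_unactivated_hf}, and the probe trace.
#' @export
simulate_tissue <- function(model, lf_hz = 5, hf_hz = 15, n_lf = 10, n_hf = 10,
                            dt_ms = 0.01, stim_mask = NULL,
                            stim_amp_per_ms = 3, probe = NULL) {
  stopifnot(inherits(model, "tissue_model"))
  cl_lf <- 1000 / lf_hz; cl_hf <- 1000 / hf_hz
  t_hf0 <- n_lf * cl_lf
  stim_times <- c((seq_len(n_lf) - 1) * cl_lf, t_hf0 + (seq_len(n_hf) - 1) * cl_hf)
  if (is.null(stim_mask)) {
    npx <- max(1L, round(0.5 / model$h_mm))
    stim_mask <- matrix(FALSE, model$nx, model$ny)
    cx <- round(model$nx / 2)
    stim_mask[max(1, cx - npx %/% 2):min(model$nx, cx + npx %/% 2), 1:npx] <- TRUE
  }
  rec_start <- c((n_lf - 1) * cl_lf, t_hf0 + (n_hf - 1) * cl_hf)
  rec_end <- c(n_lf * cl_lf, t_hf0 + n_hf * cl_hf)
  t_end <- max(rec_end)
  tags <- matrix(0L, model$nx, model$ny)
  tags[model$nonconducting] <- 1L
  raw <- .monodomain_sim(tags, model$D_l, model$D_t, model$angle_rad,
                         model$gna, model$nfib, model$myo, model$fib,
                         model$G_mf, model$h_mm, dt_ms,
                         stim_times, 2.0, stim_amp_per_ms, stim_mask,
                         rec_start, rec_end, t_end,
                         if (is.null(probe)) -1L else probe[1] - 1L,
                         if (is.null(probe)) 0L else probe[2] - 1L, 1.0)
  act_lf <- raw$activation_ms[[1]]; act_hf <- raw$activation_ms[[2]]
  cond <- tags == 0L
  both <- cond & is.finite(act_lf) & is.finite(act_hf)
  tat <- function(a) if (!any(both)) NA_real_ else diff(range(a[both]))
  list(act_lf = act_lf, act_hf = act_hf,
       tat_lf_ms = tat(act_lf), tat_hf_ms = tat(act_hf),
       prolongation_ms = tat(act_hf) - tat(act_lf),
       n_unactivated_hf = sum(cond & !is.finite(act_hf)),
       probe = if (!is.null(probe)) list(t_ms = raw$probe_t_ms,
                                         V_mV = raw$probe_V_mV))
}

#' Planar conduction velocity on a uniform sheet
#'
#' Paces one edge of a uniform sheet with a line stimulus and measures the
#' plane-wave conduction velocity between the 25 and 75 percent stations
#' along the propagation axis at mid-width.
#'
#' @param D_l,D_t diffusivities (mm^2/ms).
#' @param along propagate along the fiber axis (\code{TRUE}) or across it.
#' @param length_mm,width_mm sheet dimensions (propagation along length).
#' @param dt_ms integration step.
#' @param ... passed to \code{\link{tissue_model}}.
#' @return CV in m/s.
#' @export
planar_cv <- function(D_l = .monodomain_defaults$D_l,
                      D_t = .monodomain_defaults$D_t,
                      along = TRUE, length_mm = 8, width_mm = 1.2,
                      dt_ms = 0.01, ...) {
  h <- 0.1
  nx <- round(width_mm / h); ny <- round(length_mm / h)
  ang <- if (along) 90 else 0   # propagation is along +y
  model <- tissue_model(nx, ny, h_mm = h, fiber_angle_deg = ang,
                        D_l = D_l, D_t = D_t, ...)
  stim <- matrix(FALSE, nx, ny)
  ncol_stim <- max(2L, ceiling(sqrt(max(D_l, D_t)) * 2 / h))  # ~2 diffusion lengths
  stim[, seq_len(min(ny, ncol_stim))] <- TRUE
  raw <- .monodomain_sim(matrix(0L, nx, ny), model$D_l, model$D_t,
                         model$angle_rad, model$gna, model$nfib,
                         model$myo, model$fib, model$G_mf, h, dt_ms,
                         0, 2.0, 1.0, stim, 0, 200, 200, -1L, 0L, 1.0)
  act <- raw$activation_ms[[1]]
  i <- max(1L, round(nx / 2))
  j1 <- round(0.25 * ny); j2 <- round(0.75 * ny)
  t1 <- act[i, j1]; t2 <- act[i, j2]
  if (!is.finite(t1) || !is.finite(t2) || t2 <= t1)
    stop("planar wave did not traverse the sheet")
  (j2 - j1) * h / (t2 - t1)  # mm/ms = m/s
}

#' Depth-averaged epicardial signal
#'
#' Mimics the integration over tissue depth inherent to wide-field optical
#' mapping: for each (x, y) column of a volume, values are averaged over a
#' layer of the stated thickness below the epicardial (largest-z) tissue
#' surface.
#'
#' @param values 3D array of per-voxel values.
#' @param tissue logical 3D tissue mask.
#' @param voxel_um voxel pitch.
#' @param depth_um layer thickness (default 1000, i.e. 1 mm).
#' @return matrix (x, y) of depth-averaged values (NaN where no tissue).
#' @export
depth_average <- function(values, tissue, voxel_um, depth_um = 1000) {
  d <- dim(values)
  stopifnot(identical(d, dim(tissue)))
  nlay <- max(1L, round(depth_um / voxel_um))
  out <- matrix(NaN, d[1], d[2])
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
    zs <- which(tissue[x, y, ])
    if (length(zs) == 0) next
    ztop <- max(zs)
    sel <- zs[zs > ztop - nlay]
    out[x, y] <- mean(values[x, y, sel])
  }
  out
}

#' Censored strip-crossing prolongation of a simulated sheet
#'
#' Quantifies how much longer the wave needs to cross the fibrotic band at
#' high versus low pacing frequency. For each column of the sheet the
#' crossing delay is the activation time at the distal station minus that at
#' the proximal station; distal tissue that never activates during the
#' recorded beat is censored at the window length (total conduction block
#' counts as the maximal delay). The prolongation is the mean HF minus LF
#' crossing-delay difference over columns.
#'
#' @param sim result of \code{\link{simulate_tissue}}.
#' @param model the simulated \code{\link{tissue_model}}.
#' @param y_prox_mm,y_dist_mm stations flanking the band (mm along y).
#' @param window_lf_ms,window_hf_ms censoring caps (defaults: the recorded
#'   beat windows, i.e. the LF/HF cycle lengths).
#' @return prolongation in ms.
#' @export
strip_crossing_delay <- function(sim, model, y_prox_mm, y_dist_mm,
                                 window_lf_ms = 200, window_hf_ms = 1000 / 15) {
  jp <- max(1L, round(y_prox_mm / model$h_mm))
  jd <- min(model$ny, round(y_dist_mm / model$h_mm))
  delay <- function(act, cap) {
    prox <- act[, jp]; dist <- act[, jd]
    dist[!is.finite(dist)] <- cap
    ok <- is.finite(prox)
    mean(dist[ok] - prox[ok])
  }
  delay(sim$act_hf, window_hf_ms) - delay(sim$act_lf, window_lf_ms)
}
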