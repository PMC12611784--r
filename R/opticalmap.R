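# Optical-mapping signal analysis: dF/F0 preprocessing, AP kinetics,
# activation / conduction-velocity maps, wavefront dispersion, differential
# maps, heterogeneity, and arrhythmia inducibility.

# Block-mean 4x4 binning of a (t, y, x) stack; NA-aware (mean over valid
# in-block pixels, NaN if none). Trailing rows/cols not filling a block are
# dropped.
bin_frames <- function(frames, bin = 4L) {
  d <- dim(frames)
  nyb <- d[2] %/% bin; nxb <- d[3] %/% bin
  out <- array(NA_real_, c(d[1], nyb, nxb))
  for (by in seq_len(nyb)) for (bx in seq_len(nxb)) {
    blk <- frames[, ((by - 1) * bin + 1):(by * bin), ((bx - 1) * bin + 1):(bx * bin),
                  drop = FALSE]
    m <- apply(blk, 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    })
    out[, by, bx] <- m
  }
  out
}

#' Preprocess an optical-mapping movie (dF/F0, inversion, 4x4 binning)
#'
#' The per-pixel baseline F0 is the mean over the diastolic samples, taken as
#' the last \code{baseline_ms} before each stimulus. The movie is converted to
#' a percent change over baseline, inverted so depolarization is positive
#' (voltage-sensitive dyes dim during the AP), and block-averaged over 4x4
#' pixels, which takes the pitch from 78 um to 312 um.
#'
#' @param movie an \code{\link{optical_movie}} with stimulus times.
#' @param roi_mask optional logical (y, x) matrix at movie pitch; pixels
#'   outside become NaN before binning.
#' @param baseline_ms length of the pre-stimulus diastolic window (default 20).
#' @param bin binning factor (default 4).
#' @return preprocessed \code{\link{optical_movie}} (percent dF/F0, positive
#'   upstroke, binned pitch).
#' @export
om_preprocess <- function(movie, roi_mask = NULL, baseline_ms = 20, bin = 4L) {
  stopifnot(inherits(movie, "optical_movie"))
  if (length(movie$stimulus_times_ms) == 0)
    stop("no stimulus times: cannot locate a diastolic baseline window")
  nt <- dim(movie$frames)[1]
  tt <- (seq_len(nt) - 1) * movie$dt_ms
  base_idx <- unique(unlist(lapply(movie$stimulus_times_ms, function(s) {
    which(tt >= s - baseline_ms & tt < s)
  })))
  if (length(base_idx) == 0) stop("baseline window is empty")

  f <- movie$frames
  f0 <- apply(f[base_idx, , , drop = FALSE], c(2, 3), mean)
  d <- dim(f)
  f0a <- aperm(array(f0, c(d[2], d[3], d[1])), c(3, 1, 2))
  dff <- array(0, d)
  nz <- f0a != 0
  dff[nz] <- -100 * (f[nz] - f0a[nz]) / f0a[nz]  # inverted percent change

  if (!is.null(roi_mask)) {
    roi <- aperm(array(roi_mask, c(d[2], d[3], d[1])), c(3, 1, 2))
    dff[!roi] <- NA_real_
  }
  out <- movie
  out$frames <- bin_frames(dff, bin)
  out$pitch_um <- movie$pitch_um * bin
  out$preprocessed <- TRUE
  out
}

# Beat windows [start, end) in ms derived from stimulus times; the last
# window extends to the end of the recording.
beat_windows <- function(movie) {
  st <- movie$stimulus_times_ms
  if (length(st) == 0) stop("no stimulus times")
  ends <- c(st[-1], dim(movie$frames)[1] * movie$dt_ms)
  cbind(start = st, end = ends)
}

# Kinetics of a single-beat trace: onset (max upstroke slope), TTP and APD at
# fractional recovery levels, with linear sub-frame interpolation.
.trace_kinetics <- function(s, dt, levels = c(0.5, 0.3, 0.1)) {
  n <- length(s)
  if (n < 3 || all(!is.finite(s))) return(rep(NA_real_, 2 + length(levels)))
  amp <- max(s) - min(s)
  if (!is.finite(amp) || amp <= 1e-9) return(rep(NA_real_, 2 + length(levels)))
  ds <- diff(s)
  if (max(ds) <= 0) return(rep(NA_real_, 2 + length(levels)))
  i_on <- which.max(ds)            # start of the steepest upstroke interval
  t_on <- (i_on - 1) * dt
  i_pk <- which.max(s)
  ttp <- (i_pk - 1) * dt - t_on
  if (ttp < 0) return(rep(NA_real_, 2 + length(levels)))
  peak <- s[i_pk]
  base <- min(s[seq_len(i_on)])
  apds <- vapply(levels, function(lv) {
    thr <- base + lv * (peak - base)
    seg <- s[i_pk:n]
    j <- which(seg <= thr)[1]
    if (is.na(j) || j == 1) return(NA_real_)
    # linear interpolation between frames j-1 and j of the segment
    s1 <- seg[j - 1]; s2 <- seg[j]
    frac <- if (s1 == s2) 0 else (s1 - thr) / (s1 - s2)
    (i_pk - 1 + (j - 2) + frac) * dt - t_on
  }, 0)
  c(t_on, ttp, apds)
}

#' Per-pixel action-potential kinetics maps
#'
#' For every binned pixel and every beat window, the AP onset is the time of
#' maximum upstroke slope, TTP is onset-to-peak, and APD50/70/90 run from the
#' onset to 50/70/90 percent recovery of the signal towards baseline.
#' Per-pixel values are the median (default) over the beats of a burst, and
#' each map is also summarised by the mean over valid pixels (one value per
#' ventricle).
#'
#' @param movie_pp preprocessed movie (see \code{\link{om_preprocess}}).
#' @param windows beat windows as a 2-column (start, end) matrix in ms;
#'   default derived from the stimulus times.
#' @param reduce per-pixel reduction across beats, \code{"median"} (default)
#'   or \code{"mean"}.
#' @return list with \code{maps} (named list of \code{\link{scalar_map2d}}:
#'   TTP, APD50, APD70, APD90) and \code{means} (named numeric vector).
#' @export
ap_kinetics <- function(movie_pp, windows = NULL, reduce = c("median", "mean")) {
  stopifnot(inherits(movie_pp, "optical_movie"))
  reduce <- match.arg(reduce)
  red <- if (reduce == "median") function(x) median(x, na.rm = TRUE) else
    function(x) mean(x, na.rm = TRUE)
  if (is.null(windows)) windows <- beat_windows(movie_pp)
  d <- dim(movie_pp$frames)
  dt <- movie_pp$dt_ms
  tt <- (seq_len(d[1]) - 1) * dt
  kinds <- c("TTP", "APD50", "APD70", "APD90")
  acc <- array(NA_real_, c(nrow(windows), d[2], d[3], 4))
  for (w in seq_len(nrow(windows))) {
    sel <- tt >= windows[w, 1] & tt < windows[w, 2]
    for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      k <- .trace_kinetics(movie_pp$frames[sel, y, x], dt)
      acc[w, y, x, ] <- k[2:5]
    }
  }
  maps <- lapply(1:4, function(i) {
    m <- apply(acc[, , , i, drop = FALSE], c(2, 3), function(v)
      if (all(is.na(v))) NA_real_ else red(v))
    scalar_map2d(m, movie_pp$pitch_um, kinds[i])
  })
  names(maps) <- kinds
  means <- vapply(maps, function(m) mean(m$values, na.rm = TRUE), 0)
  list(maps = maps, means = means)
}

#' Activation map by pixelwise cross-correlation against a seed trace
#'
#' The temporal shift of each pixel's fluorescence trace relative to the seed
#' pixel is estimated by maximising the normalized cross-correlation over
#' integer lags, refined to sub-frame precision by parabolic interpolation of
#' the correlation peak. Pixels whose best correlation falls below
#' \code{floor} are left unmapped.
#'
#' @param movie_pp preprocessed movie.
#' @param seed_px seed pixel as c(y, x) on the binned grid (must be valid).
#' @param lag_max_ms maximum tested |lag|; default half the shortest pacing
#'   cycle (or 50 ms without stimulus times).
#' @param floor correlation-peak rejection floor (default 0.5).
#' @return \code{\link{scalar_map2d}} of kind \code{activation}: per-pixel
#'   delay in ms relative to the seed pixel (seed = 0).
#' @export
activation_map <- function(movie_pp, seed_px, lag_max_ms = NULL, floor = 0.5) {
  stopifnot(inherits(movie_pp, "optical_movie"))
  d <- dim(movie_pp$frames)
  dt <- movie_pp$dt_ms
  seed_tr <- movie_pp$frames[, seed_px[1], seed_px[2]]
  if (all(!is.finite(seed_tr))) stop("seed pixel trace is invalid (all NaN)")
  if (is.null(lag_max_ms)) {
    st <- movie_pp$stimulus_times_ms
    lag_max_ms <- if (length(st) >= 2) min(diff(st)) / 2 else 50
  }
  L <- max(1L, round(lag_max_ms / dt))
  lags <- -L:L
  n <- d[1]
  vals <- matrix(NA_real_, d[2], d[3])
  for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    tr <- movie_pp$frames[, y, x]
    if (all(!is.finite(tr))) next
    cc <- vapply(lags, function(k) {
      # pixel delayed by k frames w.r.t. seed: compare tr[t] with seed[t - k]
      if (k >= 0) { a <- tr[(1 + k):n]; b <- seed_tr[1:(n - k)] }
      else        { a <- tr[1:(n + k)]; b <- seed_tr[(1 - k):n] }
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
      stats::cor(a[ok], b[ok])
    }, 0)
    if (all(is.na(cc))) next
    i <- which.max(cc)
    if (cc[i] < floor) next
    delay <- lags[i]
    # parabolic sub-frame refinement on the correlation peak
    if (i > 1 && i < length(cc) && is.finite(cc[i - 1]) && is.finite(cc[i + 1])) {
      den <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
      if (den < 0) delay <- delay + 0.5 * (cc[i - 1] - cc[i + 1]) / den
    }
    vals[y, x] <- delay * dt
  }
  scalar_map2d(vals, movie_pp$pitch_um, "activation")
}

#' Conduction-velocity field from an activation map (multi-vector approach)
#'
#' The local gradient of activation time is fitted by least squares over each
#' full 3x3 neighborhood of valid pixels; velocity points along the gradient
#' (the propagation direction) with magnitude 1/|grad t|. Wavefront
#' deformation is summarised by the circular standard deviation of the vector
#' angles.
#'
#' @param act activation \code{\link{scalar_map2d}}.
#' @param grad_floor_ms_px minimum |grad t| (ms/pixel) below which speed is
#'   treated as unresolved (infinite-speed guard; default 0.01).
#' @return list with \code{speed} and \code{angle} maps
#'   (\code{\link{scalar_map2d}}, m/s and degrees), the velocity components
#'   \code{vx}, \code{vy} (m/s), \code{mean_cv_m_s} and
#'   \code{angular_dispersion_deg}.
#' @export
conduction <- function(act, grad_floor_ms_px = 0.01) {
  stopifnot(inherits(act, "scalar_map2d"), act$kind == "activation")
  a <- act$values
  ny <- nrow(a); nx <- ncol(a)
  speed <- angle <- vx <- vy <- matrix(NA_real_, ny, nx)
  off <- expand.grid(dy = -1:1, dx = -1:1)
  for (y in 2:(ny - 1)) for (x in 2:(nx - 1)) {
    tv <- a[cbind(y + off$dy, x + off$dx)]
    if (any(!is.finite(tv))) next
    X <- cbind(1, off$dx, off$dy)
    g <- qr.solve(X, tv)           # t ~ a + gx*x + gy*y, pixels
    gx <- g[2]; gy <- g[3]
    gn <- sqrt(gx^2 + gy^2)
    if (gn < grad_floor_ms_px) next
    sp <- (act$pitch_um / gn) / 1000   # um/ms -> m/s
    speed[y, x] <- sp
    angle[y, x] <- atan2(gy, gx) * 180 / pi
    vx[y, x] <- sp * gx / gn
    vy[y, x] <- sp * gy / gn
  }
  ang_r <- angle[is.finite(angle)] * pi / 180
  list(speed = scalar_map2d(speed, act$pitch_um, "CV"),
       angle = scalar_map2d(angle, act$pitch_um, "angle"),
       vx = vx, vy = vy,
       mean_cv_m_s = mean(speed, na.rm = TRUE),
       angular_dispersion_deg = circ_sd(ang_r) * 180 / pi)
}

#' Local conduction time map
#'
#' Per-pixel maximum absolute activation-time difference to the four direct
#' neighbors; reveals localized conduction slowing. Pixels with no valid
#' neighbor are NaN.
#'
#' @param act activation \code{\link{scalar_map2d}}.
#' @return \code{\link{scalar_map2d}} of kind \code{LCT} (ms).
#' @export
local_conduction_time <- function(act) {
  stopifnot(inherits(act, "scalar_map2d"), act$kind == "activation")
  a <- act$values
  ny <- nrow(a); nx <- ncol(a)
  out <- matrix(NA_real_, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    if (!is.finite(a[y, x])) next
    nb <- c(if (y > 1) a[y - 1, x], if (y < ny) a[y + 1, x],
            if (x > 1) a[y, x - 1], if (x < nx) a[y, x + 1])
    nb <- nb[is.finite(nb)]
    if (length(nb)) out[y, x] <- max(abs(a[y, x] - nb))
  }
  scalar_map2d(out, act$pitch_um, "LCT")
}

#' Differential map (high-frequency minus low-frequency pacing)
#'
#' @param map_hf,map_lf maps of the same kind on the same grid.
#' @return \code{\link{scalar_map2d}} of kind \code{delta} (HF - LF; NaN where
#'   either input is unmapped).
#' @export
differential_map <- function(map_hf, map_lf) {
  stopifnot(inherits(map_hf, "scalar_map2d"), inherits(map_lf, "scalar_map2d"))
  if (!identical(dim(map_hf$values), dim(map_lf$values)) ||
      map_hf$pitch_um != map_lf$pitch_um || map_hf$kind != map_lf$kind)
    stop("maps do not share grid and kind")
  scalar_map2d(map_hf$values - map_lf$values, map_hf$pitch_um, "delta")
}

#' Spatial heterogeneity of a parameter map
#'
#' Standard deviation (population form) across all valid pixels; invariant to
#' adding a constant.
#'
#' @param map a \code{\link{scalar_map2d}}.
#' @return scalar (same units as the map).
#' @export
heterogeneity <- function(map) {
  stopifnot(inherits(map, "scalar_map2d"))
  pop_sd(map$values)
}

#' Arrhythmia inducibility
#'
#' Fraction of premature stimuli falling within 75 ms of the preceding sinus
#' depolarization onset that induced an arrhythmic event.
#'
#' @param stimuli data.frame (or coercible) with columns
#'   \code{coupling_interval_ms} and logical \code{induced}.
#' @param window_ms coupling-interval window (default 75).
#' @return list with \code{fraction} (NaN if no stimulus fell inside the
#'   window) and \code{n} (number of qualifying stimuli).
#' @export
inducibility <- function(stimuli, window_ms = 75) {
  stimuli <- as.data.frame(stimuli)
  if (nrow(stimuli) == 0) stop("empty stimulus list")
  sel <- stimuli$coupling_interval_ms < window_ms
  n <- sum(sel)
  list(fraction = if (n == 0) NaN else mean(as.logical(stimuli$induced[sel])),
       n = n)
}
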