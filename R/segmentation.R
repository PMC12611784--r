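# Three-class tissue segmentation (MYO / CF / NCF) from dual-channel volumes,
# anatomical Boolean algebra, morphometry and radial/angular sector maps.

# Seed-aware connected components (26-neighborhood).
cc3d <- function(mask, connectivity = 26L) {
  .cc3d_label(as.logical(mask), as.integer(dim(mask)), as.integer(connectivity))
}

#' Segment the organ tissue from the two imaging channels
#'
#' The channels are min-max normalized and summed into a virtual "tissue"
#' channel, thresholded (Otsu by default), smoothed with the morphological
#' sequence erode(1), dilate(2), erode(2), dilate(2) (box kernels, radius in
#' voxels), and reduced to the largest seed-connected component. Everything
#' else is background.
#'
#' @param fluo,scatt \code{\link{volume3d}} channels on the same grid.
#' @param seeds optional matrix of voxel coordinates (rows = c(x, y, z)) known
#'   to lie in ventricular tissue; when omitted the largest component wins.
#' @param threshold optional absolute threshold on the summed normalized
#'   channel; default Otsu.
#' @return \code{\link{label_volume}} with tissue tagged MYO and the rest B.
#' @export
segment_tissue <- function(fluo, scatt, seeds = NULL, threshold = NULL) {
  stopifnot(inherits(fluo, "volume3d"), inherits(scatt, "volume3d"))
  if (!identical(dim(fluo$data), dim(scatt$data)))
    stop("channels are not on the same grid")
  norm01 <- function(a) {
    rng <- range(a)
    if (diff(rng) == 0) array(0, dim(a)) else (a - rng[1]) / diff(rng)
  }
  tc <- norm01(fluo$data) + norm01(scatt$data)
  if (is.null(threshold)) threshold <- otsu_threshold(tc)
  mask <- tc >= threshold
  if (!any(mask)) {
    q <- quantile(tc, c(0, .25, .5, .75, 1))
    stop(sprintf(
      "empty tissue mask at threshold %.4g (tissue-channel quantiles: %s)",
      threshold, paste(signif(q, 3), collapse = " ")))
  }
  mask <- dilate3(erode3(dilate3(erode3(mask, 1L), 2L), 2L), 2L)
  lab <- cc3d(mask)
  if (max(lab) == 0) stop("morphological smoothing removed all tissue")
  if (!is.null(seeds)) {
    seeds <- matrix(seeds, ncol = 3)
    ids <- unique(lab[seeds])
    ids <- ids[ids > 0]
    if (length(ids) == 0) stop("no seed falls inside the thresholded tissue")
  } else ids <- seq_len(max(lab))
  sizes <- tabulate(lab[lab > 0], max(lab))
  keep <- ids[which.max(sizes[ids])]
  tags <- array(0L, dim(mask))
  tags[lab == keep] <- .lv_codes[["MYO"]]
  label_volume(tags, fluo$voxel_um)
}

#' Apply the atrioventricular separation (AVS) slab
#'
#' A circular slab of the stated thickness through three non-collinear points
#' separates ventricular tissue from atrial remnants:
#' AVS = T AND S_circ; V = seed-connected component of (T - AVS); B = NOT(V);
#' T = V OR AVS. These identities hold exactly on the output.
#'
#' @param labels \code{\link{label_volume}} with a tissue segmentation.
#' @param p1,p2,p3 voxel coordinates c(x, y, z) of three non-collinear points
#'   on the separation plane.
#' @param thickness_um slab thickness (default 200).
#' @param seeds optional voxel coordinates inside the ventricles; default
#'   keeps the largest component of T - AVS.
#' @return updated \code{\link{label_volume}} with AVS tagged and severed
#'   tissue returned to background.
#' @export
apply_avs <- function(labels, p1, p2, p3, thickness_um = 200, seeds = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  n <- cross3(p2 - p1, p3 - p1)
  if (sqrt(sum(n^2)) < 1e-9) stop("the three points are collinear")
  n <- n / sqrt(sum(n^2))
  tis <- lv_mask(labels, "T")
  d <- dim(tis)
  X <- array(seq_len(d[1]), d)
  Y <- array(rep(seq_len(d[2]), each = d[1]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  dist_um <- abs((X - p1[1]) * n[1] + (Y - p1[2]) * n[2] + (Z - p1[3]) * n[3]) *
    labels$voxel_um
  slab <- dist_um <= thickness_um / 2
  avs <- tis & slab
  rest <- tis & !avs
  lab <- cc3d(rest)
  if (max(lab) > 0) {
    if (!is.null(seeds)) {
      seeds <- matrix(seeds, ncol = 3)
      ids <- unique(lab[seeds]); ids <- ids[ids > 0]
      if (length(ids) == 0) stop("no seed falls inside T - AVS")
    } else ids <- seq_len(max(lab))
    sizes <- tabulate(lab[lab > 0], max(lab))
    keep <- ids[which.max(sizes[ids])]
    v <- lab == keep
  } else v <- rest
  tags <- labels$tags
  tags[tis & !(v | avs)] <- .lv_codes[["B"]]
  tags[avs] <- .lv_codes[["AVS"]]
  label_volume(tags, labels$voxel_um)
}

# minimal 3-vector cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Segment compact fibrosis from the scattering channel
#'
#' CF is scattering signal at or above a fixed threshold inside tissue; at the
#' default of 10 (8-bit-scaled data) the scattering signal fills the voids the
#' dense scar leaves in the fluorescence channel.
#'
#' @param scatt scattering \code{\link{volume3d}}.
#' @param labels \code{\link{label_volume}} providing the tissue mask.
#' @param threshold absolute scattering threshold (default 10).
#' @return logical CF mask.
#' @export
segment_cf <- function(scatt, labels, threshold = 10) {
  stopifnot(inherits(scatt, "volume3d"), inherits(labels, "label_volume"))
  scatt$data >= threshold & lv_mask(labels, "T")
}

#' Calibrate the excess-collagen (EXC) threshold on control hearts
#'
#' For each control scattering volume, the candidate threshold whose EXC
#' volume fraction within tissue is closest to the target fraction is
#' selected; the returned threshold is the mean across volumes. The default
#' target of 2.5 percent matches the collagen fraction expected in healthy
#' murine ventricular myocardium.
#'
#' @param ctrl_scatts list of scattering \code{\link{volume3d}} (or one).
#' @param tissue_masks list of logical tissue masks (or one).
#' @param target_fraction target EXC volume fraction (default 0.025).
#' @return list with \code{threshold} (mean), \code{per_volume} thresholds and
#'   achieved \code{fractions}.
#' @export
calibrate_ncf_threshold <- function(ctrl_scatts, tissue_masks, target_fraction = 0.025) {
  if (inherits(ctrl_scatts, "volume3d")) ctrl_scatts <- list(ctrl_scatts)
  if (is.array(tissue_masks) || is.logical(tissue_masks)) tissue_masks <- list(tissue_masks)
  if (length(ctrl_scatts) == 0) stop("control set is empty")
  res <- mapply(function(sv, tm) {
    x <- sort(sv$data[tm])
    n <- length(x)
    cand <- unique(x)
    if (length(cand) < 2) stop("scattering channel is constant: target fraction unreachable")
    # fraction of voxels >= threshold, from first-occurrence positions in
    # the sorted sample (O(n log n) instead of per-candidate scans)
    first <- match(cand, x)
    frac <- (n - first + 1) / n
    i <- which.min(abs(frac - target_fraction))
    c(threshold = cand[i], fraction = frac[i])
  }, ctrl_scatts, tissue_masks)
  list(threshold = mean(res["threshold", ]),
       per_volume = unname(res["threshold", ]),
       fractions = unname(res["fraction", ]))
}

#' Segment non-compact fibrosis
#'
#' EXC is the scattering signal at or above the calibrated threshold inside
#' tissue; NCF = EXC AND NOT CF.
#'
#' @param scatt scattering \code{\link{volume3d}}.
#' @param threshold calibrated EXC threshold.
#' @param cf logical compact-fibrosis mask.
#' @param labels \code{\link{label_volume}} providing the tissue mask.
#' @return logical NCF mask.
#' @export
segment_ncf <- function(scatt, threshold, cf, labels) {
  exc <- scatt$data >= threshold & lv_mask(labels, "T")
  exc & !cf
}

#' Merge fibrosis masks into a label volume
#'
#' @param labels \code{\link{label_volume}}.
#' @param cf,ncf logical masks (mutually exclusive; CF wins on overlap).
#' @return updated \code{\link{label_volume}}.
#' @export
tag_fibrosis <- function(labels, cf, ncf) {
  tags <- labels$tags
  tis <- lv_mask(labels, "T")
  tags[ncf & tis] <- .lv_codes[["NCF"]]
  tags[cf & tis] <- .lv_codes[["CF"]]
  label_volume(tags, labels$voxel_um)
}

#' DICE similarity coefficient
#'
#' 2|A intersect B| / (|A| + |B|); two empty masks compare as 1.
#'
#' @param a,b logical arrays on the same grid.
#' @return value in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks are not on the same grid")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Volumetric morphometry of a label volume
#'
#' Volumes are voxel counts times the single-voxel volume in mm^3 (8e-6 mm^3
#' at 20 um pitch). Left-chamber dilation is the L_ch / T volume ratio;
#' fibrosis burdens are 100 x CF/T and 100 x NCF/T.
#'
#' @param labels \code{\link{label_volume}}.
#' @return list with \code{volumes_mm3} (named, incl. T),
#'   \code{dilation_ratio}, \code{pct_cf}, \code{pct_ncf}.
#' @export
morphometry <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  vvox <- (labels$voxel_um / 1000)^3
  counts <- vapply(names(.lv_codes), function(tag)
    sum(labels$tags == .lv_codes[[tag]]), 0)
  tcount <- sum(lv_mask(labels, "T"))
  if (tcount == 0) stop("tissue segmentation is empty")
  vols <- c(counts, T = tcount) * vvox
  list(volumes_mm3 = vols,
       dilation_ratio = unname(vols["L_ch"] / vols["T"]),
       pct_cf = unname(100 * counts["CF"] / tcount),
       pct_ncf = unname(100 * counts["NCF"] / tcount))
}

#' Left-ventricular wall thickness by ray casting
#'
#' The ventricle (z = long axis, slice 1 = apex) is split into three equally
#' thick portions of the chamber extent; at the central transverse plane of
#' the requested portion, rays are cast from the chamber centroid: six rays
#' 60 degrees apart for the basal and mid-cavity levels, four rays 90 degrees
#' apart for the apical level (angle 0 = +x). Thickness is the distance from
#' the endocardial to the epicardial crossing of the first contiguous tissue
#' run; rays that never meet tissue give NaN.
#'
#' @param labels \code{\link{label_volume}} with L_ch tagged.
#' @param level one of "basal", "mid", "apical".
#' @return data.frame with \code{angle_deg} and \code{thickness_um}.
#' @export
wall_thickness <- function(labels, level = c("basal", "mid", "apical")) {
  level <- match.arg(level)
  stopifnot(inherits(labels, "label_volume"))
  lch <- lv_mask(labels, "L_ch")
  if (!any(lch)) stop("no left chamber (L_ch) present")
  tis <- lv_mask(labels, "T")
  zs <- which(apply(lch, 3, any))
  z0 <- min(zs); z1 <- max(zs)
  third <- (z1 - z0 + 1) / 3
  zc <- switch(level,
               apical = z0 + third / 2,
               mid    = z0 + 1.5 * third,
               basal  = z0 + 2.5 * third)
  zc <- max(1L, min(dim(tis)[3], round(zc)))
  angles <- if (level == "apical") seq(0, 270, by = 90) else seq(0, 300, by = 60)
  sl_t <- tis[, , zc]
  sl_c <- lch[, , zc]
  if (!any(sl_c)) return(data.frame(angle_deg = angles, thickness_um = NaN))
  idx <- which(sl_c, arr.ind = TRUE)
  ctr <- colMeans(idx)
  nx <- nrow(sl_t); ny <- ncol(sl_t)
  step <- 0.25
  rmax <- sqrt(nx^2 + ny^2)
  thick <- vapply(angles, function(a) {
    th <- a * pi / 180
    rs <- seq(0, rmax, by = step)
    px <- round(ctr[1] + rs * cos(th))
    py <- round(ctr[2] + rs * sin(th))
    ok <- px >= 1 & px <= nx & py >= 1 & py <= ny
    inside <- rep(FALSE, length(rs))
    inside[ok] <- sl_t[cbind(px[ok], py[ok])]
    ent <- which(inside)[1]
    if (is.na(ent)) return(NaN)
    ex <- which(!inside & seq_along(inside) > ent)[1]
    if (is.na(ex)) return(NaN)  # ray leaves the volume while still in tissue
    (rs[ex] - rs[ent]) * labels$voxel_um
  }, 0)
  data.frame(angle_deg = angles, thickness_um = thick)
}

#' Radial/angular sector map of a volume
#'
#' The volume is recentred on the fluorescence center of mass; on the central
#' transverse plane the smallest and largest circles containing nonzero
#' reference signal give the endocardial (r) and epicardial (R) radii. The
#' quantified intensity is mean-projected along the long axis, min-max
#' rescaled to 0-255 (8-bit average transversal view), and summed over a
#' 16 (radial, between r and R) x 16 (angular) polar grid. Raw (unrescaled)
#' sums are kept alongside.
#'
#' @param intensity 3D array (or \code{volume3d} or logical mask) to quantify.
#' @param reference fluorescence \code{\link{volume3d}} (or array) used for
#'   recentring and radii detection.
#' @return object of class \code{sector_map}: 16 x 16 matrices
#'   \code{sectors} (8-bit scale) and \code{sectors_raw}, radii \code{r},
#'   \code{R} (voxels), annulus mask and projections.
#' @export
sector_map <- function(intensity, reference) {
  if (inherits(intensity, "volume3d")) intensity <- intensity$data
  if (is.logical(intensity)) intensity <- intensity + 0
  if (inherits(reference, "volume3d")) reference <- reference$data
  if (!identical(dim(intensity), dim(reference))) stop("grids differ")
  d <- dim(reference)
  # recentre on the fluorescence center of mass (integer shift)
  tot <- sum(reference)
  if (tot <= 0) stop("reference has no signal")
  idx <- which(reference > 0, arr.ind = TRUE)
  wts <- reference[reference > 0]
  com <- colSums(idx * wts) / sum(wts)
  ctr <- (d + 1) / 2
  sh <- round(ctr - com)
  reference <- shift3(reference, sh[1], sh[2], sh[3], fill = 0)
  intensity <- shift3(intensity, sh[1], sh[2], sh[3], fill = 0)

  zc <- max(1L, round(d[3] / 2))
  plane <- reference[, , zc]
  nz <- which(plane > 0, arr.ind = TRUE)
  if (nrow(nz) == 0) stop("no nonzero voxels on the central transverse plane")
  rad <- round(sqrt((nz[, 1] - ctr[1])^2 + (nz[, 2] - ctr[2])^2))
  r <- min(rad); R <- max(rad)
  if (r >= R) stop("degenerate annulus (r >= R) on the central plane")

  proj_raw <- apply(intensity, c(1, 2), mean)
  rng <- range(proj_raw)
  proj8 <- if (diff(rng) == 0) proj_raw * 0 else
    (proj_raw - rng[1]) / diff(rng) * 255

  X <- matrix(seq_len(d[1]), d[1], d[2])
  Y <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  rr <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2)
  ang <- atan2(Y - ctr[2], X - ctr[1]) %% (2 * pi)
  sel <- rr >= r & rr <= R
  rbin <- pmin(16L, pmax(1L, floor((rr - r) / (R - r) * 16) + 1L))
  abin <- pmin(16L, floor(ang / (2 * pi) * 16) + 1L)

  sec <- function(p) {
    m <- matrix(0, 16, 16)
    tb <- tapply(p[sel], list(factor(rbin[sel], 1:16), factor(abin[sel], 1:16)), sum)
    tb[is.na(tb)] <- 0
    m[] <- tb
    m
  }
  structure(list(sectors = sec(proj8), sectors_raw = sec(proj_raw),
                 r = r, R = R, annulus = sel,
                 projection = proj_raw, projection_8bit = proj8),
            class = "sector_map")
}

#' @export
print.sector_map <- function(x, ...) {
  cat(sprintf("sector_map: 16 x 16 sectors, r = %g, R = %g voxels\n", x$r, x$R))
  invisible(x)
}

#' Group-average sector maps
#'
#' The average endocardial and epicardial radii are the arithmetic means of
#' the per-sample radii; because each sample's sector grid is already radially
#' normalized between its own r and R, sector bins align across samples and
#' are averaged element-wise on the common (mean-radius) annulus.
#'
#' @param maps list of \code{\link{sector_map}} objects.
#' @return \code{sector_map} with averaged sectors and mean radii.
#' @export
average_sector_maps <- function(maps) {
  stopifnot(length(maps) > 0, all(vapply(maps, inherits, TRUE, "sector_map")))
  avg <- function(field) Reduce(`+`, lapply(maps, `[[`, field)) / length(maps)
  structure(list(sectors = avg("sectors"), sectors_raw = avg("sectors_raw"),
                 r = mean(vapply(maps, `[[`, 0, "r")),
                 R = mean(vapply(maps, `[[`, 0, "R")),
                 annulus = NULL, projection = NULL, projection_8bit = NULL),
            class = "sector_map")
}
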