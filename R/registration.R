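# Morpho-functional co-registration: find the 3D pose whose mean-intensity
# projection best matches the optical-mapping silhouette, score by average
# edge distance, and project 2D functional maps onto the tissue surface.
#
# Conventions: volume axes (x, y, z) with z the longitudinal axis; theta
# rotates about z, then phi about x; projections are means along the viewing
# axis y, giving images indexed [x, z].

# Rotate a 3D array about its center: theta about z, then phi about x
# (degrees), trilinear interpolation, zero fill.
rotate_volume <- function(a, theta_deg, phi_deg) {
  d <- dim(a)
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  ctr <- (d + 1) / 2
  idx <- arrayInd(seq_along(a), d)
  p <- sweep(idx, 2, ctr)
  # inverse map: undo phi (about x), then theta (about z)
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3, 3)
  Rinv <- t(Rx %*% Rz)          # forward rotation Rx(phi) %*% Rz(theta)
  q <- p %*% t(Rinv)
  q <- sweep(q, 2, ctr, `+`)
  x0 <- floor(q[, 1]); y0 <- floor(q[, 2]); z0 <- floor(q[, 3])
  fx <- q[, 1] - x0; fy <- q[, 2] - y0; fz <- q[, 3] - z0
  val <- numeric(nrow(q))
  at <- function(xi, yi, zi) {
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    v <- numeric(length(xi))
    v[ok] <- a[cbind(xi[ok], yi[ok], zi[ok])]
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
    val <- val + w * at(x0 + dx, y0 + dy, z0 + dz)
  }
  array(val, d)
}

#' Average-intensity projection of a posed volume
#'
#' Rotates the volume by theta (about the longitudinal z axis) then phi
#' (about the transverse x axis) and mean-projects along the viewing axis.
#'
#' @param vol \code{\link{volume3d}} or 3D array.
#' @param theta_deg,phi_deg pose angles in degrees.
#' @return matrix image indexed [x, z].
#' @export
project_silhouette <- function(vol, theta_deg = 0, phi_deg = 0) {
  a <- if (inherits(vol, "volume3d")) vol$data else vol
  if (!all(is.finite(c(theta_deg, phi_deg)))) stop("pose angles must be finite")
  if (theta_deg != 0 || phi_deg != 0) a <- rotate_volume(a, theta_deg, phi_deg)
  apply(a, c(1, 3), mean)
}

# --- 2D helpers -------------------------------------------------------------

# binary foreground of a projection (fraction of max; projections of padded
# volumes have true zero background)
.segment2d <- function(img, frac = 0.05) {
  m <- max(img)
  if (m <= 0) stop("empty foreground: image has no signal")
  img > frac * m
}

# principal-axis angle of a foreground mask (second moments), radians
.principal_angle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  mu <- colMeans(idx)
  cx <- idx[, 1] - mu[1]; cy <- idx[, 2] - mu[2]
  0.5 * atan2(2 * mean(cx * cy), mean(cx^2) - mean(cy^2))
}

# rotate a binary mask by `ang` radians about its centroid (nearest neighbor)
.rot2_mask <- function(mask, ang) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(mask)
  mu <- colMeans(idx)
  out <- matrix(FALSE, d[1], d[2])
  allidx <- arrayInd(seq_along(out), d)
  p <- sweep(allidx, 2, mu)
  q <- cbind(cos(ang) * p[, 1] + sin(ang) * p[, 2],
             -sin(ang) * p[, 1] + cos(ang) * p[, 2])
  q <- round(sweep(q, 2, mu, `+`))
  ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2]
  out[allidx[ok, , drop = FALSE]] <- mask[q[ok, , drop = FALSE]]
  out
}

# edge pixels: foreground with at least one 4-neighbor background
.edges2d <- function(mask) {
  d <- dim(mask)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- mask
  nb <- pad[1:d[1], 2:(d[2] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1)] &
    pad[2:(d[1] + 1), 1:d[2]] & pad[2:(d[1] + 1), 3:(d[2] + 2)]
  mask & !nb
}

# Euclidean distance-to-edge map on a padded canvas; returns list(dt, off)
# where dt[i + off, j + off] is the distance at original coords (i, j).
.edge_dt <- function(edge_idx, dims, pad = 40L) {
  canvas <- matrix(1, dims[1] + 2L * pad, dims[2] + 2L * pad)
  pts <- edge_idx + pad
  keep <- pts[, 1] >= 1 & pts[, 1] <= nrow(canvas) &
    pts[, 2] >= 1 & pts[, 2] <= ncol(canvas)
  canvas[pts[keep, , drop = FALSE]] <- 0
  dt <- EBImage::distmap(canvas, metric = "euclidean")
  list(dt = as.matrix(dt), off = pad)
}

# mean lookup of a distance map at (possibly offset) points
.dt_lookup <- function(dtobj, pts) {
  p <- round(pts) + dtobj$off
  p[, 1] <- pmin(pmax(p[, 1], 1L), nrow(dtobj$dt))
  p[, 2] <- pmin(pmax(p[, 2], 1L), ncol(dtobj$dt))
  mean(dtobj$dt[p])
}

# Preprocess a projection or camera image into aligned edge coordinates:
# segment, realign the long axis to the row direction, crop the upper part of
# the long axis, extract edges, express relative to the foreground centroid.
.edge_pipeline <- function(img, crop_frac = 0.4, realign = TRUE) {
  m <- .segment2d(img)
  if (realign) {
    ang <- .principal_angle(m)
    m <- .rot2_mask(m, ang)
  }
  if (crop_frac > 0) {
    ncut <- floor(nrow(m) * crop_frac)
    if (ncut > 0) m[seq_len(ncut), ] <- FALSE
    if (!any(m)) stop("cropping removed all foreground")
  }
  idx <- which(m, arr.ind = TRUE)
  ctr <- colMeans(idx)
  e <- which(.edges2d(m), arr.ind = TRUE)
  list(edges = sweep(e, 2, ctr), dims = dim(m))
}

#' Average edge distance between two silhouettes under a rigid search
#'
#' Both images are segmented, long-axis realigned (principal axis of the
#' foreground second moments), cropped of the upper portion of the long axis,
#' centroid-aligned, and reduced to their edges. A grid of rigid transforms
#' (rotations -30..30 degrees in 5-degree steps; translations -20..20 pixels
#' in 5-pixel steps on both axes) is applied to the first edge set and the
#' symmetric average nearest-neighbor edge distance (average Hausdorff
#' distance) is minimized; the classical max-Hausdorff is available via
#' \code{method = "max"}.
#'
#' @param proj projection image (source, e.g. posed tomogram projection).
#' @param target camera image or silhouette (reference grid).
#' @param pitch_um pixel pitch of the target image (converts the score to
#'   micrometres).
#' @param rot_deg,trans_px rigid search grids.
#' @param crop_frac fraction of the long axis cropped from the top.
#' @param realign realign long axes before matching (default TRUE).
#' @param method \code{"mean"} (average Hausdorff, default) or \code{"max"}.
#' @return list with \code{distance_um} (grid minimum), the best
#'   \code{rotation_deg} and \code{translation_px}.
#' @export
silhouette_distance <- function(proj, target, pitch_um = 78,
                                rot_deg = seq(-30, 30, by = 5),
                                trans_px = seq(-20, 20, by = 5),
                                crop_frac = 0.4, realign = TRUE,
                                method = c("mean", "max")) {
  method <- match.arg(method)
  src <- .edge_pipeline(proj, crop_frac, realign)
  tgt <- .edge_pipeline(target, crop_frac, realign)
  dims <- pmax(src$dims, tgt$dims)
  half <- (dims + 1) / 2
  tgt_abs <- sweep(tgt$edges, 2, half, `+`)
  dt_t <- .edge_dt(round(tgt_abs), dims)
  best <- list(score = Inf, rot = NA_real_, tr = c(NA_real_, NA_real_))
  for (r in rot_deg) {
    a <- r * pi / 180
    Rm <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    se <- src$edges %*% t(Rm)
    se_abs <- sweep(se, 2, half, `+`)
    dt_s <- .edge_dt(round(se_abs), dims)
    for (tx in trans_px) for (ty in trans_px) {
      moved <- sweep(se_abs, 2, c(tx, ty), `+`)
      d_ab <- .dt_lookup(dt_t, moved)
      d_ba <- .dt_lookup(dt_s, sweep(tgt_abs, 2, c(tx, ty), `-`))
      sc <- if (method == "mean") (d_ab + d_ba) / 2 else max(d_ab, d_ba)
      if (sc < best$score) best <- list(score = sc, rot = r, tr = c(tx, ty))
    }
  }
  list(distance_um = best$score * pitch_um,
       rotation_deg = best$rot, translation_px = best$tr)
}

#' Exhaustive pose search matching a volume to a target silhouette
#'
#' Projects the volume at every (theta, phi) on the search grid (default
#' -40..40 degrees in 10-degree steps on both axes), scores each projection
#' against the target with \code{\link{silhouette_distance}}, and returns the
#' score grid with the arg-minimum pose. Ties are broken deterministically:
#' smallest |theta|, then |phi|, then raster order.
#'
#' @param vol \code{\link{volume3d}} or 3D array.
#' @param target target 2D image.
#' @param theta_grid,phi_grid pose grids in degrees.
#' @param pitch_um target pixel pitch.
#' @param ... passed to \code{\link{silhouette_distance}}.
#' @return object of class \code{pose_search}: \code{scores_um} matrix
#'   (theta x phi), per-cell best rigid transforms, and \code{best} pose.
#' @export
find_pose <- function(vol, target, theta_grid = seq(-40, 40, by = 10),
                      phi_grid = seq(-40, 40, by = 10), pitch_um = 78, ...) {
  scores <- matrix(NA_real_, length(theta_grid), length(phi_grid),
                   dimnames = list(theta_grid, phi_grid))
  rigid <- vector("list", length(scores))
  dim(rigid) <- dim(scores)
  for (i in seq_along(theta_grid)) for (j in seq_along(phi_grid)) {
    pr <- project_silhouette(vol, theta_grid[i], phi_grid[j])
    sd_ <- silhouette_distance(pr, target, pitch_um = pitch_um, ...)
    scores[i, j] <- sd_$distance_um
    rigid[[i, j]] <- list(rotation_deg = sd_$rotation_deg,
                          translation_px = sd_$translation_px)
  }
  cand <- expand.grid(i = seq_along(theta_grid), j = seq_along(phi_grid))
  cand$score <- scores[cbind(cand$i, cand$j)]
  cand$ath <- abs(theta_grid[cand$i]); cand$aph <- abs(phi_grid[cand$j])
  ord <- order(cand$score, cand$ath, cand$aph, cand$j, cand$i)
  b <- cand[ord[1], ]
  structure(list(scores_um = scores, rigid = rigid,
                 best = list(theta_deg = theta_grid[b$i], phi_deg = phi_grid[b$j],
                             score_um = b$score,
                             rigid = rigid[[b$i, b$j]])),
            class = "pose_search")
}

#' @export
print.pose_search <- function(x, ...) {
  cat(sprintf("pose_search: best (theta, phi) = (%g, %g) deg, score %.2f um\n",
              x$best$theta_deg, x$best$phi_deg, x$best$score_um))
  invisible(x)
}

#' Project a 2D functional map onto the posed tissue surface
#'
#' The volume is posed, and each viewing ray (fixed x, z) is walked along the
#' viewing axis until the first tissue voxel that has at least one background
#' neighbor; the functional value at the ray's (x, z) position (nearest-pixel
#' lookup after scaling the map onto the projection grid) is assigned there.
#'
#' @param map2d \code{\link{scalar_map2d}} or matrix on the projection grid.
#' @param vol \code{\link{volume3d}} or 3D array.
#' @param pose list with \code{theta_deg}, \code{phi_deg}.
#' @param threshold tissue threshold on the posed volume (fraction of max).
#' @return data.frame with surface voxel coordinates (x, y, z, posed frame)
#'   and the assigned \code{value}.
#' @export
map_to_surface <- function(map2d, vol, pose, threshold = 0.05) {
  a <- if (inherits(vol, "volume3d")) vol$data else vol
  vals <- if (inherits(map2d, "scalar_map2d")) map2d$values else map2d
  if (pose$theta_deg != 0 || pose$phi_deg != 0)
    a <- rotate_volume(a, pose$theta_deg, pose$phi_deg)
  tis <- a > threshold * max(a)
  d <- dim(tis)
  bg_nb <- !tis |
    shift3(!tis, 1, 0, 0, TRUE) | shift3(!tis, -1, 0, 0, TRUE) |
    shift3(!tis, 0, 1, 0, TRUE) | shift3(!tis, 0, -1, 0, TRUE) |
    shift3(!tis, 0, 0, 1, TRUE) | shift3(!tis, 0, 0, -1, TRUE)
  surf <- tis & bg_nb
  out <- vector("list", d[1] * d[3])
  n <- 0L
  for (x in seq_len(d[1])) for (z in seq_len(d[3])) {
    ys <- which(tis[x, , z])
    if (length(ys) == 0) next
    y <- ys[1]
    if (!surf[x, y, z]) next
    mi <- round((x - 0.5) / d[1] * nrow(vals) + 0.5)
    mj <- round((z - 0.5) / d[3] * ncol(vals) + 0.5)
    mi <- min(max(mi, 1L), nrow(vals)); mj <- min(max(mj, 1L), ncol(vals))
    n <- n + 1L
    out[[n]] <- c(x, y, z, vals[mi, mj])
  }
  m <- do.call(rbind, out[seq_len(n)])
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3], value = m[, 4])
}
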