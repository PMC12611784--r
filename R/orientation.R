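# Structure-tensor estimation of locally prevailing cardiomyocyte
# orientation, fractional-anisotropy gating, and helix angles.

# Central-difference gradient of a 3D array (second-order accurate in the
# interior, one-sided at the borders). Returns list(gx, gy, gz).
grad3 <- function(a) {
  d <- dim(a)
  cd <- function(ax) {
    n <- d[ax]
    ip <- c(2:n, n); im <- c(1, 1:(n - 1))
    den <- array(2, d)
    # one-sided at the two border slices
    idx_first <- slice.index(a, ax) == 1
    idx_last <- slice.index(a, ax) == n
    den[idx_first | idx_last] <- 1
    hi <- switch(ax, a[ip, , , drop = FALSE], a[, ip, , drop = FALSE], a[, , ip, drop = FALSE])
    lo <- switch(ax, a[im, , , drop = FALSE], a[, im, , drop = FALSE], a[, , im, drop = FALSE])
    (hi - lo) / den
  }
  list(gx = cd(1), gy = cd(2), gz = cd(3))
}

#' Per-voxel 3D structure tensors
#'
#' S = grad(I) grad(I)^T, each of the six independent components smoothed with
#' an isotropic Gaussian of standard deviation \code{sigma} voxels (first-order
#' derivatives by second-order accurate central differences). The result is
#' symmetric positive semidefinite at every voxel up to roundoff.
#'
#' @param vol \code{\link{volume3d}} (fluorescence channel) or 3D array.
#' @param sigma Gaussian smoothing SD in voxels (default 1; 0 disables).
#' @return list of six component arrays \code{sxx, syy, szz, sxy, sxz, syz}
#'   plus \code{voxel_um}.
#' @export
structure_tensor_field <- function(vol, sigma = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  voxel_um <- if (inherits(vol, "volume3d")) vol$voxel_um else NA_real_
  a <- if (inherits(vol, "volume3d")) vol$data else vol
  if (any(dim(a) < 3)) stop("volume must be at least 3 voxels per axis")
  g <- grad3(a)
  sm <- function(x) gauss_smooth3(x, sigma)
  list(sxx = sm(g$gx * g$gx), syy = sm(g$gy * g$gy), szz = sm(g$gz * g$gz),
       sxy = sm(g$gx * g$gy), sxz = sm(g$gx * g$gz), syz = sm(g$gy * g$gz),
       voxel_um = voxel_um)
}

#' Fractional anisotropy of a tensor's eigenvalues
#'
#' FA = sqrt(1/2) * sqrt((l1-l2)^2 + (l2-l3)^2 + (l1-l3)^2) /
#' sqrt(l1^2 + l2^2 + l3^2). Zero for isotropy, one when a single eigenvalue
#' dominates.
#'
#' @param l1,l2,l3 eigenvalues (>= 0, not all zero).
#' @return FA in [0, 1].
#' @export
fractional_anisotropy <- function(l1, l2, l3) {
  ss <- l1^2 + l2^2 + l3^2
  if (any(ss == 0)) stop("FA undefined for all-zero eigenvalues")
  sqrt(0.5) * sqrt((l1 - l2)^2 + (l2 - l3)^2 + (l1 - l3)^2) / sqrt(ss)
}

#' Block-wise prevailing orientation from per-voxel structure tensors
#'
#' Voxel tensors are averaged over non-overlapping cubic blocks (16^3 voxels
#' by default, i.e. a 96-um analysis grid at 6-um pitch); the mean tensor is
#' spectrally decomposed and the unit eigenvector of the smallest eigenvalue
#' (the direction of least fluorescence-gradient variability) is the local
#' fiber orientation. Blocks with FA below \code{fa_threshold}, or with a
#' degenerate smallest eigenpair, are marked invalid. Partial border blocks
#' are completed by reflection padding.
#'
#' @param tensors output of \code{\link{structure_tensor_field}}.
#' @param block block edge length in voxels (default 16).
#' @param fa_threshold validity gate on FA (default 0.25).
#' @param degeneracy_tol relative tolerance separating the two smallest
#'   eigenvalues (default 1e-6).
#' @return \code{\link{orientation_field}}; invalid blocks carry NA vectors
#'   and a reason in \code{attr(, "invalid_reason")}.
#' @export
block_orientation <- function(tensors, block = 16L, fa_threshold = 0.25,
                              degeneracy_tol = 1e-6) {
  d <- dim(tensors$sxx)
  nb <- ceiling(d / block)
  pad_to <- nb * block
  refl_pad <- function(a) {
    for (ax in 1:3) {
      need <- pad_to[ax] - dim(a)[ax]
      if (need > 0) {
        n <- dim(a)[ax]
        idx <- c(seq_len(n), n - seq_len(need) + 1L)  # reflect the tail
        a <- switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                    a[, , idx, drop = FALSE])
      }
    }
    a
  }
  comp <- lapply(tensors[c("sxx", "syy", "szz", "sxy", "sxz", "syz")], refl_pad)
  block_mean <- function(a) {
    # collapse each block x/y/z run by mean
    dim(a) <- c(block, nb[1], block, nb[2], block, nb[3])
    apply(a, c(2, 4, 6), mean)
  }
  bm <- lapply(comp, block_mean)
  vecs <- array(NA_real_, c(nb, 3))
  fa <- array(NA_real_, nb)
  mask <- array(FALSE, nb)
  reason <- array(NA_character_, nb)
  for (i in seq_len(nb[1])) for (j in seq_len(nb[2])) for (k in seq_len(nb[3])) {
    S <- matrix(c(bm$sxx[i, j, k], bm$sxy[i, j, k], bm$sxz[i, j, k],
                  bm$sxy[i, j, k], bm$syy[i, j, k], bm$syz[i, j, k],
                  bm$sxz[i, j, k], bm$syz[i, j, k], bm$szz[i, j, k]), 3, 3)
    if (all(S == 0)) { reason[i, j, k] <- "zero tensor"; next }
    e <- eigen(S, symmetric = TRUE)        # eigenvalues descending
    l <- pmax(e$values, 0)
    if (sum(l) == 0) { reason[i, j, k] <- "zero tensor"; next }
    fa[i, j, k] <- fractional_anisotropy(l[1], l[2], l[3])
    if (fa[i, j, k] < fa_threshold) { reason[i, j, k] <- "low FA"; next }
    if ((l[2] - l[3]) <= degeneracy_tol * l[1]) {
      reason[i, j, k] <- "degenerate smallest eigenspace"; next
    }
    v <- e$vectors[, 3]
    vecs[i, j, k, ] <- v / sqrt(sum(v^2))
    mask[i, j, k] <- TRUE
  }
  pitch <- if (is.na(tensors$voxel_um)) NA_real_ else block * tensors$voxel_um
  of <- orientation_field(vecs, fa, mask, pitch)
  attr(of, "invalid_reason") <- reason
  of
}

#' Helix angle of an orientation vector
#'
#' Signed angle of the vector's projection onto the circumferential /
#' apico-basal plane, measured from the circumferential axis, in
#' (-90, 90] degrees. NaN when the vector is perpendicular to that plane.
#'
#' @param v unit orientation vector (3).
#' @param e_t,e_n,e_l orthonormal local axes: transmural, apico-basal,
#'   circumferential.
#' @param tol in-plane magnitude below which the angle is undefined.
#' @return helix angle in degrees.
#' @export
helix_angle <- function(v, e_t, e_n, e_l, tol = 1e-8) {
  cl <- sum(v * e_l); cn <- sum(v * e_n)
  if (cl^2 + cn^2 < tol^2) return(NaN)
  a <- atan2(cn, cl) * 180 / pi
  # axial data: fold into (-90, 90]
  if (a > 90) a <- a - 180
  if (a <= -90) a <- a + 180
  if (a == -90) a <- 90
  a
}

#' Helix-angle grid for an orientation field with per-block axes
#'
#' @param of \code{\link{orientation_field}}.
#' @param axes list of 4D arrays \code{e_t}, \code{e_n}, \code{e_l} on the
#'   block grid (same first three dims as \code{of$fa}, last dim 3).
#' @return \code{orientation_field} with \code{helix_deg} filled.
#' @export
helix_angle_field <- function(of, axes) {
  nb <- dim(of$fa)
  hx <- array(NA_real_, nb)
  for (i in seq_len(nb[1])) for (j in seq_len(nb[2])) for (k in seq_len(nb[3])) {
    if (!of$mask[i, j, k]) next
    hx[i, j, k] <- helix_angle(of$vectors[i, j, k, ],
                               axes$e_t[i, j, k, ], axes$e_n[i, j, k, ],
                               axes$e_l[i, j, k, ])
  }
  of$helix_deg <- hx
  of
}

#' Analytic local axes for annular (ring-phantom) geometry on a block grid
#'
#' Transmural = radial, apico-basal = +z, circumferential = tangential, for a
#' volume whose long axis is z and whose annulus axis passes through the x/y
#' center of the grid.
#'
#' @param dim_vox volume dimensions in voxels c(nx, ny, nz).
#' @param block block size used by \code{\link{block_orientation}}.
#' @return list of 4D arrays \code{e_t}, \code{e_n}, \code{e_l} on the block
#'   grid.
#' @export
annulus_block_axes <- function(dim_vox, block = 16L) {
  nb <- ceiling(dim_vox / block)
  ctr <- (dim_vox[1:2] + 1) / 2
  e_t <- e_n <- e_l <- array(0, c(nb, 3))
  for (i in seq_len(nb[1])) for (j in seq_len(nb[2])) {
    bx <- (i - 0.5) * block; by <- (j - 0.5) * block
    phi <- atan2(by - ctr[2], bx - ctr[1])
    for (k in seq_len(nb[3])) {
      e_t[i, j, k, ] <- c(cos(phi), sin(phi), 0)
      e_n[i, j, k, ] <- c(0, 0, 1)
      e_l[i, j, k, ] <- c(-sin(phi), cos(phi), 0)
    }
  }
  list(e_t = e_t, e_n = e_n, e_l = e_l)
}
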