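# Cellular-disarray quantification: circular-aware smoothing of the fiber
# angle field and disarray as deviation from the dominant direction.
#
# Fiber directions are axial (f and -f identical), so the angle alpha in
# [-pi/2, pi/2) is doubled into eta = (cos 2a, sin 2a) before smoothing. The
# dominant direction solves the screened-Poisson (Helmholtz) problem
# -delta^2 Lap(eta_bar) + eta_bar = eta with zero-flux boundaries; delta is
# the characteristic smoothing length.

# Sparse (I - delta^2 Lap) operator on the masked grid, zero-flux (Neumann)
# boundaries, finite differences with spacing h. Returns a dgCMatrix over the
# masked nodes in `which(mask)` order.
helmholtz_operator <- function(mask, delta, h) {
  d <- dim(mask); if (is.null(d)) d <- length(mask)
  nd <- length(d)
  idx <- array(0L, d)
  nodes <- which(mask)
  if (length(nodes) == 0) stop("empty mask")
  idx[nodes] <- seq_along(nodes)
  c2 <- (delta / h)^2
  ii <- jj <- integer(0); xx <- numeric(0)
  diagv <- rep(1, length(nodes))
  coords <- arrayInd(nodes, .dim = d)
  for (ax in seq_len(nd)) for (s in c(-1L, 1L)) {
    nb <- coords
    nb[, ax] <- nb[, ax] + s
    ok <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
    lin <- rep(NA_integer_, nrow(nb))
    lin[ok] <- as.integer((nb[ok, , drop = FALSE] - 1) %*%
                            cumprod(c(1, d[-nd]))) + 1L
    inmask <- ok & mask[ifelse(is.na(lin), 1L, lin)] & !is.na(lin)
    # neighbor present: -c2 off-diagonal, +c2 on diagonal; absent: zero flux
    diagv[inmask] <- diagv[inmask] + c2
    ii <- c(ii, which(inmask))
    jj <- c(jj, idx[lin[inmask]])
    xx <- c(xx, rep(-c2, sum(inmask)))
  }
  n <- length(nodes)
  Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                       x = c(diagv, xx), dims = c(n, n))
}

#' Helmholtz (Laplacian) smoothing of a scalar grid field
#'
#' Solves -delta^2 Lap(u_bar) + u_bar = u on the masked domain with
#' homogeneous natural (zero-flux) boundary conditions, by symmetric sparse
#' finite differences. delta = 0 returns the input unchanged.
#'
#' @param u numeric array (1D, 2D or 3D grid).
#' @param delta_um characteristic smoothing length (same units as
#'   \code{pitch_um}).
#' @param pitch_um grid spacing.
#' @param mask optional logical array; values outside are untouched (NA in
#'   the output).
#' @return smoothed array of the same shape.
#' @export
laplacian_smooth <- function(u, delta_um, pitch_um, mask = NULL) {
  if (delta_um < 0) stop("delta must be >= 0")
  d <- dim(u); if (is.null(d)) d <- length(u)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!any(mask)) stop("empty mask")
  if (delta_um == 0) {
    out <- array(NA_real_, d); out[mask] <- u[mask]
    if (is.null(dim(u))) out <- as.vector(out)
    return(out)
  }
  A <- helmholtz_operator(mask, delta_um, pitch_um)
  b <- u[which(mask)]
  sol <- as.vector(Matrix::solve(A, b))
  res <- sqrt(sum((as.vector(A %*% sol) - b)^2)) / max(1e-30, sqrt(sum(b^2)))
  if (is.finite(res) && res > 1e-8)
    warning(sprintf("Helmholtz solve residual %.2e above 1e-8", res))
  out <- array(NA_real_, d)
  out[which(mask)] <- sol
  if (is.null(dim(u))) out <- as.vector(out)
  out
}

# canonicalize angles to [-pi/2, pi/2)
canonical_alpha <- function(alpha) {
  ((alpha + pi / 2) %% pi) - pi / 2
}

#' Cellular disarray of a fiber-angle field
#'
#' The angle field is doubled into eta = (cos 2a, sin 2a) (making f and -f
#' identical), each component is Helmholtz-smoothed with characteristic
#' length \code{delta_um} (default 300 um, the dominant-direction scale), the
#' smoothed pair is renormalized and the dominant angle recovered as
#' a_bar = atan2(eta2_bar, eta1_bar) / 2. Local disarray is the deviation of
#' alpha from a_bar, minimized over the equivalent representations
#' alpha + k*pi, k in {-1, 0, 1}; it lies in [0, 90] degrees.
#'
#' @param alpha fiber-angle grid in radians; values are canonicalized to
#'   [-pi/2, pi/2). Non-finite values inside the mask are an error.
#' @param pitch_um grid spacing in micrometres.
#' @param delta_um smoothing length (default 300).
#' @param mask optional logical validity mask.
#' @return list with \code{disarray_deg}, \code{alpha_bar} (radians),
#'   \code{eta_bar} (list of the two smoothed components) and the inputs'
#'   \code{mask}.
#' @export
disarray_map <- function(alpha, pitch_um, delta_um = 300, mask = NULL) {
  d <- dim(alpha); if (is.null(d)) d <- length(alpha)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (any(!is.finite(alpha[mask]))) stop("non-finite angles inside the mask")
  alpha <- canonical_alpha(alpha)
  c2 <- cos(2 * alpha); s2 <- sin(2 * alpha)
  cb <- laplacian_smooth(c2, delta_um, pitch_um, mask)
  sb <- laplacian_smooth(s2, delta_um, pitch_um, mask)
  nrm <- sqrt(cb^2 + sb^2)
  nz <- is.finite(nrm) & nrm > 1e-12
  cb[nz] <- cb[nz] / nrm[nz]; sb[nz] <- sb[nz] / nrm[nz]
  # atan2(sin-component, cos-component): smoothing a constant field must
  # return the same angle
  ab <- array(NA_real_, d)
  ab[nz] <- 0.5 * atan2(sb[nz], cb[nz])
  dis <- array(NA_real_, d)
  ok <- nz & mask
  ks <- c(-1, 0, 1)
  devs <- vapply(ks, function(k) abs((alpha + k * pi) - ab), alpha)
  dim(devs) <- c(length(alpha), 3)
  dis[ok] <- apply(devs[which(ok), , drop = FALSE], 1, min) * 180 / pi
  list(disarray_deg = dis, alpha_bar = ab,
       eta_bar = list(cos2 = cb, sin2 = sb), mask = mask)
}

#' Region summaries of a disarray map
#'
#' @param dis output of \code{\link{disarray_map}}.
#' @param regions named list of logical masks (e.g. NCF, near-CF, remote).
#' @return data.frame with per-region mean, median, SD and voxel count.
#' @export
summarize_disarray <- function(dis, regions) {
  rows <- lapply(names(regions), function(nm) {
    v <- dis$disarray_deg[regions[[nm]] & dis$mask]
    v <- v[is.finite(v)]
    data.frame(region = nm, mean_deg = mean(v), median_deg = median(v),
               sd_deg = sd(v), n = length(v))
  })
  do.call(rbind, rows)
}
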