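# Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Shift a 3D array by (dx, dy, dz), filling vacated entries with `fill`.
shift3 <- function(a, dx = 0L, dy = 0L, dz = 0L, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# Binary 3D dilation / erosion with a box structuring element of radius r
# (separable along each axis, matching a (2r+1)^3 cube).
dilate3 <- function(mask, r) {
  m <- mask
  for (ax in 1:3) {
    acc <- m
    for (s in seq_len(r)) {
      args_p <- args_n <- list(0L, 0L, 0L)
      args_p[[ax]] <- s; args_n[[ax]] <- -s
      acc <- acc | do.call(shift3, c(list(m), args_p, fill = FALSE)) |
        do.call(shift3, c(list(m), args_n, fill = FALSE))
    }
    m <- acc
  }
  m
}

erode3 <- function(mask, r) !dilate3(!mask, r)

# Separable convolution of a 3D array with a normalized Gaussian of standard
# deviation `sigma` voxels, reflecting at borders.
gauss_smooth3 <- function(a, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(a)
  rad <- max(1L, ceiling(3 * sigma))
  w <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  w <- w / sum(w)
  d <- dim(a)
  for (ax in 1:3) {
    out <- array(0, d)
    for (k in seq_along(w)) {
      s <- k - rad - 1L
      # reflecting shift: indices clamped by reflection at the borders
      idx <- seq_len(d[ax]) - s
      n <- d[ax]
      idx <- ifelse(idx < 1L, 2L - idx, idx)
      idx <- ifelse(idx > n, 2L * n - idx, idx)
      sl <- switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                   a[, , idx, drop = FALSE])
      out <- out + w[k] * sl
    }
    a <- out
  }
  a
}

# Otsu threshold on a numeric vector (256-bin histogram between min and max).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# Population standard deviation (divisor n) over finite values.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NaN)
  sqrt(mean((x - mean(x))^2))
}

# Circular standard deviation of angles (radians), via the resultant length.
circ_sd <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (length(theta) == 0L) return(NaN)
  R <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  R <- min(R, 1)
  sqrt(-2 * log(max(R, .Machine$double.xmin)))
}

# Angle between two 3D directions modulo 180 degrees (axial data).
axial_angle_deg <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  cosang <- abs(sum(u * v)) / (cu * cv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Vectorized trilinear sampling of a 3D array at continuous voxel coordinates
# (columns of q), clamping to the volume.
trilinear3 <- function(a, qx, qy, qz) {
  d <- dim(a)
  qx <- pmin(pmax(qx, 1), d[1]); qy <- pmin(pmax(qy, 1), d[2])
  qz <- pmin(pmax(qz, 1), d[3])
  x0 <- pmin(floor(qx), d[1] - 1L); y0 <- pmin(floor(qy), d[2] - 1L)
  z0 <- pmin(floor(qz), d[3] - 1L)
  fx <- qx - x0; fy <- qy - y0; fz <- qz - z0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    v <- v + w * a[cbind(x0 + dx, y0 + dy, z0 + dz)]
  }
  v
}
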