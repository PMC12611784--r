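# Plain-file interchange: multi-page TIFF for volumes and movies, with a
# JSON sidecar carrying the acquisition metadata.

#' Write / read a volume as multi-page TIFF with a JSON sidecar
#'
#' Pages are z-slices; intensities are scaled to [0, 1] for TIFF storage and
#' the scale, voxel pitch and channel tag are recorded in a `.json` sidecar
#' next to the image so the volume round-trips.
#'
#' @param vol a \code{\link{volume3d}}.
#' @param path output path (`.tif`); the sidecar gets the same stem.
#' @return \code{write_volume_tiff}: the path, invisibly;
#'   \code{read_volume_tiff}: a \code{\link{volume3d}}.
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("jsonlite", quietly = TRUE))
    stop("the tiff and jsonlite packages are required for TIFF interchange")
  rng <- range(vol$data)
  scale <- if (diff(rng) == 0) 1 else diff(rng)
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[3]), function(z)
    t((vol$data[, , z] - rng[1]) / scale))  # TIFF rows = y
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(voxel_um = vol$voxel_um, channel = vol$channel,
                            offset = rng[1], scale = scale),
                       sub("\\.tiff?$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param path path of a TIFF written by \code{write_volume_tiff}.
#' @export
read_volume_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("jsonlite", quietly = TRUE))
    stop("the tiff and jsonlite packages are required for TIFF interchange")
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(lapply(pages, t))   # back to (x, y, z)
  arr <- arr * meta$scale + meta$offset
  volume3d(arr, meta$voxel_um, meta$channel)
}

#' Write a 2D parameter map as CSV
#'
#' @param map a \code{\link{scalar_map2d}}.
#' @param path output `.csv` path.
#' @return the path, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "scalar_map2d"))
  utils::write.csv(map$values, path, row.names = FALSE)
  invisible(path)
}
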