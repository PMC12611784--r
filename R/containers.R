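# Light S3 containers shared by all modules.

#' Single-channel 3D tomogram
#'
#' A 3D scalar grid with an isotropic voxel pitch and a channel tag.
#' The fluorescence channel carries myocardial signal; the scattering channel
#' carries collagen contrast.
#'
#' @param data numeric 3D array (x, y, z).
#' @param voxel_um isotropic voxel pitch in micrometres (> 0).
#' @param channel one of \code{"fluorescence"}, \code{"scattering"},
#'   \code{"other"}.
#' @return object of class \code{volume3d}.
#' @export
volume3d <- function(data, voxel_um, channel = c("fluorescence", "scattering", "other")) {
  channel <- match.arg(channel)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (!is.numeric(voxel_um) || length(voxel_um) != 1L || voxel_um <= 0)
    stop("`voxel_um` must be a single positive number")
  structure(list(data = data, voxel_um = voxel_um, channel = channel),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d [%s]: %d x %d x %d voxels @ %g um\n",
              x$channel, d[1], d[2], d[3], x$voxel_um))
  invisible(x)
}

# Canonical integer codes for anatomical tags. "T" (tissue) is the union of
# everything that is not background or chamber lumen; it is queried through
# lv_mask() rather than stored.
.lv_codes <- c(B = 0L, MYO = 1L, CF = 2L, NCF = 3L,
               L_ch = 4L, R_ch = 5L, V_ess = 6L, AVS = 7L)

#' Integer-tagged segmentation volume
#'
#' Voxel tags are mutually exclusive: background (B), healthy myocardium
#' (MYO), compact fibrosis (CF), non-compact fibrosis (NCF), left/right
#' chamber lumina (L_ch, R_ch), vessels (V_ess) and the atrioventricular
#' separation slab (AVS). The composite tissue mask T = MYO | CF | NCF |
#' V_ess | AVS is obtained with \code{lv_mask(x, "T")}.
#'
#' @param tags integer 3D array of tag codes (see \code{lv_codes()}).
#' @param voxel_um isotropic voxel pitch in micrometres.
#' @return object of class \code{label_volume}.
#' @export
label_volume <- function(tags, voxel_um = 20) {
  if (length(dim(tags)) != 3L) stop("`tags` must be a 3D array")
  storage.mode(tags) <- "integer"
  if (!all(tags %in% .lv_codes)) stop("unknown tag codes present")
  structure(list(tags = tags, voxel_um = voxel_um), class = "label_volume")
}

#' Tag code legend for label volumes
#' @return named integer vector of tag codes.
#' @export
lv_codes <- function() .lv_codes

#' Extract a boolean mask for one tag (or the composite "T")
#'
#' @param labels a \code{label_volume}.
#' @param tag a tag name from \code{lv_codes()}, or \code{"T"} for the
#'   composite ventricular tissue mask.
#' @return logical 3D array.
#' @export
lv_mask <- function(labels, tag) {
  stopifnot(inherits(labels, "label_volume"))
  if (tag == "T") {
    labels$tags %in% .lv_codes[c("MYO", "CF", "NCF", "V_ess", "AVS")] |>
      array(dim(labels$tags))
  } else {
    if (!tag %in% names(.lv_codes)) stop("unknown tag: ", tag)
    labels$tags == .lv_codes[[tag]]
  }
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$tags)
  cat(sprintf("label_volume: %d x %d x %d voxels @ %g um\n", d[1], d[2], d[3], x$voxel_um))
  tb <- table(factor(x$tags, levels = .lv_codes, labels = names(.lv_codes)))
  print(tb[tb > 0])
  invisible(x)
}

#' Optical-mapping movie
#'
#' Frame stack of voltage-sensitive-dye fluorescence. The acquisition defaults
#' (1 ms sampling, 78 um pixels) match a 1 kHz sCMOS recording of the left
#' ventricular free wall; after \code{om_preprocess} the pitch becomes 312 um.
#'
#' @param frames numeric 3D array (t, y, x).
#' @param dt_ms frame interval in ms.
#' @param pitch_um pixel pitch in micrometres.
#' @param stimulus_times_ms pacing-event timestamps (ms from first frame).
#' @param pacing_rate_hz pacing rate, if constant.
#' @return object of class \code{optical_movie}.
#' @export
optical_movie <- function(frames, dt_ms = 1, pitch_um = 78,
                          stimulus_times_ms = numeric(), pacing_rate_hz = NA_real_) {
  if (length(dim(frames)) != 3L) stop("`frames` must be a 3D (t, y, x) array")
  if (dt_ms <= 0) stop("`dt_ms` must be positive")
  if (!all(is.finite(frames))) stop("`frames` must be finite")
  structure(list(frames = frames, dt_ms = dt_ms, pitch_um = pitch_um,
                 stimulus_times_ms = as.numeric(stimulus_times_ms),
                 pacing_rate_hz = pacing_rate_hz,
                 preprocessed = FALSE),
            class = "optical_movie")
}

#' @export
print.optical_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("optical_movie: %d frames of %d x %d px @ %g um, dt %g ms%s\n",
              d[1], d[2], d[3], x$pitch_um, x$dt_ms,
              if (isTRUE(x$preprocessed)) " (dF/F0, binned)" else ""))
  invisible(x)
}

#' Per-pixel 2D parameter map
#'
#' @param values numeric matrix (y, x); NaN/NA marks unmapped pixels.
#' @param pitch_um pixel pitch in micrometres (312 after 4x4 binning).
#' @param kind map kind, one of TTP, APD50, APD70, APD90, activation, LCT,
#'   CV, angle, delta.
#' @return object of class \code{scalar_map2d}.
#' @export
scalar_map2d <- function(values, pitch_um = 312,
                         kind = c("TTP", "APD50", "APD70", "APD90",
                                  "activation", "LCT", "CV", "angle", "delta")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  structure(list(values = values, pitch_um = pitch_um, kind = kind),
            class = "scalar_map2d")
}

#' @export
print.scalar_map2d <- function(x, ...) {
  cat(sprintf("scalar_map2d[%s]: %d x %d px @ %g um (%d valid)\n",
              x$kind, nrow(x$values), ncol(x$values), x$pitch_um,
              sum(is.finite(x$values))))
  invisible(x)
}

#' Block-wise 3D orientation field
#'
#' Unit orientation vectors (direction of locally prevailing cardiomyocyte
#' alignment; v and -v are equivalent) with fractional anisotropy and a
#' validity mask, on a coarse grid of analysis blocks.
#'
#' @param vectors 4D array (bx, by, bz, 3) of unit vectors (NA where invalid).
#' @param fa 3D array of fractional anisotropy.
#' @param mask logical 3D array of valid blocks (FA-gated).
#' @param pitch_um block pitch in micrometres (block size x voxel pitch).
#' @param helix_deg optional 3D array of helix angles in degrees.
#' @return object of class \code{orientation_field}.
#' @export
orientation_field <- function(vectors, fa, mask, pitch_um, helix_deg = NULL) {
  stopifnot(length(dim(vectors)) == 4L, dim(vectors)[4] == 3L)
  structure(list(vectors = vectors, fa = fa, mask = mask,
                 pitch_um = pitch_um, helix_deg = helix_deg),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  d <- dim(x$fa)
  cat(sprintf("orientation_field: %d x %d x %d blocks @ %g um (%d valid)\n",
              d[1], d[2], d[3], x$pitch_um, sum(x$mask)))
  invisible(x)
}
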