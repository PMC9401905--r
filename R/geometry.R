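# Viewing geometry: view zenith angle, ground sample distance, ROI
# rescaling across flight altitudes, and the altitude-sensitivity metric.

#' Construct a viewing geometry
#'
#' @param altitude Flight altitude H (m), > 0.
#' @param ground_offset Horizontal distance (m) from the nadir point to
#'   the target, >= 0.
#' @param camera A [camera_profile()].
#' @return An object of class `view_geometry`.
#' @export
view_geometry <- function(altitude, ground_offset = 0,
                          camera = mca12_profile(quiet = TRUE)) {
  if (altitude <= 0) stop("altitude must be positive")
  if (ground_offset < 0) stop("ground offset must be non-negative")
  structure(list(altitude = altitude, ground_offset = ground_offset,
                 camera = camera),
            class = "view_geometry")
}

#' View zenith angle
#'
#' The angle between the line of sight to the target and the vertical,
#' `alpha = atan(x / H)`, in degrees. A target at the horizontal image
#' edge is seen at half the horizontal FOV regardless of altitude.
#'
#' @param geom A [view_geometry()], or a numeric altitude when
#'   `ground_offset` is supplied.
#' @param ground_offset Horizontal offset (m), used when `geom` is numeric.
#' @return VZA in degrees, in \[0, 90).
#' @export
view_zenith_angle <- function(geom, ground_offset = NULL) {
  if (inherits(geom, "view_geometry")) {
    H <- geom$altitude; x <- geom$ground_offset
  } else {
    H <- geom; x <- ground_offset
    if (is.null(x)) stop("ground_offset required")
    if (any(H <= 0)) stop("altitude must be positive")
    if (any(x < 0)) stop("ground offset must be non-negative")
  }
  atan(x / H) * 180 / pi
}

#' VZA profile over altitudes
#'
#' @param ground_offset Fixed horizontal offset (m).
#' @param altitudes Vector of altitudes (m), all > 0.
#' @return VZA (degrees) per altitude; strictly decreasing in altitude
#'   for a positive offset.
#' @export
vza_profile <- function(ground_offset, altitudes) {
  if (length(altitudes) == 0L) stop("empty altitude list")
  vapply(altitudes, function(H) view_zenith_angle(H, ground_offset),
         numeric(1))
}

#' Horizontal ground sample distance
#'
#' Ground footprint of one pixel: `GSD = 2 H tan(fov_h / 2) / width`,
#' linear in altitude.
#'
#' @param altitude Altitude (m), > 0.
#' @param camera A [camera_profile()].
#' @return GSD in m/pixel.
#' @export
ground_sample_distance <- function(altitude, camera = mca12_profile(quiet = TRUE)) {
  if (any(altitude <= 0)) stop("altitude must be positive")
  2 * altitude * tan(camera$fov_h / 2 * pi / 180) / camera$image_width
}

# Round half away from zero (so plot ROIs are reproducible bit-for-bit
# across platforms, unlike round()'s banker's rounding).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Rescale an ROI to a new flight altitude
#'
#' To keep an ROI covering the same ground area when the altitude (and
#' hence the GSD) changes, each pixel dimension is scaled by
#' `H_ref / H_new`, rounded to the nearest integer (ties away from
#' zero), with a minimum of 1 pixel; the ROI center is preserved.
#'
#' @param roi Integer `c(row0, col0, row1, col1)`, 0-based half-open.
#' @param h_ref Altitude (m) at which `roi` was defined.
#' @param h_new Target altitude (m).
#' @return Rescaled ROI in the same convention.
#' @export
scale_roi <- function(roi, h_ref, h_new) {
  roi <- as.integer(roi)
  if (length(roi) != 4L || roi[3] <= roi[1] || roi[4] <= roi[2])
    stop("degenerate roi")
  if (h_ref <= 0 || h_new <= 0) stop("altitudes must be positive")
  f <- h_ref / h_new
  h <- roi[3] - roi[1]; w <- roi[4] - roi[2]
  h2 <- max(1L, as.integer(round_half_away(h * f)))
  w2 <- max(1L, as.integer(round_half_away(w * f)))
  cr <- (roi[1] + roi[3]) / 2
  cw <- (roi[2] + roi[4]) / 2
  r0 <- as.integer(round_half_away(cr - h2 / 2))
  c0 <- as.integer(round_half_away(cw - w2 / 2))
  c(r0, c0, r0 + h2, c0 + w2)
}

#' Altitude sensitivity of band reflectance (STD and STDR)
#'
#' For a series of plot reflectances observed over several altitudes,
#' the sensitivity of a band is the population standard deviation (STD)
#' of its reflectance over all altitudes, and the relative version
#' (STDR) divides by the reflectance in the near-nadir (orthophoto)
#' direction, approximated by the highest reference altitude.
#'
#' @param reflectance Numeric matrix, altitudes x bands (a vector is
#'   treated as a single band).
#' @param altitudes Altitudes (m) matching the rows.
#' @param reference_altitude Altitude whose reflectance is the STDR
#'   denominator; must appear in `altitudes`.
#' @return Data frame with columns `band`, `std`, `stdr`.
#' @export
stdr_sensitivity <- function(reflectance, altitudes, reference_altitude) {
  if (is.vector(reflectance)) reflectance <- matrix(reflectance, ncol = 1)
  if (nrow(reflectance) != length(altitudes))
    stop("one altitude per row required")
  if (nrow(reflectance) < 2L) stop("need at least 2 altitudes")
  iref <- match(reference_altitude, altitudes)
  if (is.na(iref)) stop("reference altitude not among the altitudes")
  n <- nrow(reflectance)
  std <- apply(reflectance, 2L, function(v) sqrt(sum((v - mean(v))^2) / n))
  ref <- reflectance[iref, ]
  if (any(ref == 0)) stop("zero reference reflectance in band(s): ",
                          paste(which(ref == 0), collapse = ", "))
  data.frame(band = seq_len(ncol(reflectance)), std = std,
             stdr = std / ref)
}
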