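# Camera description and band-equivalent reflectance convolution.

#' Center wavelengths (nm) of the 12-lens multispectral camera
#'
#' The reference camera carries twelve independent lenses with center
#' wavelengths spanning the visible to near-infrared range.
#'
#' @format Numeric vector of length 12, strictly increasing, in nm.
#' @export
mca12_centers <- c(490, 520, 550, 570, 670, 680, 700, 720, 800, 850, 900, 950)

#' Construct a band set
#'
#' A band set is the ordered list of camera bands: 1-based index, center
#' wavelength in nm, and (optionally) a sampled spectral response function
#' per band.
#'
#' @param centers Numeric vector of strictly increasing center wavelengths
#'   (nm). Defaults to the 12-band reference camera.
#' @param responses Optional list, one element per band, each either `NULL`
#'   or a two-column data frame (`wavelength_nm`, `weight`) with
#'   non-negative weights and strictly increasing wavelengths.
#' @return An object of class `band_set`.
#' @export
band_set <- function(centers = mca12_centers, responses = NULL) {
  if (length(centers) < 1L || any(diff(centers) <= 0))
    stop("band centers must be strictly increasing")
  if (!is.null(responses)) {
    if (length(responses) != length(centers))
      stop("one response (or NULL) required per band")
    for (i in seq_along(responses)) {
      r <- responses[[i]]
      if (is.null(r)) next
      responses[[i]] <- validate_response(r, sprintf("band %d", i))
    }
  } else {
    responses <- vector("list", length(centers))
  }
  structure(list(centers = as.numeric(centers), responses = responses),
            class = "band_set")
}

validate_response <- function(r, what = "response") {
  if (!is.data.frame(r) || ncol(r) < 2L)
    stop(what, ": response must be a two-column data frame")
  names(r)[1:2] <- c("wavelength_nm", "weight")
  if (nrow(r) < 2L) stop(what, ": response needs at least 2 samples")
  if (any(diff(r$wavelength_nm) <= 0))
    stop(what, ": response wavelengths must be strictly increasing")
  if (any(r$weight < 0)) stop(what, ": response weights must be >= 0")
  r[, 1:2]
}

#' @export
print.band_set <- function(x, ...) {
  have <- vapply(x$responses, Negate(is.null), logical(1))
  cat(sprintf("<band_set> %d bands: %s nm (%d with measured response)\n",
              length(x$centers), paste(x$centers, collapse = ", "),
              sum(have)))
  invisible(x)
}

#' Synthesize a Gaussian spectral response
#'
#' When a band's true spectral response function has not been measured, a
#' Gaussian profile centered on the band center is a common stand-in. The
#' profile is sampled on a regular grid and truncated at +/- 2.5 FWHM.
#'
#' @param center Center wavelength (nm).
#' @param fwhm Full width at half maximum (nm); default 10.
#' @param step Sampling step (nm); default 0.5.
#' @return Data frame with columns `wavelength_nm`, `weight`.
#' @export
gaussian_response <- function(center, fwhm = 10, step = 0.5) {
  stopifnot(fwhm > 0, step > 0)
  half <- 2.5 * fwhm
  wl <- seq(center - half, center + half, by = step)
  w <- exp(-4 * log(2) * ((wl - center) / fwhm)^2)
  data.frame(wavelength_nm = wl, weight = w)
}

#' Construct a camera profile
#'
#' Bundles a band set with the imaging geometry: image size in pixels and
#' horizontal/vertical field of view in degrees.
#'
#' @param band_set A [band_set()].
#' @param image_width,image_height Image size in pixels.
#' @param fov_h,fov_v Field of view, degrees, in (0, 180).
#' @return An object of class `camera_profile`.
#' @export
camera_profile <- function(band_set = uavcal::band_set(),
                           image_width = 1280L, image_height = 1024L,
                           fov_h = 38.26, fov_v = 30.97) {
  stopifnot(inherits(band_set, "band_set"))
  if (image_width <= 0 || image_height <= 0) stop("image dimensions must be positive")
  if (fov_h <= 0 || fov_h >= 180 || fov_v <= 0 || fov_v >= 180)
    stop("field of view must lie in (0, 180) degrees")
  structure(list(band_set = band_set,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 fov_h = fov_h, fov_v = fov_v),
            class = "camera_profile")
}

#' Default 12-band camera profile
#'
#' The reference profile: 12 bands at 490-950 nm, 1280 x 1024 pixels,
#' horizontal/vertical FOV 38.26 / 30.97 degrees. True per-lens spectral
#' response functions are not available, so Gaussian responses
#' (configurable FWHM) are synthesized for every band and flagged as such.
#'
#' @param response_fwhm FWHM (nm) of the synthesized Gaussian responses,
#'   or `NA` to leave responses empty.
#' @param image_width,image_height Image size in pixels; the native sensor
#'   is 1280 x 1024 but reduced sizes are convenient for simulation.
#' @param quiet Suppress the synthetic-response message.
#' @return A `camera_profile`.
#' @export
mca12_profile <- function(response_fwhm = 10, image_width = 1280L,
                          image_height = 1024L, quiet = FALSE) {
  if (is.na(response_fwhm)) {
    bs <- band_set()
  } else {
    resp <- lapply(mca12_centers, gaussian_response, fwhm = response_fwhm)
    bs <- band_set(mca12_centers, resp)
    if (!quiet)
      message(sprintf(
        "using synthetic Gaussian responses (FWHM %g nm) - no measured response functions supplied",
        response_fwhm))
  }
  camera_profile(bs, image_width = image_width, image_height = image_height)
}

#' Construct a hyperspectral spectrum
#'
#' A field-spectrometer reflectance spectrum: ordered
#' (wavelength, reflectance) pairs. Reflectance is a fraction; values up
#' to 1.5 are tolerated to accommodate specular readings.
#'
#' @param wavelength_nm Strictly increasing wavelengths (nm).
#' @param reflectance Reflectance fractions in [0, 1.5].
#' @return An object of class `hyperspec` (a data frame).
#' @export
hyperspectral_spectrum <- function(wavelength_nm, reflectance) {
  if (length(wavelength_nm) != length(reflectance))
    stop("wavelength and reflectance must have equal length")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(reflectance < 0 | reflectance > 1.5))
    stop("reflectance must lie in [0, 1.5]")
  structure(data.frame(wavelength_nm = as.numeric(wavelength_nm),
                       reflectance = as.numeric(reflectance)),
            class = c("hyperspec", "data.frame"))
}

#' Band-equivalent reflectance of a spectrum under one spectral response
#'
#' Computes the response-weighted mean reflectance
#' \deqn{R_j = \int_s^e R(\lambda) S_j(\lambda)\,d\lambda \Big/
#'       \int_s^e S_j(\lambda)\,d\lambda}
#' over the support \[s, e\] of the response. Both the spectrum and the
#' response are treated as piecewise linear; their product is therefore
#' piecewise quadratic, and the numerator is integrated exactly by
#' Simpson's rule on the merged knot grid (the denominator by the
#' trapezoidal rule, exact for a piecewise-linear integrand).
#'
#' @param spectrum A [hyperspectral_spectrum()] (or data frame with
#'   `wavelength_nm`, `reflectance`).
#' @param response Two-column data frame (`wavelength_nm`, `weight`).
#' @return Band-equivalent reflectance (scalar fraction).
#' @export
band_equivalent_reflectance <- function(spectrum, response) {
  response <- validate_response(response)
  s <- min(response$wavelength_nm)
  e <- max(response$wavelength_nm)
  wl <- spectrum$wavelength_nm
  if (min(wl) > s || max(wl) < e)
    stop(sprintf(
      "spectrum [%g, %g] nm does not cover the response support [%g, %g] nm",
      min(wl), max(wl), s, e))

  grid <- sort(unique(c(response$wavelength_nm, wl[wl >= s & wl <= e], s, e)))
  R <- stats::approx(wl, spectrum$reflectance, xout = grid, rule = 2)$y
  S <- stats::approx(response$wavelength_nm, response$weight, xout = grid,
                     yleft = 0, yright = 0)$y
  h <- diff(grid)
  denom <- sum(h * (S[-length(S)] + S[-1]) / 2)
  if (denom <= 0)
    stop("degenerate response: integral of S over [s, e] is zero")

  mids <- (grid[-length(grid)] + grid[-1]) / 2
  Rm <- stats::approx(wl, spectrum$reflectance, xout = mids, rule = 2)$y
  Sm <- stats::approx(response$wavelength_nm, response$weight, xout = mids,
                      yleft = 0, yright = 0)$y
  f <- R * S
  fm <- Rm * Sm
  num <- sum(h / 6 * (f[-length(f)] + 4 * fm + f[-1]))
  num / denom
}

#' Convolve a spectrum to all camera bands
#'
#' Applies [band_equivalent_reflectance()] per band, producing the
#' camera-equivalent reflectance vector ordered by band index.
#'
#' @param spectrum A [hyperspectral_spectrum()].
#' @param camera A [camera_profile()]; every band must carry a response.
#' @return Named numeric vector, one value per band (names are band
#'   centers in nm).
#' @export
convolve_all_bands <- function(spectrum, camera) {
  stopifnot(inherits(camera, "camera_profile"))
  bs <- camera$band_set
  missing <- which(vapply(bs$responses, is.null, logical(1)))
  if (length(missing))
    stop("bands without a spectral response: ",
         paste(bs$centers[missing], collapse = ", "), " nm")
  out <- vapply(seq_along(bs$centers), function(i) {
    band_equivalent_reflectance(spectrum, bs$responses[[i]])
  }, numeric(1))
  names(out) <- as.character(bs$centers)
  out
}

#' Read a two-column spectrum CSV
#'
#' Expects a header and two columns: wavelength in nm and the value
#' (reflectance for spectra, weight for response functions).
#'
#' @param path File path.
#' @return For `read_spectrum_csv`, a [hyperspectral_spectrum()]; for
#'   `read_response_csv`, a response data frame.
#' @export
read_spectrum_csv <- function(path) {
  x <- utils::read.csv(path)
  if (ncol(x) < 2L) stop("expected two columns in ", path)
  hyperspectral_spectrum(x[[1]], x[[2]])
}

#' @rdname read_spectrum_csv
#' @export
read_response_csv <- function(path) {
  x <- utils::read.csv(path)
  if (ncol(x) < 2L) stop("expected two columns in ", path)
  validate_response(data.frame(wavelength_nm = x[[1]], weight = x[[2]]), path)
}

#' Read / write a camera profile as JSON
#'
#' The JSON carries band centers, optional per-band responses, image
#' dimensions and FOV.
#'
#' @param path File path.
#' @param camera A `camera_profile`.
#' @return `read_camera_json` returns a `camera_profile`;
#'   `write_camera_json` returns `path` invisibly.
#' @export
read_camera_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  resp <- NULL
  if (!is.null(x$responses)) {
    resp <- lapply(x$responses, function(r) {
      if (is.null(r) || (is.atomic(r) && all(is.na(r)))) return(NULL)
      data.frame(wavelength_nm = r$wavelength_nm, weight = r$weight)
    })
  }
  camera_profile(band_set(x$centers, resp),
                 image_width = x$image_width, image_height = x$image_height,
                 fov_h = x$fov_h, fov_v = x$fov_v)
}

#' @rdname read_camera_json
#' @export
write_camera_json <- function(camera, path) {
  stopifnot(inherits(camera, "camera_profile"))
  x <- list(centers = camera$band_set$centers,
            responses = camera$band_set$responses,
            image_width = camera$image_width,
            image_height = camera$image_height,
            fov_h = camera$fov_h, fov_v = camera$fov_v)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
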