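# Empirical-line radiometric calibration: EL, SEL and PEL.
#
# All three methods map raw digital numbers (DN) to surface reflectance
# using grayscale reference panels of known reflectance imaged in the
# scene:
#   EL   y = a1*x + b1                       one affine fit per band
#   SEL  y = a2*x^b2 (visible, bands 1-7)    power fit, low reflectance
#        y = a3*x + b3 (red edge/NIR, 8-12)  affine fit, high reflectance
#   PEL  y = a4*x        if y_lin <= tau     proportional, dark targets
#        y = a5*x + b5   if y_lin >  tau     affine, everything else
# where y_lin = a5*x + b5 and tau defaults to 0.03. The piecewise rule is
# evaluated on the affine prediction because the true reflectance is
# unknown at application time.

#' Construct a calibration panel descriptor
#'
#' A grayscale reference panel: a pixel ROI and its nominal per-band
#' reflectance. ROIs are 0-based, half-open rectangles
#' `(row0, col0, row1, col1)`.
#'
#' @param label Panel label.
#' @param roi Integer vector `c(row0, col0, row1, col1)`, 0-based,
#'   half-open, non-empty.
#' @param reflectance Nominal reflectance fraction(s) in (0, 1); either a
#'   scalar (spectrally flat panel) or one value per band.
#' @return An object of class `calibration_panel`.
#' @export
calibration_panel <- function(label, roi, reflectance) {
  roi <- as.integer(roi)
  if (length(roi) != 4L) stop("roi must be c(row0, col0, row1, col1)")
  if (roi[3] <= roi[1] || roi[4] <= roi[2]) stop("roi is empty")
  if (any(roi[1:2] < 0)) stop("roi has negative origin")
  if (any(reflectance <= 0 | reflectance >= 1))
    stop("nominal reflectance must lie in (0, 1)")
  structure(list(label = as.character(label), roi = roi,
                 reflectance = as.numeric(reflectance)),
            class = "calibration_panel")
}

#' Mean DN of a panel ROI
#'
#' @param image_band Numeric matrix of DN for one band.
#' @param panel A [calibration_panel()].
#' @param trim Fraction (0 to < 0.5) trimmed from each tail before
#'   averaging; default 0 (plain mean).
#' @return Mean DN over the ROI.
#' @export
extract_panel_dn <- function(image_band, panel, trim = 0) {
  stopifnot(inherits(panel, "calibration_panel"), is.matrix(image_band))
  r <- panel$roi
  if (r[3] > nrow(image_band) || r[4] > ncol(image_band))
    stop(sprintf("panel '%s' ROI extends outside the %d x %d image",
                 panel$label, nrow(image_band), ncol(image_band)))
  mean(image_band[(r[1] + 1L):r[3], (r[2] + 1L):r[4]], trim = trim)
}

#' Fit the empirical-line (EL) model for one band
#'
#' Ordinary least squares of reflectance on DN over all supplied panels:
#' `reflectance = a1 * DN + b1`.
#'
#' @param dn Per-panel mean DN.
#' @param reflectance Per-panel nominal reflectance.
#' @return List with `a1`, `b1`, and `rmse` (in-sample residual RMSE).
#' @export
fit_el <- function(dn, reflectance) {
  if (length(dn) < 2L || length(unique(dn)) < 2L)
    stop("EL fit needs at least 2 panels with distinct DN")
  fit <- stats::lm.fit(cbind(1, dn), reflectance)
  b <- unname(fit$coefficients)
  list(a1 = b[2], b1 = b[1], rmse = sqrt(mean(fit$residuals^2)))
}

#' Fit the subband empirical-line (SEL) model for one band
#'
#' Low-reflectance visible bands use a power law `y = a2 * x^b2`, fitted
#' by ordinary least squares in log-log space; red-edge/NIR bands use an
#' affine fit as in EL.
#'
#' @param dn,reflectance Per-panel mean DN and nominal reflectance.
#' @param group `"power"` (visible) or `"linear"` (red edge / NIR).
#' @return For `"power"`: list with `a2`, `b2`, `rmse`; for `"linear"`:
#'   list with `a3`, `b3`, `rmse`.
#' @export
fit_sel <- function(dn, reflectance, group = c("power", "linear")) {
  group <- match.arg(group)
  if (group == "linear") {
    f <- fit_el(dn, reflectance)
    return(list(a3 = f$a1, b3 = f$b1, rmse = f$rmse))
  }
  if (any(dn <= 0) || any(reflectance <= 0))
    stop("power fit requires strictly positive DN and reflectance")
  if (length(dn) < 2L || length(unique(dn)) < 2L)
    stop("SEL fit needs at least 2 panels with distinct DN")
  fit <- stats::lm.fit(cbind(1, log(dn)), log(reflectance))
  a2 <- exp(unname(fit$coefficients[1]))
  b2 <- unname(fit$coefficients[2])
  pred <- a2 * dn^b2
  list(a2 = a2, b2 = b2, rmse = sqrt(mean((pred - reflectance)^2)))
}

#' Fit the piecewise empirical-line (PEL) model for one band
#'
#' The affine segment (`a5`, `b5`) is fitted on all panels exactly as EL.
#' The proportional segment `a4` is fitted through the origin on the
#' low-reflectance panels only (nominal reflectance at or below
#' `low_panel_max`). If no panel qualifies, the method degrades to EL
#' (proportional slope set so the affine branch is always used) with a
#' warning.
#'
#' @param dn,reflectance Per-panel mean DN and nominal reflectance.
#' @param tau Reflectance threshold between the segments; default 0.03.
#' @param low_panel_max Largest nominal reflectance admitted to the
#'   through-origin fit; default 0.06.
#' @return List with `a4`, `a5`, `b5`, `tau`, `rmse`, and `fallback`
#'   (TRUE when no low panel was available).
#' @export
fit_pel <- function(dn, reflectance, tau = 0.03, low_panel_max = 0.06) {
  hi <- fit_el(dn, reflectance)
  low <- reflectance <= low_panel_max
  if (!any(low)) {
    warning("no panel with nominal reflectance <= ", low_panel_max,
            "; PEL falls back to EL for this band")
    return(list(a4 = NA_real_, a5 = hi$a1, b5 = hi$b1, tau = tau,
                rmse = hi$rmse, fallback = TRUE))
  }
  x <- dn[low]; y <- reflectance[low]
  a4 <- sum(x * y) / sum(x * x)
  pred <- ifelse(hi$a1 * dn + hi$b1 <= tau, a4 * dn, hi$a1 * dn + hi$b1)
  list(a4 = a4, a5 = hi$a1, b5 = hi$b1, tau = tau,
       rmse = sqrt(mean((pred - reflectance)^2)), fallback = FALSE)
}

#' Band group used by SEL
#'
#' Bands are assumed sorted by ascending center wavelength; indices 1-7
#' (490-700 nm) form the low-reflectance visible group fitted with a
#' power law, indices 8-12 (720-950 nm) the red-edge/NIR group fitted
#' linearly.
#'
#' @param band_index 1-based band index (or vector).
#' @return `"power"` or `"linear"` per index.
#' @export
sel_band_group <- function(band_index) {
  ifelse(band_index <= 7L, "power", "linear")
}

#' Fit a calibration for all bands
#'
#' @param panel_dns Matrix of mean DN, panels x bands.
#' @param reflectances Matrix of nominal reflectance, panels x bands (a
#'   vector is recycled across bands for spectrally flat panels).
#' @param method `"EL"`, `"SEL"` or `"PEL"`.
#' @param tau,low_panel_max PEL parameters, see [fit_pel()].
#' @return An object of class `calibration_fit`: per-band coefficient
#'   records plus fit diagnostics (per-band residual RMSE on the panels).
#' @export
fit_calibration <- function(panel_dns, reflectances,
                            method = c("PEL", "EL", "SEL"),
                            tau = 0.03, low_panel_max = 0.06) {
  method <- match.arg(method)
  panel_dns <- as.matrix(panel_dns)
  if (is.vector(reflectances) || (is.matrix(reflectances) && ncol(reflectances) == 1L))
    reflectances <- matrix(reflectances, nrow = nrow(panel_dns),
                           ncol = ncol(panel_dns))
  reflectances <- as.matrix(reflectances)
  stopifnot(dim(panel_dns) == dim(reflectances))
  nb <- ncol(panel_dns)
  bands <- lapply(seq_len(nb), function(j) {
    x <- panel_dns[, j]; y <- reflectances[, j]
    switch(method,
      EL = fit_el(x, y),
      SEL = c(fit_sel(x, y, sel_band_group(j)), list(group = sel_band_group(j))),
      PEL = fit_pel(x, y, tau = tau, low_panel_max = low_panel_max))
  })
  structure(list(method = method, bands = bands, n_bands = nb,
                 n_panels = nrow(panel_dns),
                 diagnostics = data.frame(
                   band = seq_len(nb),
                   rmse = vapply(bands, `[[`, numeric(1), "rmse"))),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> %s, %d bands, %d panels; mean panel RMSE %.4g\n",
              x$method, x$n_bands, x$n_panels, mean(x$diagnostics$rmse)))
  invisible(x)
}

apply_band_calibration <- function(x, rec, method) {
  switch(method,
    EL = rec$a1 * x + rec$b1,
    SEL = if (rec$group == "power") {
      if (any(x < 0)) stop("SEL power branch applied to negative DN")
      rec$a2 * x^rec$b2
    } else rec$a3 * x + rec$b3,
    PEL = {
      if (isTRUE(rec$fallback)) {
        rec$a5 * x + rec$b5
      } else {
        y_lin <- rec$a5 * x + rec$b5
        ifelse(y_lin <= rec$tau, rec$a4 * x, y_lin)
      }
    })
}

#' Apply a fitted calibration to DN imagery
#'
#' Converts per-band DN to reflectance pixel-wise. For PEL the affine
#' prediction `y_lin = a5*x + b5` selects the branch: the proportional
#' segment `a4*x` is used where `y_lin <= tau`. Output values are not
#' clamped by default; out-of-range pixels (reflectance < 0 or > 1) are
#' counted per band in the `"diagnostics"` attribute.
#'
#' @param dn Either a 3-D array (rows x cols x bands), a matrix
#'   (observations x bands), or a numeric vector (one observation across
#'   bands).
#' @param fit A [fit_calibration()] result.
#' @param clamp Optional length-2 numeric: clamp output into this range.
#' @return Reflectance in the same shape as `dn`, with attribute
#'   `diagnostics`: data frame of per-band counts `n_negative`,
#'   `n_above_one`.
#' @export
apply_calibration <- function(dn, fit, clamp = NULL) {
  stopifnot(inherits(fit, "calibration_fit"))
  nb <- fit$n_bands
  shape <- if (is.array(dn) && length(dim(dn)) == 3L) "array"
           else if (is.matrix(dn)) "matrix" else "vector"
  bands_of <- function(j) switch(shape,
    array = dn[, , j], matrix = dn[, j], vector = dn[j])
  nbands_in <- switch(shape, array = dim(dn)[3], matrix = ncol(dn),
                      vector = length(dn))
  if (nbands_in != nb)
    stop(sprintf("image has %d bands but fit has %d", nbands_in, nb))
  out <- dn * NA_real_
  neg <- above <- integer(nb)
  for (j in seq_len(nb)) {
    y <- apply_band_calibration(bands_of(j), fit$bands[[j]], fit$method)
    neg[j] <- sum(y < 0)
    above[j] <- sum(y > 1)
    if (!is.null(clamp)) y <- pmin(pmax(y, clamp[1]), clamp[2])
    switch(shape,
      array = { out[, , j] <- y },
      matrix = { out[, j] <- y },
      vector = { out[j] <- y })
  }
  attr(out, "diagnostics") <- data.frame(band = seq_len(nb),
                                         n_negative = neg,
                                         n_above_one = above)
  out
}

#' Per-band calibration accuracy against reference reflectance
#'
#' Compares estimated band reflectance with band-equivalent reference
#' reflectance, reporting the mean relative percent error (MRPE) and RMSE
#' per band.
#'
#' @param estimated Matrix, observations x bands.
#' @param reference Matrix of reference reflectance, same shape; must be
#'   non-zero everywhere for MRPE.
#' @return Data frame with columns `band`, `mrpe_pct`, `rmse`.
#' @export
evaluate_calibration <- function(estimated, reference) {
  estimated <- as.matrix(estimated); reference <- as.matrix(reference)
  stopifnot(dim(estimated) == dim(reference))
  data.frame(
    band = seq_len(ncol(reference)),
    mrpe_pct = vapply(seq_len(ncol(reference)), function(j)
      mrpe(reference[, j], estimated[, j]), numeric(1)),
    rmse = vapply(seq_len(ncol(reference)), function(j)
      rmse(reference[, j], estimated[, j]), numeric(1)))
}
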