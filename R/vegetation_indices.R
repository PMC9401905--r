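# Vegetation indices over calibrated band reflectance.

#' Names of the supported vegetation indices
#' @export
vi_names <- c("RVI", "NDVI", "NDRE", "VARI", "EVI2",
              "CIrededge", "CIgreen", "MCARI", "WDRVI")

#' Map semantic band roles to camera band centers
#'
#' Vegetation-index formulas are written over semantic bands (blue,
#' green, red, red edge, NIR); this object pins each role to a center
#' wavelength present in the band set. The red band may be 670 or 680 nm
#' and the NIR band any of 800/850/900/950 nm.
#'
#' @param blue,green,red,rededge700,rededge720,nir Center wavelengths (nm).
#' @param centers Available band centers (defaults to the 12-band camera).
#' @return An object of class `band_assignment`.
#' @export
band_assignment <- function(blue = 490, green = 550, red = 670,
                            rededge700 = 700, rededge720 = 720, nir = 800,
                            centers = mca12_centers) {
  a <- list(blue = blue, green = green, red = red,
            rededge700 = rededge700, rededge720 = rededge720, nir = nir)
  for (nm in names(a))
    if (!a[[nm]] %in% centers)
      stop(sprintf("%s band %g nm is not among the camera centers", nm, a[[nm]]))
  if (!red %in% c(670, 680)) stop("red band must be 670 or 680 nm")
  if (!nir %in% c(800, 850, 900, 950))
    stop("nir band must be one of 800, 850, 900, 950 nm")
  structure(c(a, list(centers = as.numeric(centers))),
            class = "band_assignment")
}

# Extract the plane/column/element for a given center wavelength.
band_slice <- function(reflectance, center, centers) {
  j <- match(center, centers)
  if (is.na(j)) stop("band ", center, " nm not present")
  if (is.array(reflectance) && length(dim(reflectance)) == 3L)
    reflectance[, , j]
  else if (is.matrix(reflectance)) reflectance[, j]
  else reflectance[j]
}

safe_div <- function(num, den) {
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Compute one vegetation index
#'
#' Formulas (N = NIR, R = red, G = green, B = blue, RE = red edge 720 nm,
#' R700/R670/R550 = reflectance at those centers):
#' \itemize{
#'  \item RVI = N / R
#'  \item NDVI = (N - R) / (N + R)
#'  \item NDRE = (N - RE) / (N + RE)
#'  \item VARI = (G - R) / (G + R - B)
#'  \item EVI2 = 2.5 (N - R) / (N + 2.4 R + 1)
#'  \item CIrededge = N / RE - 1
#'  \item CIgreen = N / G - 1
#'  \item MCARI = \[(R700 - R670) - 0.2 (R700 - R550)\] (R700 / R670)
#'  \item WDRVI = (alpha N - R) / (alpha N + R), default alpha = 0.1
#' }
#' Zero denominators yield `NA` (counted in the `"diagnostics"`
#' attribute), never an error, so whole-image maps always complete.
#'
#' @param name Index name, one of [vi_names].
#' @param reflectance 3-D array (rows x cols x bands), matrix
#'   (observations x bands) or vector (one observation).
#' @param assignment A [band_assignment()].
#' @param alpha Weight for WDRVI; default 0.1.
#' @return Index values in the shape of one band of the input, with
#'   attribute `diagnostics` = number of non-finite results.
#' @export
compute_index <- function(name, reflectance, assignment = band_assignment(),
                          alpha = 0.1) {
  if (!name %in% vi_names)
    stop("unknown index '", name, "'; supported: ",
         paste(vi_names, collapse = ", "))
  stopifnot(inherits(assignment, "band_assignment"))
  cc <- assignment$centers
  g <- function(role) band_slice(reflectance, assignment[[role]], cc)
  at <- function(center) band_slice(reflectance, center, cc)
  out <- switch(name,
    RVI = safe_div(g("nir"), g("red")),
    NDVI = safe_div(g("nir") - g("red"), g("nir") + g("red")),
    NDRE = safe_div(g("nir") - g("rededge720"), g("nir") + g("rededge720")),
    VARI = safe_div(g("green") - g("red"), g("green") + g("red") - g("blue")),
    EVI2 = 2.5 * (g("nir") - g("red")) / (g("nir") + 2.4 * g("red") + 1),
    CIrededge = safe_div(g("nir"), g("rededge720")) - 1,
    CIgreen = safe_div(g("nir"), g("green")) - 1,
    MCARI = {
      r700 <- at(assignment$rededge700); r670 <- at(assignment$red)
      r550 <- at(assignment$green)
      ((r700 - r670) - 0.2 * (r700 - r550)) * safe_div(r700, r670)
    },
    WDRVI = safe_div(alpha * g("nir") - g("red"), alpha * g("nir") + g("red")))
  attr(out, "diagnostics") <- sum(!is.finite(out))
  out
}

#' Compute all nine vegetation indices
#'
#' @inheritParams compute_index
#' @return For matrix/vector input, a data frame with one column per
#'   index; for 3-D array input, a named list of index planes.
#' @export
compute_all_indices <- function(reflectance, assignment = band_assignment(),
                                alpha = 0.1) {
  vals <- lapply(vi_names, compute_index, reflectance = reflectance,
                 assignment = assignment, alpha = alpha)
  names(vals) <- vi_names
  if (is.array(reflectance) && length(dim(reflectance)) == 3L) return(vals)
  as.data.frame(lapply(vals, as.numeric))
}
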