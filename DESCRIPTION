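Package: uavcal
Title: Radiometric Calibration and Canopy Phenotyping for UAV Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converting raw digital numbers from multi-lens UAV
    multispectral cameras into surface reflectance and canopy traits.
    Implements three empirical-line radiometric calibration methods against
    grayscale reference panels - the classical empirical line (EL), the
    subband empirical line (SEL, power fit for low-reflectance visible
    bands), and a piecewise empirical line (PEL, proportional through the
    origin below a reflectance threshold and affine above it) - together
    with spectral-response-function convolution of field-spectrometer
    spectra to band-equivalent reflectance, nine common vegetation indices,
    fully constrained least-squares linear spectral unmixing with background
    enhancement and attenuation factors, view-zenith-angle and
    ground-sample-distance models for flight-altitude effects, linear
    vegetation-index to trait regression with standard error metrics, and a
    synthetic-scene generator that produces multi-altitude digital-number
    image stacks with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
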