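test_that("band set and camera profile enforce their invariants", {
  bs <- band_set()
  expect_length(bs$centers, 12)
  expect_true(all(diff(bs$centers) > 0))
  expect_error(band_set(c(500, 490)), "strictly increasing")
  expect_error(band_set(c(490, 550),
                        list(data.frame(w = c(1, 2), v = c(1, 1)))),
               "one response")
  expect_error(band_set(490, list(data.frame(w = c(1, 2), v = c(1, -1)))),
               ">= 0")
  cam <- mca12_profile(quiet = TRUE)
  expect_identical(cam$image_width, 1280L)
  expect_identical(cam$image_height, 1024L)
  expect_equal(cam$fov_h, 38.26)
  expect_equal(cam$fov_v, 30.97)
  expect_error(camera_profile(bs, fov_h = 200), "field of view")
  expect_error(hyperspectral_spectrum(c(400, 400), c(0.1, 0.1)),
               "strictly increasing")
  expect_error(hyperspectral_spectrum(c(400, 500), c(0.1, 1.6)), "1.5")
})

test_that("constant spectra convolve to the constant for arbitrary responses", {
  sp <- hyperspectral_spectrum(seq(400, 1000, by = 5), rep(0.5, 121))
  set.seed(42)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    wl <- sort(runif(n, 450, 990))
    wl <- wl[c(TRUE, diff(wl) > 1e-6)]
    if (length(wl) < 2) next
    resp <- data.frame(wavelength_nm = wl, weight = runif(length(wl)))
    resp$weight[1] <- resp$weight[1] + 0.1  # guard against all-zero
    expect_equal(band_equivalent_reflectance(sp, resp), 0.5,
                 tolerance = 1e-12)
  }
})

test_that("a delta-like response samples the spectrum at its location", {
  sp <- hyperspectral_spectrum(c(700, 900), c(0.2, 0.4))
  resp <- data.frame(wavelength_nm = c(799.5, 800.5), weight = c(1, 1))
  expect_equal(band_equivalent_reflectance(sp, resp), 0.3, tolerance = 1e-9)
})

test_that("quadrature matches a 0.01 nm brute-force oracle", {
  # triangular response on [660, 680] peaking at 670; linear spectrum
  resp <- data.frame(wavelength_nm = c(660, 670, 680), weight = c(0, 1, 0))
  sp <- hyperspectral_spectrum(seq(600, 700, by = 1),
                               0.001 * (seq(600, 700, by = 1) - 600))
  expect_equal(band_equivalent_reflectance(sp, resp),
               oracle_band_reflectance(sp, resp), tolerance = 1e-6)

  # piecewise-linear vegetation-like spectrum against every default band
  wl <- seq(400, 1000, by = 2.5)
  veg <- approx(c(400, 500, 550, 640, 680, 700, 750, 800, 1000),
                c(0.04, 0.05, 0.10, 0.05, 0.04, 0.12, 0.42, 0.48, 0.50),
                xout = wl)$y
  sp <- hyperspectral_spectrum(wl, veg)
  cam <- mca12_profile(quiet = TRUE)
  got <- convolve_all_bands(sp, cam)
  want <- vapply(cam$band_set$responses, function(r)
    oracle_band_reflectance(sp, r), numeric(1))
  expect_equal(unname(got), want, tolerance = 1e-6)
})

test_that("convolution is linear and bounded by the spectrum over the support", {
  wl <- seq(600, 750, by = 1)
  r1 <- 0.001 * (wl - 600)
  r2 <- 0.3 + 0.1 * sin(wl / 20)
  resp <- gaussian_response(670, fwhm = 12)
  s1 <- hyperspectral_spectrum(wl, r1)
  s2 <- hyperspectral_spectrum(wl, r2)
  mix <- hyperspectral_spectrum(wl, 0.3 * r1 + 0.7 * r2)
  expect_equal(band_equivalent_reflectance(mix, resp),
               0.3 * band_equivalent_reflectance(s1, resp) +
               0.7 * band_equivalent_reflectance(s2, resp),
               tolerance = 1e-10)
  v <- band_equivalent_reflectance(s2, resp)
  sup <- wl >= min(resp$wavelength_nm) & wl <= max(resp$wavelength_nm)
  expect_gte(v, min(r2[sup]))
  expect_lte(v, max(r2[sup]))
})

test_that("step spectra land on the step value per band group", {
  wl <- seq(400, 1000, by = 0.5)
  sp <- hyperspectral_spectrum(wl, ifelse(wl < 700, 0.05, 0.5))
  cam <- mca12_profile(response_fwhm = 4, quiet = TRUE)
  v <- convolve_all_bands(sp, cam)
  expect_equal(unname(v[c("490", "520", "550", "570", "670", "680")]),
               rep(0.05, 6), tolerance = 1e-6)
  expect_equal(unname(v[c("720", "800", "850", "900", "950")]),
               rep(0.5, 6 - 1), tolerance = 1e-6)
})

test_that("coverage and degenerate responses raise errors", {
  sp <- hyperspectral_spectrum(c(500, 600), c(0.1, 0.2))
  expect_error(band_equivalent_reflectance(
    sp, data.frame(wavelength_nm = c(590, 650), weight = c(1, 1))),
    "does not cover")
  expect_error(band_equivalent_reflectance(
    sp, data.frame(wavelength_nm = c(510, 520), weight = c(0, 0))),
    "degenerate")
  cam <- mca12_profile(response_fwhm = NA)
  spw <- hyperspectral_spectrum(seq(400, 1000, 10), rep(0.3, 61))
  expect_error(convolve_all_bands(spw, cam), "without a spectral response")
})

test_that("spectrum and camera-profile files round trip", {
  sp <- hyperspectral_spectrum(seq(400, 1000, 10), rep(0.3, 61))
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = sp$wavelength_nm,
                       reflectance = sp$reflectance), f, row.names = FALSE)
  expect_equal(read_spectrum_csv(f)$reflectance, sp$reflectance)
  cam <- mca12_profile(quiet = TRUE)
  fj <- tempfile(fileext = ".json")
  write_camera_json(cam, fj)
  cam2 <- read_camera_json(fj)
  expect_equal(cam2$band_set$centers, cam$band_set$centers)
  expect_equal(cam2$fov_h, cam$fov_h)
  expect_equal(cam2$band_set$responses[[1]]$weight,
               cam$band_set$responses[[1]]$weight)
})
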