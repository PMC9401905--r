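test_that("generated endmembers honor their structural constraints across seeds", {
  nir <- 9:12; red <- 5
  for (s in c(1, 7, 23)) {
    em <- make_endmembers(s)
    sp <- em$spectra
    expect_identical(rownames(sp), canonical_endmember_labels)
    for (bg in c("light_water", "shaded_water", "light_soil", "shaded_soil"))
      expect_true(all(sp["light_leaf", nir] > sp[bg, nir]), info = bg)
    expect_lt(sp["light_leaf", red], sp["light_soil", red])
    for (pair in list(c("shaded_leaf", "light_leaf"),
                      c("shaded_water", "light_water"),
                      c("shaded_soil", "light_soil")))
      expect_true(all(sp[pair[1], ] < sp[pair[2], ]))
  }
  expect_false(isTRUE(all.equal(make_endmembers(1)$spectra,
                                make_endmembers(2)$spectra)))
  # shading factor 1 collapses shaded onto light exactly
  em1 <- make_endmembers(5, shading = 1)
  expect_identical(em1$spectra["shaded_leaf", ], em1$spectra["light_leaf", ])
})

test_that("sensor transfers invert their calibration models and stay monotone", {
  for (kind in c("affine", "piecewise", "power")) {
    tr <- default_transfer(kind)
    y <- seq(0.005, 0.95, length.out = 60)
    for (j in c(1, 7, 8, 12)) {
      dn <- dn_from_reflectance(tr, matrix(y, nrow = length(y),
                                           ncol = 12))[, j]
      expect_true(all(diff(dn) > 0), info = paste(kind, j))
      expect_true(all(dn >= 0))
    }
  }
  expect_error(sensor_transfer("affine", data.frame(a = -1, b = 0)),
               "positive")
  expect_warning(
    sensor_transfer("piecewise",
                    data.frame(a4 = 1e-3, a5 = 9e-4, b5 = 0.05)),
    "non-monotone")
})

test_that("scenes are bit-reproducible from their seed", {
  spec <- scene_spec(altitudes = c(100, 150), seed = 42)
  tr <- default_transfer("affine", noise_sd = 2)
  s1 <- make_scene(spec, tr)
  s2 <- make_scene(spec, tr)
  expect_identical(s1$altitudes[["100"]]$dn, s2$altitudes[["100"]]$dn)
  expect_identical(s1$altitudes[["150"]]$dn, s2$altitudes[["150"]]$dn)
  s3 <- make_scene(scene_spec(altitudes = c(100, 150), seed = 43), tr)
  expect_false(identical(s1$altitudes[["100"]]$dn, s3$altitudes[["100"]]$dn))
})

test_that("rendered reflectance is the abundance-weighted endmember mix", {
  spec <- scene_spec(altitudes = 100, seed = 3)
  sc <- make_scene(spec, default_transfer("affine"))
  b <- sc$altitudes[["100"]]
  E <- sc$endmembers$spectra
  d <- dim(b$abundance)
  ab <- matrix(b$abundance, d[1] * d[2], d[3])
  rf <- matrix(b$reflectance, d[1] * d[2], dim(b$reflectance)[3])
  ok <- !is.na(ab[, 1])              # panel pixels carry no abundance
  expect_lt(max(abs(rf[ok, ] - ab[ok, ] %*% E)), 1e-12)
  sums <- rowSums(ab[ok, , drop = FALSE])
  expect_lt(max(abs(sums - 1)), 1e-12)
  for (p in b$plots) {
    expect_equal(sum(p$abundance), 1, tolerance = 1e-12)
    expect_true(all(p$abundance >= 0))
  }
})

test_that("zero geometry gain decouples reflectance from altitude", {
  spec <- scene_spec(altitudes = c(60, 120, 250), g = 0, seed = 2)
  sc <- make_scene(spec, default_transfer("affine"))
  r1 <- sc$altitudes[[1]]$plots[[1]]$reflectance
  r2 <- sc$altitudes[[2]]$plots[[1]]$reflectance
  r3 <- sc$altitudes[[3]]$plots[[1]]$reflectance
  expect_equal(r1, r2, tolerance = 1e-14)
  expect_equal(r2, r3, tolerance = 1e-14)
})

test_that("positive gain makes NIR reflectance non-increasing in VZA", {
  for (s in 1:3) {
    spec <- scene_spec(plot_size_m = 10, g = 0.6, seed = s)
    sc <- make_scene(spec, default_transfer("affine"))
    corner <- which.max(vapply(sc$altitudes[[1]]$plots,
                               `[[`, numeric(1), "ground_offset"))
    vza <- vapply(sc$altitudes, function(b) b$plots[[corner]]$vza, numeric(1))
    nir <- vapply(sc$altitudes, function(b) b$plots[[corner]]$reflectance[9],
                  numeric(1))
    bgf <- vapply(sc$altitudes, function(b)
      b$plots[[corner]]$background_fraction, numeric(1))
    ord <- order(vza)
    expect_true(all(diff(bgf[ord]) >= -1e-12))
    expect_true(all(diff(nir[ord]) <= 1e-12))
  }
})

test_that("panels render noiseless at their nominal reflectance", {
  spec <- scene_spec(altitudes = 100, seed = 1)
  tr <- default_transfer("affine", noise_sd = 3)
  sc <- make_scene(spec, tr)
  b <- sc$altitudes[["100"]]
  pd <- panel_dn_matrix(b)
  clean <- dn_from_reflectance(default_transfer("affine"),
                               matrix(rep(pd$reflectance, 12), ncol = 12))
  expect_equal(pd$dn, unname(as.matrix(clean)), tolerance = 1e-12)
  expect_equal(pd$reflectance, spec$panel_reflectances)
})

test_that("trait datasets are reproducible with calibrated noise", {
  d1 <- make_trait_dataset(n = 200, noise_sd = 0.3, seed = 10)
  d2 <- make_trait_dataset(n = 200, noise_sd = 0.3, seed = 10)
  expect_identical(d1, d2)
  d0 <- make_trait_dataset(n = 50, noise_sd = 0, seed = 10)
  f <- fit_trait_model(d0$CIgreen, d0$LAI)
  expect_equal(f$slope, 0.336, tolerance = 1e-10)
  expect_equal(f$intercept, 1.0176, tolerance = 1e-10)
  resid <- d1$LAI - (0.336 * d1$CIgreen + 1.0176)
  expect_lt(abs(sd(resid) - 0.3) / 0.3, 0.15)
  expect_error(make_trait_dataset(n = 2), "at least 3")
})
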