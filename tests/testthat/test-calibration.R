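test_that("panel ROI extraction averages the ROI and validates bounds", {
  img <- matrix(500, 20, 20)
  p <- calibration_panel("p", c(2, 2, 6, 6), 0.12)
  expect_equal(extract_panel_dn(img, p), 500)
  img2 <- matrix(0, 4, 4)
  img2[1:2, 1:2] <- c(100, 300, 200, 400)
  expect_equal(extract_panel_dn(img2, calibration_panel("q", c(0, 0, 2, 2), 0.5)),
               250)
  expect_error(extract_panel_dn(matrix(0, 3, 3),
                                calibration_panel("r", c(0, 0, 5, 5), 0.5)),
               "outside")
  expect_error(calibration_panel("s", c(2, 2, 2, 6), 0.1), "empty")
  expect_error(calibration_panel("t", c(0, 0, 2, 2), 1.2), "\\(0, 1\\)")
})

test_that("EL recovers two-point and exact affine panel sets", {
  f <- fit_el(c(100, 1000), c(0.03, 0.80))
  expect_equal(f$a1, 0.77 / 900, tolerance = 1e-12)
  expect_equal(f$b1, 0.03 - 0.77 / 900 * 100, tolerance = 1e-12)
  dn <- c(40, 75, 140, 260, 390, 510, 590, 820)
  f2 <- fit_el(dn, 0.001 * dn + 0.01)
  expect_equal(f2$a1, 0.001, tolerance = 1e-12)
  expect_equal(f2$b1, 0.01, tolerance = 1e-12)
  expect_error(fit_el(c(100, 100), c(0.1, 0.2)), "distinct")
})

test_that("EL matches the closed-form least-squares oracle under noise", {
  set.seed(11)
  dn <- c(40, 75, 140, 260, 390, 510, 590, 820)
  y <- 0.001 * dn + 0.01 + rnorm(8, 0, 0.002)
  f <- fit_el(dn, y)
  o <- oracle_ols(dn, y)
  expect_equal(f$a1, o$slope, tolerance = 1e-10)
  expect_equal(f$b1, o$intercept, tolerance = 1e-10)
})

test_that("SEL power fit recovers exact power-law panels and degenerates at b2 = 1", {
  dn <- c(40, 75, 140, 260, 390, 510, 590)
  f <- fit_sel(dn, 0.001 * dn^1.2, "power")
  expect_equal(f$a2, 0.001, tolerance = 1e-9)
  expect_equal(f$b2, 1.2, tolerance = 1e-9)
  flin <- fit_sel(dn, 0.0009 * dn + 0.002, "linear")
  expect_equal(flin$a3, 0.0009, tolerance = 1e-12)
  expect_equal(flin$b3, 0.002, tolerance = 1e-12)
  f1 <- fit_sel(dn, 5e-4 * dn, "power")
  expect_equal(f1$a2 * dn^f1$b2, 5e-4 * dn, tolerance = 1e-9)
  expect_error(fit_sel(c(-1, 10), c(0.1, 0.2), "power"), "positive")
})

test_that("PEL fits the proportional segment through the origin on dark panels", {
  dn_dark <- c(60, 120)                      # exactly on y = 5e-4 x
  dn_rest <- ((c(0.12, 0.24, 0.36, 0.48, 0.56, 0.80)) + 0.02) / 9e-4
  dn <- c(dn_dark, dn_rest)
  y <- c(5e-4 * dn_dark, 9e-4 * dn_rest - 0.02)
  f <- fit_pel(dn, y)
  expect_equal(f$a4, 5e-4, tolerance = 1e-12)

  # darkest two panels deviating below an affine truth: a4 matches the
  # independent through-origin oracle on those panels
  set.seed(3)
  dn8 <- c(35, 70, 150, 290, 420, 560, 640, 900)
  y8 <- 9e-4 * dn8 - 0.002
  y8[1:2] <- y8[1:2] * 0.8
  f2 <- fit_pel(dn8, y8, low_panel_max = max(y8[2]) + 1e-9)
  a4_oracle <- sum(dn8[1:2] * y8[1:2]) / sum(dn8[1:2]^2)
  expect_equal(f2$a4, a4_oracle, tolerance = 1e-10)
  expect_warning(fit_pel(c(100, 500), c(0.2, 0.6)), "falls back")
})

test_that("PEL equals EL on purely affine panels and switches on the linear prediction", {
  dn <- c(40, 75, 140, 260, 390, 510, 590, 820)
  y <- 9e-4 * dn - 0.002
  y[y <= 0] <- 0.001   # keep panels in (0, 1)
  fel <- fit_el(dn, y)
  fpel <- fit_pel(dn, y)
  expect_equal(fpel$a5, fel$a1, tolerance = 1e-12)
  expect_equal(fpel$b5, fel$b1, tolerance = 1e-12)

  fit <- fit_calibration(matrix(c(40, 200), 2, 1),
                         matrix(c(0.02, 0.16), 2, 1), "PEL")
  fit$bands[[1]] <- list(a4 = 5e-4, a5 = 9e-4, b5 = -0.02, tau = 0.03,
                         rmse = 0, fallback = FALSE)
  out <- apply_calibration(c(40), fit)
  expect_equal(as.numeric(out), 5e-4 * 40, tolerance = 1e-12)  # y_lin = 0.016
  out2 <- apply_calibration(c(200), fit)
  expect_equal(as.numeric(out2), 0.16, tolerance = 1e-12)      # y_lin > tau
})

test_that("apply_calibration preserves negatives and reports diagnostics", {
  fit <- fit_calibration(matrix(c(100, 1000), 2, 1),
                         matrix(c(0.03, 0.80), 2, 1), "EL")
  out <- apply_calibration(matrix(c(0, 500), 2, 1), fit)
  expect_equal(out[1, 1], fit$bands[[1]]$b1)
  expect_lt(out[1, 1], 0)
  expect_equal(attr(out, "diagnostics")$n_negative, 1L)
  clamped <- apply_calibration(matrix(c(0, 500), 2, 1), fit, clamp = c(0, 1))
  expect_equal(clamped[1, 1], 0)
  # identity fit passes DN through
  idfit <- fit_calibration(matrix(c(0.2, 0.8), 2, 1),
                           matrix(c(0.2, 0.8), 2, 1), "EL")
  expect_equal(as.numeric(apply_calibration(c(0.37), idfit)), 0.37,
               tolerance = 1e-12)
  expect_error(apply_calibration(matrix(1, 2, 3), fit), "bands")
})

test_that("all methods recover reflectance exactly from invertible transfers", {
  spec <- scene_spec(altitudes = 100, seed = 5)
  for (kind in c("affine", "piecewise", "power")) {
    sc <- make_scene(spec, default_transfer(kind))
    b <- sc$altitudes[["100"]]
    pd <- panel_dn_matrix(b)
    method <- switch(kind, affine = "EL", piecewise = "PEL", power = "SEL")
    lpm <- if (kind == "piecewise") 0.03 else 0.06
    fit <- fit_calibration(pd$dn, pd$reflectance, method,
                           low_panel_max = lpm)
    out <- apply_calibration(b$dn, fit)
    expect_lt(max(abs(out - b$reflectance)), 1e-9)
  }
})

test_that("calibration methods are monotone in DN for positive slopes", {
  dn <- c(40, 75, 140, 260, 390, 510, 590, 820)
  y <- 0.001 * dn + 0.005
  x <- seq(0, 1000, by = 5)
  for (m in c("EL", "SEL", "PEL")) {
    fit <- fit_calibration(matrix(dn, 8, 1), matrix(y, 8, 1), m)
    out <- as.numeric(apply_calibration(matrix(x, length(x), 1), fit))
    expect_true(all(diff(out) >= -1e-12), info = m)
  }
})

test_that("evaluate_calibration reproduces hand-computed MRPE and RMSE", {
  est <- matrix(c(0.11, 0.18), 2, 1)
  ref <- matrix(c(0.10, 0.20), 2, 1)
  tab <- evaluate_calibration(est, ref)
  expect_equal(tab$mrpe_pct, 10)
  expect_equal(tab$rmse, sqrt((0.0001 + 0.0004) / 2), tolerance = 1e-12)
  same <- evaluate_calibration(ref, ref)
  expect_equal(same$mrpe_pct, 0)
  expect_equal(same$rmse, 0)
  one <- evaluate_calibration(matrix(0.2), matrix(0.1))
  expect_equal(one$mrpe_pct, 100)
  expect_equal(one$rmse, 0.1)
})
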