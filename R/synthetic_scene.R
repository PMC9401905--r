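# Synthetic multi-altitude scene generator with known ground truth.
#
# Emulates a paddy-rice field campaign: six endmember spectra (sunlit and
# shaded leaf, water, soil), plot abundances that respond to view zenith
# angle through a background fraction f(VZA) = clip(f0 + g tan(VZA), 0, 1),
# eight grayscale calibration panels, and per-band sensor transfer
# functions (the forward inverses of the EL/SEL/PEL calibration models)
# mapping reflectance to digital numbers, with optional additive Gaussian
# DN noise. Panels are rendered noiseless so calibration-recovery tests
# isolate method error.

# Evaluate expr under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a six-endmember spectral library
#'
#' Spectra are built over the 12 camera band centers with seeded
#' band-wise jitter, under structural constraints that hold by
#' construction: leaf NIR reflectance exceeds every background NIR
#' reflectance, leaf red reflectance is below sunlit-soil red
#' reflectance, and each shaded spectrum is its sunlit counterpart
#' scaled per band by `shading^gamma_b` with band exponents
#' `gamma_b` in \[0.8, 1.25\] (a spectrally non-uniform shadow, which
#' keeps the endmember matrix full rank; at `shading = 1` the shaded and
#' sunlit spectra coincide exactly).
#'
#' @param seed Integer seed.
#' @param shading Shading factor in (0, 1]; default 0.55.
#' @param centers Band centers; the canonical 12-band layout.
#' @return An [endmember_set()] with the canonical six labels.
#' @export
make_endmembers <- function(seed = 1L, shading = 0.55,
                            centers = mca12_centers) {
  stopifnot(shading > 0, shading <= 1)
  base <- rbind(
    light_leaf  = c(0.045, 0.060, 0.090, 0.080, 0.045, 0.045,
                    0.120, 0.280, 0.480, 0.500, 0.510, 0.500),
    light_water = c(0.060, 0.055, 0.050, 0.045, 0.035, 0.033,
                    0.030, 0.025, 0.020, 0.015, 0.012, 0.010),
    light_soil  = c(0.100, 0.120, 0.140, 0.160, 0.200, 0.210,
                    0.220, 0.230, 0.260, 0.270, 0.280, 0.290))
  rng <- with_seed(seed, list(
    jit = matrix(stats::runif(length(base), 0.9, 1.1),
                 nrow(base), ncol(base)),
    gamma = matrix(stats::runif(3 * ncol(base), 0.8, 1.25),
                   3, ncol(base))))
  light <- base * rng$jit
  sh <- shading^rng$gamma          # rows: leaf, water, soil exponents
  spectra <- rbind(
    light_leaf = light["light_leaf", ],
    shaded_leaf = sh[1, ] * light["light_leaf", ],
    light_water = light["light_water", ],
    shaded_water = sh[2, ] * light["light_water", ],
    light_soil = light["light_soil", ],
    shaded_soil = sh[3, ] * light["light_soil", ])
  colnames(spectra) <- as.character(centers)
  endmember_set(spectra, labels = canonical_endmember_labels)
}

#' Construct a per-band sensor transfer function
#'
#' The forward map from true reflectance to DN, per band. Kinds:
#' `"affine"` inverts `y = a x + b` (DN = (y - b)/a); `"piecewise"`
#' inverts the two-segment calibration model (DN = y/a4 below the
#' reflectance threshold `tau`, DN = (y - b5)/a5 above); `"power"`
#' inverts `y = a x^b` for the visible bands (1-7) and an affine map for
#' the red-edge/NIR bands.
#'
#' @param kind `"affine"`, `"piecewise"` or `"power"`.
#' @param params Data frame with one row per band. Columns: `a`, `b`
#'   (affine); `a4`, `a5`, `b5` (piecewise); `a`, `b` plus affine
#'   `a_lin`, `b_lin` for bands 8+ (power).
#' @param tau Breakpoint reflectance for the piecewise kind; default 0.03.
#' @param noise_sd Additive Gaussian DN noise standard deviation
#'   (applied by [make_scene()]; panels stay noiseless); default 0.
#' @return An object of class `sensor_transfer`.
#' @export
sensor_transfer <- function(kind = c("affine", "piecewise", "power"),
                            params, tau = 0.03, noise_sd = 0) {
  kind <- match.arg(kind)
  params <- as.data.frame(params)
  need <- switch(kind, affine = c("a", "b"),
                 piecewise = c("a4", "a5", "b5"),
                 power = c("a", "b", "a_lin", "b_lin"))
  if (!all(need %in% names(params)))
    stop("params must have columns: ", paste(need, collapse = ", "))
  if (kind == "affine" && any(params$a <= 0))
    stop("affine slope must be positive")
  if (kind == "piecewise") {
    if (any(params$a4 <= 0) || any(params$a5 <= 0))
      stop("piecewise slopes must be positive")
    if (any(params$a5 * tau / params$a4 + params$b5 > tau + 1e-12))
      warning("piecewise transfer is discontinuous at tau in a direction ",
              "that makes the forward map non-monotone")
  }
  structure(list(kind = kind, params = params, tau = tau,
                 noise_sd = noise_sd, n_bands = nrow(params)),
            class = "sensor_transfer")
}

#' Continuous piecewise transfer parameters
#'
#' Convenience constructor for a piecewise transfer whose two segments
#' meet at the threshold (`b5 = tau (1 - a5/a4)`), so the forward map is
#' continuous and strictly increasing.
#'
#' @param a4,a5 Proportional and affine slopes (vectors, one per band).
#' @param tau Breakpoint reflectance; default 0.03.
#' @param noise_sd DN noise SD; default 0.
#' @return A `"piecewise"` [sensor_transfer()].
#' @export
continuous_piecewise_transfer <- function(a4, a5, tau = 0.03, noise_sd = 0) {
  b5 <- tau * (1 - a5 / a4)
  sensor_transfer("piecewise", data.frame(a4 = a4, a5 = a5, b5 = b5),
                  tau = tau, noise_sd = noise_sd)
}

#' Default per-band transfer parameters
#'
#' Deterministic band-varying coefficients in a realistic range for a
#' 10-bit sensor (affine slopes around 9e-4, small offsets).
#'
#' @param kind Transfer kind.
#' @param n_bands Number of bands; default 12.
#' @param tau Breakpoint for the piecewise kind.
#' @param noise_sd DN noise SD.
#' @return A [sensor_transfer()].
#' @export
default_transfer <- function(kind = c("affine", "piecewise", "power"),
                             n_bands = 12L, tau = 0.03, noise_sd = 0) {
  kind <- match.arg(kind)
  j <- seq_len(n_bands)
  a <- 8e-4 + 2e-5 * j
  b <- -0.02 + 0.002 * j
  switch(kind,
    affine = sensor_transfer("affine", data.frame(a = a, b = b),
                             noise_sd = noise_sd),
    piecewise = continuous_piecewise_transfer(a4 = 0.6 * a, a5 = a,
                                              tau = tau, noise_sd = noise_sd),
    power = sensor_transfer("power",
      data.frame(a = 1e-3 + 2e-5 * j, b = 1.1 + 0.01 * j,
                 a_lin = a, b_lin = b), noise_sd = noise_sd))
}

#' Convert true reflectance to noiseless DN
#'
#' @param transfer A [sensor_transfer()].
#' @param reflectance 3-D array, matrix (obs x bands) or vector.
#' @return DN in the same shape (noise is not applied here).
#' @export
dn_from_reflectance <- function(transfer, reflectance) {
  stopifnot(inherits(transfer, "sensor_transfer"))
  p <- transfer$params
  fwd <- function(y, j) switch(transfer$kind,
    affine = (y - p$b[j]) / p$a[j],
    piecewise = ifelse(y <= transfer$tau, y / p$a4[j],
                       (y - p$b5[j]) / p$a5[j]),
    power = if (j <= 7L) (pmax(y, 0) / p$a[j])^(1 / p$b[j])
            else (y - p$b_lin[j]) / p$a_lin[j])
  if (is.array(reflectance) && length(dim(reflectance)) == 3L) {
    out <- reflectance * NA_real_
    for (j in seq_len(dim(reflectance)[3]))
      out[, , j] <- pmax(fwd(reflectance[, , j], j), 0)
    out
  } else if (is.matrix(reflectance)) {
    out <- reflectance * NA_real_
    for (j in seq_len(ncol(reflectance)))
      out[, j] <- pmax(fwd(reflectance[, j], j), 0)
    out
  } else {
    vapply(seq_along(reflectance),
           function(j) max(fwd(reflectance[j], j), 0), numeric(1))
  }
}

#' Specify a synthetic scene
#'
#' @param altitudes Flight altitudes (m); defaults to the 14-altitude
#'   campaign layout 60-250 m.
#' @param plot_rows,plot_cols Plot grid; default 2 x 3.
#' @param plot_size_m Plot edge length (m); default 6.
#' @param panel_reflectances Nominal panel reflectances; default the
#'   eight grayscale panels 3-80%.
#' @param panel_size_m Panel edge length (m); default 2.
#' @param f0 Background fraction at nadir; default 0.15.
#' @param g Gain of the background fraction in tan(VZA); default 0.5.
#' @param leaf_light_frac Sunlit share of the canopy fraction; default 0.7.
#' @param bg_weights Split of the background fraction over (light water,
#'   shaded water, light soil, shaded soil); default c(0.3, 0.2, 0.3, 0.2).
#' @param seed Scene seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(altitudes = c(60, 70, 80, 90, 100, 110, 120, 130,
                                     150, 170, 190, 210, 230, 250),
                       plot_rows = 2L, plot_cols = 3L, plot_size_m = 6,
                       panel_reflectances = c(0.03, 0.06, 0.12, 0.24,
                                              0.36, 0.48, 0.56, 0.80),
                       panel_size_m = 2, f0 = 0.15, g = 0.5,
                       leaf_light_frac = 0.7,
                       bg_weights = c(0.3, 0.2, 0.3, 0.2),
                       seed = 1L) {
  if (any(altitudes <= 0)) stop("altitudes must be positive")
  if (f0 < 0 || f0 > 1) stop("f0 must lie in [0, 1]")
  if (any(panel_reflectances <= 0 | panel_reflectances >= 1))
    stop("panel reflectances must lie in (0, 1)")
  bg_weights <- bg_weights / sum(bg_weights)
  structure(list(altitudes = altitudes, plot_rows = as.integer(plot_rows),
                 plot_cols = as.integer(plot_cols),
                 plot_size_m = plot_size_m,
                 panel_reflectances = panel_reflectances,
                 panel_size_m = panel_size_m, f0 = f0, g = g,
                 leaf_light_frac = leaf_light_frac,
                 bg_weights = bg_weights, seed = as.integer(seed)),
            class = "scene_spec")
}

# Plot ground-coordinate centers (m from nadir), on a centered grid with
# 1.5x plot-size spacing.
plot_centers <- function(spec) {
  sp <- 1.5 * spec$plot_size_m
  gx <- (seq_len(spec$plot_cols) - (spec$plot_cols + 1) / 2) * sp
  gy <- (seq_len(spec$plot_rows) - (spec$plot_rows + 1) / 2) * sp
  expand.grid(gy = gy, gx = gx)
}

#' Plot abundance implied by viewing geometry
#'
#' Background fraction `f = clip(f0 + g tan(VZA), 0, 1)` split over the
#' four background endmembers; the canopy fraction `1 - f` split between
#' sunlit and shaded leaf.
#'
#' @param spec A [scene_spec()].
#' @param vza_deg View zenith angle in degrees.
#' @return Named abundance vector over the canonical six labels.
#' @export
plot_abundance <- function(spec, vza_deg) {
  f <- min(max(spec$f0 + spec$g * tan(vza_deg * pi / 180), 0), 1)
  leaf <- 1 - f
  stats::setNames(
    c(leaf * spec$leaf_light_frac, leaf * (1 - spec$leaf_light_frac),
      f * spec$bg_weights),
    canonical_endmember_labels)
}

#' Render a multi-altitude synthetic scene
#'
#' For each altitude the scene contains: a DN image stack (bands as
#' planes), the true reflectance stack, the true abundance stack, eight
#' noiseless calibration-panel ROIs, plot ROIs rescaled to the
#' altitude's ground sample distance, and the viewing geometry per plot.
#' Mixed reflectance is the abundance-weighted endmember combination;
#' DN = transfer(reflectance) plus optional truncated Gaussian noise.
#'
#' @param spec A [scene_spec()].
#' @param transfer A [sensor_transfer()].
#' @param endmembers An [endmember_set()]; default generated from the
#'   scene seed.
#' @param camera A [camera_profile()]; default a reduced-resolution
#'   160 x 128 profile with the reference FOV (full sensor size is
#'   memory-hungry for simulation).
#' @return An object of class `scene_bundle`: list with `spec`,
#'   `camera`, `endmembers`, `transfer`, and `altitudes`, a named list
#'   of per-altitude bundles (`dn`, `reflectance`, `abundance`,
#'   `panels`, `plots`, `gsd`, `altitude`).
#' @export
make_scene <- function(spec = scene_spec(), transfer = default_transfer("affine"),
                       endmembers = make_endmembers(spec$seed),
                       camera = mca12_profile(image_width = 160L,
                                              image_height = 128L,
                                              quiet = TRUE)) {
  stopifnot(inherits(spec, "scene_spec"), inherits(transfer, "sensor_transfer"),
            inherits(endmembers, "endmember_set"))
  nb <- ncol(endmembers$spectra)
  if (transfer$n_bands != nb)
    stop("transfer and endmembers disagree on band count")
  w <- camera$image_width; h <- camera$image_height
  centers <- plot_centers(spec)
  bg_ab <- stats::setNames(c(0.05, 0.05, 0.30, 0.20, 0.25, 0.15),
                           canonical_endmember_labels)
  bg_refl <- as.numeric(bg_ab %*% endmembers$spectra)
  # flooded-paddy strip along the bottom edge: nearly pure water, so the
  # scene carries genuinely dark (NIR reflectance < 3%) pixels
  water_ab <- stats::setNames(c(0, 0, 0.25, 0.75, 0, 0),
                              canonical_endmember_labels)
  water_refl <- as.numeric(water_ab %*% endmembers$spectra)

  render_altitude <- function(H, alt_seed) {
    gsd <- ground_sample_distance(H, camera)
    half_fp <- c(w, h) * gsd / 2
    if (spec$plot_size_m > 2 * min(half_fp))
      stop("plot larger than the image footprint at altitude ", H, " m")
    refl <- array(rep(bg_refl, each = w * h), dim = c(h, w, nb))
    abund <- array(rep(bg_ab, each = w * h),
                   dim = c(h, w, length(bg_ab)),
                   dimnames = list(NULL, NULL, names(bg_ab)))
    strip <- (h - max(2L, h %/% 8L) + 1L):h
    for (j in seq_len(nb)) refl[strip, , j] <- water_refl[j]
    for (k in seq_along(water_ab)) abund[strip, , k] <- water_ab[k]
    plots <- vector("list", nrow(centers))
    for (p in seq_len(nrow(centers))) {
      gx <- centers$gx[p]; gy <- centers$gy[p]
      offset <- sqrt(gx^2 + gy^2)
      vza <- view_zenith_angle(H, offset)
      ab <- plot_abundance(spec, vza)
      rf <- as.numeric(ab %*% endmembers$spectra)
      half_px <- spec$plot_size_m / gsd / 2
      cr <- h / 2 + gy / gsd; cc <- w / 2 + gx / gsd
      r0 <- max(0L, as.integer(round_half_away(cr - half_px)))
      c0 <- max(0L, as.integer(round_half_away(cc - half_px)))
      r1 <- min(h, max(r0 + 1L, as.integer(round_half_away(cr + half_px))))
      c1 <- min(w, max(c0 + 1L, as.integer(round_half_away(cc + half_px))))
      rows <- (r0 + 1L):r1; cols <- (c0 + 1L):c1
      for (j in seq_len(nb)) refl[rows, cols, j] <- rf[j]
      for (k in seq_along(ab)) abund[rows, cols, k] <- ab[k]
      plots[[p]] <- list(plot_id = p, roi = c(r0, c0, r1, c1),
                         ground_offset = offset, vza = vza,
                         abundance = ab, reflectance = rf,
                         background_fraction = sum(ab[background_labels]))
    }
    dn <- dn_from_reflectance(transfer, refl)
    if (transfer$noise_sd > 0) {
      noise <- with_seed(alt_seed,
                         array(stats::rnorm(length(dn), 0, transfer$noise_sd),
                               dim = dim(dn)))
      dn <- pmax(dn + noise, 0)
    }
    # panels: noiseless, along the top edge
    np <- length(spec$panel_reflectances)
    psz <- max(2L, as.integer(round_half_away(spec$panel_size_m / gsd)))
    gap <- max(1L, psz %/% 2L)
    panels <- vector("list", np)
    for (q in seq_len(np)) {
      c0 <- (q - 1L) * (psz + gap) + 1L
      c1 <- min(c0 + psz, w)
      if (c0 >= c1) stop("panels do not fit across the image at ", H, " m")
      roi <- c(1L, c0, min(1L + psz, h), c1)
      rows <- (roi[1] + 1L):roi[3]; cols <- (roi[2] + 1L):roi[4]
      y <- spec$panel_reflectances[q]
      pdn <- dn_from_reflectance(transfer, rep(y, nb))
      for (j in seq_len(nb)) {
        refl[rows, cols, j] <- y
        dn[rows, cols, j] <- pdn[j]
      }
      abund[rows, cols, ] <- NA_real_
      panels[[q]] <- calibration_panel(sprintf("panel_%02.0f", 100 * y),
                                       roi, y)
    }
    list(altitude = H, gsd = gsd, dn = dn, reflectance = refl,
         abundance = abund, panels = panels, plots = plots)
  }

  alt_seeds <- spec$seed + seq_along(spec$altitudes)
  bundles <- Map(render_altitude, spec$altitudes, alt_seeds)
  names(bundles) <- as.character(spec$altitudes)
  structure(list(spec = spec, camera = camera, endmembers = endmembers,
                 transfer = transfer, altitudes = bundles),
            class = "scene_bundle")
}

#' Mean panel DN matrix for one altitude bundle
#'
#' @param bundle One element of `scene$altitudes`.
#' @return List with `dn` (panels x bands matrix) and `reflectance`
#'   (per-panel nominal reflectance vector).
#' @export
panel_dn_matrix <- function(bundle) {
  nb <- dim(bundle$dn)[3]
  dn <- t(vapply(bundle$panels, function(p)
    vapply(seq_len(nb), function(j) extract_panel_dn(bundle$dn[, , j], p),
           numeric(1)), numeric(nb)))
  list(dn = dn,
       reflectance = vapply(bundle$panels, function(p) p$reflectance[1],
                            numeric(1)))
}

#' Simulate a linear VI-trait table
#'
#' Trait values follow `trait = slope * vi + intercept + N(0, noise_sd)`
#' with VI drawn uniformly over `vi_range`; fully reproducible from the
#' seed.
#'
#' @param n Number of plots (>= 3).
#' @param slope,intercept Linear coefficients; defaults follow a typical
#'   LAI-CIgreen relationship.
#' @param noise_sd Residual SD; default 0.3.
#' @param seed Integer seed.
#' @param vi_range Uniform range for the VI; default c(0.5, 6).
#' @param trait_name,vi_name Column labels.
#' @return Data frame with columns `plot_id`, `vi_name`, `trait_name`.
#' @export
make_trait_dataset <- function(n = 200L, slope = 0.336, intercept = 1.0176,
                               noise_sd = 0.3, seed = 1L,
                               vi_range = c(0.5, 6),
                               trait_name = "LAI", vi_name = "CIgreen") {
  if (n < 3L) stop("need at least 3 plots")
  dat <- with_seed(seed, {
    vi <- stats::runif(n, vi_range[1], vi_range[2])
    trait <- slope * vi + intercept + stats::rnorm(n, 0, noise_sd)
    data.frame(plot_id = seq_len(n), vi = vi, trait = trait)
  })
  names(dat) <- c("plot_id", vi_name, trait_name)
  dat
}
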