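# Raster and table I/O plus the end-to-end processing pipeline.
#
# Conventions used throughout: pixel coordinates are 0-based and
# row-major; ROIs are half-open rectangles (row0, col0, row1, col1).
# Integer DN imagery travels as 16-bit multi-page TIFF (lossless for
# counts up to 65535); floating-point rasters (reflectance, abundance)
# travel as flat-binary band-sequential files with an ENVI-style text
# header (`.bsq` + `.hdr`), stored as 64-bit doubles so write/read round
# trips are bit-exact. No installed package reads multiband float
# rasters, so the BSQ reader/writer lives here.

#' Write a multiband raster
#'
#' Dispatch on extension: `.tif`/`.tiff` stores integer DN as 16-bit
#' multi-page TIFF (values must be integral, in 0..65535); `.bsq` stores
#' any numeric raster as band-sequential 64-bit doubles with an
#' ENVI-style `.hdr` sidecar.
#'
#' @param x 3-D array, rows x cols x bands (a matrix is treated as one
#'   band).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multiband_raster <- function(x, path) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (any(x != round(x)) || any(x < 0) || any(x > 65535))
      stop("TIFF output carries integer DN in 0..65535; ",
           "use a .bsq path for floating-point rasters")
    planes <- lapply(seq_len(dim(x)[3]), function(j) x[, , j] / 65535)
    tiff::writeTIFF(planes, path, bits.per.sample = 16L,
                    compression = "none")
  } else if (ext == "bsq") {
    hdr <- sub("\\.bsq$", ".hdr", path, ignore.case = TRUE)
    con <- file(path, "wb")
    on.exit(close(con))
    for (j in seq_len(dim(x)[3]))
      writeBin(as.numeric(t(x[, , j])), con, size = 8,
               endian = "little")
    writeLines(c("ENVI",
                 paste("samples =", dim(x)[2]),
                 paste("lines =", dim(x)[1]),
                 paste("bands =", dim(x)[3]),
                 "header offset = 0",
                 "file type = ENVI Standard",
                 "data type = 5",
                 "interleave = bsq",
                 "byte order = 0"), hdr)
  } else stop("unsupported raster extension '.", ext, "'")
  invisible(path)
}

#' Read a multiband raster
#'
#' Reads `.tif`/`.tiff` (integer DN) or `.bsq` (+`.hdr`) rasters written
#' by [write_multiband_raster()].
#'
#' @param path Input path.
#' @param expected_bands Optional band count; a mismatch raises a
#'   warning (not an error).
#' @return 3-D array, rows x cols x bands.
#' @export
read_multiband_raster <- function(path, expected_bands = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (is.matrix(planes)) planes <- list(planes)
    x <- array(NA_real_, dim = c(dim(planes[[1]]), length(planes)))
    for (j in seq_along(planes)) x[, , j] <- planes[[j]]
  } else if (ext == "bsq") {
    hdr <- sub("\\.bsq$", ".hdr", path, ignore.case = TRUE)
    if (!file.exists(hdr)) stop("missing header sidecar: ", hdr)
    lines <- readLines(hdr)
    getv <- function(key) {
      m <- grep(paste0("^", key, " *="), lines, value = TRUE)
      if (!length(m)) stop("header lacks field '", key, "' in ", hdr)
      as.integer(sub(".*= *", "", m[1]))
    }
    w <- getv("samples"); h <- getv("lines"); nb <- getv("bands")
    if (getv("data type") != 5L) stop("only data type 5 (double) supported")
    con <- file(path, "rb")
    on.exit(close(con))
    x <- array(NA_real_, dim = c(h, w, nb))
    for (j in seq_len(nb))
      x[, , j] <- t(matrix(readBin(con, "double", n = w * h, size = 8,
                                   endian = "little"),
                           nrow = w))
  } else stop("unsupported raster extension '.", ext, "'")
  if (!is.null(expected_bands) && dim(x)[3] != expected_bands)
    warning(sprintf("raster %s has %d bands, expected %d; proceeding",
                    path, dim(x)[3], expected_bands))
  x
}

#' Read / write calibration panels as CSV
#'
#' Columns: `label`, `row0`, `col0`, `row1`, `col1`, then one
#' reflectance column per band named `r_<center>`.
#'
#' @param path File path.
#' @return `read_panels_csv` returns a list of [calibration_panel()].
#' @export
read_panels_csv <- function(path) {
  x <- utils::read.csv(path)
  rcols <- grep("^r_", names(x))
  if (!length(rcols)) stop("no reflectance columns (r_*) in ", path)
  lapply(seq_len(nrow(x)), function(i)
    calibration_panel(x$label[i],
                      c(x$row0[i], x$col0[i], x$row1[i], x$col1[i]),
                      as.numeric(x[i, rcols])))
}

#' @rdname read_panels_csv
#' @param panels List of [calibration_panel()].
#' @param centers Band centers used to name the reflectance columns.
#' @export
write_panels_csv <- function(panels, path, centers = mca12_centers) {
  refl <- t(vapply(panels, function(p) {
    r <- p$reflectance
    if (length(r) == 1L) rep(r, length(centers)) else r
  }, numeric(length(centers))))
  colnames(refl) <- paste0("r_", centers)
  df <- data.frame(label = vapply(panels, `[[`, character(1), "label"),
                   t(vapply(panels, `[[`, integer(4), "roi")), refl)
  names(df)[2:5] <- c("row0", "col0", "row1", "col1")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' @param images Named list (names = altitudes in m) of either raster
#'   file paths or in-memory 3-D DN arrays.
#' @param panels List of [calibration_panel()] or a panels CSV path.
#' @param camera A [camera_profile()] or camera JSON path.
#' @param method Calibration method: `"PEL"`, `"EL"` or `"SEL"`.
#' @param plots Named list of plot ROIs (0-based half-open
#'   `c(row0, col0, row1, col1)`) defined at `reference_altitude`.
#' @param reference_altitude Altitude (m) at which `plots` are defined.
#' @param assignment A [band_assignment()].
#' @param tau,low_panel_max PEL parameters.
#' @param clamp Optional length-2 reflectance clamp.
#' @param endmembers Optional [endmember_set()] (or CSV path) to also
#'   unmix plot spectra.
#' @param out_dir Output directory for tables and sidecars.
#' @param seed Integer seed recorded in the provenance (the pipeline
#'   itself is deterministic).
#' @param verbose Emit stage timings on stderr.
#' @return An object of class `run_config`.
#' @export
run_config <- function(images, panels, camera = mca12_profile(quiet = TRUE),
                       method = c("PEL", "EL", "SEL"), plots,
                       reference_altitude = as.numeric(names(images)[1]),
                       assignment = band_assignment(), tau = 0.03,
                       low_panel_max = 0.06, clamp = NULL,
                       endmembers = NULL, out_dir = tempfile("uavcal_run_"),
                       seed = 1L, verbose = FALSE) {
  method <- match.arg(method)
  if (is.null(names(images)) || any(!nzchar(names(images))))
    stop("'images' must be named by altitude (m)")
  if (is.character(panels)) panels <- read_panels_csv(panels)
  if (is.character(camera)) camera <- read_camera_json(camera)
  if (is.character(endmembers)) endmembers <- read_endmembers_csv(endmembers)
  if (is.null(names(plots)))
    names(plots) <- paste0("plot_", seq_along(plots))
  structure(list(images = images, panels = panels, camera = camera,
                 method = method, plots = plots,
                 reference_altitude = reference_altitude,
                 assignment = assignment, tau = tau,
                 low_panel_max = low_panel_max, clamp = clamp,
                 endmembers = endmembers, out_dir = out_dir,
                 seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

config_hash <- function(config) {
  # hash the canonical serialization (version 2 for stability)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config[setdiff(names(config), c("out_dir", "verbose"))]),
          tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

pipe_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full calibration-to-traits pipeline
#'
#' For every altitude: extract panel DN, fit the chosen calibration,
#' convert the image to reflectance, rescale the plot ROIs from the
#' reference altitude to the altitude's resolution, average plot
#' reflectance, compute the nine vegetation indices, and (when
#' endmembers are supplied) unmix the plot spectra and report background
#' enhancement/attenuation factors. Tables are written as CSV under
#' `config$out_dir` together with a JSON provenance sidecar carrying the
#' configuration hash; identical configurations produce byte-identical
#' tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `reflectance` (plot x band table),
#'   `indices`, `abundance` (or NULL), `calibration` (per-altitude
#'   fits), `diagnostics`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()["elapsed"]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  nb <- length(config$camera$band_set$centers)
  centers <- config$camera$band_set$centers
  refl_rows <- list(); vi_rows <- list(); ab_rows <- list()
  diag_rows <- list(); fits <- list()

  for (alt_name in names(config$images)) {
    H <- as.numeric(alt_name)
    img <- config$images[[alt_name]]
    if (is.character(img)) img <- read_multiband_raster(img, nb)
    if (dim(img)[3] != nb)
      stop(sprintf("stage calibrate: image at %s m has %d bands, camera has %d",
                   alt_name, dim(img)[3], nb))
    pipe_log(config$verbose, "[%s m] calibrating (%s)", alt_name,
             config$method)
    pdn <- t(vapply(config$panels, function(p)
      vapply(seq_len(nb), function(j) extract_panel_dn(img[, , j], p),
             numeric(1)), numeric(nb)))
    prefl <- t(vapply(config$panels, function(p) {
      r <- p$reflectance
      if (length(r) == 1L) rep(r, nb) else r
    }, numeric(nb)))
    fit <- fit_calibration(pdn, prefl, config$method, tau = config$tau,
                           low_panel_max = config$low_panel_max)
    fits[[alt_name]] <- fit
    refl <- apply_calibration(img, fit, clamp = config$clamp)
    dg <- attr(refl, "diagnostics")
    dg$altitude <- H
    diag_rows[[alt_name]] <- dg

    for (pn in names(config$plots)) {
      roi <- scale_roi(config$plots[[pn]], config$reference_altitude, H)
      roi[3] <- min(roi[3], dim(img)[1]); roi[4] <- min(roi[4], dim(img)[2])
      if (roi[3] <= roi[1] || roi[4] <= roi[2])
        stop("stage plots: ROI for ", pn, " collapsed at ", alt_name, " m")
      mu <- vapply(seq_len(nb), function(j)
        mean(refl[(roi[1] + 1L):roi[3], (roi[2] + 1L):roi[4], j]),
        numeric(1))
      refl_rows[[paste(alt_name, pn)]] <- data.frame(
        altitude = H, plot = pn, band = centers, reflectance = mu)
      vi <- compute_all_indices(mu, config$assignment)
      vi_rows[[paste(alt_name, pn)]] <- cbind(
        data.frame(altitude = H, plot = pn), vi)
      if (!is.null(config$endmembers)) {
        ab <- fcls_unmix(mu, config$endmembers)
        bf <- tryCatch(background_factors(ab),
                       error = function(e) list(attenuation_nir = NA_real_,
                                                enhancement_vis = NA_real_))
        ab_rows[[paste(alt_name, pn)]] <- cbind(
          data.frame(altitude = H, plot = pn,
                     residual = ab$residual_norm,
                     attenuation_nir = bf$attenuation_nir,
                     enhancement_vis = bf$enhancement_vis),
          as.data.frame(as.list(ab$values)))
      }
    }
  }

  reflectance <- do.call(rbind, unname(refl_rows))
  indices <- do.call(rbind, unname(vi_rows))
  diagnostics <- do.call(rbind, unname(diag_rows))
  abundance <- if (length(ab_rows)) do.call(rbind, unname(ab_rows)) else NULL

  utils::write.csv(reflectance, file.path(config$out_dir, "plot_reflectance.csv"),
                   row.names = FALSE)
  utils::write.csv(indices, file.path(config$out_dir, "vegetation_indices.csv"),
                   row.names = FALSE)
  utils::write.csv(diagnostics,
                   file.path(config$out_dir, "calibration_diagnostics.csv"),
                   row.names = FALSE)
  if (!is.null(abundance))
    utils::write.csv(abundance, file.path(config$out_dir, "abundance.csv"),
                     row.names = FALSE)
  coef_json <- lapply(fits, function(f)
    list(method = f$method, bands = f$bands,
         panel_rmse = f$diagnostics$rmse))
  jsonlite::write_json(coef_json,
                       file.path(config$out_dir, "calibration_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = "uavcal",
         version = as.character(utils::packageVersion("uavcal")),
         config_hash = config_hash(config),
         method = config$method, seed = config$seed,
         altitudes = as.numeric(names(config$images))),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA)
  pipe_log(config$verbose, "pipeline done in %.1f s",
           proc.time()["elapsed"] - t0)
  invisible(list(reflectance = reflectance, indices = indices,
                 abundance = abundance, calibration = fits,
                 diagnostics = diagnostics, out_dir = config$out_dir))
}
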