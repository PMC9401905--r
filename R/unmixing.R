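# Fully constrained least-squares linear spectral mixture analysis.
#
# A mixed pixel is modeled as R = sum_i A_i R_i + e with abundances
# constrained to the simplex: 0 <= A_i <= 1 and sum A_i = 1. The solver
# augments the endmember matrix with a sum-to-one row scaled by a large
# weight and solves the resulting non-negative least-squares problem with
# a Lawson-Hanson active-set iteration, then renormalizes the solution
# onto the simplex; the renormalization shift is bounded by the penalty
# weight and is far below the stated 1e-8 constraint tolerance.

# Lawson-Hanson non-negative least squares: minimize ||A x - b|| s.t.
# x >= 0. Deterministic; the active set changes by one variable per outer
# step so termination is finite.
nnls_solve <- function(A, b) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  tol <- 10 * .Machine$double.eps * max(abs(A)) * max(dim(A))
  w <- crossprod(A, b)
  maxit <- 30L * n
  for (it in seq_len(maxit)) {
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (min(s[passive]) > tol) { x <- s; break }
      drop_set <- passive & s <= tol
      alpha <- min(x[drop_set] / (x[drop_set] - s[drop_set]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Canonical endmember labels for a paddy-rice scene
#'
#' Six endmembers: sunlit and shaded rice leaves plus four background
#' components (sunlit/shaded water, sunlit/shaded soil).
#' @export
canonical_endmember_labels <- c("light_leaf", "shaded_leaf",
                                "light_water", "shaded_water",
                                "light_soil", "shaded_soil")

background_labels <- c("light_water", "shaded_water",
                       "light_soil", "shaded_soil")

#' Construct an endmember set
#'
#' @param spectra Numeric matrix, endmembers x bands, reflectance
#'   fractions (finite, non-negative).
#' @param labels Unique endmember labels (rownames of `spectra` by
#'   default).
#' @param background Subset of `labels` regarded as background; defaults
#'   to the water/soil labels present.
#' @return An object of class `endmember_set`.
#' @export
endmember_set <- function(spectra, labels = rownames(spectra),
                          background = NULL) {
  spectra <- as.matrix(spectra)
  if (is.null(labels)) labels <- paste0("em", seq_len(nrow(spectra)))
  if (nrow(spectra) < 2L) stop("need at least 2 endmembers")
  if (anyDuplicated(labels)) stop("endmember labels must be unique")
  if (length(labels) != nrow(spectra))
    stop("one label per endmember row required")
  if (!all(is.finite(spectra)) || any(spectra < 0))
    stop("endmember spectra must be finite and non-negative")
  if (any(rowSums(spectra) == 0)) stop("all-zero endmember spectrum")
  if (is.null(background)) background <- intersect(background_labels, labels)
  if (!all(background %in% labels))
    stop("background labels must be a subset of the endmember labels")
  rownames(spectra) <- labels
  structure(list(labels = as.character(labels), spectra = spectra,
                 background = as.character(background)),
            class = "endmember_set")
}

#' @export
print.endmember_set <- function(x, ...) {
  cat(sprintf("<endmember_set> %d endmembers x %d bands (%d background)\n",
              nrow(x$spectra), ncol(x$spectra), length(x$background)))
  invisible(x)
}

#' Read endmember spectra from CSV
#'
#' Expects a `label` column followed by one reflectance column per band.
#'
#' @param path File path.
#' @return An [endmember_set()].
#' @export
read_endmembers_csv <- function(path) {
  x <- utils::read.csv(path)
  endmember_set(as.matrix(x[, -1, drop = FALSE]), labels = x[[1]])
}

#' @rdname read_endmembers_csv
#' @param em An `endmember_set`.
#' @export
write_endmembers_csv <- function(em, path) {
  stopifnot(inherits(em, "endmember_set"))
  df <- data.frame(label = em$labels, em$spectra, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Solve one pixel given the pre-augmented system; returns abundances.
fcls_solve <- function(E_aug, pixel, delta) {
  a <- nnls_solve(E_aug, c(pixel, delta))
  s <- sum(a)
  if (s <= 0) stop("degenerate unmixing problem: all abundances zero")
  a / s
}

#' Fully constrained least-squares unmixing of one pixel
#'
#' Minimizes the 2-norm of `pixel - t(spectra) %*% A` subject to
#' `A >= 0` and `sum(A) = 1`. Deterministic for fixed input.
#'
#' @param pixel Reflectance vector (one value per band).
#' @param endmembers An [endmember_set()] with matching band count.
#' @return An object of class `abundance`: list with `values` (named
#'   per-endmember fractions on the simplex) and `residual_norm` (RMS of
#'   the reconstruction error over bands).
#' @export
fcls_unmix <- function(pixel, endmembers) {
  stopifnot(inherits(endmembers, "endmember_set"))
  E <- t(endmembers$spectra)                       # bands x endmembers
  if (length(pixel) != nrow(E))
    stop(sprintf("pixel has %d bands but endmembers have %d",
                 length(pixel), nrow(E)))
  check_endmember_matrix(E)
  delta <- 1e3 * max(sqrt(colSums(E^2)))
  E_aug <- rbind(E, delta)
  a <- fcls_solve(E_aug, as.numeric(pixel), delta)
  resid <- as.numeric(pixel) - as.numeric(E %*% a)
  structure(list(values = stats::setNames(a, endmembers$labels),
                 residual_norm = sqrt(mean(resid^2))),
            class = "abundance")
}

check_endmember_matrix <- function(E) {
  if (qr(E)$rank < ncol(E))
    warning("endmember matrix is column-rank deficient; abundances are not unique")
  else if (kappa(E, exact = TRUE) > 1e8)
    warning("endmember matrix is ill-conditioned (condition number > 1e8)")
  invisible(E)
}

#' @export
print.abundance <- function(x, ...) {
  cat("<abundance>", paste(sprintf("%s=%.3f", names(x$values), x$values),
                           collapse = " "),
      sprintf("(residual %.3g)\n", x$residual_norm))
  invisible(x)
}

#' Unmix a whole reflectance image
#'
#' Applies [fcls_unmix()] per pixel. Pixels with identical spectra are
#' solved once and the solution reused, which makes plot-structured
#' scenes fast.
#'
#' @param reflectance 3-D array, rows x cols x bands.
#' @param endmembers An [endmember_set()].
#' @return List with `abundance` (rows x cols x endmembers array, planes
#'   summing to 1 per pixel) and `residual` (rows x cols RMS residual).
#' @export
unmix_image <- function(reflectance, endmembers) {
  stopifnot(is.array(reflectance), length(dim(reflectance)) == 3L,
            inherits(endmembers, "endmember_set"))
  d <- dim(reflectance)
  E <- t(endmembers$spectra)
  if (d[3] != nrow(E))
    stop(sprintf("image has %d bands but endmembers have %d", d[3], nrow(E)))
  check_endmember_matrix(E)
  delta <- 1e3 * max(sqrt(colSums(E^2)))
  E_aug <- rbind(E, delta)

  px <- matrix(reflectance, nrow = d[1] * d[2], ncol = d[3])
  key <- apply(px, 1L, paste, collapse = "\r")
  idx <- match(key, key)                 # first occurrence of each spectrum
  uniq <- which(idx == seq_along(idx))
  sols <- matrix(NA_real_, length(key), ncol(E))
  for (u in uniq) sols[u, ] <- fcls_solve(E_aug, px[u, ], delta)
  sols <- sols[idx, , drop = FALSE]
  recon <- sols %*% t(E)
  rms <- sqrt(rowMeans((px - recon)^2))
  ab <- array(sols, dim = c(d[1], d[2], ncol(E)),
              dimnames = list(NULL, NULL, endmembers$labels))
  list(abundance = ab, residual = matrix(rms, d[1], d[2]))
}

#' Background enhancement and attenuation factors
#'
#' Summaries of the background abundances that drive the altitude
#' response of plot reflectance: the NIR attenuation factor is the total
#' background abundance (light water + shaded water + light soil +
#' shaded soil); the visible-band enhancement factor combines them with
#' shaded water subtracted (light water + light soil + shaded soil -
#' shaded water).
#'
#' @param abundance An [fcls_unmix()] result (or a named numeric vector)
#'   carrying the six canonical labels.
#' @return Named list: `attenuation_nir` in \[0, 1\] and
#'   `enhancement_vis` in \[-1, 1\].
#' @export
background_factors <- function(abundance) {
  v <- if (inherits(abundance, "abundance")) abundance$values else abundance
  missing <- setdiff(canonical_endmember_labels, names(v))
  if (length(missing))
    stop("abundance vector lacks canonical labels: ",
         paste(missing, collapse = ", "))
  list(
    attenuation_nir = unname(v["light_water"] + v["shaded_water"] +
                             v["light_soil"] + v["shaded_soil"]),
    enhancement_vis = unname(v["light_water"] + v["light_soil"] +
                             v["shaded_soil"] - v["shaded_water"]))
}
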