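# Vegetation-index to trait regression and error metrics.
#
# Traits: LAI (leaf area index, unitless), AGB (above-ground biomass,
# g/m2), CCC (canopy chlorophyll content, LAI_green x SPAD_upper), and
# grain yield (g/m2). Metrics: MRPE (mean relative percent error), RMSE,
# and RRMSE (RMSE over the observed mean, percent).

#' Canopy chlorophyll content
#'
#' CCC is the product of green leaf area index and the upper-leaf SPAD
#' reading used as a chlorophyll proxy.
#'
#' @param lai_green Green LAI, >= 0.
#' @param spad_upper Upper-leaf SPAD, >= 0.
#' @return CCC (elementwise product).
#' @export
ccc <- function(lai_green, spad_upper) {
  if (any(lai_green < 0) || any(spad_upper < 0))
    stop("LAI and SPAD must be non-negative")
  lai_green * spad_upper
}

#' Mean relative percent error
#'
#' `MRPE = mean(|(estimated - observed) / observed|) * 100`.
#'
#' @param observed Observed values, non-zero elementwise.
#' @param estimated Estimated values, same length.
#' @return MRPE in percent.
#' @export
mrpe <- function(observed, estimated) {
  if (length(observed) != length(estimated)) stop("length mismatch")
  bad <- which(observed == 0)
  if (length(bad))
    stop("observed value is zero at position(s): ",
         paste(bad, collapse = ", "))
  mean(abs((estimated - observed) / observed)) * 100
}

#' Root-mean-square error and its relative form
#'
#' `RMSE = sqrt(mean((estimated - observed)^2))`;
#' `RRMSE = RMSE / mean(observed) * 100` (percent of the observed mean).
#'
#' @param observed,estimated Equal-length numeric vectors.
#' @return RMSE in the units of `observed`; RRMSE in percent.
#' @export
rmse <- function(observed, estimated) {
  if (length(observed) != length(estimated)) stop("length mismatch")
  sqrt(mean((estimated - observed)^2))
}

#' @rdname rmse
#' @export
rrmse <- function(observed, estimated) {
  m <- mean(observed)
  if (m == 0) stop("mean of observed values is zero")
  rmse(observed, estimated) / m * 100
}

#' Fit a linear VI-trait model
#'
#' Ordinary least squares `trait = slope * vi + intercept`, with
#' in-sample R-squared, RMSE and RRMSE.
#'
#' @param vi Vegetation-index values (n >= 3, not constant).
#' @param trait Trait values, same length.
#' @param trait_name,vi_name Labels stored in the model.
#' @return An object of class `trait_model`.
#' @export
fit_trait_model <- function(vi, trait, trait_name = "trait", vi_name = "vi") {
  if (length(vi) != length(trait)) stop("length mismatch")
  if (length(vi) < 3L) stop("need at least 3 observations")
  if (stats::sd(vi) == 0) stop("vi is constant; slope is undefined")
  fit <- stats::lm.fit(cbind(1, vi), trait)
  b <- unname(fit$coefficients)
  pred <- b[1] + b[2] * vi
  sst <- sum((trait - mean(trait))^2)
  r2 <- if (sst == 0) 1 else 1 - sum((trait - pred)^2) / sst
  trait_model(trait_name, vi_name, slope = b[2], intercept = b[1],
              r2 = r2, rmse = rmse(trait, pred), rrmse = rrmse(trait, pred),
              provenance = "fitted", n = length(vi))
}

#' Construct a trait model
#'
#' @param trait,vi Names of the trait and index.
#' @param slope,intercept Linear coefficients.
#' @param r2 Coefficient of determination in \[0, 1\] (NA allowed).
#' @param rmse,rrmse Error metrics, >= 0 (NA allowed).
#' @param provenance `"fitted"` or `"reference_table"`.
#' @param n Number of observations (NA for reference models).
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(trait, vi, slope, intercept, r2 = NA_real_,
                        rmse = NA_real_, rrmse = NA_real_,
                        provenance = c("fitted", "reference_table"),
                        n = NA_integer_) {
  provenance <- match.arg(provenance)
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop("R2 must lie in [0, 1]")
  if (!is.na(rmse) && rmse < 0) stop("RMSE must be >= 0")
  if (!is.na(rrmse) && rrmse < 0) stop("RRMSE must be >= 0")
  structure(list(trait = trait, vi = vi, slope = slope,
                 intercept = intercept, r2 = r2, rmse = rmse,
                 rrmse = rrmse, provenance = provenance, n = n),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model> %s = %.4f x %s + %.4f  (R2 %.3f, RMSE %.4g, RRMSE %.2f%%, %s)\n",
              x$trait, x$slope, x$vi, x$intercept, x$r2, x$rmse, x$rrmse,
              x$provenance))
  invisible(x)
}

#' Predict a trait from a VI value
#'
#' @param model A [trait_model()].
#' @param vi VI value(s).
#' @return `slope * vi + intercept`.
#' @export
predict_trait <- function(model, vi) {
  stopifnot(inherits(model, "trait_model"))
  model$slope * vi + model$intercept
}

#' Reference catalog of published VI-trait models
#'
#' A read-only catalog of linear VI-trait models shipped with the
#' package: CIgreen-based LAI/AGB/CCC models per calibration method and
#' per flight altitude for two rice campaigns, and stage-specific yield
#' models (EVI2 at booting, WDRVI at heading). Keyed by
#' (`experiment`, `selector`, `trait`), where `selector` is a
#' calibration method (EL/SEL/PEL) or a flight altitude in meters, and
#' for yield models carries the growth stage.
#'
#' @return Data frame with columns `set`, `experiment`, `selector`,
#'   `stage`, `trait`, `vi`, `slope`, `intercept`, `r2`, `rmse`,
#'   `rrmse_pct`.
#' @export
trait_model_catalog <- function() {
  path <- system.file("extdata", "trait_model_catalog.csv",
                      package = "uavcal", mustWork = TRUE)
  utils::read.csv(path, colClasses = c(selector = "character"))
}

#' Look up one catalog model
#'
#' @param experiment Campaign name, e.g. `"Test1"`.
#' @param selector Calibration method (`"EL"`, `"SEL"`, `"PEL"`) or
#'   altitude in meters as a string (e.g. `"100"`).
#' @param trait Trait name (`"LAI"`, `"AGB"`, `"CCC"`, `"Yield"`).
#' @param stage Growth stage, required only for yield models.
#' @return A [trait_model()] with provenance `"reference_table"`.
#' @export
catalog_model <- function(experiment, selector, trait, stage = NA) {
  cat_df <- trait_model_catalog()
  hit <- cat_df$experiment == experiment &
    cat_df$selector == as.character(selector) & cat_df$trait == trait
  if (!is.na(stage)) hit <- hit & cat_df$stage == stage
  row <- cat_df[hit, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("catalog lookup (%s, %s, %s%s) matched %d models",
                 experiment, selector, trait,
                 if (is.na(stage)) "" else paste0(", ", stage), nrow(row)))
  trait_model(row$trait, row$vi, slope = row$slope,
              intercept = row$intercept, r2 = row$r2, rmse = row$rmse,
              rrmse = row$rrmse_pct, provenance = "reference_table")
}
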