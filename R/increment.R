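#' Fit the hemolysis-driven NSE increment model
#'
#' Fits the straight line relating the NSE concentration increment caused by
#' red-blood-cell lysis (y, in ug/L) to the measured hemolysis index of the
#' spiked specimen (x): `increment = slope * HI + intercept`. Data pairs come
#' from a spike-recovery experiment in which serial lysate dilutions are added
#' to serum pools and the increment is the spiked measurement minus the
#' pool's saline baseline. Only hemolyzed points (HI above `hi_filter`)
#' contribute, since the correction is only ever applied to hemolyzed
#' specimens.
#'
#' The published model class is linear, so the fit is ordinary least squares;
#' no robust or weighted variants are provided.
#'
#' @param hi measured HI of the spiked aliquots (or a data frame with columns
#'   `hi` and `increment`, e.g. from [spiking_increments()]).
#' @param increment NSE increment over the pool baseline (ug/L); omit when
#'   `hi` is a data frame.
#' @param hi_filter points with `hi <= hi_filter` are dropped before fitting
#'   (default 5, the hemolysis cutoff). Use `-Inf` to keep everything.
#' @return An object of class `"increment_fit"` with components
#'   `coefficients` (named `intercept`, `slope`), `n_points`, `r_squared`,
#'   `fitted`, `residuals`, `data`, and the underlying `lm` fit.
#' @examples
#' fit <- fit_increment_model(c(10, 20, 40, 80), c(4, 7, 13, 25))
#' coef(fit)
#' predict(fit, hi = 11)
#' @seealso [personalize()], [increment_model()] for a model from known
#'   coefficients.
#' @export
fit_increment_model <- function(hi, increment, hi_filter = 5) {
  if (is.data.frame(hi)) {
    stopifnot(all(c("hi", "increment") %in% names(hi)))
    increment <- hi$increment
    hi <- hi$hi
  }
  stopifnot(length(hi) == length(increment))
  if (!all(is.finite(hi)) || !all(is.finite(increment)))
    stop("hi and increment must be finite")
  keep <- hi > hi_filter
  x <- hi[keep]
  y <- increment[keep]
  if (length(x) < 2L)
    stop("fewer than 2 points remain after HI filtering")
  if (length(unique(x)) < 2L)
    stop("degenerate design: all HI values identical")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(coefficients = c(intercept = unname(cf[1L]),
                                  slope = unname(cf[2L])),
                 n_points = length(x),
                 r_squared = r2,
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::resid(fit)),
                 data = data.frame(hi = x, increment = y),
                 lm = fit),
            class = "increment_fit")
}

#' Increment model from known coefficients
#'
#' Builds an `increment_fit` object directly from a slope and intercept, for
#' evaluating or personalizing a previously derived equation (for instance
#' one taken from a report) without refitting.
#'
#' @param slope ug/L NSE per HI unit.
#' @param intercept ug/L NSE.
#' @return An `"increment_fit"` object (`n_points` and `r_squared` are `NA`).
#' @examples
#' m <- increment_model(slope = 0.2757, intercept = 0.9793)
#' predict(m, hi = 11)  # ~4.0 ug/L false elevation
#' @export
increment_model <- function(slope, intercept) {
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(coefficients = c(intercept = intercept, slope = slope),
                 n_points = NA_integer_, r_squared = NA_real_,
                 fitted = NULL, residuals = NULL, data = NULL, lm = NULL),
            class = "increment_fit")
}

#' @export
coef.increment_fit <- function(object, ...) object$coefficients

#' @export
residuals.increment_fit <- function(object, ...) object$residuals

#' Predict the NSE increment at given HI values
#'
#' @param object an `"increment_fit"`.
#' @param hi HI values at which to evaluate the line; defaults to the
#'   fitting data.
#' @param ... unused.
#' @return Predicted NSE increments (ug/L).
#' @export
predict.increment_fit <- function(object, hi = NULL, ...) {
  if (is.null(hi)) {
    if (is.null(object$fitted)) stop("no fitting data stored; supply 'hi'")
    return(object$fitted)
  }
  cf <- object$coefficients
  cf[["slope"]] * hi + cf[["intercept"]]
}

#' @export
print.increment_fit <- function(x, digits = 4, ...) {
  cf <- x$coefficients
  cat("Hemolysis NSE-increment model\n")
  cat(sprintf("  increment = %.*g * HI + %.*g   (ug/L)\n",
              digits, cf[["slope"]], digits, cf[["intercept"]]))
  if (!is.na(x$n_points))
    cat(sprintf("  n = %d points, R-squared = %.4f\n", x$n_points, x$r_squared))
  invisible(x)
}

#' @export
summary.increment_fit <- function(object, ...) {
  cat("Hemolysis NSE-increment model (ordinary least squares)\n\n")
  print(object)
  if (!is.null(object$lm)) {
    cat("\nCoefficient table:\n")
    stats::printCoefmat(summary(object$lm)$coefficients)
  }
  invisible(object)
}

#' @export
plot.increment_fit <- function(x, ...) {
  if (is.null(x$data)) stop("no fitting data stored")
  graphics::plot(x$data$hi, x$data$increment,
                 xlab = "Measured HI", ylab = "NSE increment (ug/L)",
                 main = "Hemolysis-driven NSE increment", ...)
  graphics::abline(x$coefficients[["intercept"]], x$coefficients[["slope"]],
                   col = "red3")
  invisible(x)
}

#' NSE/HI ratio of a red-blood-cell lysate
#'
#' The patient-specific ratio R of NSE (ug/L) to HI measured in a diluted RBC
#' lysate. R scales the hemolysis-driven NSE increment per HI unit for that
#' patient. Because both the numerator and the denominator are measured on
#' the same dilution, the dilution factor (typically 1:30 with saline)
#' cancels and R is dilution invariant.
#'
#' @param nse_lysate NSE of the diluted lysate (ug/L); must lie within the
#'   assay measurable range (above it the lysate needs re-dilution).
#' @param hi_lysate HI of the diluted lysate; must be positive.
#' @param nse_max assay ceiling above which re-dilution is required
#'   (default 370 ug/L).
#' @return The dimensionless ratio R.
#' @examples
#' measure_ratio(155, 500)  # 0.31
#' @export
measure_ratio <- function(nse_lysate, hi_lysate, nse_max = 370) {
  hi_lysate <- hi_value(hi_lysate)
  stopifnot(is.finite(nse_lysate), is.finite(hi_lysate))
  if (any(hi_lysate <= 0)) stop("lysate HI must be positive")
  if (any(nse_lysate < 0)) stop("lysate NSE must be non-negative")
  if (any(nse_lysate > nse_max))
    stop("lysate NSE above assay ceiling (", nse_max, " ug/L): re-dilute")
  nse_lysate / hi_lysate
}

#' Personalize an increment model with a donor NSE/HI ratio
#'
#' Re-expresses the generic increment line in terms of the NSE/HI ratio R of
#' the red cells that produced it, so that the model can be applied to any
#' patient by substituting that patient's own R:
#' `increment = (slope/R_donor) * R * HI + (intercept/R_donor) * R`.
#'
#' @param fit an `"increment_fit"` (fitted or built from coefficients).
#' @param donor_r NSE/HI ratio of the lysate used in the spiking experiment;
#'   must be positive.
#' @return An object of class `"nse_correction_model"` with `slope_per_r`,
#'   `intercept_per_r`, `donor_r` and the generic coefficients.
#' @examples
#' m <- personalize(increment_model(0.2757, 0.9793), donor_r = 0.31)
#' m            # slope_per_r ~0.889, intercept_per_r ~3.159
#' predict(m, hi = 11, r = 0.31)
#' @export
personalize <- function(fit, donor_r) {
  stopifnot(inherits(fit, "increment_fit"),
            length(donor_r) == 1L, is.finite(donor_r))
  if (donor_r <= 0)
    stop("donor NSE/HI ratio must be positive: model not personalizable")
  cf <- fit$coefficients
  structure(list(slope_per_r = cf[["slope"]] / donor_r,
                 intercept_per_r = cf[["intercept"]] / donor_r,
                 donor_r = donor_r,
                 generic = cf),
            class = "nse_correction_model")
}

#' @export
print.nse_correction_model <- function(x, digits = 4, ...) {
  cat("Personalized NSE correction model\n")
  cat(sprintf("  increment = %.*g * R * HI + %.*g * R   (ug/L)\n",
              digits, x$slope_per_r, digits, x$intercept_per_r))
  cat(sprintf("  donor NSE/HI ratio R = %g\n", x$donor_r))
  invisible(x)
}

#' Predicted increment for a patient
#'
#' @param object an `"nse_correction_model"`.
#' @param hi measured HI of the specimen.
#' @param r the patient's NSE/HI ratio.
#' @param ... unused.
#' @return Predicted hemolysis-driven NSE increment (ug/L).
#' @export
predict.nse_correction_model <- function(object, hi, r, ...) {
  stopifnot(all(r >= 0))
  object$slope_per_r * r * hi_value(hi) + object$intercept_per_r * r
}

#' Correct a measured NSE for hemolysis interference
#'
#' Subtracts the patient-specific hemolysis-driven increment from the
#' measured NSE: `NSE_corr = NSE_meas - slope_per_r*R*HI - intercept_per_r*R`.
#' Corrections that would push the result below the assay's lower measurable
#' limit are clamped there and flagged. Correction is clinically meaningful
#' only for hemolyzed specimens (HI above the cutoff); the decision cascade
#' in [decide()] applies that gate.
#'
#' @param nse_meas measured NSE (ug/L).
#' @param hi_meas measured HI of the same specimen.
#' @param r the patient's NSE/HI ratio (from [measure_ratio()]); `r = 0`
#'   means the red cells contribute no NSE and the result is returned
#'   unchanged.
#' @param model an `"nse_correction_model"` from [personalize()].
#' @param floor assay lower measurable limit (default 0.05 ug/L).
#' @return data.frame with `nse_meas`, `hi_meas`, `r`, `increment`,
#'   `nse_corr` and `clamped`.
#' @examples
#' m <- personalize(increment_model(0.2757, 0.9793), donor_r = 0.31)
#' correct_nse(20, 11, r = 0.31, model = m)
#' @export
correct_nse <- function(nse_meas, hi_meas, r, model, floor = 0.05) {
  stopifnot(inherits(model, "nse_correction_model"))
  hi_meas <- hi_value(hi_meas)
  if (any(!is.finite(nse_meas)) || any(!is.finite(hi_meas)))
    stop("nse_meas and hi_meas must be finite")
  if (any(nse_meas < 0) || any(hi_meas < 0))
    stop("negative measurements are invalid")
  if (any(is.na(r)))
    stop("patient NSE/HI ratio is required for correction")
  if (any(r < 0)) stop("NSE/HI ratio must be non-negative")
  inc <- predict(model, hi = hi_meas, r = r)
  corr <- nse_meas - inc
  clamped <- corr < floor
  corr[clamped] <- floor
  data.frame(nse_meas = nse_meas, hi_meas = hi_meas, r = r,
             increment = inc, nse_corr = corr, clamped = clamped)
}

#' Write / read a correction model as JSON
#'
#' Serializes the generic and personalized coefficients
#' (`slope, intercept, donor_r, slope_per_r, intercept_per_r, n_points,
#' r_squared`) so a derived model can be stored alongside laboratory
#' configuration.
#'
#' @param model an `"nse_correction_model"`.
#' @param path output JSON path.
#' @param fit optional originating `"increment_fit"` supplying `n_points`
#'   and `r_squared`.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, fit = NULL) {
  stopifnot(inherits(model, "nse_correction_model"))
  obj <- list(slope = model$generic[["slope"]],
              intercept = model$generic[["intercept"]],
              donor_r = model$donor_r,
              slope_per_r = model$slope_per_r,
              intercept_per_r = model$intercept_per_r,
              n_points = if (!is.null(fit)) fit$n_points else NA,
              r_squared = if (!is.null(fit)) fit$r_squared else NA)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  personalize(increment_model(slope = obj$slope, intercept = obj$intercept),
              donor_r = obj$donor_r)
}

#' Read a spiking-experiment table
#'
#' Reads a CSV of spike-recovery measurements with the exact header
#' `pool_id, aliquot, hi_meas, nse_meas, baseline_hi, baseline_nse` and
#' returns per-aliquot increments ready for [fit_increment_model()].
#'
#' @param path CSV file path.
#' @param x which HI to use as the model's x-variable: the measured HI of
#'   the spiked sample (`"hi_meas"`, the default, the variable the published
#'   coefficients are defined against) or the baseline-subtracted
#'   `"delta_hi"`.
#' @return data.frame with columns `pool_id`, `hi`, `increment`.
#' @export
read_spiking_csv <- function(path, x = c("hi_meas", "delta_hi")) {
  x <- match.arg(x)
  want <- c("pool_id", "aliquot", "hi_meas", "nse_meas",
            "baseline_hi", "baseline_nse")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!identical(names(tab), want))
    stop("expected header '", paste(want, collapse = ","), "'")
  num <- c("hi_meas", "nse_meas", "baseline_hi", "baseline_nse")
  tab[num] <- lapply(tab[num], as.numeric)
  if (anyNA(tab[num])) stop("unparseable numeric fields in spiking table")
  data.frame(pool_id = tab$pool_id,
             hi = if (x == "hi_meas") tab$hi_meas else
               tab$hi_meas - tab$baseline_hi,
             increment = tab$nse_meas - tab$baseline_nse)
}
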