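# Size-exclusion chromatography: log-linear molecular-weight calibration
# and oligomeric-state calling.

#' Bio-Rad gel-filtration standard masses (kDa)
#'
#' Thyroglobulin, gamma-globulin, ovalbumin, myoglobin, vitamin B12.
#' @export
biorad_standard_masses <- c(
  thyroglobulin = 670, gamma_globulin = 158, ovalbumin = 44,
  myoglobin = 17, vitamin_B12 = 1.35
)

#' Fit a size-exclusion calibration line
#'
#' Ordinary least squares of log10(mass in kDa) on elution volume (ml),
#' the standard column-calibration model: a physical column has a negative
#' slope, and the fitted line converts elution volume to apparent mass.
#'
#' @param standards Data frame (or list/matrix coercible to one) with
#'   columns `mass_kda` and `elution_ml`, or two numeric vectors via
#'   `mass_kda` and `elution_ml` arguments.
#' @param mass_kda,elution_ml Alternative vector interface.
#' @return Object of class `sec_calibration`: `slope` (per ml),
#'   `intercept` (log10 kDa), `r_squared`, `standards`, and the underlying
#'   `lm` fit.
#' @seealso [predict.sec_calibration], [estimate_mass], [call_oligomer]
#' @export
#' @examples
#' cal <- sec_calibration(data.frame(
#'   mass_kda = c(670, 158, 44, 17, 1.35),
#'   elution_ml = c(45, 60, 73, 83, 110)))
#' coef(cal)
sec_calibration <- function(standards = NULL, mass_kda = NULL,
                            elution_ml = NULL) {
  if (is.null(standards)) {
    standards <- data.frame(mass_kda = mass_kda, elution_ml = elution_ml)
  }
  standards <- as.data.frame(standards)
  if (!all(c("mass_kda", "elution_ml") %in% names(standards))) {
    names(standards)[1:2] <- c("mass_kda", "elution_ml")
  }
  if (nrow(standards) < 2) stop("need at least 2 standards")
  if (length(unique(standards$elution_ml)) < 2) {
    stop("need at least 2 distinct elution volumes")
  }
  if (any(standards$mass_kda <= 0)) stop("masses must be positive")
  fit <- stats::lm(log10(mass_kda) ~ elution_ml, data = standards)
  cf <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  structure(list(slope = unname(cf[["elution_ml"]]),
                 intercept = unname(cf[["(Intercept)"]]),
                 r_squared = r2, standards = standards, lm = fit),
            class = "sec_calibration")
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf("SEC calibration: log10(kDa) = %.4f * ml + %.4f  (R^2 = %.4f, %d standards)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$standards)))
  if (x$slope >= 0) cat("  warning: non-negative slope, unphysical column\n")
  invisible(x)
}

#' @export
coef.sec_calibration <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
residuals.sec_calibration <- function(object, ...) {
  stats::residuals(object$lm)
}

#' Apparent mass at an elution volume
#'
#' Evaluates the calibration line: mass = 10^(intercept + slope * ml).
#' A warning is issued when the elution volume lies outside the calibrated
#' range extended by 20% of its width.
#'
#' @param cal A [sec_calibration], or a numeric slope (with `intercept`).
#' @param elution Elution volume(s), ml.
#' @param intercept Intercept when `cal` is given as a numeric slope.
#' @return Apparent mass in kDa.
#' @export
#' @examples
#' estimate_mass(-0.0423, 89.6, intercept = 5.1333)  # 22.0 kDa
estimate_mass <- function(cal, elution, intercept = NULL) {
  if (is.numeric(cal)) {
    slope <- cal
    if (is.null(intercept)) stop("intercept required with a numeric slope")
  } else {
    stopifnot(inherits(cal, "sec_calibration"))
    slope <- cal$slope
    intercept <- cal$intercept
    rng <- range(cal$standards$elution_ml)
    pad <- 0.2 * diff(rng)
    if (any(elution < rng[1] - pad | elution > rng[2] + pad)) {
      warning("elution volume outside calibrated range (+/- 20%)")
    }
  }
  10^(intercept + slope * elution)
}

#' @export
predict.sec_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(estimate_mass(object, object$standards$elution_ml))
  }
  el <- if (is.data.frame(newdata)) newdata$elution_ml else newdata
  estimate_mass(object, el)
}

#' Plot a SEC calibration
#'
#' Standards on a log10 mass scale with the fitted line.
#' @param x A [sec_calibration].
#' @param ... Passed to [graphics::plot].
#' @export
plot.sec_calibration <- function(x, ...) {
  graphics::plot(x$standards$elution_ml, log10(x$standards$mass_kda),
                 xlab = "elution volume (ml)", ylab = "log10 mass (kDa)",
                 ...)
  graphics::abline(x$intercept, x$slope, col = 2)
  invisible(x)
}

#' Call the oligomeric state from an apparent mass
#'
#' The n-mer is the nearest integer to the mass ratio (ties round up,
#' minimum 1). Apparent masses below half the monomer mass flag a
#' column-matrix interaction (e.g. a lectin binding the dextran matrix
#' elutes far too late and reports a nonsense small mass).
#'
#' @param estimated_mass Apparent mass from SEC, kDa.
#' @param monomer_mass Sequence/monomer mass, kDa.
#' @return List of class `oligomer_call`: `estimated_mass`,
#'   `monomer_mass`, `ratio`, `n_mer`, `matrix_interaction_flag`.
#' @export
#' @examples
#' call_oligomer(63.2, 17.3)  # tetramer
call_oligomer <- function(estimated_mass, monomer_mass) {
  if (estimated_mass <= 0 || monomer_mass <= 0) {
    stop("masses must be positive")
  }
  ratio <- estimated_mass / monomer_mass
  n_mer <- max(1L, as.integer(floor(ratio + 0.5)))  # ties round up
  structure(list(estimated_mass = estimated_mass,
                 monomer_mass = monomer_mass, ratio = ratio,
                 n_mer = n_mer,
                 matrix_interaction_flag = estimated_mass <
                   0.5 * monomer_mass),
            class = "oligomer_call")
}

#' @export
print.oligomer_call <- function(x, ...) {
  cat(sprintf("apparent %.1f kDa / monomer %.1f kDa: ratio %.2f -> %d-mer\n",
              x$estimated_mass, x$monomer_mass, x$ratio, x$n_mer))
  if (x$matrix_interaction_flag) {
    cat("  flag: apparent mass < half the monomer - matrix interaction?\n")
  }
  invisible(x)
}
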