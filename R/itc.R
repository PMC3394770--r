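# Single-site (Wiseman) isothermal titration calorimetry: forward
# simulation and nonlinear least-squares fitting with the full
# thermodynamic decomposition dG = -RT ln K_A, -TdS = dG - dH and the
# c-value diagnostic c = n K_A [M].

#' Gas constant in kcal mol^-1 K^-1
#' @export
R_GAS <- 1.987e-3

#' ITC titration protocol
#'
#' Describes the instrument protocol of a titration experiment.
#'
#' @param cell_volume Cell volume in microlitre (default 280, an iTC200).
#' @param injection_volume Volume per injection, microlitre (default 2).
#' @param n_injections Number of injections (default 18).
#' @param cell_conc Macromolecule concentration in the cell, mM.
#' @param syringe_conc Ligand concentration in the syringe, mM.
#' @param temperature Kelvin (default 298.15, i.e. 25 C).
#' @return A list of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_volume = 280, injection_volume = 2,
                         n_injections = 18, cell_conc = 1,
                         syringe_conc = 25, temperature = 298.15) {
  p <- list(cell_volume = cell_volume, injection_volume = injection_volume,
            n_injections = n_injections, cell_conc = cell_conc,
            syringe_conc = syringe_conc, temperature = temperature)
  if (any(unlist(p) <= 0)) stop("all protocol values must be positive")
  if (n_injections %% 1 != 0) stop("n_injections must be an integer")
  if (n_injections * injection_volume > 0.5 * cell_volume) {
    stop("total injected volume must be well below the cell volume")
  }
  class(p) <- "itc_protocol"
  p
}

# Running cell concentrations after i injections, Origin's symmetric
# displacement convention: the fraction x = i dV / V0 of cell content is
# displaced, splitting the correction evenly, M_t = M0 (1-x/2)/(1+x/2).
.itc_concentrations <- function(protocol, i) {
  x <- i * protocol$injection_volume / protocol$cell_volume
  M0 <- protocol$cell_conc * 1e-3     # M
  X0 <- protocol$syringe_conc * 1e-3  # M
  list(Mt = M0 * (1 - x / 2) / (1 + x / 2),
       Xt = X0 * x / (1 + x / 2))
}

# cumulative heat content (cal) of the cell after i injections
.itc_Q <- function(K_A, n, dH, protocol, i) {
  if (K_A <= 0) return(rep(0, length(i)))
  cc <- .itc_concentrations(protocol, i)
  V0 <- protocol$cell_volume * 1e-6   # litre
  Mt <- cc$Mt
  Xt <- cc$Xt
  r <- 1 + Xt / (n * Mt) + 1 / (n * K_A * Mt)
  theta <- (r - sqrt(pmax(0, r^2 - 4 * Xt / (n * Mt)))) / 2
  n * theta * Mt * dH * 1e3 * V0  # dH kcal/mol -> cal/mol
}

# per-injection heats (ucal) with the displaced-volume correction
.itc_heats <- function(K_A, n, dH, protocol, offset_ucal = 0) {
  i <- seq_len(protocol$n_injections)
  Q <- .itc_Q(K_A, n, dH, protocol, i)
  Qprev <- c(0, Q[-length(Q)])
  dvf <- protocol$injection_volume / protocol$cell_volume
  dq <- Q - Qprev + dvf * (Q + Qprev) / 2
  dq * 1e6 + offset_ucal
}

#' Simulate a single-site ITC titration
#'
#' Forward-simulates per-injection heats under the Wiseman single-site
#' model with the standard cell-displacement correction, plus optional
#' i.i.d. Gaussian noise. Deterministic for a fixed seed.
#'
#' @param K_A Association constant, M^-1 (0 allowed: no binding).
#' @param n Stoichiometry (sites per macromolecule).
#' @param dH Binding enthalpy, kcal/mol.
#' @param protocol An [itc_protocol].
#' @param noise_sd Gaussian noise standard deviation in microcalories
#'   (default 0).
#' @param seed Optional integer seed for the noise.
#' @return An `itc_data` object: list with `heats` (ucal per injection),
#'   `molar_ratio` (ligand/macromolecule after each injection),
#'   `protocol`, `truth` (the simulation parameters).
#' @export
#' @examples
#' d <- simulate_titration(7040, 1, -5.56, itc_protocol(cell_conc = 1))
#' round(d$heats[1:3], 1)
simulate_titration <- function(K_A, n = 1, dH = -5, protocol = itc_protocol(),
                               noise_sd = 0, seed = NULL) {
  stopifnot(inherits(protocol, "itc_protocol"))
  if (K_A < 0) stop("K_A must be non-negative")
  heats <- .itc_heats(K_A, n, dH, protocol)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    heats <- heats + stats::rnorm(length(heats), 0, noise_sd)
  }
  cc <- .itc_concentrations(protocol, seq_len(protocol$n_injections))
  structure(list(heats = heats, molar_ratio = cc$Xt / cc$Mt,
                 protocol = protocol,
                 truth = list(K_A = K_A, n = n, dH = dH,
                              noise_sd = noise_sd)),
            class = "itc_data")
}

#' @export
print.itc_data <- function(x, ...) {
  cat(sprintf("ITC titration: %d injections of %g ul into %g ul cell\n",
              x$protocol$n_injections, x$protocol$injection_volume,
              x$protocol$cell_volume))
  cat(sprintf("  [cell] %g mM, [syringe] %g mM, T %.2f K\n",
              x$protocol$cell_conc, x$protocol$syringe_conc,
              x$protocol$temperature))
  cat("  heats (ucal):", paste(sprintf("%.2f", x$heats), collapse = " "),
      "\n")
  invisible(x)
}

#' Read a two-column ITC heat table
#'
#' Plain-text input: injection index and heat in microcalories, whitespace
#' or tab separated, `#` comments allowed.
#'
#' @param path File path.
#' @param protocol An [itc_protocol] describing the experiment.
#' @return An `itc_data` object.
#' @export
read_itc <- function(path, protocol) {
  tb <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tb) < 2) stop("expected two columns: injection index, heat (ucal)")
  heats <- tb[[2]][order(tb[[1]])]
  if (length(heats) != protocol$n_injections) {
    stop("heat count does not match protocol n_injections")
  }
  cc <- .itc_concentrations(protocol, seq_len(protocol$n_injections))
  structure(list(heats = heats, molar_ratio = cc$Xt / cc$Mt,
                 protocol = protocol, truth = NULL),
            class = "itc_data")
}

#' Thermodynamic decomposition of a binding constant
#'
#' \eqn{\Delta G = -RT\ln K_A} and \eqn{-T\Delta S = \Delta G - \Delta H},
#' with R = 1.987e-3 kcal/mol/K.
#'
#' @param K_A Association constant, M^-1 (> 0).
#' @param dH Binding enthalpy, kcal/mol.
#' @param temperature Kelvin (default 298.15).
#' @return Named list `dG`, `minus_TdS` (kcal/mol).
#' @export
#' @examples
#' thermodynamics(7040, -5.56)
thermodynamics <- function(K_A, dH, temperature = 298.15) {
  if (K_A <= 0) stop("K_A must be positive")
  dG <- -R_GAS * temperature * log(K_A)
  list(dG = dG, minus_TdS = dG - dH)
}

#' Protein concentration by the Beer-Lambert law
#'
#' \eqn{C = A / (\epsilon b)}.
#'
#' @param A280 Absorbance at 280 nm.
#' @param epsilon Molar extinction coefficient, M^-1 cm^-1 (the lectin's
#'   sequence-predicted value is 22920).
#' @param path Path length in cm (default 1).
#' @return Concentration in molar.
#' @export
beer_lambert_conc <- function(A280, epsilon = 22920, path = 1) {
  if (epsilon <= 0 || path <= 0) stop("epsilon and path must be positive")
  if (A280 < 0) stop("absorbance must be non-negative")
  A280 / (epsilon * path)
}

#' Fit the single-site Wiseman model to an ITC titration
#'
#' Nonlinear least squares (Levenberg-Marquardt) of per-injection heats
#' against the single-site isotherm. K_A is fitted on a log10 scale (which
#' bars negative trial values); stoichiometry n is fixed at 1 by default,
#' mirroring common practice for low-c titrations; a baseline offset
#' absorbing unsubtracted dilution heat is included by default.
#'
#' @param data An `itc_data` object (see [simulate_titration], [read_itc]).
#' @param fix_n Fix the stoichiometry at this value (default 1); `NULL`
#'   frees n.
#' @param offset Include a constant per-injection baseline offset
#'   (default `TRUE`).
#' @param control_heats Optional per-injection dilution heats (ucal) to
#'   subtract before fitting.
#' @return An object of class `itc_fit` with components `K_A`, `n`, `dH`
#'   (kcal/mol), `baseline_offset` (kcal/mol of injectant), `dG`,
#'   `minus_TdS`, `c_value`, `std_errors`, `fitted`, `residuals`, `data`,
#'   `temperature`.
#' @seealso [coef.itc_fit], [predict.itc_fit], [simulate.itc_fit],
#'   [plot.itc_fit]
#' @export
#' @examples
#' d <- simulate_titration(7040, 1, -5.56, itc_protocol(cell_conc = 1))
#' fit <- itc_fit(d)
#' coef(fit)
itc_fit <- function(data, fix_n = 1, offset = TRUE, control_heats = NULL) {
  stopifnot(inherits(data, "itc_data"))
  heats <- data$heats
  if (!is.null(control_heats)) {
    if (length(control_heats) != length(heats)) {
      stop("control_heats length mismatch")
    }
    heats <- heats - control_heats
  }
  usable <- sum(is.finite(heats))
  if (usable < 5) stop("need at least 5 usable injections")
  protocol <- data$protocol
  free_n <- is.null(fix_n)

  # initialization: K_A ~ 1/[cell]; dH from the largest-magnitude heat per
  # mole of injectant
  mol_per_inj <- protocol$syringe_conc * 1e-3 *
    protocol$injection_volume * 1e-6
  dH0 <- heats[which.max(abs(heats))] * 1e-9 / mol_per_inj
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -1
  start <- list(logK = log10(1 / (protocol$cell_conc * 1e-3)), dH = dH0)
  if (free_n) start$n <- 1
  if (offset) start$off <- 0

  model <- function(logK, dH, n, off) {
    .itc_heats(10^logK, n, dH, protocol, offset_ucal = off)
  }
  fml <- if (free_n && offset) {
    heats ~ model(logK, dH, n, off)
  } else if (free_n) {
    heats ~ model(logK, dH, n, 0)
  } else if (offset) {
    heats ~ model(logK, dH, fix_n, off)
  } else {
    heats ~ model(logK, dH, fix_n, 0)
  }

  fit <- NULL
  for (kick in c(0, 1, -1, 2)) {
    st <- start
    st$logK <- start$logK + kick
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("one-site fit failed to converge after restarts; ",
         "check heats and protocol (c-value may be far outside 1-1000)")
  }
  cf <- stats::coef(fit)
  se_raw <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e)
                       stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  K_A <- 10^cf[["logK"]]
  dH <- cf[["dH"]]
  n <- if (free_n) cf[["n"]] else fix_n
  off_ucal <- if (offset) cf[["off"]] else 0
  th <- thermodynamics(K_A, dH, protocol$temperature)
  c_value <- n * K_A * protocol$cell_conc * 1e-3
  if (c_value < 1) {
    warning(sprintf("c-value %.2f < 1: low-c titration, fix n for fitting",
                    c_value))
  } else if (c_value > 1000) {
    warning(sprintf("c-value %.0f > 1000: curve too steep to resolve K_A",
                    c_value))
  }
  se <- c(K_A = if (is.na(se_raw[["logK"]])) NA_real_ else
    K_A * log(10) * se_raw[["logK"]],
    dH = se_raw[["dH"]],
    n = if (free_n) se_raw[["n"]] else NA_real_,
    offset = if (offset) se_raw[["off"]] else NA_real_)
  structure(list(
    K_A = K_A, n = n, dH = dH,
    baseline_offset = off_ucal * 1e-9 / mol_per_inj,
    dG = th$dG, minus_TdS = th$minus_TdS, c_value = c_value,
    std_errors = se,
    fitted = stats::fitted(fit), residuals = stats::residuals(fit),
    nls = fit, data = data, temperature = protocol$temperature,
    fixed_n = !free_n, has_offset = offset
  ), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, digits = 4, ...) {
  cat("Single-site ITC fit\n")
  cat(sprintf("  K_A = %s M^-1%s,  n = %.2f%s\n",
              format(signif(x$K_A, digits)),
              if (is.na(x$std_errors[["K_A"]])) "" else
                sprintf(" (+/- %s)", format(signif(x$std_errors[["K_A"]],
                                                   3))),
              x$n, if (x$fixed_n) " [fixed]" else ""))
  cat(sprintf("  dH = %.2f kcal/mol, dG = %.2f, -TdS = %.2f (T = %.2f K)\n",
              x$dH, x$dG, x$minus_TdS, x$temperature))
  cat(sprintf("  c-value = %.2f\n", x$c_value))
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  out <- data.frame(
    parameter = c("K_A (M^-1)", "n", "dH (kcal/mol)", "dG (kcal/mol)",
                  "-TdS (kcal/mol)", "c"),
    value = c(object$K_A, object$n, object$dH, object$dG,
              object$minus_TdS, object$c_value),
    std_error = c(object$std_errors[["K_A"]], object$std_errors[["n"]],
                  object$std_errors[["dH"]], NA, NA, NA)
  )
  class(out) <- c("summary.itc_fit", "data.frame")
  out
}

#' @export
coef.itc_fit <- function(object, ...) {
  c(K_A = object$K_A, n = object$n, dH = object$dH,
    offset = object$baseline_offset)
}

#' Predicted per-injection heats of a fitted ITC model
#' @param object An `itc_fit`.
#' @param ... Unused.
#' @return Numeric vector of heats (microcalories).
#' @export
predict.itc_fit <- function(object, ...) object$fitted

#' @export
residuals.itc_fit <- function(object, ...) object$residuals

#' Simulate new titrations from a fitted ITC model
#'
#' @param object An `itc_fit`.
#' @param nsim Number of simulated datasets.
#' @param seed Optional seed.
#' @param noise_sd Noise sd (ucal); defaults to the residual sd of the fit.
#' @param ... Unused.
#' @return A list of `itc_data` objects.
#' @export
simulate.itc_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = NULL, ...) {
  if (is.null(noise_sd)) noise_sd <- stats::sd(object$residuals)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(k)
    simulate_titration(object$K_A, object$n, object$dH,
                       object$data$protocol, noise_sd = noise_sd))
}

#' Plot an ITC titration and fit
#'
#' Integrated heats per mole of injectant versus molar ratio, with the
#' fitted isotherm overlaid.
#'
#' @param x An `itc_fit`.
#' @param ... Passed to [graphics::plot].
#' @export
plot.itc_fit <- function(x, ...) {
  protocol <- x$data$protocol
  mol <- protocol$syringe_conc * 1e-3 * protocol$injection_volume * 1e-6
  obs <- x$data$heats * 1e-9 / mol
  fitv <- x$fitted * 1e-9 / mol
  graphics::plot(x$data$molar_ratio, obs, xlab = "molar ratio",
                 ylab = "kcal/mol of injectant", ...)
  graphics::lines(x$data$molar_ratio, fitv, col = 2)
  invisible(x)
}
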