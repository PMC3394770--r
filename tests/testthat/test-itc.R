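# single-site ITC: forward model, fitting, thermodynamics

study_protocol <- function(cell_conc = 1, syringe_conc = 25) {
  itc_protocol(cell_volume = 280, injection_volume = 2, n_injections = 18,
               cell_conc = cell_conc, syringe_conc = syringe_conc)
}

test_that("no binding means no heat", {
  d <- simulate_titration(0, 1, -5.56, study_protocol())
  expect_equal(d$heats, rep(0, 18))
})

test_that("infinitely tight binding is stoichiometric then saturates", {
  p <- study_protocol()
  d <- simulate_titration(1e12, 1, -5.56, p)
  mol_inj <- p$syringe_conc * 1e-3 * p$injection_volume * 1e-6
  # first injections: heat = dH x moles injected (to within the small
  # displacement correction)
  expect_equal(d$heats[1] * 1e-9 / mol_inj, -5.56, tolerance = 0.01)
  expect_equal(d$heats[2] * 1e-9 / mol_inj, -5.56, tolerance = 0.01)
  # after the equivalence point (molar ratio 1) the heats vanish
  post <- which(d$molar_ratio > 1.1)
  expect_true(all(abs(d$heats[post]) < 1e-3 * abs(d$heats[1])))
})

test_that("total heat approaches n dH V0 min(M, X/n) as K grows", {
  p <- study_protocol()
  d <- simulate_titration(1e12, 1, -5.56, p)
  V0 <- p$cell_volume * 1e-6
  cc <- ipolectin:::.itc_concentrations(p, p$n_injections)
  bound <- min(cc$Mt, cc$Xt)  # n = 1
  expect_equal(sum(d$heats) * 1e-6, -5.56e3 * V0 * bound, tolerance = 0.02)
})

test_that("the titration sigmoid inflects near molar ratio n", {
  d <- simulate_titration(7.04e3, 1, -5.56, study_protocol())
  # steepest change in per-injection heat near the equivalence point
  i <- which.max(abs(diff(d$heats)))
  expect_gt(d$molar_ratio[i + 1], 0.7)
  expect_lt(d$molar_ratio[i + 1], 1.3)
})

test_that("simulation with a fixed seed is reproducible", {
  d1 <- simulate_titration(7040, 1, -5.56, study_protocol(),
                           noise_sd = 2, seed = 99)
  d2 <- simulate_titration(7040, 1, -5.56, study_protocol(),
                           noise_sd = 2, seed = 99)
  expect_identical(d1$heats, d2$heats)
})

test_that("noise-free fits recover the generating parameters", {
  d <- simulate_titration(7.04e3, 1, -5.56, study_protocol())
  fit <- itc_fit(d)
  expect_equal(fit$K_A, 7.04e3, tolerance = 1e-3)
  expect_equal(fit$dH, -5.56, tolerance = 1e-3)
  expect_equal(fit$c_value, 7.04, tolerance = 1e-3)
})

test_that("c-value equals n K_A [cell] for the reported experiments", {
  fit1 <- itc_fit(simulate_titration(7.04e3, 1, -5.56, study_protocol(1)))
  expect_equal(fit1$c_value, 7.04, tolerance = 1e-2)
  fit2 <- itc_fit(simulate_titration(37.94e3, 1, -13.64,
                                     study_protocol(0.5, 12.5)))
  expect_equal(fit2$c_value, 18.97, tolerance = 1e-2)
})

test_that("thermodynamic identities hold for every fit", {
  for (ka in c(2.01e3, 7.04e3)) {
    fit <- itc_fit(simulate_titration(ka, 1, -4.5, study_protocol()))
    expect_equal(fit$dG, -ipolectin::R_GAS * 298.15 * log(fit$K_A))
    expect_equal(fit$minus_TdS, fit$dG - fit$dH)
    expect_equal(fit$c_value, fit$n * fit$K_A *
                   fit$data$protocol$cell_conc * 1e-3)
  }
})

test_that("thermodynamics() matches hand values", {
  expect_equal(thermodynamics(1, -5)$dG, 0)
  th <- thermodynamics(4.09e3, -5.14)
  expect_equal(th$dG, -1.987e-3 * 298.15 * log(4.09e3))
  expect_equal(th$dG, -4.93, tolerance = 1e-2)
  # printed enthalpy/free-energy pair for the mannoside
  expect_equal(-5.17 - (-5.56), 0.39)
  expect_error(thermodynamics(0, -5), "positive")
})

test_that("Beer-Lambert concentrations divide out correctly", {
  expect_equal(beer_lambert_conc(0, 22920), 0)
  expect_equal(beer_lambert_conc(0.2292, 22920, 1), 10e-6)
  expect_equal(beer_lambert_conc(1.146, 22920, 1), 50e-6)
  expect_error(beer_lambert_conc(1, 0), "positive")
})

test_that("fits are invariant to rescaling heats (with matching dH)", {
  d <- simulate_titration(7.04e3, 1, -5.56, study_protocol())
  d2 <- d
  d2$heats <- d$heats * 2
  f1 <- itc_fit(d)
  f2 <- itc_fit(d2)
  expect_equal(f2$K_A, f1$K_A, tolerance = 1e-6)
  expect_equal(f2$dH, 2 * f1$dH, tolerance = 1e-6)
})

test_that("low-c titrations warn to fix the stoichiometry", {
  d <- simulate_titration(0.11e3, 1, -4.61,
                          study_protocol(3, 75))
  expect_warning(fit <- itc_fit(d), "c-value.*fix n")
  expect_equal(fit$c_value, 0.33, tolerance = 0.02)
})

test_that("control heats are subtracted and short series rejected", {
  d <- simulate_titration(7.04e3, 1, -5.56, study_protocol())
  ctrl <- rep(0.5, 18)
  f <- itc_fit(d, control_heats = ctrl)
  d0 <- d
  d0$heats <- d$heats - ctrl
  f0 <- itc_fit(d0)
  expect_equal(f$K_A, f0$K_A)
  expect_error(itc_fit(d, control_heats = 1:3), "mismatch")
  short <- d
  short$heats[5:18] <- NA
  expect_error(itc_fit(short), "at least 5")
})

test_that("fit methods expose coefficients, predictions and residuals", {
  d <- simulate_titration(7.04e3, 1, -5.56, study_protocol(),
                          noise_sd = 1, seed = 12)
  fit <- itc_fit(d)
  cf <- coef(fit)
  expect_named(cf, c("K_A", "n", "dH", "offset"))
  expect_length(predict(fit), 18)
  expect_equal(predict(fit) + residuals(fit), d$heats,
               ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "itc_data")
  s <- summary(fit)
  expect_true("K_A (M^-1)" %in% s$parameter)
})

test_that("itc file round trip preserves the heats", {
  d <- simulate_titration(7.04e3, 1, -5.56, study_protocol(),
                          noise_sd = 1, seed = 3)
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("# injection  heat_ucal",
               sprintf("%d\t%.6f", seq_along(d$heats), d$heats)), tf)
  d2 <- read_itc(tf, study_protocol())
  expect_equal(d2$heats, d$heats, tolerance = 1e-6)
  f1 <- itc_fit(d)
  f2 <- itc_fit(d2)
  expect_equal(f2$K_A, f1$K_A, tolerance = 1e-4)
  unlink(tf)
})
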