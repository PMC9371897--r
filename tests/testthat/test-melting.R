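test_that("sigmoid curves take their defining values", {
  expect_equal(boltzmann_curve(53, 1, 0, 53, 3), 0.5)
  expect_equal(boltzmann_curve(-Inf, 1, 0, 53, 3), 1)
  expect_equal(boltzmann_curve(Inf, 1, 0, 53, 3), 0)
  expect_equal(double_boltzmann_curve(-Inf, 1, 0, 40, 2, 60, 2, 0.5), 1)
  expect_equal(double_boltzmann_curve(Inf, 1, 0, 40, 2, 60, 2, 0.5), 0)
  # at T between the transitions, the curve sits near the phi plateau
  expect_equal(double_boltzmann_curve(50, 1, 0, 40, 1, 60, 1, 0.3), 0.7,
               tolerance = 1e-3)
})

test_that("zero-noise closure: fits recover the generator's truth exactly", {
  tr <- melt_truth("single", T_half = 53, w = 3, noise_sd = 0)
  ds <- gen_survival_dataset(tr, seed = 1)
  fit <- fit_boltzmann(ds)
  expect_equal(unname(fit$par["T_half"]), 53, tolerance = 1e-4)
  expect_equal(unname(fit$par["w"]), 3, tolerance = 1e-4)
  expect_equal(fit$Tm, 53, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)
  tr2 <- melt_truth("double", T1 = 40, T2 = 60, noise_sd = 0)
  fit2 <- fit_double_boltzmann(gen_survival_dataset(tr2, seed = 1))
  expect_equal(unname(fit2$par["T1"]), 40, tolerance = 1e-3)
  expect_equal(unname(fit2$par["T2"]), 60, tolerance = 1e-3)
  expect_lt(fit2$rss, 1e-8)
})

test_that("noisy single-Boltzmann fits recover Tm within 1 degC", {
  tr <- melt_truth("single", T_half = 53, w = 3, noise_sd = 0.05)
  for (s in 1:5) {
    fit <- fit_boltzmann(gen_survival_dataset(tr, seed = s))
    expect_lt(abs(fit$Tm - 53), 1)
  }
})

test_that("Tm is the 0.5 crossing of the fitted curve, not T_half", {
  # asymmetric plateaus shift the crossing away from the midpoint parameter
  tr <- melt_truth("single", S_top = 1, S_bottom = 0.2, T_half = 53, w = 3,
                   noise_sd = 0)
  fit <- fit_boltzmann(gen_survival_dataset(tr, seed = 1))
  expected <- 53 + 3 * log((1 - 0.5) / (0.5 - 0.2))
  expect_equal(fit$Tm, expected, tolerance = 1e-3)
  expect_equal(fit$curve(fit$Tm), 0.5, tolerance = 1e-6)
})

test_that("a curve that never crosses 0.5 yields a Tm-undefined error", {
  tr <- melt_truth("single", S_top = 0.95, S_bottom = 0.6, noise_sd = 0.02)
  ds <- gen_survival_dataset(tr, seed = 3)
  expect_error(fit_boltzmann(ds), "never crosses")
})

test_that("degenerate inputs are rejected", {
  flat <- data.frame(temperature_C = rep(seq(30, 95, 5), 3),
                     replicate = rep(1:3, each = 14), survival = 0.8)
  expect_error(fit_boltzmann(flat), "constant")
  few <- data.frame(temperature_C = rep(c(40, 60), 2), replicate = 1,
                    survival = c(1, 0, 0.9, 0.1))
  expect_error(fit_boltzmann(few), "temperatures")
  expect_error(fit_double_boltzmann(
    data.frame(temperature_C = rep(seq(40, 60, 5), 2), replicate = 1,
               survival = runif(10))), "temperatures")
})

test_that("survival_rates inverts the band-table generator", {
  tr <- melt_truth("single", noise_sd = 0)
  bt <- gen_survival_band_table(tr, gain = 100, noise_sd = 0)
  sr <- survival_rates(bt)
  for (r in 1:3) {
    s <- sr[sr$replicate == r, ]
    expect_equal(s$survival[order(s$temperature_C)], tr$curve(tr$temperatures),
                 tolerance = 1e-12)
  }
  bad <- bt[bt$role == "target", ]
  expect_error(survival_rates(bad), "control")
})

test_that("yield_from_standard inverts the gel generator's linear rule", {
  g <- gen_band_table(c(lattice = 7.5), standard_mass = 12, gain = 50,
                      noise_sd = 0, seed = 1)
  y <- yield_from_standard(g, "sample", "lattice", input_mass = 30)
  expect_equal(y$mass, 7.5, tolerance = 1e-12)
  expect_equal(y$yield, 0.25, tolerance = 1e-12)
  expect_error(yield_from_standard(g, "sample", "nope"), "not found")
  g2 <- g[g$role != "standard", ]
  expect_error(yield_from_standard(g2, "sample", "lattice"), "standard")
})

test_that("model comparison prefers the generator's own model", {
  tr2 <- melt_truth("double", T1 = 40, T2 = 60, noise_sd = 0.05)
  ds2 <- gen_survival_dataset(tr2, seed = 7)
  cmp <- compare_melt_fits(fit_boltzmann(ds2), fit_double_boltzmann(ds2))
  expect_equal(attr(cmp, "preferred"), "double")
})

test_that("delta_tm reports the ligated-minus-unligated increment", {
  unlig <- fit_boltzmann(gen_survival_dataset(
    melt_truth("single", T_half = 53, w = 3, noise_sd = 0), seed = 1))
  lig <- fit_boltzmann(gen_survival_dataset(
    melt_truth("single", T_half = 74, w = 3, noise_sd = 0,
               temperatures = seq(55, 95, by = 5)), seed = 1))
  expect_equal(delta_tm(lig, unlig), 21, tolerance = 1e-3)
})
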