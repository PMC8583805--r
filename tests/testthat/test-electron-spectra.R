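test_that("the low-energy LET expression evaluates correctly", {
  # direct evaluation of the analytic form at its two reference energies
  direct <- function(T) (4376 * log(T) - 19803) / T + 129622 / T^2
  expect_equal(let_low_energy(1000), direct(1000))
  expect_equal(let_low_energy(100), direct(100))
  expect_equal(let_electron(100), direct(100))
  expect_equal(let_low_energy(1000), 10.555, tolerance = 1e-4)
})

test_that("LET evaluation enforces the 50 eV cutoff", {
  expect_error(let_electron(49), "50 eV")
  expect_silent(let_electron(50))
})

test_that("LET is continuous enough across the 1 keV crossover", {
  gap <- let_crossover_gap()
  expect_lt(abs(gap), 0.25)
  lo <- let_electron(999.9)
  hi <- let_electron(1000.1)
  expect_lt(abs(hi - lo) / max(hi, lo), abs(gap) + 0.01)
})

test_that("high-energy LET interpolates the stopping-power table", {
  model <- stopping_power_model()
  tab <- model$high_energy_table
  expect_equal(let_electron(tab$energy_eV[5]), tab$let_eV_per_nm[5])
  # log-log interpolation lies between neighbouring tabulated values
  mid <- sqrt(tab$energy_eV[5] * tab$energy_eV[6])
  v <- let_electron(mid)
  expect_true(v <= max(tab$let_eV_per_nm[5:6]) &&
                v >= min(tab$let_eV_per_nm[5:6]))
})

test_that("photon sources validate and map to photoelectron lines", {
  expect_error(photon_source("x", -1), "positive")
  expect_error(photon_source("x", c(1, 2), weights = 1), "one per line")
  src <- photon_source("Al", 1490)
  fl <- photoelectron_fluence(src)
  expect_true(is_line_spectrum(fl))
  expect_equal(fl$energy_eV, 1490)
  expect_equal(sum(fl$fluence), 1)
  expect_error(photoelectron_fluence(photon_source("co", 1.17e6)),
               "20 keV")
})

test_that("the Compton edge and electron spectrum behave as expected", {
  expect_equal(compton_edge(1.33e6), 1.33e6 * 2 * (1.33e6 / 511e3) /
                 (1 + 2 * 1.33e6 / 511e3))
  src <- photon_source("Co-60", c(1.17e6, 1.33e6))
  fl <- compton_electron_fluence(src)
  expect_false(is_line_spectrum(fl))
  expect_true(all(fl$fluence >= 0))
  expect_lte(max(fl$energy_eV), compton_edge(1.33e6) * (1 + 1e-12))
  expect_error(compton_electron_fluence(photon_source("Al", 1490)),
               "100 keV")
})

test_that("slowing-down fluence is Q(E)/LET(E) for a line source", {
  model <- stopping_power_model()
  src <- photon_source("Al", 1490)
  init <- photoelectron_fluence(src)
  eq <- slowing_down_fluence(init, model)
  # below every line, Q equals the full source weight
  idx <- which(eq$energy_eV < min(init$energy_eV))
  expect_equal(eq$fluence[idx],
               sum(init$fluence) / let_electron(eq$energy_eV[idx], model))
  # at the line energy itself the full weight is still in flight
  expect_equal(eq$fluence[length(eq$fluence)],
               sum(init$fluence) / let_electron(1490, model))
  # grid bounds are enforced
  expect_error(slowing_down_fluence(init, model, grid = c(10, 100)),
               "50 eV")
})

test_that("dose-mean LET separates ultrasoft X rays from Co-60", {
  model <- stopping_power_model()
  usx <- slowing_down_fluence(
    photoelectron_fluence(photon_source("Carbon K-shell", 280)), model
  )
  co <- slowing_down_fluence(
    compton_electron_fluence(photon_source("Co-60", c(1.17e6, 1.33e6))),
    model
  )
  expect_gt(dose_mean_let(usx, model), 5 * dose_mean_let(co, model))
})
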