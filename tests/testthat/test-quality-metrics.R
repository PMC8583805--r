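test_that("rbe, hrf and reduction_percent have ratio semantics", {
  expect_equal(rbe(5, 5), 1)
  expect_equal(hrf(5, 5), 1)
  expect_equal(reduction_percent(5, 5), 0)
  expect_equal(reduction_percent(5, 0), 100)
  expect_error(rbe(1, 0), "positive")
  expect_error(hrf(1, 0), "positive")
  expect_error(reduction_percent(0, 1), "positive")
})

test_that("rbe is transitive and scale invariant", {
  a <- 21.2; b <- 8.1; c <- 3.7
  expect_equal(rbe(a, b) * rbe(b, c), rbe(a, c))
  expect_equal(rbe(3 * a, 3 * b), rbe(a, b))
  expect_equal(hrf(3 * a, 3 * b), hrf(a, b))
})

test_that("dose-weighted average reduces to the plain yield on a delta line", {
  model <- stopping_power_model()
  fl <- photoelectron_fluence(photon_source("Al", 1490))
  yields <- tibble::tibble(energy_eV = c(100, 1490, 5000),
                           yield = c(9, 7, 5))
  expect_equal(dose_weighted_average(yields, fl, model), 7)
})

test_that("dose-weighted average of a constant is exactly the constant", {
  model <- stopping_power_model()
  co <- slowing_down_fluence(
    compton_electron_fluence(photon_source("Co-60", c(1.17e6, 1.33e6))),
    model
  )
  const <- tibble::tibble(energy_eV = 1000, yield = 4.25)
  expect_equal(dose_weighted_average(const, co, model), 4.25)
  # probability column multiplies in
  const2 <- tibble::tibble(energy_eV = 1000, yield = 4, p = 0.5)
  expect_equal(dose_weighted_average(const2, co, model, prob_col = "p"), 2)
})

test_that("dose-weighted average is invariant to fluence rescaling", {
  model <- stopping_power_model()
  fl <- slowing_down_fluence(
    photoelectron_fluence(photon_source("Ti", 4550)), model
  )
  yields <- tibble::tibble(energy_eV = 10^seq(2, 3.65, length.out = 12),
                           yield = seq(12, 6, length.out = 12))
  v1 <- dose_weighted_average(yields, fl, model)
  fl2 <- fl
  fl2$fluence <- fl2$fluence * 17.3
  expect_equal(dose_weighted_average(yields, fl2, model), v1)
})

test_that("dose-weighted average converges under grid refinement", {
  model <- stopping_power_model()
  src <- photon_source("Ti", 4550)
  init <- photoelectron_fluence(src)
  grid_c <- exp(seq(log(50), log(4550), length.out = 80))
  grid_f <- exp(seq(log(50), log(4550), length.out = 800))
  grid_c[c(1, 80)] <- c(50, 4550)
  grid_f[c(1, 800)] <- c(50, 4550)
  coarse <- slowing_down_fluence(init, model, grid = grid_c)
  fine <- slowing_down_fluence(init, model, grid = grid_f)
  yields <- tibble::tibble(energy_eV = 10^seq(1.7, 3.66, length.out = 30),
                           yield = 5 + 10 / (1 + (10^seq(1.7, 3.66,
                                                length.out = 30)) / 500))
  vc <- dose_weighted_average(yields, coarse, model)
  vf <- dose_weighted_average(yields, fine, model)
  expect_lt(abs(vc / vf - 1), 0.01)
})

test_that("dose_weighted_average validates its inputs", {
  model <- stopping_power_model()
  fl <- photoelectron_fluence(photon_source("Al", 1490))
  expect_error(dose_weighted_average(tibble::tibble(x = 1), fl, model),
               "energy_eV")
  co <- slowing_down_fluence(
    compton_electron_fluence(photon_source("Co-60", c(1.17e6, 1.33e6))),
    model
  )
  disjoint <- tibble::tibble(energy_eV = c(1e9, 2e9), yield = c(1, 2))
  expect_error(dose_weighted_average(disjoint, co, model), "overlap")
})

test_that("report rounding helpers follow the stated conventions", {
  expect_equal(round_yield(9.3976), 9.4)
  expect_equal(round_probability(0.017349), 0.017)
  expect_equal(round_ratio(2.617), 2.6)
  expect_equal(round_percent(26.89), 27)
})

test_that("build_report assembles consistent tables", {
  ref <- suppressWarnings(reference_tables()$yields)
  sub <- ref[ref$label %in% c("Co-60", "Titanium K-shell"), ]
  outcomes <- tibble::tibble(
    label = c("Co-60", "Titanium K-shell"),
    p_correct = c(0.96, 0.95), p_mutation = c(0.028, 0.033),
    p_conversion = c(0.011, 0.017)
  )
  rep <- build_report(sub, outcomes)
  expect_named(rep, c("induction", "dsb_summary", "repair", "conversion",
                      "hrf", "notes"))
  co21 <- rep$dsb_summary[rep$dsb_summary$label == "Co-60" &
                            rep$dsb_summary$oxygen_percent == 21, ]
  expect_equal(co21$rbe_dsb, 1)
  ti <- rep$conversion[rep$conversion$label == "Titanium K-shell", ]
  expect_equal(ti$dsb_conversion,
               sub$total_damage[sub$label == "Titanium K-shell" &
                                  sub$oxygen_percent == 21] * 0.017)
  expect_true(all(rep$hrf$hrf > 1))
  expect_error(build_report(sub, reference_label = "nope"), "missing")
})

test_that("build_report single quality and oxygen level degenerates", {
  ref <- suppressWarnings(reference_tables()$yields)
  one <- ref[ref$label == "Co-60" & ref$oxygen_percent == 21, ]
  rep <- build_report(one)
  expect_identical(nrow(rep$induction), 1L)
  expect_identical(nrow(rep$dsb_summary), 1L)
  expect_identical(nrow(rep$hrf), 0L)
  expect_null(rep$repair)
})
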