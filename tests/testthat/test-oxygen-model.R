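test_that("oxygen_response validates and recycles parameters", {
  resp <- oxygen_response(s_min = 0.4, half_effect_k = 1, hill_exponent = 1)
  expect_identical(nrow(resp), 7L)
  expect_setequal(resp$category, damage_categories())
  expect_error(oxygen_response(s_min = -0.1, half_effect_k = 1,
                               hill_exponent = 1))
  expect_error(oxygen_response(s_min = 0.4, half_effect_k = -1,
                               hill_exponent = 1))
})

test_that("oxygen_scale is a monotone non-decreasing function of oxygen", {
  resp <- oxygen_response(s_min = 0.4, half_effect_k = 0.8,
                          hill_exponent = 1.2)
  o2 <- c(0, 10^seq(-3, log10(21), length.out = 50))
  for (cc in c("BD", "SSB", "DSB")) {
    s <- oxygen_scale(o2, cc, resp)
    expect_true(all(diff(s) >= -1e-12))
    expect_equal(s[1], 0.4)
    expect_true(all(s <= 1 + 1e-12))
  }
})

test_that("apply_oxygen is the identity at 21% and preserves totals", {
  sp <- damage_spectrum("q", c(BD = 400, SSB = 170, SSBp = 8, twoSSB = 1,
                               DSB = 7, DSBp = 1, DSBpp = 0.1))
  resp <- oxygen_response(s_min = 0.4, half_effect_k = 0.8,
                          hill_exponent = 1.2)
  same <- apply_oxygen(sp, 21, resp)
  expect_equal(as.data.frame(same[, damage_categories()]),
               as.data.frame(sp[, damage_categories()]))
  low <- apply_oxygen(sp, 0.5, resp)
  expect_identical(low$oxygen_percent, 0.5)
  expect_true(all(low$total_DSB < sp$total_DSB))
  expect_equal(low$total_damage,
               low$BD + low$total_SSB + low$total_DSB)
})

test_that("calibrate_oxygen reproduces the relative yields it was fed", {
  # steep response with a genuine sub-0.1% plateau, so the fit's plateau
  # constraint is inactive at the truth
  true_resp <- oxygen_response(
    s_min = c(BD = 0.9, SSB = 0.55, SSBp = 0.5, twoSSB = 0.5, DSB = 0.43,
              DSBp = 0.4, DSBpp = 0.35),
    half_effect_k = 0.5, hill_exponent = 2.2
  )
  sp21 <- damage_spectrum("q", c(BD = 400, SSB = 170, SSBp = 8, twoSSB = 1,
                                 DSB = 7, DSBp = 1, DSBpp = 0.1))
  levels <- c(21, 5, 2, 0.5, 0.1)
  spectra <- dplyr::bind_rows(lapply(levels, function(o) {
    apply_oxygen(sp21, o, true_resp)
  }))
  fit <- calibrate_oxygen(spectra)
  for (o in levels) {
    pred <- apply_oxygen(sp21, o, fit$response)
    obs <- spectra[spectra$oxygen_percent == o, ]
    for (cc in damage_categories()) {
      expect_lt(abs(pred[[cc]] / obs[[cc]] - 1), 0.02)
    }
  }
  expect_identical(nrow(tidy(fit)), 7L)
  expect_identical(nrow(glance(fit)), 1L)
})

test_that("calibrate_oxygen enforces its preconditions", {
  sp <- damage_spectrum("q", c(BD = 400, SSB = 170, SSBp = 8, twoSSB = 1,
                               DSB = 7, DSBp = 1, DSBpp = 0.1))
  expect_error(calibrate_oxygen(sp), "3 oxygen levels")
  two <- dplyr::bind_rows(sp, damage_spectrum("other", c(
    BD = 1, SSB = 1, SSBp = 1, twoSSB = 1, DSB = 1, DSBp = 1, DSBpp = 1
  )))
  expect_error(calibrate_oxygen(two), "single")
})

test_that("hrf_curve is 1 at 21%, non-increasing in oxygen, and plateaus", {
  ref <- suppressWarnings(reference_tables()$yields)
  co <- ref[ref$label == "Co-60", ]
  fit <- calibrate_oxygen(co)
  sp21 <- co[co$oxygen_percent == 21, ]
  crv <- hrf_curve(sp21, fit)
  expect_equal(crv$hrf[which.max(crv$o2_percent)], 1)
  expect_true(all(diff(crv$hrf) / diff(crv$o2_percent) <= 1e-9))
  deep <- hrf_curve(sp21, fit, o2_percent = c(0.001, 0.05, 0.1))
  expect_lt(max(abs(deep$hrf / deep$hrf[1] - 1)), 0.02)
})

test_that("hrf_from_tables matches direct ratios", {
  ref <- suppressWarnings(reference_tables()$yields)
  co <- ref[ref$label == "Co-60", ]
  tab <- hrf_from_tables(co)
  h01 <- tab$hrf[tab$o2_percent == 0.1]
  y21 <- co$total_DSB[co$oxygen_percent == 21]
  y01 <- co$total_DSB[co$oxygen_percent == 0.1]
  expect_equal(h01, y21 / y01)
})
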