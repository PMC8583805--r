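mk_lesions <- function(p, s, k) tibble::tibble(
  position = p, strand = s,
  kind = ifelse(k == 1, "strand_break", "base_damage")
)

test_that("repair_params validates its arguments", {
  p <- repair_params()
  expect_identical(p$inhibition_distance, 8L)
  expect_identical(p$lp_patch_min, 2L)
  expect_identical(p$lp_patch_max, 13L)
  expect_error(repair_params(p_first_strand_break = 1.2), "0, 1")
  expect_error(repair_params(lp_patch_min = 5, lp_patch_max = 2))
  expect_error(repair_params(inhibition_distance = 0))
})

test_that("DSB-containing clusters are rejected unless overridden", {
  dsb <- mk_lesions(c(0, 5), c(0, 1), c(1, 1))
  expect_error(outcome_probabilities(dsb, "SP_BER", n_trials = 10),
               "DSB")
  out <- outcome_probabilities(dsb, "SP_BER", n_trials = 200, seed = 1,
                               check_category = FALSE)
  # the machine itself converts opposite breaks within the inhibition
  # distance with certainty
  expect_equal(out$p_conversion, 1)
})

test_that("outcome probabilities conserve probability exactly", {
  les <- mk_lesions(c(0, 4, 9), c(0, 1, 0), c(1, 0, 1))
  for (pw in repair_pathways()) {
    out <- outcome_probabilities(les, pw, n_trials = 500, seed = 2)
    expect_equal(out$p_correct + out$p_mutation + out$p_conversion, 1)
    expect_identical(out$n_trials, 500L)
  }
})

test_that("Monte Carlo outcomes match the analytic branch-tree oracle", {
  params <- repair_params()
  cases <- list(
    list(les = mk_lesions(5, 0, 0), pw = "NER_LP_BER"),
    list(les = mk_lesions(c(2, 7), c(0, 1), c(0, 0)), pw = "LP_BER"),
    list(les = mk_lesions(c(0, 9), c(0, 1), c(0, 1)), pw = "NER_SP_BER"),
    list(les = mk_lesions(c(0, 6, 12), c(0, 1, 1), c(1, 0, 1)),
         pw = "SP_BER"),
    list(les = mk_lesions(c(0, 4, 7), c(0, 1, 0), c(1, 0, 1)),
         pw = "NER_LP_BER")
  )
  n <- 4e4
  for (cs in cases) {
    p <- oracle_repair_probs_df(cs$les, cs$pw, params)
    out <- outcome_probabilities(cs$les, cs$pw, params, n_trials = n,
                                 seed = 42)
    est <- c(out$p_correct, out$p_mutation, out$p_conversion)
    for (j in 1:3) {
      se <- sqrt(p[j] * (1 - p[j]) / n)
      expect_lt(abs(est[j] - p[j]), max(3 * se, 12 / n))
    }
  }
})

test_that("isolated lesions repair with the pathway error rates", {
  params <- repair_params()
  # single SSB: SP excision in every pathway except pure LP
  p <- oracle_repair_probs_df(mk_lesions(3, 0, 1), "SP_BER", params)
  expect_equal(unname(p["p_mutation"]), params$err_sp)
  p <- oracle_repair_probs_df(mk_lesions(3, 0, 1), "LP_BER", params)
  expect_equal(unname(p["p_mutation"]), params$err_lp_ner)
  # single BD under NER routes through the NER patch
  p <- oracle_repair_probs_df(mk_lesions(3, 0, 0), "NER_SP_BER", params)
  expect_equal(unname(p["p_mutation"]), params$err_lp_ner)
  expect_equal(unname(p["p_conversion"]), 0)
})

test_that("a BD opposite a template break mis-inserts at the damaged rate", {
  params <- repair_params()
  # SSB whose 1 nt patch template holds a damaged base: mis-insertion at
  # the damaged-template rate no matter which lesion is excised first
  les <- mk_lesions(c(5, 5), c(0, 1), c(1, 0))
  p <- oracle_repair_probs_df(les, "SP_BER", params)
  out <- outcome_probabilities(les, "SP_BER", params, n_trials = 4e4,
                               seed = 3)
  expect_lt(abs(out$p_mutation - p["p_mutation"]),
            3 * sqrt(p["p_mutation"] * (1 - p["p_mutation"]) / 4e4))
  expect_gt(p["p_mutation"], 0.3)
})

test_that("pathway ordering holds on the standard cluster battery", {
  battery <- standard_cluster_battery()
  params <- repair_params()
  agg <- sapply(repair_pathways(), function(pw) {
    probs <- sapply(battery$lesions, function(les) {
      oracle_repair_probs_df(les, pw, params)
    })
    rowMeans(probs)
  })
  # combined NER/LP BER repairs worst and converts most; SP BER is safest
  expect_identical(names(which.min(agg["p_correct", ])), "NER_LP_BER")
  expect_identical(names(which.max(agg["p_conversion", ])), "NER_LP_BER")
  expect_identical(names(which.max(agg["p_correct", ])), "SP_BER")
})

test_that("category_outcome_probabilities covers sampled categories", {
  cfg <- induction_config(site_rate = 300, lesion_multiplicity = 1.5,
                          sb_fraction = 0.26, segment_length = 57)
  out <- category_outcome_probabilities(cfg, "LP_BER", n_sites = 3e3,
                                        n_trials = 50, seed = 9)
  expect_identical(out$category, damage_categories())
  seen <- out[out$n_clusters > 0, ]
  expect_gt(nrow(seen), 3)
  sums <- seen$p_correct + seen$p_mutation + seen$p_conversion
  expect_equal(sums, rep(1, nrow(seen)))
  # BD-only clusters can never convert under pure-BER pathways
  bd <- out[out$category == "BD", ]
  expect_equal(bd$p_conversion, 0)
})

test_that("aggregate_outcomes weights by yield and renormalizes", {
  sp <- damage_spectrum("q", c(BD = 3, SSB = 1, SSBp = 0, twoSSB = 0,
                               DSB = 0, DSBp = 0, DSBpp = 0))
  per <- tibble::tibble(
    category = c("BD", "SSB"),
    p_correct = c(1, 0.5), p_mutation = c(0, 0.5), p_conversion = c(0, 0)
  )
  out <- aggregate_outcomes(sp, per)
  expect_equal(out$p_correct, 0.75 * 1 + 0.25 * 0.5)
  expect_equal(out$p_mutation, 0.125)
  sp2 <- damage_spectrum("q", c(BD = 3, SSB = 1, SSBp = 1e-6, twoSSB = 0,
                                DSB = 0, DSBp = 0, DSBpp = 0))
  per2 <- dplyr::bind_rows(per, tibble::tibble(
    category = "SSBp", p_correct = NA_real_, p_mutation = NA_real_,
    p_conversion = NA_real_
  ))
  expect_warning(out2 <- aggregate_outcomes(sp2, per2), "renormalizing")
  expect_equal(out2$p_correct, out$p_correct, tolerance = 1e-6)
  expect_error(aggregate_outcomes(sp, per[1, ]), "missing")
})

test_that("enzymatic_dsb_yield multiplies yield by conversion probability", {
  expect_equal(enzymatic_dsb_yield(552.8, 0.017), 9.3976)
  expect_equal(enzymatic_dsb_yield(0, 0.5), 0)
  expect_error(enzymatic_dsb_yield(-1, 0.5))
})

test_that("the standard cluster battery is non-DSB by construction", {
  battery <- standard_cluster_battery()
  cats <- vapply(battery$lesions, classify_cluster, character(1))
  expect_false(any(cats %in% c("DSB", "DSBp", "DSBpp")))
  expect_setequal(unique(cats), c("BD", "SSB", "SSBp", "twoSSB"))
})
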