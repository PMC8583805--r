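test_that("induction_config validates its parameters", {
  cfg <- induction_config(site_rate = 100, lesion_multiplicity = 1,
                          sb_fraction = 0.4)
  expect_s3_class(cfg, "induction_config")
  expect_identical(cfg$segment_length, 25L)
  expect_identical(cfg$cluster_gap, 10L)
  expect_error(induction_config(-1, 1, 0.4))
  expect_error(induction_config(100, -0.1, 0.4))
  expect_error(induction_config(100, 1, 1.5))
  expect_error(induction_config(100, 1, 0.4, segment_length = 2))
})

test_that("sample_site is reproducible and respects the site geometry", {
  cfg <- induction_config(site_rate = 100, lesion_multiplicity = 2,
                          sb_fraction = 0.4, segment_length = 25)
  a <- sample_site(cfg, n_sites = 500, seed = 3)
  b <- sample_site(cfg, n_sites = 500, seed = 3)
  expect_identical(a, b)
  expect_setequal(names(a), c("site", "position", "strand", "kind"))
  expect_true(all(a$position >= 0 & a$position < 25))
  expect_true(all(a$strand %in% 0:1))
  expect_true(all(a$kind %in% c("strand_break", "base_damage")))
  expect_true(all(table(a$site) >= 1))
  # no two lesions share a (position, strand) slot within a site
  expect_false(any(duplicated(a[, c("site", "position", "strand")])))
})

test_that("cluster_lesions chains lesions at the gap boundary", {
  les <- tibble::tibble(position = c(0, 10, 21, 40),
                        strand = c(0, 1, 0, 1),
                        kind = rep("strand_break", 4))
  cl <- cluster_lesions(les, gap = 10)
  # 0-10 chained (diff == gap), 21 joins via 10+11? no: diff 11 splits
  expect_identical(cl$cluster, c(1L, 1L, 2L, 3L))
  cl2 <- cluster_lesions(les, gap = 11)
  expect_identical(cl2$cluster, c(1L, 1L, 1L, 2L))
  empty <- cluster_lesions(les[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("classify_cluster covers all seven categories", {
  mk <- function(p, s, k) tibble::tibble(
    position = p, strand = s,
    kind = ifelse(k == 1, "strand_break", "base_damage")
  )
  expect_identical(classify_cluster(mk(c(2, 5), c(0, 1), c(0, 0))), "BD")
  expect_identical(classify_cluster(mk(3, 0, 1)), "SSB")
  expect_identical(classify_cluster(mk(c(0, 4), c(0, 0), c(1, 1))), "SSBp")
  # opposite-strand breaks 12 bp apart, chained through a central BD
  expect_identical(classify_cluster(mk(c(0, 6, 12), c(0, 1, 1),
                                       c(1, 0, 1))), "twoSSB")
  expect_identical(classify_cluster(mk(c(0, 10), c(0, 1), c(1, 1))), "DSB")
  expect_identical(classify_cluster(mk(c(0, 11), c(0, 1), c(1, 1))),
                   "twoSSB")
  expect_identical(classify_cluster(mk(c(0, 3, 5), c(0, 1, 0),
                                       c(1, 1, 1))), "DSBp")
  expect_identical(classify_cluster(mk(c(0, 2, 8, 10), c(0, 1, 0, 1),
                                       c(1, 1, 1, 1))), "DSBpp")
  expect_error(classify_cluster(mk(integer(), integer(), integer())))
})

test_that("greedy pairing counts the maximum number of disjoint DSBs", {
  # breaks at 0(s0), 8(s1), 16(s0): 8 pairs with either neighbour but only
  # one disjoint pair exists; with an extra break it must find two
  mk <- function(p, s) tibble::tibble(position = p, strand = s,
                                      kind = "strand_break")
  expect_identical(classify_cluster(mk(c(0, 8, 16), c(0, 1, 0))), "DSBp")
  expect_identical(classify_cluster(mk(c(0, 8, 16, 24), c(0, 1, 0, 1))),
                   "DSBpp")
})

test_that("classify_lesions handles multi-site fields", {
  cfg <- induction_config(site_rate = 100, lesion_multiplicity = 1.5,
                          sb_fraction = 0.4)
  les <- sample_site(cfg, n_sites = 50, seed = 11)
  out <- classify_lesions(les)
  expect_true(all(out$category %in% damage_categories()))
  expect_true(nrow(out) >= 50)  # at least one cluster per site
})

test_that("simulate_damage_spectrum is deterministic with exact totals", {
  cfg <- induction_config(site_rate = 300, lesion_multiplicity = 1.5,
                          sb_fraction = 0.26, segment_length = 57)
  a <- simulate_damage_spectrum(cfg, n_sites = 2e4, label = "x", seed = 5)
  b <- simulate_damage_spectrum(cfg, n_sites = 2e4, label = "x", seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(a$total_SSB, a$SSB + a$SSBp + a$twoSSB)
  expect_equal(a$total_DSB, a$DSB + a$DSBp + a$DSBpp)
  expect_equal(a$total_damage, a$BD + a$total_SSB + a$total_DSB)
  expect_true(is.numeric(attr(a, "n_clusters")))
  # yields scale category counts by site_rate / n_sites: the implied
  # cluster count per category must be a whole number
  counts <- vapply(damage_categories(), function(cc) a[[cc]], numeric(1)) *
    2e4 / 300
  expect_equal(counts, round(counts), tolerance = 1e-8)
  expect_equal(sum(counts), attr(a, "n_clusters"))
})

test_that("a fine lesion field with sb_fraction 1 yields only SSBs", {
  cfg <- induction_config(site_rate = 10, lesion_multiplicity = 0,
                          sb_fraction = 1)
  sp <- simulate_damage_spectrum(cfg, n_sites = 5e3, label = "x", seed = 8)
  expect_equal(sp$SSB, 10)
  expect_equal(sp$total_damage, 10)
  expect_equal(sp$BD + sp$SSBp + sp$twoSSB + sp$total_DSB, 0)
})

test_that("calibration recovers a self-generated target", {
  true_cfg <- induction_config(site_rate = 200, lesion_multiplicity = 0.8,
                               sb_fraction = 0.3, segment_length = 25)
  target <- simulate_damage_spectrum(true_cfg, n_sites = 2e5,
                                     label = "self", seed = 21)
  fit <- calibrate_induction(target, n_sites = 5e4, seed = 4,
                             calibrate_segment = FALSE, maxit = 200,
                             restarts = 1)
  expect_s3_class(fit, "induction_fit")
  expect_lt(abs(fit$config$site_rate / 200 - 1), 0.15)
  expect_lt(abs(fit$config$sb_fraction / 0.3 - 1), 0.15)
  td <- tidy(fit)
  expect_identical(td$column, damage_categories())
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("objective", "site_rate", "sb_fraction") %in% names(gl)))
})

test_that("calibrate_induction validates inputs", {
  ref <- suppressWarnings(reference_tables()$yields)
  two_rows <- ref[ref$label == "Co-60", ]
  expect_error(calibrate_induction(two_rows), "one-row")
  one <- ref[ref$label == "Co-60" & ref$oxygen_percent == 21, ]
  expect_error(calibrate_induction(one, columns = c("BD", "nope")),
               "lacks columns")
  expect_error(calibrate_induction(one, weights = c(1, 2)), "weights")
})
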