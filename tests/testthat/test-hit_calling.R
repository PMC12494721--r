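test_that("plate z-scores follow the plate-matched formula", {
  expect_equal(plate_zscore(100, 100, 5), 0)
  expect_equal(plate_zscore(110, 100, 5), 2)
  expect_equal(plate_zscore(c(90, 110), 100, 5), c(-2, 2))
  expect_warning(z <- plate_zscore(100, 95, 0), "flagged")
  expect_true(all(is.na(z)))
})

test_that("z-to-p conversion uses the normal survival function", {
  expect_equal(z_to_pvalue(0), 1.0)
  expect_equal(z_to_pvalue(1.959964), 0.05, tolerance = 1e-6)
  expect_equal(z_to_pvalue(-3), z_to_pvalue(3))
  expect_equal(z_to_pvalue(1.644854, "one_sided_upper"), 0.05,
               tolerance = 1e-6)
  expect_equal(z_to_pvalue(-2, "one_sided_upper"), pnorm(2))
  expect_true(is.na(z_to_pvalue(NA_real_)))
})

test_that("BH adjustment matches hand-worked examples and is monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_equal(bh_adjust(c(0.02, NA, 0.04)), c(0.04, NA, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::local_seed(42)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    # raising one p-value never lowers any adjusted value
    j <- sample(length(p), 1)
    p2 <- p
    p2[j] <- min(1, p[j] + runif(1) * (1 - p[j]))
    expect_true(all(bh_adjust(p2) >= q - 1e-12))
  }
})

test_that("dual-replicate hit rule combines significance, direction and effect size", {
  base <- tibble::tibble(
    species = "s", metabolite = "m", replicate = rep(1:2, each = 3),
    compound_id = rep(c("a", "b", "c"), 2), plate_id = "p1",
    corrected_conc_uM = 1,
    fc = c(1.5, 1.2, 1.6, 1.4, 1.2, 0.7),
    z = 3, p = 0.01,
    p_adj = c(0.01, 0.001, 0.01, 0.02, 0.001, 0.01))
  hits <- call_hits(base, NULL, screen_config())
  hits <- hits[order(hits$compound_id), ]
  # a: fc (1.5, 1.4): mean log2 fc ~ 0.536 > 0.32, both significant -> hit, up
  expect_true(hits$is_hit[1]); expect_equal(hits$direction[1], "up")
  expect_equal(hits$mean_log2_fc[1], (log2(1.5) + log2(1.4)) / 2)
  # b: fc (1.2, 1.2): |log2 1.2| = 0.263 <= 0.32 -> not a hit despite p
  expect_false(hits$is_hit[2])
  # c: fc (1.6, 0.7): opposite directions -> not a hit
  expect_false(hits$is_hit[3])
})

test_that("records without exactly two replicates are skipped with a warning", {
  one_rep <- tibble::tibble(
    species = "s", metabolite = "m", replicate = 1L, compound_id = "a",
    plate_id = "p1", corrected_conc_uM = 1, fc = 2, z = 3, p = 0.001,
    p_adj = 0.001)
  expect_warning(out <- call_hits(one_rep, NULL, screen_config()), "skip")
  expect_equal(nrow(out), 0)
})

test_that("growth concordance uses a strict linear-scale difference", {
  expect_true(classify_concordance(0.5, 0.5))
  expect_false(classify_concordance(1.0, 2.0))
  # boundary: |1.25 - 1.0| = 0.25 is NOT below 0.25 -> non-concordant
  expect_false(classify_concordance(1.0, 1.25))
  expect_true(is.na(classify_concordance(NA, 1.0)))
  expect_equal(classify_concordance(c(1, 1), c(1.1, 1.6)), c(TRUE, FALSE))
})

test_that("hit decisions are invariant to the concentration unit of a plate", {
  sim <- generate_screen(small_scenario(rng_seed = 33))
  cfg <- screen_config()
  res1 <- run_screen_pipeline(sim$measurements, sim$growth, cfg)
  scaled <- sim$measurements
  scaled$raw_conc_uM <- scaled$raw_conc_uM * 1000  # report in nM instead
  res2 <- run_screen_pipeline(scaled, sim$growth, cfg)
  h1 <- dplyr::arrange(res1$hits, species, metabolite, compound_id)
  h2 <- dplyr::arrange(res2$hits, species, metabolite, compound_id)
  expect_equal(h2$is_hit, h1$is_hit)
  expect_equal(h2$mean_log2_fc, h1$mean_log2_fc, tolerance = 1e-9)
  expect_equal(h2$concordant, h1$concordant)
})

test_that("plates with degenerate DMSO spread are flagged, not scored", {
  corrected <- tibble::tibble(
    species = "s", metabolite = "m", replicate = 1L, plate_id = "p1",
    role = c(rep("dmso_control", 11), rep("experimental", 4)),
    compound_id = c(rep(NA, 11), letters[1:4]),
    corrected_conc_uM = c(rep(100, 11), 80, 90, 110, 120))
  expect_warning(stats <- replicate_statistics(corrected, screen_config()),
                 "flagged")
  expect_true(all(is.na(stats$z)))
  expect_true(all(is.na(stats$p_adj)))
  # fold changes are still defined (they do not need the DMSO sd)
  expect_equal(sort(stats$fc), c(80, 90, 110, 120) / 100)
})
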