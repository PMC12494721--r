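test_that("class enrichment matches the hypergeometric oracle and definitions", {
  hit_flags <- tibble::tibble(
    compound_id = sprintf("c%03d", 1:100),
    is_hit = c(rep(TRUE, 10), rep(FALSE, 90)))
  membership <- tibble::tibble(
    compound_id = sprintf("c%03d", 1:5), class_label = "classA")
  res <- class_enrichment(hit_flags, membership)
  expect_equal(unlist(res[, c("a", "b", "c", "d")]),
               c(a = 5, b = 0, c = 5, d = 90))
  expect_equal(res$p, oracle_fisher_p(5, 0, 5, 90), tolerance = 1e-10)
  expect_true(res$positively_enriched)
  expect_equal(res$hit_rate, 1)

  # class with no hits is never positively enriched
  memb0 <- tibble::tibble(compound_id = sprintf("c%03d", 91:95),
                          class_label = "classB")
  res0 <- class_enrichment(hit_flags, memb0)
  expect_false(res0$positively_enriched)

  # class covering the whole library is degenerate: p = 1
  memball <- tibble::tibble(compound_id = hit_flags$compound_id,
                            class_label = "all")
  resall <- class_enrichment(hit_flags, memball)
  expect_equal(resall$p, 1)
  expect_false(resall$positively_enriched)

  # unknown compounds in the membership table are a validation error
  membbad <- tibble::tibble(compound_id = "nope", class_label = "x")
  expect_error(class_enrichment(hit_flags, membbad), "absent")
})

test_that("Fisher p equals hypergeometric enumeration for all small tables", {
  worst <- 0
  for (n in c(8, 12, 20, 30)) {
    for (m in 1:(n - 1)) {        # class size
      for (k in 0:n) {            # total hits
        a_min <- max(0, k - (n - m)); a_max <- min(k, m)
        for (a in a_min:a_max) {
          tab <- matrix(c(a, m - a, k - a, n - m - (k - a)), nrow = 2)
          worst <- max(worst, abs(stats::fisher.test(tab)$p.value -
                                    oracle_fisher_p(a, m - a, k - a,
                                                    n - m - (k - a))))
        }
      }
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("enrichment p-values are calibrated under label permutation", {
  withr::local_seed(1234)
  n <- 200
  hit_flags <- tibble::tibble(compound_id = sprintf("c%03d", 1:n),
                              is_hit = rep(c(TRUE, FALSE), c(30, n - 30)))
  p_perm <- replicate(1000, {
    members <- sample(hit_flags$compound_id, 20)
    memb <- tibble::tibble(compound_id = members, class_label = "perm")
    class_enrichment(hit_flags, memb)$p
  })
  # the discrete exact test must not be anticonservative at any level
  for (a in c(0.01, 0.05, 0.1, 0.2)) {
    expect_lte(mean(p_perm < a), a + 3 * sqrt(a * (1 - a) / 1000))
  }
})

test_that("strata split enrichment into independent BH families", {
  hit_flags <- tibble::tibble(
    species = rep(c("s1", "s2"), each = 50),
    compound_id = rep(sprintf("c%03d", 1:50), 2),
    is_hit = c(rep(TRUE, 10), rep(FALSE, 40), rep(TRUE, 5), rep(FALSE, 45)))
  memb <- tibble::tibble(compound_id = sprintf("c%03d", 1:10),
                         class_label = rep(c("A", "B"), 5))
  res <- class_enrichment(hit_flags, memb, strata = "species")
  expect_equal(nrow(res), 4)     # 2 species x 2 classes
  for (sp in c("s1", "s2")) {
    sub <- res[res$species == sp, ]
    expect_equal(sub$p_adj, bh_adjust(sub$p))
  }
})

test_that("hit rates per class count active compounds", {
  hits <- tibble::tibble(
    compound_id = rep(sprintf("p%03d", 1:166), each = 2),
    is_hit = rep(c(rep(TRUE, 10), rep(FALSE, 156)), each = 2))
  memb <- tibble::tibble(compound_id = sprintf("p%03d", 1:166),
                         class_label = "pesticide")
  hr <- hit_rate_by_class(hits, memb)
  expect_equal(hr$n_class, 166)
  expect_equal(hr$n_active, 10)
  expect_equal(hr$hit_rate, 10 / 166, tolerance = 1e-12)  # 0.0602

  # all active -> rate 1; empty classes never appear
  hr2 <- hit_rate_by_class(dplyr::mutate(hits, is_hit = TRUE), memb)
  expect_equal(hr2$hit_rate, 1)
  expect_false("ghost" %in% hit_rate_by_class(hits, memb)$class_label)
})

test_that("cross-species correlation matches the covariance formula", {
  a <- tibble::tibble(compound_id = sprintf("c%02d", 1:10), value = 1:10)
  expect_equal(cross_species_correlation(a, a)$r, 1)
  b <- dplyr::mutate(a, value = -value)
  expect_equal(cross_species_correlation(a, b)$r, -1)

  withr::local_seed(8)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  ta <- tibble::tibble(compound_id = sprintf("c%02d", 1:50), value = x)
  tb <- tibble::tibble(compound_id = sprintf("c%02d", 1:50), value = y)
  res <- cross_species_correlation(ta, tb)
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_brute, tolerance = 1e-12)
  expect_equal(res$n_pairs, 50)
  expect_error(cross_species_correlation(ta[1:2, ], tb[1:2, ]), "fewer than 3")
})

test_that("dose-response fractions count dual-replicate stimulation", {
  doses <- c(2.5, 20)
  tbl <- tidyr::crossing(
    compound_id = sprintf("c%02d", 1:13), species = "E. coli",
    metabolite = "putrescine", dose_uM = doses) |>
    dplyr::mutate(
      stim = compound_id %in% sprintf("c%02d", 1:5) & dose_uM == 2.5 |
        compound_id %in% sprintf("c%02d", 1:2) & dose_uM == 20,
      mean_fc = ifelse(stim, 1.8, 1.0),
      mean_log2_fc = log2(mean_fc),
      p_adj_1 = ifelse(stim, 0.001, 0.5),
      p_adj_2 = ifelse(stim, 0.001, 0.5)) |>
    dplyr::select(-stim)
  out <- dose_response_fractions(tbl, screen_config())
  fr <- out$fractions
  expect_equal(fr$fraction_stimulated[fr$dose_uM == 2.5], 5 / 13,
               tolerance = 1e-12)   # 0.385
  expect_equal(fr$fraction_stimulated[fr$dose_uM == 20], 2 / 13,
               tolerance = 1e-12)

  # invariant to compound ordering
  out2 <- dose_response_fractions(tbl[sample(nrow(tbl)), ], screen_config())
  expect_equal(out2$fractions, fr)

  # no stimulation anywhere -> all fractions zero
  none <- dplyr::mutate(tbl, p_adj_1 = 0.9, p_adj_2 = 0.9)
  expect_true(all(dose_response_fractions(none,
                                          screen_config())$fractions$fraction_stimulated == 0))

  # compounds missing a level are excluded everywhere
  dropped <- tbl[-1, ]
  expect_message(out3 <- dose_response_fractions(dropped, screen_config()),
                 "excluded")
  expect_true(all(out3$fractions$n_tested == 12))
})

test_that("monotone flags separate interior-dose maxima from monotone responses", {
  sim <- simulate_dose_response(
    n_compounds = 6, profile = c(rep("interior", 3), rep("monotone", 3)),
    noise_cv = 0, drift_amplitude = 0, plate_effect_sd = 0, rng_seed = 5)
  suppressWarnings({
    scored <- score_dose_response(sim$measurements,
                                  screen_config(trend_radius = 30))
  })
  out <- dose_response_fractions(scored, screen_config())
  flags <- dplyr::inner_join(out$compounds, sim$profiles, by = "compound_id")
  expect_true(all(!flags$monotone[flags$profile == "interior"]))
  expect_true(all(flags$monotone[flags$profile == "monotone"]))
})

test_that("QC metrics reproduce the CV and replicate-correlation formulas", {
  corrected <- tibble::tibble(
    species = "s", replicate = 1L, plate_id = "p1", metabolite = "m",
    role = "dmso_control", compound_id = NA_character_,
    corrected_conc_uM = c(90, 100, 110))
  qc <- qc_metrics(corrected)
  expect_equal(qc$dmso_cv$cv, 0.10, tolerance = 1e-12)  # sample sd 10, mean 100
  expect_equal(qc$median_cv, 0.10, tolerance = 1e-12)

  reps <- tidyr::crossing(replicate = 1:2,
                          compound_id = sprintf("c%02d", 1:5)) |>
    dplyr::mutate(species = "s", metabolite = "m", plate_id = "p1",
                  role = "experimental",
                  corrected_conc_uM = rep(c(10, 20, 30, 40, 50), 2))
  qc2 <- qc_metrics(dplyr::bind_rows(corrected, reps))
  expect_equal(qc2$replicate_cor$r, 1)
  expect_equal(qc2$median_replicate_cor, 1)
})
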