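#' Therapeutic-class enrichment among hit compounds
#'
#' Two-sided Fisher's exact test on the 2x2 table (class x hit) for every
#' annotation class, with Benjamini-Hochberg adjustment across classes —
#' within each stratum when `strata` columns are supplied (e.g. species,
#' metabolite, direction, concordance), or pooled otherwise. A class is
#' positively enriched when its hit frequency exceeds the background hit
#' frequency; the direction filter is applied by the caller, not here.
#'
#' @param hit_flags Tibble with `compound_id`, logical `is_hit`, and any
#'   `strata` columns. One row per compound (per stratum).
#' @param class_membership Long tibble with `compound_id`, `class_label`;
#'   compounds may carry several labels or none. Compounds appearing here
#'   but absent from `hit_flags` raise a validation error.
#' @param alpha Significance level recorded alongside (does not filter).
#' @param strata Character vector of stratum column names in `hit_flags`,
#'   or `NULL` for pooled analysis.
#' @return Tibble with one row per (stratum x) class: counts `a`, `b`, `c`,
#'   `d` (class&hit, class&non-hit, non-class&hit, non-class&non-hit),
#'   `odds_ratio` (sample odds ratio, possibly infinite), `p`, `p_adj`,
#'   `hit_rate`, `positively_enriched`.
#' @export
class_enrichment <- function(hit_flags, class_membership, alpha = 0.05,
                             strata = NULL) {
  extra <- setdiff(unique(class_membership$compound_id),
                   unique(hit_flags$compound_id))
  if (length(extra) > 0) {
    abort(paste0("class_enrichment: membership table contains compounds ",
                 "absent from the hit table, e.g. ", extra[1]))
  }
  groups <- if (is.null(strata)) list(hit_flags) else {
    split(hit_flags, hit_flags[strata], drop = TRUE)
  }
  res <- bind_rows(lapply(groups, function(g) {
    if (anyDuplicated(g$compound_id)) {
      abort("class_enrichment: multiple rows per compound within a stratum")
    }
    total_hits <- sum(g$is_hit)
    n <- nrow(g)
    labs <- class_membership |>
      filter(.data$compound_id %in% g$compound_id) |>
      distinct(.data$compound_id, .data$class_label)
    per_class <- labs |>
      left_join(select(g, "compound_id", "is_hit"), by = "compound_id") |>
      group_by(.data$class_label) |>
      summarise(a = sum(.data$is_hit), size = dplyr::n(), .groups = "drop")
    if (nrow(per_class) == 0) return(NULL)
    stats <- lapply(seq_len(nrow(per_class)), function(i) {
      a <- per_class$a[i]; size <- per_class$size[i]
      b <- size - a; c <- total_hits - a; d <- n - size - c
      p <- fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
      tibble(a = a, b = b, c = c, d = d,
             odds_ratio = (a * d) / (b * c), p = p)
    })
    out <- bind_cols(select(per_class, "class_label"), bind_rows(stats))
    g_strata <- if (is.null(strata)) NULL else g[1, strata, drop = FALSE]
    out <- if (is.null(g_strata)) out else bind_cols(g_strata, out)
    out
  }))
  grp <- if (is.null(strata)) res else group_by(res, across(dplyr::all_of(strata)))
  grp |>
    mutate(
      p_adj = bh_adjust(.data$p),
      hit_rate = .data$a / (.data$a + .data$b),
      positively_enriched =
        .data$hit_rate > (.data$a + .data$c) / (.data$a + .data$b + .data$c + .data$d),
      alpha = alpha
    ) |>
    ungroup()
}

#' Hit rate per compound class
#'
#' A compound is *active* when it is a hit for at least one species x
#' metabolite pair; the hit rate of a class is active compounds / class
#' size. Classes without members are absent from the output.
#'
#' @param hits Hit table ([call_hits()] output, or any tibble with
#'   `compound_id` and `is_hit`, possibly several rows per compound).
#' @param class_membership Long tibble with `compound_id`, `class_label`.
#' @return Tibble: `class_label`, `n_class`, `n_active`, `hit_rate`.
#' @export
hit_rate_by_class <- function(hits, class_membership) {
  active <- hits |>
    group_by(.data$compound_id) |>
    summarise(active = any(.data$is_hit, na.rm = TRUE), .groups = "drop")
  class_membership |>
    distinct(.data$compound_id, .data$class_label) |>
    inner_join(active, by = "compound_id") |>
    group_by(.data$class_label) |>
    summarise(n_class = dplyr::n(), n_active = sum(.data$active),
              .groups = "drop") |>
    mutate(hit_rate = .data$n_active / .data$n_class)
}

#' Cross-species response correlation
#'
#' Pearson correlation (and two-sided p-value) between the per-compound mean
#' responses of two species, paired by compound over pairwise-complete
#' observations.
#'
#' @param responses_a,responses_b Tibbles with `compound_id` and a numeric
#'   `value` column (e.g. mean log2 fold change of growth or of a
#'   metabolite).
#' @return A one-row tibble: `n_pairs`, `r`, `p`.
#' @export
cross_species_correlation <- function(responses_a, responses_b) {
  joined <- inner_join(
    select(responses_a, "compound_id", a = "value"),
    select(responses_b, "compound_id", b = "value"),
    by = "compound_id")
  joined <- filter(joined, is.finite(.data$a), is.finite(.data$b))
  if (nrow(joined) < 3) {
    abort("cross_species_correlation: fewer than 3 complete compound pairs")
  }
  ct <- cor.test(joined$a, joined$b, method = "pearson",
                 alternative = "two.sided")
  tibble(n_pairs = nrow(joined), r = unname(ct$estimate), p = ct$p.value)
}

#' Dose-response stimulation fractions and monotonicity
#'
#' For each species x metabolite x concentration, the fraction of tested
#' compounds that *stimulated* amine production: adjusted p < alpha in both
#' biological replicates and mean fold change > 1 (optionally also the
#' screen's log2 fold-change threshold). Compounds missing any concentration
#' level are excluded from the fractions at all levels. Each compound also
#' receives a `monotone` flag: `TRUE` when its absolute mean log2 fold
#' change is non-decreasing with dose; interior-dose maxima (the atypical,
#' non-monotonic behaviour) give `FALSE`.
#'
#' @param dose_hits Hit-style table with one row per compound x species x
#'   metabolite x dose: columns `compound_id`, `species`, `metabolite`,
#'   `dose_uM`, `mean_fc`, `mean_log2_fc`, `p_adj_1`, `p_adj_2`.
#' @param config A [screen_config()].
#' @param require_lfc Also require `|mean_log2_fc| > lfc_threshold` for a
#'   dose to count as stimulated? Default FALSE (significance-only, as in
#'   the dose-response read-out).
#' @return A list of two tibbles: `fractions` (`species`, `metabolite`,
#'   `dose_uM`, `n_tested`, `n_stimulated`, `fraction_stimulated`) and
#'   `compounds` (`compound_id`, `species`, `metabolite`, `monotone`).
#' @export
dose_response_fractions <- function(dose_hits, config = screen_config(),
                                    require_lfc = FALSE) {
  levels_per_sm <- dose_hits |>
    group_by(.data$species, .data$metabolite) |>
    mutate(n_levels = dplyr::n_distinct(.data$dose_uM)) |>
    group_by(.data$species, .data$metabolite, .data$compound_id) |>
    mutate(complete = dplyr::n_distinct(.data$dose_uM) == .data$n_levels[1]) |>
    ungroup()
  n_dropped <- levels_per_sm |>
    filter(!.data$complete) |>
    distinct(.data$species, .data$metabolite, .data$compound_id) |>
    nrow()
  if (n_dropped > 0) {
    inform(sprintf(
      "dose_response_fractions: %d compound record(s) missing a concentration level were excluded",
      n_dropped))
  }
  complete_tbl <- filter(levels_per_sm, .data$complete)

  stim <- complete_tbl |>
    mutate(stimulated = !is.na(.data$p_adj_1) & !is.na(.data$p_adj_2) &
             .data$p_adj_1 < config$alpha & .data$p_adj_2 < config$alpha &
             .data$mean_fc > 1 &
             (!require_lfc | abs(.data$mean_log2_fc) > config$lfc_threshold))

  fractions <- stim |>
    group_by(.data$species, .data$metabolite, .data$dose_uM) |>
    summarise(n_tested = dplyr::n(), n_stimulated = sum(.data$stimulated),
              fraction_stimulated = mean(.data$stimulated), .groups = "drop") |>
    arrange(.data$species, .data$metabolite, .data$dose_uM)

  compounds <- stim |>
    group_by(.data$species, .data$metabolite, .data$compound_id) |>
    arrange(.data$dose_uM, .by_group = TRUE) |>
    summarise(monotone = !is.unsorted(abs(.data$mean_log2_fc)),
              .groups = "drop")

  list(fractions = fractions, compounds = compounds)
}

#' Quality-control metrics
#'
#' Two screen-level quality indicators: the coefficient of variation of
#' corrected DMSO-control concentrations per plate x metabolite (sample
#' sd / mean; plates with fewer than 2 DMSO controls are skipped), and the
#' Pearson correlation between the two biological replicates' per-compound
#' corrected concentrations for each species x metabolite (groups with
#' fewer than 3 compounds are skipped).
#'
#' @param corrected Output of [normalise_screen()].
#' @return A list: `dmso_cv` (per plate x metabolite tibble), `median_cv`,
#'   `replicate_cor` (per species x metabolite tibble), `median_replicate_cor`.
#' @export
qc_metrics <- function(corrected) {
  dmso_cv <- corrected |>
    filter(.data$role == "dmso_control",
           is.finite(.data$corrected_conc_uM)) |>
    group_by(.data$species, .data$replicate, .data$plate_id,
             .data$metabolite) |>
    summarise(n = dplyr::n(),
              cv = sd(.data$corrected_conc_uM) / mean(.data$corrected_conc_uM),
              .groups = "drop") |>
    filter(.data$n >= 2)

  rep_wide <- corrected |>
    filter(.data$role == "experimental",
           is.finite(.data$corrected_conc_uM)) |>
    select("species", "metabolite", "compound_id", "replicate",
           "corrected_conc_uM") |>
    pivot_wider(names_from = "replicate", values_from = "corrected_conc_uM",
                names_prefix = "rep_")
  replicate_cor <- NULL
  if (all(c("rep_1", "rep_2") %in% names(rep_wide))) {
    replicate_cor <- rep_wide |>
      filter(is.finite(.data$rep_1), is.finite(.data$rep_2)) |>
      group_by(.data$species, .data$metabolite) |>
      summarise(n = dplyr::n(),
                r = if (dplyr::n() >= 3)
                  stats::cor(.data$rep_1, .data$rep_2) else NA_real_,
                .groups = "drop") |>
      filter(!is.na(.data$r))
  }
  list(
    dmso_cv = dmso_cv,
    median_cv = median(dmso_cv$cv),
    replicate_cor = replicate_cor,
    median_replicate_cor = if (is.null(replicate_cor) ||
                               nrow(replicate_cor) == 0) NA_real_ else
      median(replicate_cor$r)
  )
}
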