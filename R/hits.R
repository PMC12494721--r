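#' Plate-matched z-score
#'
#' `z = (corrected - plate_reference_median) / dmso_sd`, where the reference
#' is either the plate-wide median of corrected concentrations (default) or
#' the median of the plate's DMSO controls, and `dmso_sd` is the sample
#' (n - 1) standard deviation of the plate's DMSO-control corrected
#' concentrations.
#'
#' @param corrected Corrected concentration(s).
#' @param plate_reference_median Plate reference median.
#' @param dmso_sd Standard deviation of the plate's DMSO controls; must be
#'   positive. A zero/non-finite value yields `NA` z-scores with a warning.
#' @return z-score(s), vectorised over `corrected`.
#' @export
plate_zscore <- function(corrected, plate_reference_median, dmso_sd) {
  if (!is.finite(dmso_sd) || dmso_sd <= 0) {
    warn("plate_zscore: DMSO standard deviation is zero or undefined; z set to NA (plate flagged)")
    return(rep(NA_real_, length(corrected)))
  }
  (corrected - plate_reference_median) / dmso_sd
}

#' Convert z-scores to p-values via the normal survival function
#'
#' @param z z-score(s); non-finite values yield `NA`.
#' @param sidedness `"two_sided"` (default): `p = min(1, 2 * SF(|z|))`;
#'   `"one_sided_upper"`: `p = SF(z)`.
#' @return p-value(s) in `[0, 1]`.
#' @export
z_to_pvalue <- function(z, sidedness = c("two_sided", "one_sided_upper")) {
  sidedness <- match.arg(sidedness)
  p <- switch(sidedness,
    two_sided = pmin(1, 2 * pnorm(abs(z), lower.tail = FALSE)),
    one_sided_upper = pnorm(z, lower.tail = FALSE)
  )
  p[!is.finite(z)] <- NA_real_
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up procedure: sort ascending, `q_(i) = p_(i) * n / i`,
#' enforce monotone non-decreasing adjusted values from the largest rank
#' downwards, cap at 1, return in original order. `n` counts the non-missing
#' p-values; missing entries stay missing.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("bh_adjust: p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  p <- pvalues[ok]
  n <- length(p)
  if (n == 0) return(out)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  out[ok] <- q
  out
}

#' Per-replicate plate statistics for every experimental well
#'
#' Computes, for each species x metabolite x replicate, the plate reference
#' median and DMSO standard deviation, then fold changes, z-scores,
#' p-values, and Benjamini-Hochberg adjusted p-values (adjusted within each
#' species x metabolite, separately per replicate).
#'
#' @param corrected Output of [normalise_screen()].
#' @param config A [screen_config()].
#' @return Tibble with one row per experimental well x metabolite:
#'   `species`, `metabolite`, `replicate`, `compound_id`, `plate_id`,
#'   `dose_uM` (if present), `corrected_conc_uM`, `fc`, `z`, `p`, `p_adj`.
#' @export
replicate_statistics <- function(corrected, config = screen_config()) {
  plate_stats <- corrected |>
    filter(.data$role %in% .sample_roles,
           is.finite(.data$corrected_conc_uM)) |>
    group_by(.data$species, .data$replicate, .data$plate_id,
             .data$metabolite) |>
    summarise(
      plate_median = median(.data$corrected_conc_uM),
      dmso_median = median(.data$corrected_conc_uM[.data$role == "dmso_control"]),
      dmso_sd = sd(.data$corrected_conc_uM[.data$role == "dmso_control"]),
      n_dmso = sum(.data$role == "dmso_control"),
      .groups = "drop"
    ) |>
    mutate(reference = if (config$plate_reference == "plate_median")
      .data$plate_median else .data$dmso_median)

  degenerate <- plate_stats$n_dmso < 3 |
    !is.finite(plate_stats$dmso_sd) | plate_stats$dmso_sd <= 0
  if (any(degenerate)) {
    warn(sprintf(
      "replicate_statistics: %d plate x metabolite group(s) flagged (fewer than 3 DMSO controls or zero DMSO sd); z set to NA",
      sum(degenerate)))
    plate_stats$dmso_sd[degenerate] <- NA_real_
  }

  out <- corrected |>
    filter(.data$role == "experimental") |>
    left_join(select(plate_stats, "species", "replicate", "plate_id",
                     "metabolite", "reference", "dmso_sd"),
              by = c("species", "replicate", "plate_id", "metabolite")) |>
    mutate(
      fc = .data$corrected_conc_uM / .data$reference,
      z = (.data$corrected_conc_uM - .data$reference) / .data$dmso_sd,
      p = z_to_pvalue(.data$z, config$sidedness)
    ) |>
    group_by(.data$species, .data$metabolite, .data$replicate) |>
    mutate(p_adj = bh_adjust(.data$p)) |>
    ungroup()

  keep <- intersect(c("species", "metabolite", "replicate", "compound_id",
                      "plate_id", "dose_uM", "corrected_conc_uM", "fc", "z",
                      "p", "p_adj"), names(out))
  select(out, dplyr::all_of(keep))
}

#' Growth-concordance classification
#'
#' A hit is growth-concordant when the absolute difference between its mean
#' growth fold change and mean metabolite fold change (both on the linear
#' scale, both relative to the plate-matched reference) is strictly below
#' `threshold`.
#'
#' @param mean_growth_fc Mean growth fold change across replicates.
#' @param mean_metab_fc Mean metabolite fold change across replicates.
#' @param threshold Strict bound on the absolute difference. Default 0.25.
#' @return Logical, vectorised: `TRUE` = concordant; `NA` when either input
#'   is missing.
#' @export
classify_concordance <- function(mean_growth_fc, mean_metab_fc,
                                 threshold = 0.25) {
  ifelse(is.finite(mean_growth_fc) & is.finite(mean_metab_fc),
         abs(mean_growth_fc - mean_metab_fc) < threshold,
         NA)
}

#' Dual-replicate hit calls with growth concordance
#'
#' A compound x species x metabolite triple is a hit when the adjusted
#' p-value is below `alpha` in both biological replicates, both replicates
#' change in the same direction, and the absolute mean log2 fold change
#' exceeds `lfc_threshold`. Hits are classified as growth-concordant or not
#' via [classify_concordance()] (missing when growth is artifact-filtered).
#'
#' @param rep_stats Output of [replicate_statistics()].
#' @param growth_summary Optional output of [summarise_growth()]; when
#'   omitted, growth columns are missing.
#' @param config A [screen_config()].
#' @return Tibble with one row per compound x species x metabolite:
#'   per-replicate `fc`, `z`, `p_adj` columns (suffixes `_1`, `_2`),
#'   `mean_fc`, `mean_log2_fc`, `direction`, `is_hit`, `mean_growth_fc`,
#'   `concordant`.
#' @export
call_hits <- function(rep_stats, growth_summary = NULL,
                      config = screen_config()) {
  n_rep <- rep_stats |>
    count(.data$species, .data$metabolite, .data$compound_id)
  bad <- filter(n_rep, .data$n != 2)
  if (nrow(bad) > 0) {
    warn(sprintf(
      "call_hits: %d compound x species x metabolite record(s) without exactly 2 replicates were skipped",
      nrow(bad)))
  }

  wide <- rep_stats |>
    semi_join(filter(n_rep, .data$n == 2),
              by = c("species", "metabolite", "compound_id")) |>
    select("species", "metabolite", "compound_id", "replicate", "fc", "z",
           "p_adj") |>
    pivot_wider(names_from = "replicate", values_from = c("fc", "z", "p_adj"),
                names_sep = "_")
  if (nrow(wide) == 0) {
    wide <- tibble(species = character(), metabolite = character(),
                   compound_id = character(), fc_1 = numeric(),
                   fc_2 = numeric(), z_1 = numeric(), z_2 = numeric(),
                   p_adj_1 = numeric(), p_adj_2 = numeric())
  }

  hits <- wide |>
    mutate(
      mean_fc = (.data$fc_1 + .data$fc_2) / 2,
      mean_log2_fc = (log2(.data$fc_1) + log2(.data$fc_2)) / 2,
      direction = ifelse(.data$mean_log2_fc > 0, "up", "down"),
      is_hit = !is.na(.data$p_adj_1) & !is.na(.data$p_adj_2) &
        .data$p_adj_1 < config$alpha & .data$p_adj_2 < config$alpha &
        sign(log2(.data$fc_1)) == sign(log2(.data$fc_2)) &
        abs(.data$mean_log2_fc) > config$lfc_threshold
    )

  if (!is.null(growth_summary)) {
    hits <- hits |>
      left_join(select(growth_summary, "species", "compound_id",
                       "mean_growth_fc"),
                by = c("species", "compound_id"))
  } else {
    hits$mean_growth_fc <- NA_real_
  }
  hits$concordant <- classify_concordance(hits$mean_growth_fc, hits$mean_fc,
                                          config$concordance_threshold)
  hits
}
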