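#' Convert raw 595 nm absorbance to optical density
#'
#' Subtracts the blank and the compound's own background absorbance (some
#' xenobiotics form coloured solutions that absorb at 595 nm), multiplies by
#' the instrument calibration factor, and clips at 0 so that strong growth
#' inhibition plus measurement noise cannot produce negative OD.
#'
#' @param raw Raw absorbance at 595 nm.
#' @param blank Blank absorbance (medium-only wells).
#' @param compound_background Blank-corrected absorbance of the compound
#'   solution itself at the screening concentration. Default 0.
#' @param od_multiplier Calibration factor to conventional OD. Default 5.
#' @return Non-negative OD values, vectorised.
#' @examples
#' absorbance_to_od(0.25, 0.05) # 1.0
#' @export
absorbance_to_od <- function(raw, blank, compound_background = 0,
                             od_multiplier = 5) {
  if (!is.finite(od_multiplier) || od_multiplier <= 0) {
    abort("absorbance_to_od: `od_multiplier` must be finite and > 0")
  }
  n <- max(length(raw), length(blank), length(compound_background))
  raw <- rep_len(as.numeric(raw), n)
  blank <- rep_len(as.numeric(blank), n)
  compound_background <- rep_len(as.numeric(compound_background), n)
  bad <- (!is.na(raw) & !is.finite(raw)) | (!is.na(blank) & !is.finite(blank)) |
    (!is.na(compound_background) & !is.finite(compound_background))
  if (any(bad)) abort("absorbance_to_od: non-finite inputs")
  pmax(0, raw - blank - compound_background) * od_multiplier
}

#' Plate-relative growth fold changes with artifact filtering
#'
#' Divides each well's OD by the median OD of the DMSO-control wells on the
#' same plate (DMSO wells themselves get fold changes too, used for QC).
#' Fold changes strictly above `artifact_threshold` are set to missing:
#' growth gains that large are caused by cell aggregation confounding the OD
#' reading, not by real growth stimulation.
#'
#' @param od Vector of OD values for one plate.
#' @param role Matching vector of well roles.
#' @param artifact_threshold Strict upper bound on plausible fold changes.
#'   Default 1.5.
#' @return Numeric vector of fold changes with `NA` where the artifact rule
#'   fired or inputs were missing. If the plate's DMSO median is 0 (or no
#'   finite DMSO OD exists), all fold changes are `NA` with a warning.
#' @export
growth_fold_change <- function(od, role, artifact_threshold = 1.5) {
  stopifnot(length(od) == length(role))
  dmso <- od[role == "dmso_control" & is.finite(od)]
  if (length(dmso) == 0 || median(dmso) == 0) {
    warn("growth_fold_change: plate has no usable DMSO reference (median 0 or missing); all fold changes set to NA")
    return(rep(NA_real_, length(od)))
  }
  fc <- od / median(dmso)
  fc[!is.na(fc) & fc > artifact_threshold] <- NA_real_
  fc
}

#' Process a raw growth table
#'
#' Applies [absorbance_to_od()] and [growth_fold_change()] plate by plate.
#'
#' @param growth_tbl Growth table as read by
#'   `read_measurements(schema = "growth")`.
#' @param config A [screen_config()].
#' @return The input tibble with `od` and `growth_fc` columns added.
#' @export
process_growth <- function(growth_tbl, config = screen_config()) {
  if (!"compound_background" %in% names(growth_tbl)) {
    inform("process_growth: no `compound_background` column; assuming 0")
    growth_tbl$compound_background <- 0
  }
  growth_tbl |>
    mutate(od = absorbance_to_od(.data$raw_absorbance, .data$blank,
                                 dplyr::coalesce(.data$compound_background, 0),
                                 config$od_multiplier)) |>
    group_by(.data$species, .data$replicate, .data$plate_id) |>
    mutate(growth_fc = growth_fold_change(
      .data$od, .data$role, config$growth_artifact_threshold)) |>
    ungroup()
}

#' Summarise growth per compound and species
#'
#' Mean growth fold change across replicates of each compound's experimental
#' wells; artifact-filtered replicates are excluded from the mean, and the
#' result is `NA` when no replicate survives.
#'
#' @param growth_processed Output of [process_growth()].
#' @return Tibble with `species`, `compound_id`, `mean_growth_fc`,
#'   `n_growth_reps` (replicates contributing).
#' @export
summarise_growth <- function(growth_processed) {
  growth_processed |>
    filter(.data$role == "experimental") |>
    group_by(.data$species, .data$compound_id) |>
    summarise(
      n_growth_reps = sum(is.finite(.data$growth_fc)),
      mean_growth_fc = ifelse(.data$n_growth_reps > 0,
                              mean(.data$growth_fc[is.finite(.data$growth_fc)]),
                              NA_real_),
      .groups = "drop"
    )
}
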