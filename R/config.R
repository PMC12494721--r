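#' Screen analysis configuration
#'
#' Bundles every tunable threshold of the analysis pipeline with the defaults
#' used throughout the screen. All thresholds must be strictly positive and
#' `alpha` must lie in (0, 1).
#'
#' @param alpha Significance level applied to Benjamini-Hochberg adjusted
#'   p-values (per replicate). Default 0.05.
#' @param lfc_threshold Minimum absolute mean log2 fold change for a hit.
#'   Default 0.32, i.e. fold changes outside roughly 0.8-1.25.
#' @param concordance_threshold Maximum absolute difference between mean
#'   growth fold change and mean metabolite fold change (linear scale) for a
#'   hit to count as growth-concordant. Default 0.25.
#' @param growth_artifact_threshold Growth fold changes strictly above this
#'   value are treated as optical-density aggregation artifacts and set to
#'   missing. Default 1.5.
#' @param od_multiplier Factor converting blank- and background-subtracted
#'   595 nm absorbance to conventional OD. Default 5.
#' @param conc_clip_uM Lower clip (in µM) applied to drift-corrected
#'   concentrations, removing zero and negative values. Default 0.01.
#' @param trend_radius Radius, in acquisition-index units, of the neighbour
#'   window used for the signal-drift trend. Default 20; use 30 for
#'   dose-response batches.
#' @param sidedness `"two_sided"` (default) converts z-scores to
#'   `2 * SF(|z|)`; `"one_sided_upper"` uses `SF(z)`.
#' @param plate_reference Reference for fold changes and z-scores:
#'   `"plate_median"` (default; median over all sample wells of the 96-well
#'   plate) or `"dmso_median"` (median over the plate's DMSO controls only).
#' @param screen_median_scope Which samples define the screen-wide median a
#'   metabolite is rescaled to after drift correction: `"experimental"`
#'   (default; compound-treated wells only) or `"samples"` (experimental plus
#'   control wells).
#' @param rng_seed Integer seed for any randomised step. Default 1.
#'
#' @return An object of class `screen_config` (a named list).
#' @examples
#' cfg <- screen_config()
#' cfg$lfc_threshold
#' @export
screen_config <- function(alpha = 0.05,
                          lfc_threshold = 0.32,
                          concordance_threshold = 0.25,
                          growth_artifact_threshold = 1.5,
                          od_multiplier = 5,
                          conc_clip_uM = 0.01,
                          trend_radius = 20,
                          sidedness = c("two_sided", "one_sided_upper"),
                          plate_reference = c("plate_median", "dmso_median"),
                          screen_median_scope = c("experimental", "samples"),
                          rng_seed = 1L) {
  sidedness <- match.arg(sidedness)
  plate_reference <- match.arg(plate_reference)
  screen_median_scope <- match.arg(screen_median_scope)

  num_pos <- c(
    lfc_threshold = lfc_threshold,
    concordance_threshold = concordance_threshold,
    growth_artifact_threshold = growth_artifact_threshold,
    od_multiplier = od_multiplier,
    conc_clip_uM = conc_clip_uM,
    trend_radius = trend_radius
  )
  bad <- names(num_pos)[!is.finite(num_pos) | num_pos <= 0]
  if (length(bad) > 0) {
    abort(paste0("screen_config: thresholds must be finite and > 0: ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    abort("screen_config: `alpha` must lie strictly between 0 and 1")
  }

  structure(
    list(
      alpha = alpha,
      lfc_threshold = lfc_threshold,
      concordance_threshold = concordance_threshold,
      growth_artifact_threshold = growth_artifact_threshold,
      od_multiplier = od_multiplier,
      conc_clip_uM = conc_clip_uM,
      trend_radius = trend_radius,
      sidedness = sidedness,
      plate_reference = plate_reference,
      screen_median_scope = screen_median_scope,
      rng_seed = as.integer(rng_seed)
    ),
    class = "screen_config"
  )
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

# Roles recognised in sample tables. "Sample" wells (experimental and the two
# control types) carry biological material; standards, blanks and QC injections
# are instrument-run furniture excluded from trend fitting.
.roles <- c("experimental", "dmso_control", "tetracycline_control",
            "blank", "qc", "standard")
.sample_roles <- c("experimental", "dmso_control", "tetracycline_control")
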