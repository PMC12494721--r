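#' Boxplot outlier mask
#'
#' Flags values outside the standard boxplot fences: below
#' `Q1 - 1.5 * IQR` or above `Q3 + 1.5 * IQR`, with quartiles computed by
#' linear interpolation. Used to keep genuinely perturbed wells from
#' dragging the signal-drift trend line.
#'
#' @param values Numeric vector.
#' @return Logical vector, `TRUE` where a value is an outlier. Missing
#'   values are never flagged. With fewer than 4 finite values no masking is
#'   done (warning).
#' @export
boxplot_outlier_mask <- function(values) {
  out <- rep(FALSE, length(values))
  fin <- is.finite(values)
  if (sum(fin) < 4) {
    warn("boxplot_outlier_mask: fewer than 4 finite values; no outliers flagged")
    return(out)
  }
  q <- quantile(values[fin], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  out[fin] <- values[fin] < q[1] - 1.5 * iqr | values[fin] > q[2] + 1.5 * iqr
  out
}

#' Radius-neighbour drift trend over acquisition order
#'
#' For each acquisition position, the trend is the unweighted mean of the
#' included values whose acquisition index lies within `radius` (in index
#' units) of it — a radius-neighbour local regression with uniform weights.
#' Positions whose neighbourhood contains no included value inherit the
#' trend at the nearest included position, ties resolving to the earlier
#' acquisition position (logged via a message).
#'
#' @param acq_index Integer acquisition indices (need not be sorted or
#'   contiguous).
#' @param values Measured values, same length.
#' @param radius Neighbourhood radius in index units; must be > 0.
#' @param include_mask Logical; which observations participate in the fit
#'   (sample wells that are neither outliers nor standards/blanks/QC).
#' @return Numeric trend vector aligned with the input rows.
#' @export
fit_drift_trend <- function(acq_index, values, radius,
                            include_mask = rep(TRUE, length(values))) {
  n <- length(values)
  stopifnot(length(acq_index) == n, length(include_mask) == n)
  if (!is.finite(radius) || radius <= 0) {
    abort("fit_drift_trend: `radius` must be finite and > 0")
  }
  inc <- include_mask & is.finite(values) & is.finite(acq_index)
  if (!any(inc)) abort("fit_drift_trend: no included values to fit a trend")

  ord <- order(acq_index[inc])
  x <- as.numeric(acq_index[inc])[ord]
  v <- values[inc][ord]
  cs0 <- c(0, cumsum(v))
  # window [acq - radius, acq + radius] on the sorted included positions
  lo <- findInterval(acq_index - radius, x, left.open = TRUE) + 1L
  hi <- findInterval(acq_index + radius, x)
  trend <- rep(NA_real_, n)
  has <- hi >= lo
  trend[has] <- (cs0[hi[has] + 1L] - cs0[lo[has]]) / (hi[has] - lo[has] + 1L)

  if (any(!has)) {
    inform(sprintf(
      "fit_drift_trend: %d position(s) had no neighbours within radius %s; using nearest defined trend",
      sum(!has), format(radius)))
    for (i in which(!has)) {
      j <- which.min(abs(x - acq_index[i]))
      lo_i <- findInterval(x[j] - radius, x, left.open = TRUE) + 1L
      hi_i <- findInterval(x[j] + radius, x)
      trend[i] <- (cs0[hi_i + 1L] - cs0[lo_i]) / (hi_i - lo_i + 1L)
    }
  }
  trend
}

#' Ratio correction against the drift trend
#'
#' Divides each observation by its trend value (the local deviation) and
#' rescales by the screen-wide median concentration of that metabolite, then
#' clips at `clip` to remove zero and negative values.
#'
#' @param values Raw concentrations.
#' @param trend Trend values from [fit_drift_trend()]; must be positive
#'   wherever a finite value is corrected.
#' @param screen_median Median concentration of this metabolite x species
#'   across the entire screen's experimental samples; must be > 0.
#' @param clip Lower clip in µM. Default 0.01.
#' @return Corrected concentrations, `>= clip` wherever input was finite.
#' @export
correct_concentrations <- function(values, trend, screen_median, clip = 0.01) {
  stopifnot(length(values) == length(trend))
  if (!is.finite(screen_median) || screen_median <= 0) {
    abort("correct_concentrations: `screen_median` must be finite and > 0")
  }
  fin <- is.finite(values)
  bad <- fin & (!is.finite(trend) | trend <= 0)
  if (any(bad)) {
    abort(paste0("correct_concentrations: non-positive trend at position(s) ",
                 paste(head(which(bad), 5), collapse = ", ")))
  }
  out <- rep(NA_real_, length(values))
  out[fin] <- pmax(values[fin] / trend[fin] * screen_median, clip)
  out
}

#' Within-batch signal-drift correction of a measurement table
#'
#' Runs the full correction per batch x species x metabolite: boxplot
#' outlier fences on the sample wells, radius-neighbour trend over
#' acquisition order (standards, blanks and QC injections never participate
#' in the fit), ratio correction, rescaling to the screen-wide per-metabolite
#' median, and clipping. Row order is irrelevant and preserved.
#'
#' @param measurements Metabolite measurement tibble
#'   (`read_measurements(schema = "metabolite")` or
#'   `generate_screen()$measurements`).
#' @param config A [screen_config()]; uses `trend_radius`, `conc_clip_uM`
#'   and `screen_median_scope`.
#' @return The input tibble with `trend_value` and `corrected_conc_uM`
#'   columns added.
#' @export
normalise_screen <- function(measurements, config = screen_config()) {
  scope_roles <- switch(config$screen_median_scope,
                        experimental = "experimental",
                        samples = .sample_roles)
  med_tbl <- measurements |>
    filter(.data$role %in% scope_roles, is.finite(.data$raw_conc_uM)) |>
    group_by(.data$species, .data$metabolite) |>
    summarise(screen_median = median(.data$raw_conc_uM), .groups = "drop")
  if (any(med_tbl$screen_median <= 0)) {
    abort("normalise_screen: non-positive screen-wide median concentration")
  }

  measurements |>
    mutate(.row = dplyr::row_number()) |>
    left_join(med_tbl, by = c("species", "metabolite")) |>
    group_by(.data$batch_id, .data$species, .data$metabolite) |>
    group_modify(function(df, key) {
      sample_well <- df$role %in% .sample_roles
      keep <- sample_well & !boxplot_outlier_mask(
        ifelse(sample_well, df$raw_conc_uM, NA_real_))
      df$trend_value <- fit_drift_trend(df$acquisition_index, df$raw_conc_uM,
                                        config$trend_radius, keep)
      df$corrected_conc_uM <- correct_concentrations(
        df$raw_conc_uM, df$trend_value, df$screen_median[1],
        config$conc_clip_uM)
      df
    }) |>
    ungroup() |>
    arrange(.data$.row) |>
    select(-"screen_median", -".row")
}
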