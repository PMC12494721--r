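#' Run the full screen analysis pipeline
#'
#' Ties the stages together: growth processing (OD conversion, plate fold
#' changes, artifact filter), drift normalisation of metabolite
#' concentrations, per-replicate plate statistics, dual-replicate hit calls
#' with growth concordance, and QC metrics.
#'
#' @param measurements Long metabolite measurement table.
#' @param growth Raw growth table, or `NULL` to skip growth-dependent
#'   outputs.
#' @param config A [screen_config()].
#' @return A list: `corrected`, `growth` (processed), `growth_summary`,
#'   `rep_stats`, `hits`, `qc`.
#' @export
run_screen_pipeline <- function(measurements, growth = NULL,
                                config = screen_config()) {
  corrected <- normalise_screen(measurements, config)
  growth_processed <- NULL
  growth_summary <- NULL
  if (!is.null(growth)) {
    growth_processed <- process_growth(growth, config)
    growth_summary <- summarise_growth(growth_processed)
  }
  rep_stats <- replicate_statistics(corrected, config)
  hits <- call_hits(rep_stats, growth_summary, config)
  list(
    corrected = corrected,
    growth = growth_processed,
    growth_summary = growth_summary,
    rep_stats = rep_stats,
    hits = hits,
    qc = qc_metrics(corrected)
  )
}

#' Simulate a dose-response screen
#'
#' Generates the dose-response follow-up design: a small compound panel
#' measured at an increasing concentration series (default six 2x steps,
#' 0.625-20 µM), two biological replicates per dose, each dose acquired as
#' its own batch. Growth responds monotonically (standard log-logistic
#' inhibition), while the metabolite response is either `"monotone"`
#' (magnitude increasing with dose) or `"interior"` (maximal response at an
#' intermediate dose — the atypical behaviour of mildly stressed cells).
#'
#' @param n_compounds Panel size. Default 13.
#' @param doses Increasing concentration series in µM.
#' @param species Single species name.
#' @param metabolites Metabolites measured for the species.
#' @param profile Either a single profile (`"interior"` or `"monotone"`)
#'   applied to all responders, or a vector of per-compound profiles
#'   (`"none"` for inert compounds).
#' @param peak_log2fc Maximal absolute log2 metabolite effect.
#' @param fraction_responders Share of compounds with a metabolite response
#'   when `profile` is scalar.
#' @param noise_cv,drift_amplitude,plate_effect_sd,rng_seed Passed to the
#'   underlying scenario.
#' @return A list: `measurements`, `growth`, `library`, `truth` (as in
#'   [generate_screen()], with `dose_uM` distinguishing the sub-screens) and
#'   `profiles` (per-compound truth).
#' @export
simulate_dose_response <- function(n_compounds = 13,
                                   doses = c(0.625, 1.25, 2.5, 5, 10, 20),
                                   species = "E. coli",
                                   metabolites = c("cadaverine", "putrescine"),
                                   profile = "interior",
                                   peak_log2fc = 1.0,
                                   fraction_responders = 0.4,
                                   noise_cv = 0.094,
                                   drift_amplitude = 0.2,
                                   plate_effect_sd = 0.1,
                                   rng_seed = 1L) {
  stopifnot(!is.unsorted(doses, strictly = TRUE))
  withr::with_seed(as.integer(rng_seed), {
    if (length(profile) == 1) {
      profiles <- ifelse(runif(n_compounds) < fraction_responders, profile,
                         "none")
    } else {
      stopifnot(length(profile) == n_compounds)
      profiles <- profile
    }
    seeds <- sample.int(.Machine$integer.max - 1L, length(doses))
  })
  mm <- setNames(list(metabolites), species)
  peak_dose <- doses[ceiling(length(doses) / 2)]
  ic50 <- max(doses) / 2

  profile_tbl <- tibble(
    compound_id = sprintf("cmpd_%04d", seq_len(n_compounds)),
    profile = profiles
  )

  out <- vector("list", length(doses))
  for (i in seq_along(doses)) {
    d <- doses[i]
    # interior profile: Gaussian bump (in log-dose) centred on an interior
    # dose; monotone: saturating increase with dose
    lfc <- ifelse(
      profiles == "none", 0,
      ifelse(profiles == "interior",
             peak_log2fc * exp(-((log2(d) - log2(peak_dose))^2) / 2),
             peak_log2fc * d / max(doses)))
    growth_fc <- 1 / (1 + (d / ic50)^2)
    effects <- bind_rows(lapply(metabolites, function(m) {
      tibble(compound_id = profile_tbl$compound_id, species = species,
             metabolite = m, true_log2_fc = lfc, true_growth_fc = growth_fc)
    }))
    scen <- simulation_scenario(
      n_compounds = n_compounds, species = species, metabolite_map = mm,
      library_fractions = c(drug = 1), noise_cv = noise_cv,
      drift_amplitude = drift_amplitude, plate_effect_sd = plate_effect_sd,
      artifact_rate = 0, dose_uM = d, rng_seed = seeds[i])
    sim <- generate_screen(scen, effects = effects)
    sim$measurements$dose_uM[sim$measurements$role == "experimental"] <- d
    sim$measurements$batch_id <- paste0(sim$measurements$batch_id,
                                        "_d", format(d))
    sim$growth$batch_id <- paste0(sim$growth$batch_id, "_d", format(d))
    sim$growth$dose_uM <- ifelse(sim$growth$role == "experimental", d, 0)
    sim$truth$effects$dose_uM <- d
    out[[i]] <- sim
  }
  list(
    measurements = bind_rows(lapply(out, `[[`, "measurements")),
    growth = bind_rows(lapply(out, `[[`, "growth")),
    library = out[[1]]$library,
    truth = list(effects = bind_rows(lapply(out, function(x) x$truth$effects)),
                 noise_cv = noise_cv),
    profiles = profile_tbl
  )
}

#' Score a dose-response screen
#'
#' Runs drift normalisation (radius 30, the dose-response setting, unless
#' overridden) and per-replicate statistics separately per dose, then
#' assembles the per compound x species x metabolite x dose table consumed
#' by [dose_response_fractions()].
#'
#' @param measurements Dose-response measurement table with a `dose_uM`
#'   column on experimental wells.
#' @param config A [screen_config()]; default uses `trend_radius = 30`.
#' @return Tibble with `compound_id`, `species`, `metabolite`, `dose_uM`,
#'   `mean_fc`, `mean_log2_fc`, `p_adj_1`, `p_adj_2`.
#' @export
score_dose_response <- function(measurements,
                                config = screen_config(trend_radius = 30)) {
  corrected <- normalise_screen(measurements, config)
  doses <- sort(unique(corrected$dose_uM[corrected$role == "experimental"]))
  bind_rows(lapply(doses, function(d) {
    # each dose is its own sub-screen: restrict to its batches (controls
    # carry dose 0, so membership goes via the batch)
    batches <- unique(corrected$batch_id[corrected$role == "experimental" &
                                           corrected$dose_uM == d])
    rep_stats <- replicate_statistics(
      filter(corrected, .data$batch_id %in% batches), config)
    call_hits(rep_stats, NULL, config) |> mutate(dose_uM = d)
  })) |>
    select("compound_id", "species", "metabolite", "dose_uM", "mean_fc",
           "mean_log2_fc", "p_adj_1", "p_adj_2")
}
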