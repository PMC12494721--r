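#' Simulation scenario for a synthetic plate screen
#'
#' Describes the world the generator emits: library composition, species and
#' their measured amines, plate layout constraints, spike-in effect sizes,
#' measurement noise, signal drift and OD-artifact rate. Defaults mirror the
#' screen the pipeline was built for: 1772 compounds (1518 drugs, 166
#' pesticides, 47 industrial chemicals, 41 sweeteners), four amine-producing
#' gut bacteria with two biological replicates, 10-13 DMSO controls and one
#' tetracycline control per 96-well plate, lognormal noise at 9.4% CV,
#' baseline amine concentrations between 35 and 1100 µM, and a 7.7% rate of
#' aggregation artifacts in the growth readout.
#'
#' @param n_compounds Number of library compounds.
#' @param library_fractions Named counts (or weights) per library class;
#'   scaled to `n_compounds`.
#' @param species Character vector of species names.
#' @param metabolite_map Named list: species -> measured metabolites.
#' @param replicates Biological replicates per compound (screens use 2).
#' @param fraction_hits Probability that a compound truly perturbs one
#'   metabolite of a given species.
#' @param effect_log2fc Absolute true log2 fold change of a spiked effect.
#' @param prob_up Probability a spiked effect is an increase.
#' @param growth_coupling Probability a spiked metabolite effect is coupled
#'   to growth (growth fold change tracks the metabolite fold change).
#' @param growth_fc_cap Upper cap on true growth fold changes of coupled
#'   effects. Kept just below the 1.5 artifact threshold: real growth gains
#'   beyond ~1.4 are indistinguishable from aggregation artifacts and would
#'   be deleted by the pipeline's own filter.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise (applies to concentrations and OD).
#' @param drift_amplitude Relative amplitude of the smooth multiplicative
#'   within-batch signal drift, in `[0, 1)`.
#' @param plate_effect_sd Lognormal sigma of multiplicative plate effects.
#' @param artifact_rate Probability a compound x species growth measurement
#'   is an OD aggregation artifact (applied to both replicates; artifacts
#'   were observed to be largely replicate-consistent).
#' @param baseline_range_uM Range the per species x metabolite baseline
#'   concentration is drawn from (log-uniform), in µM.
#' @param dmso_per_plate Integer range of DMSO controls per plate.
#' @param plates_per_batch Plates per acquisition batch; `Inf` (default)
#'   puts each species x replicate into a single batch.
#' @param n_plates Optional fixed number of plates per species x replicate;
#'   an error is raised if the library does not fit.
#' @param dose_uM Screening concentration (µM); `sweetener_dose_uM` is used
#'   for sweeteners (consumed in larger quantities).
#' @param sweetener_dose_uM Screening concentration for sweeteners (µM).
#' @param blank_absorbance Blank 595 nm absorbance of medium-filled wells.
#' @param control_od Expected stationary-phase OD of solvent-control wells.
#' @param rng_seed Integer seed; the whole screen is a deterministic
#'   function of the scenario.
#'
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_compounds = 1772,
                                library_fractions = c(drug = 1518,
                                                      pesticide = 166,
                                                      industrial = 47,
                                                      sweetener = 41),
                                species = c("E. coli", "K. aerogenes",
                                            "C. sporogenes", "R. gnavus"),
                                metabolite_map = list(
                                  "E. coli" = c("cadaverine", "putrescine"),
                                  "K. aerogenes" = c("histamine", "cadaverine",
                                                     "putrescine"),
                                  "C. sporogenes" = "tryptamine",
                                  "R. gnavus" = c("tryptamine",
                                                  "2-phenylethylamine")),
                                replicates = 2L,
                                fraction_hits = 0.05,
                                effect_log2fc = 1.0,
                                prob_up = 0.5,
                                growth_coupling = 0.66,
                                growth_fc_cap = 1.4,
                                noise_cv = 0.094,
                                drift_amplitude = 0.2,
                                plate_effect_sd = 0.1,
                                artifact_rate = 0.077,
                                baseline_range_uM = c(35, 1100),
                                dmso_per_plate = c(10L, 13L),
                                plates_per_batch = Inf,
                                n_plates = NULL,
                                dose_uM = 20,
                                sweetener_dose_uM = 50,
                                blank_absorbance = 0.05,
                                control_od = 1.0,
                                rng_seed = 1L) {
  rates <- c(fraction_hits = fraction_hits, prob_up = prob_up,
             growth_coupling = growth_coupling, artifact_rate = artifact_rate)
  bad <- names(rates)[!is.finite(rates) | rates < 0 | rates > 1]
  if (length(bad) > 0) {
    abort(paste0("simulation_scenario: rates must lie in [0, 1]: ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.finite(noise_cv) || noise_cv < 0) {
    abort("simulation_scenario: `noise_cv` must be >= 0")
  }
  if (!is.finite(drift_amplitude) || drift_amplitude < 0 || drift_amplitude >= 1) {
    abort("simulation_scenario: `drift_amplitude` must lie in [0, 1)")
  }
  if (any(baseline_range_uM <= 0)) {
    abort("simulation_scenario: baselines must be positive")
  }
  if (!all(species %in% names(metabolite_map))) {
    abort("simulation_scenario: every species needs an entry in `metabolite_map`")
  }
  structure(
    list(n_compounds = as.integer(n_compounds),
         library_fractions = library_fractions, species = species,
         metabolite_map = metabolite_map, replicates = as.integer(replicates),
         fraction_hits = fraction_hits, effect_log2fc = effect_log2fc,
         prob_up = prob_up, growth_coupling = growth_coupling,
         growth_fc_cap = growth_fc_cap, noise_cv = noise_cv,
         drift_amplitude = drift_amplitude, plate_effect_sd = plate_effect_sd,
         artifact_rate = artifact_rate, baseline_range_uM = baseline_range_uM,
         dmso_per_plate = as.integer(dmso_per_plate),
         plates_per_batch = plates_per_batch, n_plates = n_plates,
         dose_uM = dose_uM, sweetener_dose_uM = sweetener_dose_uM,
         blank_absorbance = blank_absorbance, control_od = control_od,
         rng_seed = as.integer(rng_seed)),
    class = "simulation_scenario"
  )
}

#' Smooth multiplicative signal-drift curve
#'
#' Emulates slow LC-MS sensitivity drift over a batch's acquisition order as
#' a low-frequency random curve: a sum of three low-order cosine harmonics
#' with random coefficients, centred and rescaled so every value lies within
#' `[1 - amplitude, 1 + amplitude]` and the mean is exactly 1.
#'
#' @param batch_size Number of acquisition positions.
#' @param amplitude Relative amplitude in `[0, 1)`; 0 gives a constant 1.
#' @param seed Optional integer seed; the curve is deterministic given it.
#' @return A strictly positive numeric vector of length `batch_size`.
#' @export
drift_profile <- function(batch_size, amplitude = 0.2, seed = NULL) {
  if (!is.finite(amplitude) || amplitude < 0 || amplitude >= 1) {
    abort("drift_profile: `amplitude` must lie in [0, 1)")
  }
  batch_size <- as.integer(batch_size)
  if (batch_size < 1) abort("drift_profile: `batch_size` must be >= 1")
  if (amplitude == 0 || batch_size == 1) return(rep(1, batch_size))
  make_curve <- function() {
    a <- runif(3, -1, 1)
    ph <- runif(3, 0, 2 * pi)
    t <- seq(0, 1, length.out = batch_size)
    s <- a[1] * cos(pi * t + ph[1]) +
      a[2] * cos(2 * pi * t + ph[2]) +
      a[3] * cos(3 * pi * t + ph[3])
    s <- s - mean(s)
    m <- max(abs(s))
    if (m == 0) return(rep(1, batch_size))
    1 + amplitude * s / m
  }
  if (is.null(seed)) make_curve() else withr::with_seed(as.integer(seed), make_curve())
}

# lognormal multiplicative noise with unit mean and the requested CV
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

.well_names <- function() paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))

.species_code <- function(x) {
  toupper(gsub("[^A-Za-z]", "", abbreviate(gsub("\\.", "", x), 2)))
}

# Fixed library plate layout shared by all species and replicates: which
# compound sits in which well of which plate, plus control positions.
.make_layout <- function(scenario) {
  n <- scenario$n_compounds
  rng <- scenario$dmso_per_plate
  draw_dmso <- function() sample(seq(rng[1], rng[2]), 1)
  plates <- list()
  remaining <- n
  first <- 1L
  k <- 0L
  n_plates <- scenario$n_plates
  while (remaining > 0) {
    k <- k + 1L
    if (!is.null(n_plates) && k > n_plates) {
      abort(sprintf(
        "generate_screen: %d compounds do not fit on %d plates (sizing error)",
        n, n_plates))
    }
    dmso_n <- draw_dmso()
    cap <- 96L - dmso_n - 1L
    m <- min(cap, remaining)
    wells <- sample(.well_names())
    plates[[k]] <- tibble(
      plate = k,
      well = wells[seq_len(m + dmso_n + 1L)],
      role = c(rep("experimental", m), rep("dmso_control", dmso_n),
               "tetracycline_control"),
      compound_idx = c(seq(first, first + m - 1L), rep(NA_integer_, dmso_n + 1L))
    )
    first <- first + m
    remaining <- remaining - m
  }
  if (!is.null(n_plates) && length(plates) < n_plates) {
    # trailing all-control plates to honour a fixed plate count
    for (k2 in seq(length(plates) + 1L, n_plates)) {
      dmso_n <- draw_dmso()
      wells <- sample(.well_names())
      plates[[k2]] <- tibble(
        plate = k2, well = wells[seq_len(dmso_n + 1L)],
        role = c(rep("dmso_control", dmso_n), "tetracycline_control"),
        compound_idx = rep(NA_integer_, dmso_n + 1L))
    }
  }
  bind_rows(plates)
}

# Draw per compound x species ground-truth effects.
.draw_effects <- function(scenario, library) {
  grid <- expand.grid(compound_id = library$compound_id,
                      species = scenario$species,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  is_hit <- runif(n) < scenario$fraction_hits
  sign_up <- ifelse(runif(n) < scenario$prob_up, 1, -1)
  coupled <- runif(n) < scenario$growth_coupling
  artifact <- runif(n) < scenario$artifact_rate
  per_cs <- as_tibble(grid) |>
    mutate(
      hit_log2fc = ifelse(is_hit, scenario$effect_log2fc * sign_up, 0),
      true_growth_fc = ifelse(is_hit & coupled,
                              pmin(2^.data$hit_log2fc, scenario$growth_fc_cap),
                              1),
      true_artifact = artifact
    )
  # a hit perturbs one randomly chosen metabolite of that species
  per_cs$target_metabolite <- vapply(per_cs$species, function(sp) {
    mets <- scenario$metabolite_map[[sp]]
    mets[sample.int(length(mets), 1)]
  }, character(1), USE.NAMES = FALSE)
  met_tbl <- bind_rows(lapply(scenario$species, function(sp) {
    tibble(species = sp, metabolite = scenario$metabolite_map[[sp]])
  }))
  per_cs |>
    inner_join(met_tbl, by = "species", relationship = "many-to-many") |>
    mutate(true_log2_fc = ifelse(.data$metabolite == .data$target_metabolite,
                                 .data$hit_log2fc, 0),
           true_hit = .data$true_log2_fc != 0,
           true_concordant = ifelse(
             .data$true_hit,
             abs(.data$true_growth_fc - 2^.data$true_log2_fc) < 0.25,
             NA)) |>
    select("compound_id", "species", "metabolite", "true_log2_fc", "true_hit",
           "true_growth_fc", "true_artifact", "true_concordant")
}

#' Generate a synthetic multi-batch plate screen with known ground truth
#'
#' Emits everything the downstream pipeline consumes: a long metabolite
#' measurement table (with blanks, QC injections and a 6-level external
#' standard series interleaved in acquisition order), a growth table of raw
#' 595 nm absorbances, a compound library with therapeutic-class
#' annotations, and the ground truth (true effects, drift curves, plate
#' effects, baselines) used to spike the data.
#'
#' The observation model is multiplicative: observed concentration =
#' baseline x 2^true_log2_fc x plate effect x drift(acquisition index) x
#' lognormal noise with the scenario's CV. Observed growth fold change is
#' the true growth fold change times noise; artifact wells are replaced by
#' implausibly high values (> 1.5) without touching metabolite values,
#' emulating cell aggregation that confounds OD readings.
#'
#' @param scenario A [simulation_scenario()].
#' @param effects Optional explicit ground-truth effect table overriding the
#'   random spike-ins: columns `compound_id`, `species`, `metabolite`,
#'   `true_log2_fc`, `true_growth_fc` and optionally `true_artifact`.
#' @return A list with tibbles `measurements`, `growth`, `library`, and
#'   `truth` (a list: `effects`, `baselines`, `plate_effects`, `drift`,
#'   `noise_cv`).
#' @export
generate_screen <- function(scenario, effects = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  withr::with_seed(scenario$rng_seed, .generate_screen_impl(scenario, effects))
}

.generate_screen_impl <- function(scenario, effects = NULL) {
  library_tbl <- .make_library(scenario)
  layout <- .make_layout(scenario)
  layout$compound_id <- library_tbl$compound_id[layout$compound_idx]

  if (is.null(effects)) {
    effects <- .draw_effects(scenario, library_tbl)
  } else {
    effects <- as_tibble(effects)
    if (!"true_artifact" %in% names(effects)) effects$true_artifact <- FALSE
    if (!"true_hit" %in% names(effects)) effects$true_hit <- effects$true_log2_fc != 0
    if (!"true_concordant" %in% names(effects)) {
      effects$true_concordant <- ifelse(
        effects$true_hit,
        abs(effects$true_growth_fc - 2^effects$true_log2_fc) < 0.25, NA)
    }
  }

  baselines <- bind_rows(lapply(scenario$species, function(sp) {
    tibble(species = sp, metabolite = scenario$metabolite_map[[sp]])
  }))
  lo <- log(scenario$baseline_range_uM[1]); hi <- log(scenario$baseline_range_uM[2])
  baselines$baseline_uM <- exp(runif(nrow(baselines), lo, hi))

  n_plates <- max(layout$plate)
  reps <- seq_len(scenario$replicates)
  grids <- expand.grid(species = scenario$species, replicate = reps,
                       plate = seq_len(n_plates),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plate_effects <- as_tibble(grids) |>
    arrange(.data$species, .data$replicate, .data$plate) |>
    mutate(
      plate_id = sprintf("%s_r%d_p%02d", .species_code(.data$species),
                         .data$replicate, .data$plate),
      plate_effect = if (scenario$plate_effect_sd == 0) 1 else
        rlnorm(dplyr::n(), 0, scenario$plate_effect_sd),
      od_plate_effect = if (scenario$plate_effect_sd == 0) 1 else
        rlnorm(dplyr::n(), 0, scenario$plate_effect_sd)
    )

  ppb <- scenario$plates_per_batch
  plate_effects$batch_id <- sprintf(
    "%s_r%d_b%02d", .species_code(plate_effects$species),
    plate_effects$replicate,
    if (is.finite(ppb)) ((plate_effects$plate - 1L) %/% ppb) + 1L else 1L)

  measurements <- list(); growth <- list(); drift_out <- list()
  for (sp in scenario$species) {
    for (r in reps) {
      pe <- filter(plate_effects, .data$species == sp, .data$replicate == r)
      sr <- .simulate_species_replicate(scenario, sp, r, layout, library_tbl,
                                        effects, baselines, pe)
      measurements[[length(measurements) + 1L]] <- sr$measurements
      growth[[length(growth) + 1L]] <- sr$growth
      drift_out[[length(drift_out) + 1L]] <- sr$drift
    }
  }

  list(
    measurements = bind_rows(measurements),
    growth = bind_rows(growth),
    library = library_tbl,
    truth = list(
      effects = effects,
      baselines = baselines,
      plate_effects = select(plate_effects, "species", "replicate", "plate_id",
                             "batch_id", "plate_effect", "od_plate_effect"),
      drift = bind_rows(drift_out),
      noise_cv = scenario$noise_cv
    )
  )
}

.therapeutic_pool <- c("antibacterial", "antifungal", "antiprotozoal",
                       "antineoplastic", "antihypertensive", "antidepressant",
                       "antihistamine", "analgesic", "antiviral",
                       "anti-inflammatory")
.antibiotic_pool <- c("beta-lactam", "fluoroquinolone", "tetracycline",
                      "macrolide", "aminoglycoside", "sulfonamide")

.make_library <- function(scenario) {
  fr <- scenario$library_fractions
  n <- scenario$n_compounds
  counts <- floor(fr / sum(fr) * n)
  short <- n - sum(counts)
  if (short > 0) {
    top <- order(fr / sum(fr) * n - counts, decreasing = TRUE)
    counts[top[seq_len(short)]] <- counts[top[seq_len(short)]] + 1L
  }
  classes <- rep(names(counts), counts)
  lib <- tibble(
    compound_id = sprintf("cmpd_%04d", seq_len(n)),
    name = sprintf("compound %04d", seq_len(n)),
    library_class = classes
  )
  n_labels <- ifelse(lib$library_class == "drug", rbinom(n, 2, 0.35), 0L)
  lib$therapeutic_classes <- lapply(seq_len(n), function(i) {
    if (n_labels[i] == 0) character(0) else
      sample(.therapeutic_pool, n_labels[i])
  })
  is_abx <- vapply(lib$therapeutic_classes,
                   function(x) "antibacterial" %in% x, logical(1))
  lib$antibiotic_class <- ifelse(
    is_abx & runif(n) < 0.6,
    sample(.antibiotic_pool, n, replace = TRUE), NA_character_)
  lib
}

# One species x replicate acquisition batch (or several, if plates_per_batch
# is finite): plates measured in order, blocks of 12 sample injections
# interleaved with a blank and a QC injection, a 6-level standard dilution
# series plus blank at the start of each batch.
.simulate_species_replicate <- function(scenario, sp, r, layout, library_tbl,
                                        effects, baselines, pe) {
  mets <- scenario$metabolite_map[[sp]]
  base_sp <- filter(baselines, .data$species == sp)

  samples <- layout |>
    inner_join(select(pe, "plate", "plate_id", "batch_id", "plate_effect",
                      "od_plate_effect"), by = "plate") |>
    arrange(.data$plate)

  inj <- vector("list", length(unique(samples$batch_id)))
  bi <- 0L
  for (b in unique(samples$batch_id)) {
    sb <- filter(samples, .data$batch_id == b)
    n_s <- nrow(sb)
    head_block <- tibble(
      batch_id = b, plate_id = NA_character_, well = NA_character_,
      role = c(rep("standard", 6L), "blank", "qc"),
      standard_level = c(1:6, NA_integer_, NA_integer_),
      compound_id = NA_character_, plate_effect = 1, od_plate_effect = 1)
    sb_rows <- tibble(
      batch_id = b, plate_id = sb$plate_id, well = sb$well, role = sb$role,
      standard_level = NA_integer_, compound_id = sb$compound_id,
      plate_effect = sb$plate_effect, od_plate_effect = sb$od_plate_effect)
    blocks <- split(seq_len(n_s), (seq_len(n_s) - 1L) %/% 12L)
    body <- bind_rows(lapply(blocks, function(ix) {
      bind_rows(sb_rows[ix, ],
                tibble(batch_id = b, plate_id = NA_character_,
                       well = NA_character_, role = c("blank", "qc"),
                       standard_level = NA_integer_,
                       compound_id = NA_character_,
                       plate_effect = 1, od_plate_effect = 1))
    }))
    out <- bind_rows(head_block, body)
    out$acquisition_index <- seq_len(nrow(out))
    bi <- bi + 1L
    inj[[bi]] <- out
  }
  inj <- bind_rows(inj)

  # drift per batch over its acquisition axis
  drift_tbl <- inj |>
    group_by(.data$batch_id) |>
    summarise(n = max(.data$acquisition_index), .groups = "drop")
  drift_tbl <- bind_rows(lapply(seq_len(nrow(drift_tbl)), function(i) {
    tibble(batch_id = drift_tbl$batch_id[i],
           acquisition_index = seq_len(drift_tbl$n[i]),
           drift = drift_profile(drift_tbl$n[i], scenario$drift_amplitude))
  }))
  inj <- left_join(inj, drift_tbl, by = c("batch_id", "acquisition_index"))

  eff_sp <- filter(effects, .data$species == sp)

  met_rows <- bind_rows(lapply(mets, function(m) mutate(inj, metabolite = m)))
  met_rows <- met_rows |>
    left_join(select(base_sp, "metabolite", "baseline_uM"), by = "metabolite") |>
    left_join(select(eff_sp, "compound_id", "metabolite", "true_log2_fc"),
              by = c("compound_id", "metabolite"))

  top_std <- 2 * max(base_sp$baseline_uM)
  effect_factor <- dplyr::case_when(
    met_rows$role == "experimental" ~ 2^dplyr::coalesce(met_rows$true_log2_fc, 0),
    met_rows$role == "tetracycline_control" ~ 0.25,
    TRUE ~ 1
  )
  expected <- dplyr::case_when(
    met_rows$role %in% .sample_roles ~
      met_rows$baseline_uM * effect_factor * met_rows$plate_effect,
    met_rows$role == "qc" ~ met_rows$baseline_uM,
    met_rows$role == "standard" ~ top_std / 3^(met_rows$standard_level - 1),
    met_rows$role == "blank" ~ 0.02
  )
  met_rows$raw_conc_uM <- expected * met_rows$drift *
    .ln_noise(nrow(met_rows), scenario$noise_cv)

  dose <- dplyr::case_when(
    met_rows$role == "experimental" ~ ifelse(
      library_tbl$library_class[match(met_rows$compound_id,
                                      library_tbl$compound_id)] == "sweetener",
      scenario$sweetener_dose_uM, scenario$dose_uM),
    TRUE ~ 0
  )

  measurements <- tibble(
    batch_id = met_rows$batch_id,
    acquisition_index = met_rows$acquisition_index,
    plate_id = met_rows$plate_id,
    well = met_rows$well,
    role = met_rows$role,
    standard_level = met_rows$standard_level,
    species = sp,
    replicate = r,
    compound_id = met_rows$compound_id,
    dose_uM = dose,
    metabolite = met_rows$metabolite,
    raw_conc_uM = met_rows$raw_conc_uM
  )

  # growth table: sample wells only (plate-reader readout, no acquisition axis)
  gw <- filter(inj, .data$role %in% .sample_roles)
  eff_cs <- eff_sp |> distinct(.data$compound_id, .data$true_growth_fc,
                               .data$true_artifact)
  gw <- left_join(gw, eff_cs, by = "compound_id")
  g_fc <- dplyr::case_when(
    gw$role == "experimental" ~ dplyr::coalesce(gw$true_growth_fc, 1),
    gw$role == "tetracycline_control" ~ 0.05,
    TRUE ~ 1
  )
  od <- scenario$control_od * gw$od_plate_effect * g_fc *
    .ln_noise(nrow(gw), scenario$noise_cv)
  artifact <- gw$role == "experimental" & dplyr::coalesce(gw$true_artifact, FALSE)
  if (any(artifact)) {
    od[artifact] <- scenario$control_od * gw$od_plate_effect[artifact] *
      runif(sum(artifact), 1.7, 3.0)
  }
  growth <- tibble(
    batch_id = gw$batch_id,
    plate_id = gw$plate_id,
    well = gw$well,
    role = gw$role,
    species = sp,
    replicate = r,
    compound_id = gw$compound_id,
    raw_absorbance = od / 5 + scenario$blank_absorbance,
    blank = scenario$blank_absorbance,
    compound_background = 0
  )

  drift_tbl$species <- sp
  drift_tbl$replicate <- r
  list(measurements = measurements, growth = growth, drift = drift_tbl)
}
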