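#' Read a long-format measurement table
#'
#' Reads a CSV/TSV with one row per measured well (growth schema) or per
#' well x metabolite (metabolite schema). The layout is long/tidy because
#' acquisition order within a batch is first-class in the drift correction.
#'
#' Required columns, metabolite schema: `batch_id`, `acquisition_index`,
#' `plate_id`, `well`, `role`, `species`, `replicate`, `compound_id`,
#' `metabolite`, `raw_conc_uM`. Growth schema: `batch_id`, `plate_id`,
#' `well`, `role`, `species`, `replicate`, `compound_id`, `raw_absorbance`,
#' `blank`. Optional everywhere: `dose_uM`, `standard_level`,
#' `compound_background` (growth; defaults to 0 with a notice when absent).
#'
#' @param path Path to a delimited text file (delimiter inferred from the
#'   extension: `.tsv`/`.txt` tab, otherwise comma).
#' @param schema `"metabolite"` or `"growth"`.
#' @param col_map Optional named character vector mapping file headers to the
#'   canonical names above, e.g. `c(Batch = "batch_id")`, for tables exported
#'   with other headers.
#' @param validate Run plate-layout validation (warnings only)? Default TRUE.
#'
#' @return A tibble with typed columns; row count equals the file's.
#' @export
read_measurements <- function(path, schema = c("metabolite", "growth"),
                              col_map = NULL, validate = TRUE) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(paste0("read_measurements: no such file: ", path))
  tbl <- .read_delim_auto(path)
  if (!is.null(col_map)) {
    idx <- match(names(col_map), names(tbl))
    if (anyNA(idx)) {
      abort(paste0("read_measurements: col_map names absent from file: ",
                   paste(names(col_map)[is.na(idx)], collapse = ", ")))
    }
    names(tbl)[idx] <- unname(col_map)
  }

  required <- switch(schema,
    metabolite = c("batch_id", "acquisition_index", "plate_id", "well", "role",
                   "species", "replicate", "compound_id", "metabolite",
                   "raw_conc_uM"),
    growth = c("batch_id", "plate_id", "well", "role", "species", "replicate",
               "compound_id", "raw_absorbance", "blank")
  )
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("read_measurements: missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  tbl <- tbl |>
    mutate(
      across(any_of(c("batch_id", "plate_id", "well", "role", "species",
                      "compound_id", "metabolite")), as.character),
      across(any_of(c("acquisition_index", "replicate", "standard_level")),
             as.integer),
      across(any_of(c("raw_conc_uM", "raw_absorbance", "blank",
                      "compound_background", "dose_uM")), as.numeric)
    )

  bad_role <- setdiff(unique(tbl$role), .roles)
  if (length(bad_role) > 0) {
    abort(paste0("read_measurements: unknown role(s): ",
                 paste(bad_role, collapse = ", ")))
  }

  if (schema == "metabolite") {
    dup <- tbl |>
      distinct(.data$batch_id, .data$acquisition_index, .data$well, .data$plate_id) |>
      count(.data$batch_id, .data$acquisition_index) |>
      filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort(sprintf(
        "read_measurements: duplicate (batch_id, acquisition_index): e.g. (%s, %d)",
        dup$batch_id[1], dup$acquisition_index[1]))
    }
  }
  if (schema == "growth" && !"compound_background" %in% names(tbl)) {
    inform("read_measurements: no `compound_background` column; assuming 0")
    tbl$compound_background <- 0
  }
  if (validate) validate_plate_layout(tbl)
  tbl
}

#' Validate 96-well plate layout constraints
#'
#' Checks, without mutating anything, that experimental wells carry a
#' compound, DMSO controls do not, each plate has between 10 and 13 DMSO
#' controls and exactly one tetracycline control. Violations raise warnings,
#' not errors, since partially filled last plates are legitimate.
#'
#' @param tbl A measurement tibble (either schema).
#' @return `tbl`, invisibly.
#' @export
validate_plate_layout <- function(tbl) {
  wells <- distinct(tbl, .data$plate_id, .data$well, .data$role,
                    .data$compound_id,
                    .data$replicate)
  no_cmpd <- wells$role == "experimental" &
    (is.na(wells$compound_id) | wells$compound_id == "")
  if (any(no_cmpd)) {
    warn(sprintf("%d experimental well(s) lack a compound_id", sum(no_cmpd)))
  }
  dmso_cmpd <- wells$role == "dmso_control" &
    !(is.na(wells$compound_id) | wells$compound_id == "")
  if (any(dmso_cmpd)) {
    warn(sprintf("%d DMSO control well(s) carry a compound_id", sum(dmso_cmpd)))
  }
  counts <- wells |>
    filter(.data$role %in% c("dmso_control", "tetracycline_control")) |>
    count(.data$plate_id, .data$replicate, .data$role) |>
    pivot_wider(names_from = "role", values_from = "n", values_fill = 0L)
  if (!"dmso_control" %in% names(counts)) counts$dmso_control <- 0L
  if (!"tetracycline_control" %in% names(counts)) counts$tetracycline_control <- 0L
  bad_dmso <- counts$dmso_control < 10 | counts$dmso_control > 13
  if (any(bad_dmso)) {
    warn(sprintf("%d plate(s) have a DMSO-control count outside [10, 13]",
                 sum(bad_dmso)))
  }
  bad_tet <- counts$tetracycline_control != 1
  if (any(bad_tet)) {
    warn(sprintf("%d plate(s) do not have exactly one tetracycline control",
                 sum(bad_tet)))
  }
  invisible(tbl)
}

#' Read a compound library metadata table
#'
#' @param path CSV/TSV with columns `compound_id`, `name`, `library_class`
#'   and optionally `therapeutic_classes` (delimiter-separated labels, `;` or
#'   `|`) and `antibiotic_class`.
#' @return A tibble with one row per compound; `therapeutic_classes` is a
#'   list-column of character vectors (empty vector when unannotated).
#' @export
read_compound_library <- function(path) {
  if (!file.exists(path)) abort(paste0("read_compound_library: no such file: ", path))
  tbl <- .read_delim_auto(path)
  required <- c("compound_id", "library_class")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("read_compound_library: missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tbl$compound_id)) {
    abort("read_compound_library: duplicate compound_id")
  }
  if (any(is.na(tbl$library_class) | tbl$library_class == "")) {
    abort("read_compound_library: library_class required for every compound")
  }
  if (!"name" %in% names(tbl)) tbl$name <- tbl$compound_id
  tc <- if ("therapeutic_classes" %in% names(tbl)) tbl$therapeutic_classes else
    rep(NA_character_, nrow(tbl))
  tbl$therapeutic_classes <- lapply(tc, .split_labels)
  if (!"antibiotic_class" %in% names(tbl)) tbl$antibiotic_class <- NA_character_
  as_tibble(tbl)
}

.split_labels <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  unique(trimws(strsplit(x, "[;|]")[[1]]))
}

.read_delim_auto <- function(path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, na = c("", "NA"))
}

#' Write result tables to a directory
#'
#' Writes each named table as `<name>.csv` with a deterministic column order
#' (as given), full float precision (shortest round-trip representation) and
#' missing values as empty fields. List-columns (e.g. `therapeutic_classes`)
#' are serialised as `;`-joined labels. Two runs on identical input produce
#' byte-identical files.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("write_results: cannot create directory: ", out_dir))
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tbl <- tables[[nm]]
    is_list_col <- vapply(tbl, is.list, logical(1))
    for (col in names(tbl)[is_list_col]) {
      tbl[[col]] <- vapply(tbl[[col]], paste, character(1), collapse = ";")
    }
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tbl, path, na = "", progress = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Convert a plate-matrix table to long format
#'
#' Convenience importer for 8 x 12 plate layouts (rows A-H, columns 1-12),
#' as exported by plate readers, into the long one-row-per-well layout the
#' pipeline uses.
#'
#' @param mat A data frame or matrix with 8 rows and 12 columns of values;
#'   row order is taken as A-H, column order as 1-12.
#' @param plate_id Plate identifier to attach.
#' @param value_name Name for the value column. Default `"value"`.
#' @return A 96-row tibble with `plate_id`, `well` and the value column.
#' @export
plate_matrix_to_long <- function(mat, plate_id, value_name = "value") {
  mat <- as.matrix(mat)
  if (!all(dim(mat) == c(8L, 12L))) {
    abort("plate_matrix_to_long: expected an 8 x 12 matrix (rows A-H, columns 1-12)")
  }
  out <- tibble(
    plate_id = plate_id,
    well = paste0(rep(LETTERS[1:8], times = 12), rep(1:12, each = 8)),
    value = as.numeric(mat)
  )
  names(out)[names(out) == "value"] <- value_name
  out
}
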