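#' Path to a bundled example data file
#'
#' The package ships plain-text transcriptions of the study's concentration
#' tables (raw tobacco, ash, bowl water for five commercial tobaccos), the
#' toxicity-reference table, instrument detection limits, sample metadata,
#' and example YAML configs for partition parameters and exposure scenarios.
#'
#' @param file File name; with no argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @examples
#' hookah_example()
#' hookah_example("tobacco_concentrations.csv")
#' @export
hookah_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "hookahrisk"))
  } else {
    path <- system.file("extdata", file, package = "hookahrisk", mustWork = FALSE)
    if (!nzchar(path)) abort(sprintf("No bundled file '%s'", file))
    path
  }
}

#' Build a concentration table from an in-memory data frame
#'
#' Validates and normalizes a long-format data frame with columns
#' `sample_id`, `compartment`, `element`, `value` (character, censoring as
#' `"<LOD"`, missing as `"*****"` or empty; plain numerics also accepted)
#' and `unit`.
#'
#' @param df A data frame.
#' @return A validated, unit-normalized concentration tibble with columns
#'   `sample_id`, `compartment`, `element`, `state`, `value`, `unit`.
#' @export
as_concentration_table <- function(df) {
  required <- c("sample_id", "compartment", "element", "value", "unit")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) abort("Concentration table is empty")

  bad_comp <- setdiff(unique(df$compartment), compartments)
  if (length(bad_comp)) {
    abort(sprintf("Unknown compartment(s): %s (expected raw, ash, water)",
                  paste(bad_comp, collapse = ", ")))
  }
  bad_el <- setdiff(unique(df$element), hookah_elements)
  if (length(bad_el)) {
    abort(sprintf("Unknown element symbol(s): %s (panel is the 29 symbols %s...%s)",
                  paste(bad_el, collapse = ", "),
                  hookah_elements[1], hookah_elements[29]))
  }
  dup <- df |>
    count(.data$sample_id, .data$compartment, .data$element) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf(
      "Duplicated (sample, compartment, element) record(s): %s",
      paste(paste(dup$sample_id, dup$compartment, dup$element, sep = "/"),
            collapse = ", ")))
  }

  parsed <- parse_censored(df$value)
  out <- df |>
    mutate(state = parsed$state, value = parsed$value) |>
    select("sample_id", "compartment", "element", "state", "value", "unit") |>
    normalize_units() |>
    as_tibble()
  class(out) <- c("hookah_conc", class(out))
  out
}

#' Read a censored multi-element concentration table
#'
#' Long schema: CSV columns `sample_id,compartment,element,value,unit` with
#' censoring encoded as `"<LOD"` in `value` (extra columns are kept but
#' ignored by the pipeline). Wide schema: one row per (sample, compartment),
#' one column per element, with a unit declaration row whose `sample_id` is
#' `#units`.
#'
#' @param path CSV file path.
#' @param schema `"long"` (default) or `"wide"`.
#' @return A validated, unit-normalized concentration tibble; see
#'   [as_concentration_table()].
#' @examples
#' conc <- read_concentration_table(hookah_example("tobacco_concentrations.csv"))
#' dplyr::count(conc, compartment, state)
#' @export
read_concentration_table <- function(path, schema = c("long", "wide")) {
  schema <- match.arg(schema)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (schema == "wide") {
    id_cols <- c("sample_id", "compartment")
    if (!all(id_cols %in% names(raw))) {
      abort("Wide schema needs 'sample_id' and 'compartment' columns")
    }
    unit_row <- raw |> filter(.data$sample_id == "#units")
    if (nrow(unit_row) != 1) {
      abort("Wide schema needs exactly one unit declaration row with sample_id '#units'")
    }
    units <- unit_row |>
      select(-dplyr::all_of(id_cols)) |>
      pivot_longer(dplyr::everything(), names_to = "element", values_to = "unit")
    raw <- raw |>
      filter(.data$sample_id != "#units") |>
      pivot_longer(-dplyr::all_of(id_cols), names_to = "element",
                   values_to = "value") |>
      left_join(units, by = "element")
  }
  tbl <- as_concentration_table(raw)
  inform(sprintf("Read %d records: %d samples x %d elements x %d compartments",
                 nrow(tbl), dplyr::n_distinct(tbl$sample_id),
                 dplyr::n_distinct(tbl$element),
                 dplyr::n_distinct(tbl$compartment)))
  tbl
}

#' Write a concentration table as a long CSV
#'
#' Serializes with the same censoring conventions the readers accept
#' (`"<LOD"`, `"*****"`), so write -> read round-trips.
#'
#' @param table A concentration tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(table, path) {
  table |>
    mutate(value = format_censored(.data$state, .data$value)) |>
    select("sample_id", "compartment", "element", "value", "unit") |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}

#' Validate a concentration table and print a report
#'
#' @param table A concentration tibble (or any long-format data frame
#'   accepted by [as_concentration_table()]).
#' @return The validated table, invisibly.
#' @export
validate_concentration_table <- function(table) {
  if (all(c("state", "value") %in% names(table))) {
    table <- mutate(table, value = format_censored(.data$state, .data$value)) |>
      select(-"state")
  }
  tbl <- as_concentration_table(table)
  counts <- tbl |> count(.data$compartment, .data$state)
  inform(paste0(
    "Valid concentration table: ",
    dplyr::n_distinct(tbl$sample_id), " samples, ",
    dplyr::n_distinct(tbl$element), " elements.\n",
    paste(sprintf("  %s/%s: %d", counts$compartment, counts$state, counts$n),
          collapse = "\n")
  ))
  invisible(tbl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read per-element toxicity references
#'
#' CSV columns `element,rfd_mg_kg_day,slope_factor`: the inhalation
#' reference dose (mg/kg/day) and the cancer slope factor
#' ((mg/kg/day)^-1). Either may be empty when no value is published
#' (e.g. no slope factor for Cu, Hg, Ni).
#'
#' @param path CSV file path.
#' @return A tibble with one row per element.
#' @examples
#' read_toxicity_references(hookah_example("toxicity_references.csv"))
#' @export
read_toxicity_references <- function(path) {
  tox <- readr::read_csv(path, col_types = "cdd", progress = FALSE)
  required <- c("element", "rfd_mg_kg_day", "slope_factor")
  if (!all(required %in% names(tox))) {
    abort(sprintf("Toxicity CSV needs columns %s", paste(required, collapse = ", ")))
  }
  bad_el <- setdiff(tox$element, hookah_elements)
  if (length(bad_el)) {
    abort(sprintf("Unknown element symbol(s) in toxicity table: %s",
                  paste(bad_el, collapse = ", ")))
  }
  if (any(tox$rfd_mg_kg_day <= 0, na.rm = TRUE)) {
    abort("Reference doses must be strictly positive")
  }
  if (any(tox$slope_factor < 0, na.rm = TRUE)) {
    abort("Slope factors must be non-negative")
  }
  if (anyDuplicated(tox$element)) abort("Duplicated element in toxicity table")
  tox
}

#' Read sample metadata
#'
#' CSV columns `sample_id,tobacco_type,label`; `tobacco_type` must be
#' `"maassel"` (flavored) or `"traditional"`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_csv(path, col_types = "ccc", progress = FALSE)
  if (!all(c("sample_id", "tobacco_type") %in% names(meta))) {
    abort("Sample metadata needs 'sample_id' and 'tobacco_type' columns")
  }
  bad <- setdiff(unique(meta$tobacco_type), c("maassel", "traditional"))
  if (length(bad)) {
    abort(sprintf("tobacco_type must be 'maassel' or 'traditional', got: %s",
                  paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) abort("Duplicated sample_id in metadata")
  meta
}

#' Read smoking-session partition parameters from YAML
#'
#' Keys: `ash_yield` (mass fraction), `water_volume_l` (L),
#' `tobacco_mass_kg` (kg). See [partition_params()].
#'
#' @param path YAML file path.
#' @return A `partition_params` object.
#' @examples
#' read_partition_params(hookah_example("example_partition_params.yaml"))
#' @export
read_partition_params <- function(path) {
  y <- yaml::read_yaml(path)
  partition_params(ash_yield = y$ash_yield,
                   water_volume_l = y$water_volume_l,
                   tobacco_mass_kg = y$tobacco_mass_kg)
}

#' Read a chronic exposure scenario from YAML
#'
#' Keys: `IR_kg_per_day`, `EF_days_per_year`, `ED_years`, `BW_kg`,
#' `AT_days`. See [exposure_scenario()].
#'
#' @param path YAML file path.
#' @return An `exposure_scenario` object.
#' @examples
#' read_exposure_scenario(hookah_example("example_scenario.yaml"))
#' @export
read_exposure_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  exposure_scenario(IR_kg_per_day = y$IR_kg_per_day,
                    EF_days_per_year = y$EF_days_per_year,
                    ED_years = y$ED_years,
                    BW_kg = y$BW_kg,
                    AT_days = y$AT_days)
}

#' Read the bundled instrument detection limits
#'
#' Per-element limits of detection of the ICP-MS method, in micrograms per
#' litre of measured solution. Used as censoring defaults by the synthetic
#' study generator.
#'
#' @return A tibble with columns `element` and `lod_ug_l`.
#' @export
instrument_lods <- function() {
  readr::read_csv(hookah_example("instrument_lods.csv"),
                  col_types = "cd", progress = FALSE)
}
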