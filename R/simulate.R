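# Synthetic hookah studies with known ground truth. Raw concentrations are
# lognormal per element (the measured panels span orders of magnitude and
# are strictly positive); ash and water concentrations are derived from
# fixed transfer fractions through the same mass balance the analysis
# inverts, so the pipeline's smoke percentages are recoverable exactly.

#' Configuration for the synthetic study generator
#'
#' Defaults encode the emulated study: 5 samples per tobacco type, the
#' 29-element panel with per-element lognormal log-means taken from the
#' bundled raw-tobacco medians (half-LOD substitution) and log-sd 0.5;
#' transfer fractions `t_ash = 0.2`, `t_water = 0.05` (so 75 % of every
#' element's burden leaves with the smoke, inside the reported 69.5-93 %
#' range); session parameters ash_yield 0.25, 0.8 L bowl water, 15 g
#' charge; censoring limits from the bundled instrument LODs (µg/L),
#' converted to matrix scale through the digestion dilution (0.5 g in
#' 25 mL, i.e. x0.05 to mg/kg for solids; /1000 to mg/L for water).
#'
#' @param seed Integer seed; a fixed seed makes the generated study
#'   byte-identical.
#' @param n_per_type Samples per tobacco type.
#' @param elements Element panel (character).
#' @param meanlog,sdlog Lognormal parameters of the raw concentrations
#'   (scalar or one value per element).
#' @param type_effect Multiplicative concentration factor applied to
#'   traditional samples (scalar or named per-element vector); 1 = no
#'   type difference.
#' @param t_ash,t_water Ground-truth transfer fractions into ash and bowl
#'   water (scalar or per element); `t_ash + t_water <= 1`.
#' @param params A [partition_params()] object used by the generator's
#'   mass balance.
#' @param lod Optional tibble with columns `element`, `lod_solid` (mg/kg),
#'   `lod_water` (mg/L) overriding the instrument-LOD defaults.
#' @param lod_scale Multiplier on all LODs (0 disables censoring).
#' @return A `simulate_config` object (named list).
#' @export
simulate_config <- function(seed = 1L, n_per_type = 5L,
                            elements = hookah_elements,
                            meanlog = NULL, sdlog = 0.5,
                            type_effect = 1,
                            t_ash = 0.2, t_water = 0.05,
                            params = partition_params(0.25, 0.8, 0.015),
                            lod = NULL, lod_scale = 1) {
  stopifnot(inherits(params, "partition_params"), n_per_type >= 1,
            lod_scale >= 0)
  ne <- length(elements)
  # scalars recycle; partially-named vectors fall back to `fill` elsewhere
  expand <- function(x, what, fill = NA_real_) {
    if (length(x) == 1 && is.null(names(x))) {
      return(setNames(rep(as.numeric(x), ne), elements))
    }
    if (!is.null(names(x))) {
      full <- setNames(rep(as.numeric(fill), ne), elements)
      bad <- setdiff(names(x), elements)
      if (length(bad)) {
        abort(sprintf("%s names not in the element panel: %s", what,
                      paste(bad, collapse = ", ")))
      }
      full[names(x)] <- x
      if (anyNA(full)) {
        abort(sprintf("%s is incomplete: supply all %d elements or a scalar",
                      what, ne))
      }
      return(full)
    }
    if (length(x) != ne) {
      abort(sprintf("%s must be scalar, named, or length %d", what, ne))
    }
    setNames(as.numeric(x), elements)
  }
  if (is.null(meanlog)) meanlog <- default_meanlog(elements)
  meanlog <- expand(meanlog, "meanlog")
  sdlog <- expand(sdlog, "sdlog", fill = 0.5)
  eff <- expand(type_effect, "type_effect", fill = 1)
  t_ash <- expand(t_ash, "t_ash", fill = 0.2)
  t_water <- expand(t_water, "t_water", fill = 0.05)
  if (any(t_ash < 0) || any(t_water < 0) || any(t_ash + t_water > 1)) {
    abort("Need t_ash, t_water >= 0 and t_ash + t_water <= 1 for every element")
  }

  if (is.null(lod)) lod <- default_lods(elements)
  if (!all(elements %in% lod$element)) {
    abort("LOD table does not cover the element panel")
  }
  if (any(lod$lod_solid <= 0) || any(lod$lod_water <= 0)) abort("LODs must be positive")

  structure(list(seed = as.integer(seed), n_per_type = as.integer(n_per_type),
                 elements = elements, meanlog = meanlog, sdlog = sdlog,
                 type_effect = eff, t_ash = t_ash, t_water = t_water,
                 params = params, lod = lod, lod_scale = lod_scale),
            class = "simulate_config")
}

# Per-element lognormal log-means from the bundled raw-tobacco table
# (median over the five samples, half-LOD substitution).
default_meanlog <- function(elements) {
  conc <- as_concentration_table(readr::read_csv(
    hookah_example("tobacco_concentrations.csv"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE))
  med <- conc |>
    filter(.data$compartment == "raw") |>
    substitute_censored("half_lod") |>
    group_by(.data$element) |>
    summarise(m = median(.data$concentration, na.rm = TRUE), .groups = "drop")
  out <- setNames(log(med$m), med$element)
  missing_el <- setdiff(elements, names(out))
  if (length(missing_el)) {
    abort(sprintf("No bundled raw medians for: %s; supply meanlog explicitly",
                  paste(missing_el, collapse = ", ")))
  }
  out[elements]
}

# Instrument LODs (µg/L in solution) on matrix scale: solids were digested
# 0.5 g to 25 mL (x50 to µg/kg, /1000 to mg/kg => x0.05); water was
# measured directly (/1000 to mg/L).
default_lods <- function(elements) {
  instrument_lods() |>
    filter(.data$element %in% elements) |>
    transmute(.data$element,
              lod_solid = .data$lod_ug_l * 25 / 0.5 / 1000,
              lod_water = .data$lod_ug_l / 1000)
}

#' Generate a complete synthetic hookah study
#'
#' Draws raw-tobacco concentrations, derives ash and water concentrations
#' from the configured transfer fractions through the session mass
#' balance, applies LOD censoring, and returns the study together with
#' its ground truth. With censoring off and matching partition
#' parameters, [partition_table()] on the output recovers
#' `smoke_percent = 100 * (1 - t_ash - t_water)` exactly.
#'
#' @param config A [simulate_config()] object.
#' @return A list with elements `concentrations` (a censored, normalized
#'   concentration tibble), `meta` (sample metadata) and `ground_truth`
#'   (list: `transfer` with per-element `t_ash`, `t_water`,
#'   `smoke_percent`; `raw_true` with the uncensored raw concentrations;
#'   `params`).
#' @examples
#' study <- simulate_hookah_study(simulate_config(seed = 42, n_per_type = 2))
#' dplyr::count(study$concentrations, compartment, state)
#' @export
simulate_hookah_study <- function(config) {
  stopifnot(inherits(config, "simulate_config"))
  cfg <- config
  p <- cfg$params

  meta <- tibble(
    sample_id = c(sprintf("maassel_%02d", seq_len(cfg$n_per_type)),
                  sprintf("traditional_%02d", seq_len(cfg$n_per_type))),
    tobacco_type = rep(c("maassel", "traditional"), each = cfg$n_per_type)
  ) |>
    mutate(label = .data$sample_id)

  grid <- expand_grid(sample_id = meta$sample_id, element = cfg$elements) |>
    left_join(meta |> select("sample_id", "tobacco_type"), by = "sample_id")

  raw_true <- withr::with_seed(cfg$seed, {
    grid |>
      mutate(concentration = unname(
        rlnorm(dplyr::n(),
               meanlog = cfg$meanlog[.data$element],
               sdlog = cfg$sdlog[.data$element]) *
          ifelse(.data$tobacco_type == "traditional",
                 cfg$type_effect[.data$element], 1)))
  })

  long <- raw_true |>
    mutate(
      raw = .data$concentration,
      ash = .data$concentration * unname(cfg$t_ash[.data$element]) / p$ash_yield,
      water = .data$concentration * unname(cfg$t_water[.data$element]) *
        p$tobacco_mass_kg / p$water_volume_l
    ) |>
    select("sample_id", "element", "raw", "ash", "water") |>
    pivot_longer(c("raw", "ash", "water"), names_to = "compartment",
                 values_to = "conc") |>
    left_join(cfg$lod, by = "element") |>
    mutate(
      lod = ifelse(.data$compartment == "water",
                   .data$lod_water, .data$lod_solid) * cfg$lod_scale,
      state = ifelse(.data$conc < .data$lod, "censored", "observed"),
      value = ifelse(.data$state == "censored", .data$lod, .data$conc),
      unit = ifelse(.data$compartment == "water", "mg/L", "mg/kg")
    ) |>
    select("sample_id", "compartment", "element", "state", "value", "unit") |>
    arrange(factor(.data$compartment, compartments), .data$sample_id,
            .data$element)
  class(long) <- c("hookah_conc", class(long))

  list(
    concentrations = long,
    meta = meta,
    ground_truth = list(
      transfer = tibble(element = cfg$elements,
                        t_ash = unname(cfg$t_ash),
                        t_water = unname(cfg$t_water),
                        smoke_percent = 100 * (1 - unname(cfg$t_ash) -
                                                 unname(cfg$t_water))),
      raw_true = raw_true |> select("sample_id", "element", "concentration"),
      params = p
    )
  )
}

#' Rescale detection limits for censoring sensitivity tests
#'
#' Regenerates the configured study with all LODs multiplied by
#' `lod_scale`: 0 turns censoring off entirely, large values censor
#' everything.
#'
#' @param config A [simulate_config()] object.
#' @param lod_scale Non-negative multiplier.
#' @return A censored concentration tibble.
#' @export
censoring_stress <- function(config, lod_scale) {
  stopifnot(inherits(config, "simulate_config"), lod_scale >= 0)
  config$lod_scale <- lod_scale
  simulate_hookah_study(config)$concentrations
}
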