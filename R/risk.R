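#' Chronic exposure scenario
#'
#' The exposure-assessment inputs of the intake equation
#' `CDI = CF * IR * EF * ED / (BW * AT)`. The study reports no scenario
#' values, so they are mandatory inputs; an example YAML with labelled
#' assumptions ships with the package
#' (`hookah_example("example_scenario.yaml")`).
#'
#' @param IR_kg_per_day Intake rate of tobacco, kg per person per day.
#' @param EF_days_per_year Exposure frequency, days per year (at most 365).
#' @param ED_years Exposure duration, years.
#' @param BW_kg Body weight, kg.
#' @param AT_days Averaging time, days (70-year lifetime = 25 550 for
#'   carcinogens).
#' @return An `exposure_scenario` object (named list).
#' @examples
#' exposure_scenario(0.01, 365, 30, 70, 25550)
#' @export
exposure_scenario <- function(IR_kg_per_day, EF_days_per_year, ED_years,
                              BW_kg, AT_days) {
  vals <- c(IR = IR_kg_per_day, EF = EF_days_per_year, ED = ED_years,
            BW = BW_kg, AT = AT_days)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All exposure-scenario values must be strictly positive")
  }
  if (EF_days_per_year > 365) abort("EF_days_per_year cannot exceed 365")
  structure(list(IR_kg_per_day = IR_kg_per_day,
                 EF_days_per_year = EF_days_per_year,
                 ED_years = ED_years, BW_kg = BW_kg, AT_days = AT_days),
            class = "exposure_scenario")
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf(
    "Exposure scenario: IR = %g kg/day, EF = %g d/y, ED = %g y, BW = %g kg, AT = %g d\n",
    x$IR_kg_per_day, x$EF_days_per_year, x$ED_years, x$BW_kg, x$AT_days))
  invisible(x)
}

#' Chronic daily intake
#'
#' `CDI = (CF * IR * EF * ED) / (BW * AT)` in mg per kg body weight per
#' day, where CF is the exposure-point concentration (mg/kg). Linear in CF.
#'
#' @param cf Exposure-point concentration, mg/kg (vectorized).
#' @param scenario An [exposure_scenario()] object.
#' @return CDI in mg/kg/day.
#' @examples
#' chronic_daily_intake(2, exposure_scenario(0.01, 365, 30, 70, 25550))
#' @export
chronic_daily_intake <- function(cf, scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (any(cf < 0, na.rm = TRUE)) abort("CF must be non-negative")
  cf * scenario$IR_kg_per_day * scenario$EF_days_per_year * scenario$ED_years /
    (scenario$BW_kg * scenario$AT_days)
}

#' Hazard quotient
#'
#' `HQ = CDI / RfD`. Quotients at or above 1 carry the hazard flag
#' ("potential for hazard"); an element with no published reference dose
#' yields `NA` rather than an error — absence of a reference value is not
#' absence of risk.
#'
#' @param cdi Chronic daily intake, mg/kg/day (vectorized).
#' @param rfd Inhalation reference dose, mg/kg/day; `NA` allowed.
#' @return A tibble with columns `hq` and `hazard_flag`.
#' @examples
#' hazard_quotient(1.2245e-4, 0.00012)
#' @export
hazard_quotient <- function(cdi, rfd) {
  if (any(rfd <= 0, na.rm = TRUE)) abort("Reference doses must be positive")
  if (any(cdi < 0, na.rm = TRUE)) abort("CDI must be non-negative")
  hq <- cdi / rfd
  tibble(hq = hq, hazard_flag = !is.na(hq) & hq >= 1)
}

#' Incremental lifetime cancer risk
#'
#' `CR = CDI * CSF`, a dimensionless lifetime probability. Elements with
#' no published slope factor yield `NA`.
#'
#' @param cdi Chronic daily intake, mg/kg/day (vectorized).
#' @param slope_factor Cancer slope factor, (mg/kg/day)^-1; `NA` allowed.
#' @return Numeric vector of cancer risks.
#' @examples
#' cancer_risk(1.2245e-4, 150)
#' @export
cancer_risk <- function(cdi, slope_factor) {
  if (any(slope_factor < 0, na.rm = TRUE)) abort("Slope factors must be non-negative")
  if (any(cdi < 0, na.rm = TRUE)) abort("CDI must be non-negative")
  cdi * slope_factor
}

#' Classify a cancer risk into bands
#'
#' The standard one-in-a-million / one-in-ten-thousand bands:
#' `CR <= 1e-6` is negligible (boundary inclusive), `CR > 1e-4` is high,
#' anything in between is tolerable. `NA` (no slope factor) maps to
#' `"not_applicable"`.
#'
#' @param cr Cancer risk (vectorized).
#' @return Character vector with values `"negligible"`, `"tolerable"`,
#'   `"high"`, `"not_applicable"`.
#' @examples
#' classify_cr(c(1e-6, 5e-5, 2e-3, NA))
#' @export
classify_cr <- function(cr) {
  if (any(cr < 0, na.rm = TRUE)) abort("Cancer risk cannot be negative")
  dplyr::case_when(
    is.na(cr) ~ "not_applicable",
    cr <= 1e-6 ~ "negligible",
    cr > 1e-4 ~ "high",
    TRUE ~ "tolerable"
  )
}

#' Full per-element risk table
#'
#' Joins a concentration table with toxicity references and an exposure
#' scenario and computes CDI, HQ and CR for every (sample, element). The
#' exposure-point concentration CF is the raw-tobacco concentration
#' (mg/kg), optionally scaled by the smoke fraction from a mass-balance
#' [partition_table()] (`source = "smoke"`): only the share of the burden
#' that actually leaves with the smoke is inhaled.
#'
#' @param table A normalized concentration tibble.
#' @param toxrefs Toxicity references, see [read_toxicity_references()].
#' @param scenario An [exposure_scenario()] object.
#' @param source `"raw"` (CF = raw concentration) or `"smoke"`
#'   (CF = raw x smoke_percent / 100; requires `partition`).
#' @param partition A `hookah_partition` object when `source = "smoke"`.
#' @param policy Censoring substitution policy.
#' @return A tibble of class `hookah_risk` with columns `sample_id`,
#'   `element`, `cf`, `cdi`, `hq`, `hazard_flag`, `cr`, `band`. Elements
#'   lacking both an RfD and a slope factor keep a row with band
#'   `"not_applicable"`. Summarise hazard indices with [glance()].
#' @examples
#' conc <- read_concentration_table(hookah_example("tobacco_concentrations.csv"))
#' tox <- read_toxicity_references(hookah_example("toxicity_references.csv"))
#' sc <- read_exposure_scenario(hookah_example("example_scenario.yaml"))
#' risk_table(conc, tox, sc)
#' @export
risk_table <- function(table, toxrefs, scenario,
                       source = c("raw", "smoke"), partition = NULL,
                       policy = c("zero", "half_lod", "lod")) {
  source <- match.arg(source)
  policy <- match.arg(policy)
  cf_tbl <- table |>
    filter(.data$compartment == "raw") |>
    substitute_censored(policy) |>
    transmute(.data$sample_id, .data$element, cf = .data$concentration)
  if (nrow(cf_tbl) == 0) abort("Concentration table has no raw records")

  if (source == "smoke") {
    if (!inherits(partition, "hookah_partition")) {
      abort("source = 'smoke' needs a partition_table() result in `partition`")
    }
    cf_tbl <- cf_tbl |>
      inner_join(as_tibble(partition) |>
                   select("sample_id", "element", "smoke_percent"),
                 by = c("sample_id", "element")) |>
      mutate(cf = .data$cf * .data$smoke_percent / 100) |>
      select(-"smoke_percent")
  }

  out <- cf_tbl |>
    left_join(toxrefs, by = "element") |>
    mutate(cdi = chronic_daily_intake(dplyr::coalesce(.data$cf, 0), scenario),
           cdi = ifelse(is.na(.data$cf), NA_real_, .data$cdi))
  hqr <- hazard_quotient(dplyr::coalesce(out$cdi, 0), out$rfd_mg_kg_day)
  out <- out |>
    mutate(
      hq = ifelse(is.na(.data$cdi), NA_real_, hqr$hq),
      hazard_flag = !is.na(.data$hq) & hqr$hazard_flag,
      cr = cancer_risk(.data$cdi, .data$slope_factor),
      band = classify_cr(.data$cr)
    ) |>
    select("sample_id", "element", "cf", "cdi", "hq", "hazard_flag",
           "cr", "band") |>
    arrange(.data$sample_id, .data$element)
  attr(out, "scenario") <- scenario
  attr(out, "source") <- source
  class(out) <- c("hookah_risk", class(out))
  out
}

#' @export
tidy.hookah_risk <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Per-sample hazard index
#'
#' The hazard index is the sum of the hazard quotients of all elements
#' with a reference dose; values above 1 flag a potential noncancer
#' hazard from the mixture.
#'
#' @param x A `hookah_risk` object.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `hazard_index`,
#'   `n_hq`, `n_cr`, `n_high`.
#' @export
glance.hookah_risk <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$sample_id) |>
    summarise(
      hazard_index = sum(.data$hq, na.rm = TRUE),
      n_hq = sum(!is.na(.data$hq)),
      n_cr = sum(!is.na(.data$cr)),
      n_high = sum(.data$band == "high"),
      .groups = "drop"
    )
}

#' @describeIn risk_table Cancer risks per element and sample on a log
#'   scale, with the negligible/tolerable/high band boundaries.
#' @param object A `hookah_risk` object.
#' @param ... Unused.
#' @export
autoplot.hookah_risk <- function(object, ...) {
  d <- as_tibble(object) |> filter(!is.na(.data$cr), .data$cr > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$element, y = .data$cr,
                                  colour = .data$sample_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(1e-6, 1e-4), linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "lifetime cancer risk",
                  caption = "dashed: negligible (1e-6) and high (1e-4) boundaries") +
    ggplot2::theme_minimal()
}
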