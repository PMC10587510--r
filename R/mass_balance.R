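#' Smoking-session partition parameters
#'
#' The per-session quantities that make the smoke-by-difference subtraction
#' dimensionally coherent. None of them is reported by the study protocol,
#' so they are mandatory inputs with no defaults; an example YAML with
#' clearly-labelled assumed values ships with the package
#' (`hookah_example("example_partition_params.yaml")`).
#'
#' @param ash_yield Mass fraction of the tobacco charge remaining as ash
#'   after combustion, in (0, 1).
#' @param water_volume_l Bowl water volume per session, litres (> 0).
#' @param tobacco_mass_kg Tobacco charge per session, kilograms (> 0).
#' @return A `partition_params` object (named list).
#' @examples
#' partition_params(ash_yield = 0.25, water_volume_l = 0.8,
#'                  tobacco_mass_kg = 0.015)
#' @export
partition_params <- function(ash_yield, water_volume_l, tobacco_mass_kg) {
  stopifnot(is.numeric(ash_yield), is.numeric(water_volume_l),
            is.numeric(tobacco_mass_kg))
  if (!(ash_yield > 0 && ash_yield < 1)) {
    abort("ash_yield must be a mass fraction strictly between 0 and 1")
  }
  if (water_volume_l <= 0) abort("water_volume_l must be positive")
  if (tobacco_mass_kg <= 0) abort("tobacco_mass_kg must be positive")
  structure(list(ash_yield = ash_yield, water_volume_l = water_volume_l,
                 tobacco_mass_kg = tobacco_mass_kg),
            class = "partition_params")
}

#' @export
print.partition_params <- function(x, ...) {
  cat(sprintf(
    "Partition parameters: ash_yield = %g, water = %g L, charge = %g kg\n",
    x$ash_yield, x$water_volume_l, x$tobacco_mass_kg))
  invisible(x)
}

#' Per-session compartment burdens
#'
#' Converts concentrations to absolute element masses per smoking session:
#' raw burden = raw concentration x tobacco charge; ash burden = ash
#' concentration x ash yield x tobacco charge (the ash weighs only
#' `ash_yield` of the charge); water burden = water concentration x bowl
#' volume.
#'
#' @param raw_c,ash_c Concentrations in mg/kg (vectors recycle).
#' @param water_c Concentration in mg/L.
#' @param params A [partition_params()] object.
#' @return A tibble with columns `burden_raw`, `burden_ash`, `burden_water`
#'   in mg per session.
#' @examples
#' compartment_burdens(100, 50, 10,
#'   partition_params(0.2, 0.5, 0.01))  # 1.0, 0.1, 5.0 mg
#' @export
compartment_burdens <- function(raw_c, ash_c, water_c, params) {
  stopifnot(inherits(params, "partition_params"))
  if (any(c(raw_c, ash_c, water_c) < 0, na.rm = TRUE)) {
    abort("Concentrations must be non-negative")
  }
  tibble(
    burden_raw = raw_c * params$tobacco_mass_kg,
    burden_ash = ash_c * params$ash_yield * params$tobacco_mass_kg,
    burden_water = water_c * params$water_volume_l
  )
}

#' Percentage of the raw burden ending up in smoke
#'
#' The smoke burden is defined by difference: raw minus ash minus water.
#' Measurement noise can push the difference outside `[0, 100]` percent;
#' such values are clipped and flagged rather than silently propagated.
#'
#' @param burden_raw,burden_ash,burden_water Burdens in mg (vectors
#'   recycle); `burden_raw` must be strictly positive.
#' @return A tibble with columns `smoke_percent` in `[0, 100]` and
#'   `clipped` (logical).
#' @examples
#' smoke_retention_percent(1.0, 0.1, 0.1)  # 80 %
#' @export
smoke_retention_percent <- function(burden_raw, burden_ash, burden_water) {
  if (any(burden_raw <= 0, na.rm = TRUE)) {
    abort("smoke percentage is undefined for a zero raw burden")
  }
  pct <- 100 * (burden_raw - burden_ash - burden_water) / burden_raw
  clipped <- pct < 0 | pct > 100
  tibble(smoke_percent = pmin(pmax(pct, 0), 100), clipped = clipped)
}

#' Partition every element's burden across ash, water and smoke
#'
#' Applies the censoring policy, converts each (sample, element) triple of
#' concentrations to per-session burdens, and computes the smoke percentage
#' by difference. Rows whose raw burden is zero after substitution (a
#' censored raw cell under the zero policy) or that have a missing
#' determination in any compartment are skipped with a message: the
#' percentage is undefined there, and skipping is more honest than a
#' division by zero or an imputation.
#'
#' @param table A normalized concentration tibble in which every sample has
#'   raw, ash and water records.
#' @param params A [partition_params()] object.
#' @param policy Censoring substitution policy.
#' @return A tibble of class `hookah_partition` with columns `sample_id`,
#'   `element`, `burden_raw`, `burden_ash`, `burden_water` (mg/session),
#'   `smoke_percent`, `clipped`. Summarise with [glance()], plot with
#'   [autoplot()].
#' @export
partition_table <- function(table, params, policy = c("zero", "half_lod", "lod")) {
  policy <- match.arg(policy)
  have <- table |> distinct(.data$sample_id, .data$compartment)
  need <- expand_grid(sample_id = unique(table$sample_id),
                      compartment = compartments)
  missing_comp <- anti_join(need, have, by = c("sample_id", "compartment"))
  if (nrow(missing_comp)) {
    abort(sprintf("Sample(s) missing a compartment: %s",
                  paste(missing_comp$sample_id, missing_comp$compartment,
                        sep = "/", collapse = ", ")))
  }

  wide <- table |>
    substitute_censored(policy) |>
    select("sample_id", "compartment", "element", "concentration") |>
    pivot_wider(names_from = "compartment", values_from = "concentration")

  undefined <- wide |>
    filter(is.na(.data$raw) | is.na(.data$ash) | is.na(.data$water) |
             .data$raw <= 0)
  if (nrow(undefined)) {
    inform(sprintf(
      "Skipping %d (sample, element) row(s) with missing or zero raw burden: %s",
      nrow(undefined),
      paste(utils::head(paste(undefined$sample_id, undefined$element, sep = "/"), 8),
            collapse = ", ")))
  }
  wide <- anti_join(wide, undefined, by = c("sample_id", "element"))

  burdens <- compartment_burdens(wide$raw, wide$ash, wide$water, params)
  smoke <- smoke_retention_percent(burdens$burden_raw, burdens$burden_ash,
                                   burdens$burden_water)
  out <- bind_cols(wide |> select("sample_id", "element"), burdens, smoke) |>
    arrange(.data$sample_id, .data$element)
  attr(out, "params") <- params
  attr(out, "policy") <- policy
  class(out) <- c("hookah_partition", class(out))
  out
}

#' @export
tidy.hookah_partition <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Per-sample smoke-percentage range
#'
#' One row per sample: the element-wise minimum and maximum smoke
#' percentage and the number of clipped cells.
#'
#' @param x A `hookah_partition` object.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `n_elements`,
#'   `smoke_percent_min`, `smoke_percent_max`, `n_clipped`.
#' @export
glance.hookah_partition <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$sample_id) |>
    summarise(
      n_elements = dplyr::n(),
      smoke_percent_min = min(.data$smoke_percent),
      smoke_percent_max = max(.data$smoke_percent),
      n_clipped = sum(.data$clipped),
      .groups = "drop"
    )
}

#' @describeIn partition_table Heatmap of smoke percentages (elements x
#'   samples); clipped cells are marked.
#' @param object A `hookah_partition` object.
#' @param ... Unused.
#' @export
autoplot.hookah_partition <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$element,
                                  fill = .data$smoke_percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = filter(d, .data$clipped), shape = 8, size = 1) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "smoke (%)",
                  caption = "* clipped into [0, 100]") +
    ggplot2::theme_minimal()
}
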