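#' Per-compartment elemental totals
#'
#' Sums the substituted concentrations of all non-missing panel elements
#' within each (sample, compartment), in mg/kg for solids and mg/L for
#' water. Missing determinations are excluded from the sum, never imputed;
#' censored cells enter according to `policy`.
#'
#' @param table A normalized concentration tibble.
#' @param policy Censoring substitution policy, see [substitute_censored()].
#' @return A tibble with columns `sample_id`, `compartment`, `n_elements`,
#'   `n_censored`, `n_missing`, `total`.
#' @examples
#' conc <- read_concentration_table(hookah_example("tobacco_concentrations.csv"))
#' element_totals(conc)
#' @export
element_totals <- function(table, policy = c("zero", "half_lod", "lod")) {
  policy <- match.arg(policy)
  grouped <- table |>
    group_by(.data$sample_id, .data$compartment)
  empty <- grouped |>
    summarise(all_missing = all(.data$state == "missing"), .groups = "drop") |>
    filter(.data$all_missing)
  if (nrow(empty)) {
    abort(sprintf("No non-missing elements for: %s",
                  paste(empty$sample_id, empty$compartment, sep = "/",
                        collapse = ", ")))
  }
  table |>
    substitute_censored(policy) |>
    group_by(.data$sample_id, .data$compartment) |>
    summarise(
      n_elements = dplyr::n(),
      n_censored = NA_integer_,  # filled below from the original table
      n_missing = sum(is.na(.data$concentration)),
      total = sum(.data$concentration, na.rm = TRUE),
      .groups = "drop"
    ) |>
    select(-"n_censored") |>
    left_join(
      table |>
        group_by(.data$sample_id, .data$compartment) |>
        summarise(n_censored = sum(.data$state == "censored"), .groups = "drop"),
      by = c("sample_id", "compartment")
    ) |>
    relocate("n_censored", .after = "n_elements")
}

#' Main-element share of a single (sample, compartment)
#'
#' The percentage of the panel total contributed by the five bulk elements
#' Ca, K, Na, Mg and P: `100 * sum(main) / sum(all)`, over non-missing
#' elements after censoring substitution. Full precision is returned;
#' display rounding is one decimal, half-up.
#'
#' @param table A normalized concentration tibble.
#' @param sample_id,compartment Which cell of the study to evaluate.
#' @inheritParams element_totals
#' @return A single percentage in `[0, 100]`.
#' @examples
#' conc <- read_concentration_table(hookah_example("tobacco_concentrations.csv"))
#' main_element_share(conc, "apple", "ash")  # 97.6 when rounded
#' @export
main_element_share <- function(table, sample_id, compartment,
                               policy = c("zero", "half_lod", "lod")) {
  policy <- match.arg(policy)
  sub <- table |>
    filter(.data$sample_id == !!sample_id, .data$compartment == !!compartment)
  if (nrow(sub) == 0) {
    abort(sprintf("No records for %s/%s", sample_id, compartment))
  }
  prof <- composition_profile(sub, policy = policy, fractions = FALSE)
  if (prof$total <= 0) {
    abort(sprintf("Total concentration of %s/%s is zero; share undefined",
                  sample_id, compartment))
  }
  prof$main_share
}

#' Composition profiles for every sample and compartment
#'
#' For each (sample, compartment): the panel total, each element's fraction
#' of that total (summing to 1 over non-missing elements), and the
#' main-element share in percent.
#'
#' @inheritParams element_totals
#' @param fractions Include the per-element fraction columns (default TRUE).
#' @return A tibble of class `hookah_composition` with columns `sample_id`,
#'   `compartment`, `total`, `main_share`, and (optionally) `frac_<element>`
#'   columns. Plot with [autoplot()].
#' @examples
#' conc <- read_concentration_table(hookah_example("tobacco_concentrations.csv"))
#' composition_profile(conc) |> dplyr::select(1:4)
#' @export
composition_profile <- function(table, policy = c("zero", "half_lod", "lod"),
                                fractions = TRUE) {
  policy <- match.arg(policy)
  sub <- substitute_censored(table, policy)
  prof <- sub |>
    group_by(.data$sample_id, .data$compartment) |>
    summarise(
      total = sum(.data$concentration, na.rm = TRUE),
      main_share = 100 * sum(.data$concentration[.data$element %in% main_elements],
                             na.rm = TRUE) /
        sum(.data$concentration, na.rm = TRUE),
      .groups = "drop"
    )
  if (fractions) {
    frac <- sub |>
      group_by(.data$sample_id, .data$compartment) |>
      mutate(frac = .data$concentration / sum(.data$concentration, na.rm = TRUE)) |>
      ungroup() |>
      select("sample_id", "compartment", "element", "frac") |>
      pivot_wider(names_from = "element", values_from = "frac",
                  names_prefix = "frac_")
    prof <- left_join(prof, frac, by = c("sample_id", "compartment"))
  }
  prof <- prof |>
    mutate(main_share = ifelse(.data$total > 0, .data$main_share, NA_real_))
  attr(prof, "policy") <- policy
  class(prof) <- c("hookah_composition", class(prof))
  prof
}

#' Round half-up to one decimal, for display
#'
#' Matches the reporting convention used for share percentages (base R's
#' `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @describeIn composition_profile Stacked-bar figure of the main-element
#'   shares per compartment.
#' @param object A `hookah_composition` object.
#' @param ... Unused.
#' @export
autoplot.hookah_composition <- function(object, ...) {
  frac_cols <- paste0("frac_", main_elements)
  if (!all(frac_cols %in% names(object))) {
    abort("autoplot needs a profile computed with fractions = TRUE")
  }
  long <- object |>
    as_tibble() |>
    select("sample_id", "compartment", dplyr::all_of(frac_cols)) |>
    pivot_longer(dplyr::all_of(frac_cols), names_to = "element",
                 values_to = "fraction") |>
    mutate(element = sub("^frac_", "", .data$element))
  other <- object |>
    as_tibble() |>
    transmute(.data$sample_id, .data$compartment, element = "other",
              fraction = 1 - rowSums(as.matrix(object[, frac_cols]), na.rm = TRUE))
  long <- bind_rows(long, other) |>
    mutate(element = factor(.data$element, c(main_elements, "other")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = 100 * .data$fraction,
                                     fill = .data$element)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~compartment) +
    ggplot2::labs(x = NULL, y = "share of panel total (%)", fill = "element") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
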