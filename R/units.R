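# Unit handling. Solid compartments (raw, ash) are mass-per-mass; bowl water
# is mass-per-volume. "ppm"/"ppb" are accepted as aliases and resolved by
# compartment. After normalization every solid record is mg/kg and every
# water record is mg/L; censoring limits are converted identically.

unit_spec <- function(unit, compartment) {
  u <- trimws(unit)
  u <- sub("^µ", "u", u)  # µg -> ug
  water <- compartment == "water"
  norm <- dplyr::case_when(
    tolower(u) == "ppm" & !water ~ "mg/kg",
    tolower(u) == "ppb" & !water ~ "ug/kg",
    tolower(u) == "ppm" & water ~ "mg/L",
    tolower(u) == "ppb" & water ~ "ug/L",
    TRUE ~ u
  )
  known <- c("mg/kg", "ug/kg", "mg/L", "ug/L")
  if (any(!norm %in% known)) {
    abort(sprintf("Unknown unit(s): %s",
                  paste(unique(unit[!norm %in% known]), collapse = ", ")))
  }
  mismatch <- (norm %in% c("mg/kg", "ug/kg")) & water |
    (norm %in% c("mg/L", "ug/L")) & !water
  if (any(mismatch)) {
    abort(paste0(
      "Unit/compartment mismatch: solid compartments (raw, ash) need ",
      "mass-per-mass units and water needs mass-per-volume units; offending: ",
      paste(unique(paste(compartment[mismatch], unit[mismatch])), collapse = ", ")
    ))
  }
  list(
    scale = ifelse(startsWith(norm, "ug"), 1e-3, 1),
    target = ifelse(water, "mg/L", "mg/kg")
  )
}

#' Normalize concentration units
#'
#' Converts every solid-compartment record to mg/kg and every water record
#' to mg/L (micrograms divide by 1000). Detection limits of censored cells
#' are converted identically, so censoring state is preserved, and the
#' operation is idempotent.
#'
#' @param table A concentration tibble with `compartment`, `state`, `value`
#'   and `unit` columns.
#' @return The table with `value` rescaled and `unit` set to `"mg/kg"` or
#'   `"mg/L"`.
#' @export
normalize_units <- function(table) {
  stopifnot(all(c("compartment", "value", "unit") %in% names(table)))
  spec <- unit_spec(table$unit, table$compartment)
  table |>
    mutate(value = .data$value * spec$scale, unit = spec$target)
}
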