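#' Parse left-censored concentration tokens
#'
#' Concentration cells come in three states: an observed number (`"221"`),
#' a left-censored value reported as less-than the detection limit
#' (`"<50"`), or a missing determination (`"*****"`, an empty cell, or
#' `NA`). Thousands separators (`"17,214"`) are tolerated.
#'
#' @param tokens Character vector of raw cell contents.
#' @return A tibble with one row per token and columns
#'   `state` (`"observed"`, `"censored"`, `"missing"`) and `value`
#'   (the measurement if observed, the limit of detection if censored,
#'   `NA` if missing).
#' @examples
#' parse_censored(c("<50", "221", "*****", "17,214"))
#' @export
parse_censored <- function(tokens) {
  x <- trimws(as.character(tokens))
  state <- dplyr::case_when(
    is.na(x) | x == "" | grepl("^\\*+$", x) ~ "missing",
    grepl("^<", x) ~ "censored",
    TRUE ~ "observed"
  )
  numeric_part <- ifelse(state == "censored", sub("^<\\s*", "", x), x)
  value <- suppressWarnings(as.numeric(gsub(",", "", numeric_part)))
  value[state == "missing"] <- NA_real_

  bad <- state != "missing" & is.na(value)
  if (any(bad)) {
    abort(sprintf(
      "Cannot parse concentration cell(s): %s",
      paste0("'", unique(x[bad]), "' (position ",
             vapply(unique(x[bad]), function(t) which(x == t)[1], 1L), ")",
             collapse = ", ")
    ))
  }
  if (any(value < 0, na.rm = TRUE)) {
    abort("Negative concentrations are not allowed")
  }
  tibble(state = state, value = value)
}

#' Serialize censored values back to table tokens
#'
#' Inverse of [parse_censored()]: observed values print as plain numbers,
#' censored values as `"<LOD"`, missing values as `"*****"`.
#'
#' @param state,value Vectors as returned by [parse_censored()].
#' @return Character vector of tokens.
#' @export
format_censored <- function(state, value) {
  out <- dplyr::case_when(
    state == "missing" ~ "*****",
    state == "censored" ~ paste0("<", format(value, trim = TRUE, scientific = FALSE)),
    TRUE ~ format(value, trim = TRUE, scientific = FALSE)
  )
  out
}

#' Substitute censored values with plain numbers
#'
#' Left-censored cells are replaced according to `policy`: `"zero"`
#' (the default throughout the package; censored cells contribute nothing
#' to totals), `"half_lod"` (LOD/2, the common sensitivity choice) or
#' `"lod"` (upper bound). Observed values are untouched and missing values
#' stay `NA` so they can be excluded from sums rather than imputed.
#'
#' @param table A concentration tibble with `state` and `value` columns
#'   (see [read_concentration_table()]).
#' @param policy One of `"zero"`, `"half_lod"`, `"lod"`.
#' @return The table with a numeric `concentration` column and the
#'   `state`/`value` columns dropped.
#' @examples
#' tbl <- tibble::tibble(state = c("observed", "censored", "missing"),
#'                       value = c(221, 50, NA))
#' substitute_censored(tbl, "half_lod")
#' @export
substitute_censored <- function(table, policy = c("zero", "half_lod", "lod")) {
  policy <- match.arg(policy)
  stopifnot(all(c("state", "value") %in% names(table)))
  factor <- c(zero = 0, half_lod = 0.5, lod = 1)[[policy]]
  table |>
    mutate(concentration = dplyr::case_when(
      .data$state == "observed" ~ .data$value,
      .data$state == "censored" ~ .data$value * factor,
      TRUE ~ NA_real_
    )) |>
    select(-"state", -"value")
}
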