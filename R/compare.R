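#' Compare tobacco types and raw-vs-ash concentrations per element
#'
#' For each element (and for the per-sample panel total as a final
#' `"Total concentration"` row) two contrasts are evaluated:
#'
#' * **time** (raw vs ash): the in-house Friedman rank test with samples
#'   as blocks and the two compartments as treatments (exact permutation
#'   p on these small designs);
#' * **type** (traditional vs Maassel): an exact Wilcoxon rank-sum test
#'   on the per-sample mean of the raw and ash concentrations.
#'
#' Directions are derived from group medians and reported only when the
#' corresponding p-value is at or below `alpha`; an interaction note
#' describes the sign of the ash-minus-raw change within each type.
#'
#' @param table A normalized concentration tibble with raw and ash
#'   records for every sample.
#' @param meta Sample metadata, see [read_sample_meta()].
#' @param alpha Significance level (default 0.10).
#' @param policy Censoring substitution policy.
#' @return A tibble with columns `element`, `p_type`, `direction_type`
#'   (`"traditional>maassel"`, `"maassel>traditional"`, `"none"`),
#'   `p_time`, `direction_time` (`"ash>raw"`, `"ash<raw"`, `"none"`) and
#'   `note`.
#' @examples
#' conc <- read_concentration_table(hookah_example("tobacco_concentrations.csv"))
#' meta <- read_sample_meta(hookah_example("sample_meta.csv"))
#' compare_conditions(conc, meta)
#' @export
compare_conditions <- function(table, meta, alpha = 0.10,
                               policy = c("zero", "half_lod", "lod")) {
  policy <- match.arg(policy)
  stopifnot(alpha > 0, alpha < 1)

  per_type <- meta |> count(.data$tobacco_type)
  small <- filter(per_type, .data$n < 2)
  type_ok <- nrow(small) == 0 && nrow(per_type) == 2
  if (!type_ok) {
    warn("A tobacco-type group has fewer than 2 samples; type comparisons skipped")
  }

  sub <- table |>
    filter(.data$compartment %in% c("raw", "ash")) |>
    substitute_censored(policy) |>
    inner_join(meta, by = "sample_id")

  totals <- sub |>
    group_by(.data$sample_id, .data$tobacco_type, .data$compartment) |>
    summarise(concentration = sum(.data$concentration, na.rm = TRUE),
              .groups = "drop") |>
    mutate(element = "Total concentration")

  data <- bind_rows(
    sub |> select("sample_id", "tobacco_type", "compartment",
                  "element", "concentration"),
    totals |> select("sample_id", "tobacco_type", "compartment",
                     "element", "concentration")
  )

  elements <- c(intersect(hookah_elements, unique(sub$element)),
                "Total concentration")

  map_dfr(elements, function(el) {
    d <- filter(data, .data$element == el) |>
      tidyr::drop_na("concentration")
    wide <- d |>
      pivot_wider(id_cols = c("sample_id", "tobacco_type"),
                  names_from = "compartment", values_from = "concentration") |>
      tidyr::drop_na("raw", "ash")
    if (nrow(wide) < 2) {
      return(tibble(element = el, p_type = NA_real_, direction_type = "none",
                    p_time = NA_real_, direction_time = "none",
                    note = "fewer than 2 complete samples"))
    }

    ft <- friedman_rank_test(as.matrix(wide[, c("raw", "ash")]))
    med_diff <- median(wide$ash - wide$raw)
    direction_time <- if (ft$p.value <= alpha && med_diff != 0) {
      if (med_diff > 0) "ash>raw" else "ash<raw"
    } else "none"

    p_type <- NA_real_
    direction_type <- "none"
    if (type_ok) {
      lvl <- wide |> mutate(level = (.data$raw + .data$ash) / 2)
      trad <- lvl$level[lvl$tobacco_type == "traditional"]
      maas <- lvl$level[lvl$tobacco_type == "maassel"]
      p_type <- if (length(unique(c(trad, maas))) == 1) {
        1  # fully tied groups carry no ordering information
      } else {
        suppressWarnings(wilcox.test(trad, maas, exact = TRUE)$p.value)
      }
      if (!is.na(p_type) && p_type <= alpha && median(trad) != median(maas)) {
        direction_type <- if (median(trad) > median(maas)) {
          "traditional>maassel"
        } else {
          "maassel>traditional"
        }
      }
    }

    note <- interaction_note(wide)
    tibble(element = el, p_type = p_type, direction_type = direction_type,
           p_time = ft$p.value, direction_time = direction_time, note = note)
  })
}

# Descriptive interaction note from the sign of the within-type median
# ash-minus-raw change. Not a formal interaction test.
interaction_note <- function(wide) {
  trend <- wide |>
    group_by(.data$tobacco_type) |>
    summarise(d = median(.data$ash - .data$raw), .groups = "drop")
  word <- function(d) if (d > 0) "rising" else if (d < 0) "falling" else "flat"
  if (nrow(trend) < 2) return(NA_character_)
  tr <- trend$d[trend$tobacco_type == "traditional"]
  ma <- trend$d[trend$tobacco_type == "maassel"]
  if (!length(tr) || !length(ma)) return(NA_character_)
  if (sign(tr) == sign(ma)) {
    sprintf("both types %s from raw to ash", word(tr))
  } else {
    sprintf("maassel %s while traditional %s from raw to ash",
            word(ma), word(tr))
  }
}
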