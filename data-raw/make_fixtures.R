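# Builds the bundled plain-text fixtures under inst/extdata/ from hand-checked
# transcriptions of the published concentration tables (raw tobacco, tobacco
# ash, bowl water) plus the toxicity-reference and instrument-LOD tables.
# Cells that are typographically merged in the source and admit more than one
# reading carry low_confidence = TRUE; the chosen reading is the one
# structurally parallel to the unambiguous rows (and, for the Orange raw
# As/B/Ba triple, the one consistent with the printed main-element share).
#
# Run from the package root:  Rscript data-raw/make_fixtures.R

suppressPackageStartupMessages(library(tibble))
suppressPackageStartupMessages(library(dplyr))
suppressPackageStartupMessages(library(tidyr))
suppressPackageStartupMessages(library(readr))

samples <- c("apple", "blueberry", "orange", "khansar", "borazjan")

# element -> 5 sample tokens (Apple, Blueberry, Orange, Khansar, Borazjan).
# ppb elements (As, Cd, Hg) are recorded in ug/kg (solids) / ug/L (water).
raw <- list(
  Al = c("182.3", "197.4", "171.4", "1836.2", "984.6"),
  As = c("66", "<50", "309", "462", "237"),
  B  = c("134.2", "121.3", "311", "223.4", "223.6"),
  Ba = c("16.4", "14.2", "116.9", "118.9", "60.4"),
  Ca = c("17214", "9676", "6418", "66743", "66797"),
  Cd = c("221", "231", "346", "269", "328"),
  Ce = c("1.4", "0.5", "<0.5", "3.9", "2.6"),
  Co = c("<0.5", "0.8", "0.8", "2.7", "1.2"),
  Cr = c("<0.5", "<0.5", "<0.5", "4.7", "2.8"),
  Cu = c("5.2", "3.7", "2.3", "12.8", "12.9"),
  Fe = c("256.4", "78.1", "47.8", "2360.9", "1415.1"),
  Hg = c("23", "21", "22", "72", "47"),
  K  = c("15422", "10576", "9671", "46276", "36826"),
  Mg = c("3503", "1362", "1752", "14179", "18108"),
  Mn = c("40.4", "48.6", "42.7", "130.7", "113.7"),
  Mo = c("0.3", "<0.5", "<0.5", "2.9", "3.9"),
  Na = c("6932.1", "983.1", "544.3", "71050.0", "45489.0"),
  Ni = c("2.2", "<0.5", "<0.5", "8.0", "4.9"),
  P  = c("874.2", "595.6", "448.1", "2513.0", "1928.5"),
  Pb = c("3.3", "1.5", "3.8", "9.7", "5.9"),
  S  = c("198", "100", "70", "683", "937"),
  Sb = c("<1", "<1", "<1", "<1", "<1"),
  Se = c("1.3", "1.9", "4.7", "4.1", "3.3"),
  Si = c("203.5", "192.0", "182.1", "243.7", "166.8"),
  Sn = c("3.7", "1.9", "<1", "2.3", "1.6"),
  Sr = c("161.8", "41.9", "26.6", "699.1", "924.2"),
  Ti = c("2.4", "<1", "<1", "25.8", "19.2"),
  V  = c("0.7", "<0.5", "<0.5", "4.2", "3.1"),
  Zn = c("16.2", "14.6", "12.2", "30.7", "29.7")
)

ash <- list(
  Al = c("138.1", "195.0", "307.1", "1043.1", "846.4"),
  As = c("2031", "339", "<50", "316", "<50"),
  B  = c("126.2", "117.5", "132.8", "209.6", "248.6"),
  Ba = c("18.3", "16.8", "21.6", "77.1", "56.3"),
  Ca = c("20890", "12481", "27930", "58661", "70561"),
  Cd = c("406", "806", "80", "375", "318"),
  Ce = c("1.1", "<0.5", "<0.5", "1.5", "2.5"),
  Co = c("1.0", "0.5", "0.3", "1.7", "1.3"),
  Cr = c("<0.5", "<0.5", "<0.5", "2.7", "2.3"),
  Cu = c("15.3", "6.2", "9.7", "9.4", "17.5"),
  Fe = c("173.4", "131.0", "280.3", "1357.3", "1126.5"),
  Hg = c("<50", "<50", "126", "38", "<50"),
  K  = c("20424", "11913", "13550", "33543", "49687"),
  Mg = c("2850", "1318", "3457", "13058", "21759"),
  Mn = c("40.4", "55.5", "24.2", "114.4", "129.3"),
  Mo = c("<0.5", "<0.5", "0.6", "3.0", "4.7"),
  Na = c("2133.1", "700.9", "4493.5", "48296.0", "56909.0"),
  Ni = c("8.7", "4.4", "2.8", "6.3", "5.9"),
  P  = c("1249.2", "862.1", "982.1", "1897.2", "2151.3"),
  Pb = c("6.5", "2.1", "6.7", "3.8", "3.1"),
  S  = c("240", "146", "188", "490", "752"),
  Sb = c("<1", "<1", "<1", "<1", "<1"),
  Se = c("<1", "<1", "1.4", "1.0", "4.1"),
  Si = c("256.2", "172.1", "208.8", "118.7", "127.4"),
  Sn = c("<1", "2.2", "1.4", "1.0", "5.7"),
  Sr = c("113.3", "53.6", "178.8", "663.1", "1260.6"),
  Ti = c("1.4", "<1", "2.8", "17.0", "16.6"),
  V  = c("<0.5", "<0.5", "0.5", "3.1", "3.2"),
  Zn = c("25.8", "19.4", "17.2", "26.0", "42.7")
)

water <- list(
  Al = c("21", "81", "66", "52", "36"),
  As = c("367", "<5", "286", "<5", "<5"),
  B  = c("39", "68", "68", "65", "65"),
  Ba = c("83", "78", "87", "72", "12"),
  Ca = c("105", "5108", "105", "255", "456"),
  Cd = c("<5", "<5", "<5", "<5", "<5"),
  Ce = c("<10", "<10", "<10", "<10", "<10"),
  Co = c("<10", "<10", "<10", "<10", "<10"),
  Cr = c("<10", "<10", "<10", "<10", "<10"),
  Cu = c("11", "26", "24", "29", "<20"),
  Fe = c("46", "42", "67", "<50", "<50"),
  Hg = c("<10", "<10", "<10", "<10", "<10"),
  K  = c("8.96", "4.42", "8.86", "7.39", "7.40"),
  Mg = c("17.59", "18.49", "17.72", "6.55", "8.76"),
  Mn = c("42", "19", "10", "12", "15"),
  Mo = c("<20", "<20", "<20", "<20", "<20"),
  Na = c("30.09", "32.56", "29.02", "16.91", "20.12"),
  Ni = c("<20", "39.00", "<20", "<20", "<20"),
  P  = c("416", "332", "361", "51", "67"),
  Pb = c("16", "384", "96", "<20", "22"),
  S  = c("*****", "*****", "*****", "*****", "*****"),
  Sb = c("<20", "<20", "<20", "<20", "<20"),
  Se = c("<20", "<20", "<20", "<20", "<20"),
  Si = c("13.90", "14.77", "12.69", "9.81", "9.76"),
  Sn = c("<20", "53", "22", "<20", "<20"),
  Sr = c("694", "751", "722", "303", "339"),
  Ti = c("<50", "<50", "<50", "<50", "<50"),
  V  = c("<50", "<50", "<50", "<50", "<50"),
  Zn = c("58", "217", "72", "26", "29")
)

ppb_elements <- c("As", "Cd", "Hg")

low_confidence <- tribble(
  ~sample_id,  ~compartment, ~element,
  "orange",    "raw",        "As",
  "orange",    "raw",        "B",
  "orange",    "raw",        "Ba",
  "blueberry", "water",      "B",
  "blueberry", "water",      "Ba",
  "blueberry", "water",      "Ca",
  "khansar",   "water",      "Ba",
  "khansar",   "water",      "Ca",
  "borazjan",  "water",      "Ba",
  "borazjan",  "water",      "Ca",
  "blueberry", "water",      "P",
  "blueberry", "water",      "Pb",
  "orange",    "water",      "P",
  "orange",    "water",      "Pb"
)

block <- function(lst, compartment) {
  purrr::map_dfr(names(lst), function(el) {
    unit <- if (compartment == "water") {
      if (el %in% ppb_elements) "ug/L" else "mg/L"
    } else {
      if (el %in% ppb_elements) "ug/kg" else "mg/kg"
    }
    tibble(sample_id = samples, compartment = compartment,
           element = el, value = lst[[el]], unit = unit)
  })
}

conc <- bind_rows(block(raw, "raw"), block(ash, "ash"), block(water, "water")) |>
  left_join(mutate(low_confidence, low_confidence = TRUE),
            by = c("sample_id", "compartment", "element")) |>
  mutate(low_confidence = coalesce(low_confidence, FALSE)) |>
  arrange(factor(compartment, c("raw", "ash", "water")),
          factor(sample_id, samples), element)

write_csv(conc, "inst/extdata/tobacco_concentrations.csv")

write_csv(tibble(
  sample_id = samples,
  tobacco_type = c("maassel", "maassel", "maassel", "traditional", "traditional"),
  label = c("Apple", "Blueberry", "Orange", "Khansar", "Borazjan")
), "inst/extdata/sample_meta.csv")

# Inhalation reference doses (mg/kg/day) and cancer slope factors
# ((mg/kg/day)^-1); empty slope_factor = no published value ("ND").
write_csv(tribble(
  ~element, ~rfd_mg_kg_day, ~slope_factor,
  "As", 0.00012,   150,
  "Cd", 0.00001,   6.3,
  "Co", 0.0000057, 9.8,
  "Cr", 0.00028,   41,
  "Cu", 0.004,     NA,
  "Hg", 0.000086,  NA,
  "Ni", 0.02,      NA,
  "Pb", 0.0035,    0.042,
  "Zn", 0.3,       1.5
), "inst/extdata/toxicity_references.csv")

# Instrument LODs (ug/L in the measured solution).
write_csv(tribble(
  ~element, ~lod_ug_l,
  "Al", 0.01,  "As", 0.007, "B", 0.2,   "Ba", 0.01, "Ca", 0.1,
  "Cd", 0.01,  "Ce", 0.01,  "Co", 0.1,  "Cr", 0.1,  "Cu", 0.01,
  "Fe", 4.1,   "Hg", 0.03,  "K", 0.5,   "Mg", 0.01, "Mn", 0.4,
  "Mo", 0.01,  "Na", 0.01,  "Ni", 0.02, "P", 43,    "Pb", 0.02,
  "S", 8.1,    "Sb", 0.02,  "Se", 0.4,  "Si", 6.1,  "Sn", 0.02,
  "Sr", 0.01,  "Ti", 0.02,  "V", 0.02,  "Zn", 40.1
), "inst/extdata/instrument_lods.csv")

# Example session/exposure configs. These are labelled assumptions: the study
# protocol does not report ash yield, bowl-water volume, tobacco charge or an
# exposure scenario, so the pipeline requires them as explicit inputs.
writeLines(c(
  "# Example smoking-session partition parameters (assumed, not measured):",
  "# ash_yield         mass fraction of the charge left as ash after burning",
  "# water_volume_l    bowl water volume per session (L)",
  "# tobacco_mass_kg   tobacco charge per session (kg)",
  "ash_yield: 0.25",
  "water_volume_l: 0.8",
  "tobacco_mass_kg: 0.015"
), "inst/extdata/example_partition_params.yaml")

writeLines(c(
  "# Example chronic exposure scenario (assumed, not from the study):",
  "# a daily waterpipe user consuming 10 g tobacco/day over 30 years,",
  "# 70 kg body weight, risks averaged over a 70-year lifetime (in days).",
  "IR_kg_per_day: 0.01",
  "EF_days_per_year: 365",
  "ED_years: 30",
  "BW_kg: 70",
  "AT_days: 25550"
), "inst/extdata/example_scenario.yaml")

message("fixtures written")
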