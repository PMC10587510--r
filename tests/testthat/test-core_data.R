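test_that("censored tokens parse into the three states and round-trip", {
  p <- parse_censored(c("<50", "221", "*****", "", "17,214", "<0.5"))
  expect_equal(p$state,
               c("censored", "observed", "missing", "missing", "observed",
                 "censored"))
  expect_equal(p$value, c(50, 221, NA, NA, 17214, 0.5))

  # round trip over every state
  tokens <- format_censored(p$state, p$value)
  p2 <- parse_censored(tokens)
  expect_equal(p2$state, p$state)
  expect_equal(p2$value, p$value)
})

test_that("garbage and negative cells are rejected with the offending token", {
  expect_error(parse_censored(c("221", "n.d.")), "n\\.d\\.")
  expect_error(parse_censored("-3"), "Negative")
})

test_that("unit normalization converts micrograms, preserves censoring, and is idempotent", {
  tbl <- tibble::tibble(
    sample_id = "s1",
    compartment = c("raw", "raw", "water", "water"),
    element = c("Cd", "As", "As", "Ca"),
    state = c("observed", "censored", "observed", "observed"),
    value = c(221, 50, 367, 5.2),
    unit = c("ug/kg", "ug/kg", "ug/L", "mg/L")
  )
  norm <- normalize_units(tbl)
  expect_equal(norm$value, c(0.221, 0.05, 0.367, 5.2))
  expect_equal(norm$unit, c("mg/kg", "mg/kg", "mg/L", "mg/L"))
  expect_equal(norm$state, tbl$state)
  expect_identical(normalize_units(norm), norm)

  expect_error(normalize_units(dplyr::mutate(tbl, unit = "mol/L")), "Unknown unit")
  expect_error(
    normalize_units(dplyr::mutate(tbl, unit = c("mg/L", "mg/kg", "ug/L", "mg/L"))),
    "mismatch")
})

test_that("ppm/ppb aliases resolve by compartment", {
  tbl <- tibble::tibble(
    sample_id = "s1", compartment = c("raw", "water"),
    element = c("Ca", "Ca"), state = "observed",
    value = c(100, 100), unit = c("ppb", "ppm")
  )
  norm <- normalize_units(tbl)
  expect_equal(norm$value, c(0.1, 100))
  expect_equal(norm$unit, c("mg/kg", "mg/L"))
})

test_that("substitution policies honour state and dominate element-wise", {
  tbl <- tibble::tibble(
    state = c("observed", "censored", "missing"),
    value = c(221, 50, NA)
  )
  expect_equal(substitute_censored(tbl, "zero")$concentration, c(221, 0, NA))
  expect_equal(substitute_censored(tbl, "half_lod")$concentration, c(221, 25, NA))
  expect_equal(substitute_censored(tbl, "lod")$concentration, c(221, 50, NA))

  # property: lod >= half_lod >= zero element-wise on random censored tables
  withr::with_seed(99, {
    for (i in 1:10) {
      rnd <- tibble::tibble(
        state = sample(c("observed", "censored"), 30, replace = TRUE),
        value = stats::runif(30, 0, 10)
      )
      z <- substitute_censored(rnd, "zero")$concentration
      h <- substitute_censored(rnd, "half_lod")$concentration
      l <- substitute_censored(rnd, "lod")$concentration
      expect_true(all(l >= h & h >= z))
    }
  })
})

test_that("the bundled study table loads with the expected shape and values", {
  conc <- fixture_conc()
  expect_s3_class(conc, "hookah_conc")
  expect_equal(nrow(conc), 5 * 29 * 3)
  expect_equal(dplyr::n_distinct(conc$sample_id), 5)
  expect_equal(sort(unique(conc$compartment)), sort(c("raw", "ash", "water")))
  raw <- dplyr::filter(conc, compartment == "raw")
  expect_equal(nrow(raw), 5 * 29)

  # ppb columns arrive on the mg/kg scale
  apple_as <- dplyr::filter(raw, sample_id == "apple", element == "As")
  expect_equal(apple_as$value, 0.066)
  apple_cd <- dplyr::filter(raw, sample_id == "apple", element == "Cd")
  expect_equal(apple_cd$value, 0.221)
  # the missing water sulfur determinations survive as missing
  s_water <- dplyr::filter(conc, compartment == "water", element == "S")
  expect_true(all(s_water$state == "missing"))
})

test_that("schema violations are rejected", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,compartment,element,value,unit", empty)
  expect_error(suppressMessages(read_concentration_table(empty)), "empty")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,compartment,element,value,unit",
               "apple,raw,Cd,221,ug/kg",
               "apple,raw,Cd,200,ug/kg"), dup)
  expect_error(suppressMessages(read_concentration_table(dup)),
               "apple/raw/Cd")

  alien <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,compartment,element,value,unit",
               "apple,raw,Xx,1,mg/kg"), alien)
  expect_error(suppressMessages(read_concentration_table(alien)), "Xx")
})

test_that("wide schema with a unit declaration row reads like long schema", {
  wide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,compartment,Ca,Cd,As",
               "#units,,mg/kg,ug/kg,ug/kg",
               "apple,raw,17214,221,66",
               "apple,ash,20890,406,<50"), wide)
  tbl <- suppressMessages(read_concentration_table(wide, schema = "wide"))
  expect_equal(nrow(tbl), 6)
  cd <- dplyr::filter(tbl, element == "Cd", compartment == "raw")
  expect_equal(cd$value, 0.221)
  as_ash <- dplyr::filter(tbl, element == "As", compartment == "ash")
  expect_equal(as_ash$state, "censored")
  expect_equal(as_ash$value, 0.05)
})

test_that("write -> read round-trips a concentration table", {
  conc <- fixture_conc()
  path <- withr::local_tempfile(fileext = ".csv")
  write_concentration_table(conc, path)
  back <- suppressMessages(read_concentration_table(path))
  expect_equal(as.data.frame(back), as.data.frame(conc))
})

test_that("toxicity references carry reference doses and slope factors", {
  tox <- fixture_tox()
  expect_equal(nrow(tox), 9)
  as_row <- dplyr::filter(tox, element == "As")
  expect_equal(as_row$rfd_mg_kg_day, 0.00012)
  expect_equal(as_row$slope_factor, 150)
  zn_row <- dplyr::filter(tox, element == "Zn")
  expect_equal(zn_row$rfd_mg_kg_day, 0.3)
  expect_equal(zn_row$slope_factor, 1.5)
  # no slope factor published for Cu, Hg, Ni
  expect_true(all(is.na(tox$slope_factor[tox$element %in% c("Cu", "Hg", "Ni")])))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("element,rfd_mg_kg_day,slope_factor", "As,-1,150"), bad)
  expect_error(read_toxicity_references(bad), "positive")
})

test_that("validation reports and YAML configs load", {
  conc <- fixture_conc()
  expect_message(validate_concentration_table(conc), "Valid concentration table")
  params <- example_params()
  expect_s3_class(params, "partition_params")
  expect_equal(params$ash_yield, 0.25)
  sc <- example_scenario()
  expect_s3_class(sc, "exposure_scenario")
  expect_equal(sc$AT_days, 25550)
})
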