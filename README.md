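# hookahrisk

Waterpipe (hookah) smoking delivers metals: whatever share of an element's
mass in the tobacco charge does not stay in the ash or dissolve into the
bowl water leaves with the smoke. `hookahrisk` is an R package for analysts
working with multi-element (ICP-MS style) concentration panels on hookah
tobacco and its combustion compartments. It turns left-censored
concentration tables into composition shares, a per-session elemental mass
balance, and chronic inhalation risk indices, and ships a seeded
synthetic-study generator so that every stage of the pipeline is testable
without laboratory data.

The core quantities, in the field's standard notation:

- **Main-element share**: `100 · Σ_{e∈{Ca,K,Na,Mg,P}} c_e / Σ_all c_e`
  per sample and compartment, on mg/kg (solids) or mg/L (water)
  concentrations, censored cells substituted by policy (`zero`, `half_lod`,
  `lod`).
- **Session mass balance**: raw burden = `c_raw · m_tobacco`; ash burden =
  `c_ash · y_ash · m_tobacco`; water burden = `c_water · V_water`; smoke
  share = `100 · (raw − ash − water) / raw`, clipped into [0, 100] and
  flagged when noise pushes it outside.
- **Risk**: `CDI = CF·IR·EF·ED / (BW·AT)` (mg/kg/day), `HQ = CDI/RfD`
  (flag at HQ ≥ 1), `CR = CDI·CSF`, banded `negligible (≤ 1e−6)` /
  `tolerable` / `high (> 1e−4)`.
- **Group comparison**: a Friedman rank test implemented from first
  principles (mid-ranks, the standard tie correction
  `1 − Σ(t³−t)/(n(k³−k))`, exact permutation p-values by enumerating all
  `(k!)ⁿ` rank orders when `n·k ≤ 12`), plus an exact rank-sum contrast of
  traditional vs flavored (Maassel) tobaccos at α = 0.10.

Bundled under `inst/extdata/` are plain-text transcriptions of a published
five-tobacco study (raw/ash/water concentrations for 29 elements, with
`"<LOD"` censoring and `"*****"` missing markers preserved), a
toxicity-reference table (inhalation RfDs and cancer slope factors), the
instrument detection limits, and example YAML configs for the session
parameters and the exposure scenario — both of which are deliberately
mandatory inputs, because the study reports neither.

## Worked example

```r
library(hookahrisk)
library(dplyr)

conc <- read_concentration_table(hookah_example("tobacco_concentrations.csv"))
#> Read 435 records: 5 samples x 29 elements x 3 compartments

composition_profile(conc, policy = "zero", fractions = FALSE) |>
  filter(compartment == "ash") |>
  mutate(main_share = round_half_up(main_share, 1))
#> # A tibble: 5 × 4
#>   sample_id compartment   total main_share
#>   <chr>     <chr>         <dbl>      <dbl>
#> 1 apple     ash          48714.       97.6
#> 2 blueberry ash          28198.       96.7
#> 3 borazjan  ash         205724.       97.7
#> 4 khansar   ash         159606.       97.4
#> 5 orange    ash          51798.       97.3
```

The `total` column is the 29-element panel sum (mg/kg of ash) and
`main_share` the percentage held by Ca, K, Na, Mg and P — the five values
match the study's reported ash shares digit for digit.

```r
params <- read_partition_params(hookah_example("example_partition_params.yaml"))
pt <- partition_table(conc, params, policy = "zero")
#> Skipping 25 (sample, element) row(s) with missing or zero raw burden: ...
glance(pt)
#> # A tibble: 5 × 5
#>   sample_id n_elements smoke_percent_min smoke_percent_max n_clipped
#>   <chr>          <int>             <dbl>             <dbl>     <int>
#> 1 apple             25                 0             100          12
#> 2 blueberry         21                 0             100          14
#> 3 borazjan          27                 0             100          10
#> 4 khansar           27                 0              93.9         9
#> 5 orange            20                 0              94.2        16
```

Each row summarises the element-wise smoke percentages of one tobacco under
the *assumed* example session (ash yield 0.25, 0.8 L bowl water, 15 g
charge); `n_clipped` counts cells where the by-difference share fell outside
[0, 100] and was clipped — with only the printed concentration tables and
assumed session parameters, many cells are at the bounds, which is exactly
why those parameters are explicit inputs rather than defaults.

```r
tox <- read_toxicity_references(hookah_example("toxicity_references.csv"))
sc  <- read_exposure_scenario(hookah_example("example_scenario.yaml"))
risk_table(conc, tox, sc, source = "smoke", partition = pt) |>
  filter(element == "As")
#> # A tibble: 4 × 8
#>   sample_id element    cf       cdi    hq hazard_flag      cr band
#>   <chr>     <chr>   <dbl>     <dbl> <dbl> <lgl>         <dbl> <chr>
#> 1 apple     As      0     0         0     FALSE       0       negligible
#> 2 borazjan  As      0.237 0.0000145 0.121 FALSE       0.00218 high
#> 3 khansar   As      0.383 0.0000234 0.195 FALSE       0.00352 high
#> 4 orange    As      0     0         0     FALSE       0       negligible
```

For the traditional tobaccos, smoke-borne arsenic under a 10 g/day scenario
sits in the `high` cancer-risk band (CR > 10⁻⁴) even though the noncancer
hazard quotient stays below 1; apple and orange collapse to zero here
because their smoke share of As clipped to 0 under these session
assumptions, and blueberry's censored raw As is skipped by the zero policy
rather than divided by.

`compare_conditions(conc, read_sample_meta(hookah_example("sample_meta.csv")))`
adds the per-element Friedman raw-vs-ash and traditional-vs-Maassel
verdicts, and `autoplot()` methods draw the composition bars, the
smoke-percentage heatmap and the cancer-risk bands.

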