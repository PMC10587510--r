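# Independent oracles and small fixture builders used across the suite.

# All k! permutations of 1:k, built by filtering the full k^k grid --
# deliberately different code from the package's recursive generator.
oracle_perms <- function(k) {
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(k)), k)))
  grid[apply(grid, 1, function(r) length(unique(r)) == k), , drop = FALSE]
}

# Uncorrected Friedman statistic straight from the definition, given a
# rank matrix (blocks x treatments).
oracle_q_from_ranks <- function(ranks) {
  n <- nrow(ranks)
  k <- ncol(ranks)
  rj <- colSums(ranks)
  12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
}

# Exact permutation p-value by enumerating every combination of
# within-block rank orders ((k!)^n tables) and taking the tail fraction.
oracle_exact_p <- function(q_obs, n, k) {
  perms <- oracle_perms(k)
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(nrow(perms))), n)))
  qs <- apply(idx, 1, function(ix) {
    oracle_q_from_ranks(perms[ix, , drop = FALSE])
  })
  mean(qs >= q_obs - 1e-9)
}

# Small in-memory long-format concentration table (already normalized
# units) built from a named list element -> value token.
make_conc <- function(values, sample_id = "s1", compartment = "raw") {
  unit <- if (compartment == "water") "mg/L" else "mg/kg"
  as_concentration_table(tibble::tibble(
    sample_id = sample_id, compartment = compartment,
    element = names(values), value = unname(unlist(values)), unit = unit
  ))
}

fixture_conc <- function() {
  suppressMessages(read_concentration_table(
    hookah_example("tobacco_concentrations.csv")))
}

fixture_meta <- function() {
  read_sample_meta(hookah_example("sample_meta.csv"))
}

fixture_tox <- function() {
  read_toxicity_references(hookah_example("toxicity_references.csv"))
}

example_scenario <- function() {
  read_exposure_scenario(hookah_example("example_scenario.yaml"))
}

example_params <- function() {
  read_partition_params(hookah_example("example_partition_params.yaml"))
}
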