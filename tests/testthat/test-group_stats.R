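test_that("a consistently ordered 3x3 design gives Q = 6", {
  m <- rbind(c(1, 2, 3), c(10, 20, 30), c(0.1, 0.5, 0.9))
  st <- friedman_statistic(m)
  expect_equal(st$statistic, 6)  # ranks (1,2,3) in every block, R = (3,6,9)
  expect_equal(st$df, 2)
  expect_false(st$degenerate)
  expect_equal(friedman_pvalue(6, 2), 0.0498, tolerance = 1e-3)
})

test_that("identical columns collapse to a degenerate zero statistic", {
  m <- matrix(5, nrow = 3, ncol = 3)
  st <- friedman_statistic(m)
  expect_equal(st$statistic, 0)
  expect_true(st$degenerate)
  ft <- friedman_rank_test(m)
  expect_equal(ft$p.value, 1)
})

test_that("the statistic matches stats::friedman.test on tie-free designs", {
  withr::with_seed(21, {
    for (dims in list(c(3, 3), c(5, 2), c(5, 4), c(8, 3))) {
      m <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
      ours <- friedman_statistic(m)
      ref <- stats::friedman.test(m)
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$df, unname(ref$parameter))
      expect_equal(friedman_pvalue(ours$statistic, ours$df), ref$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("on tie-free designs the corrected statistic equals the raw formula", {
  withr::with_seed(33, {
    for (i in 1:5) {
      m <- matrix(stats::rnorm(12), 4, 3)
      ranks <- t(apply(m, 1, rank))
      expect_equal(friedman_statistic(m)$statistic,
                   oracle_q_from_ranks(ranks), tolerance = 1e-12)
    }
  })
})

test_that("ties get mid-ranks with the standard correction", {
  # one tied pair in one of three 3-treatment blocks:
  # correction = 1 - (2^3 - 2) / (3 * (27 - 3)) = 11/12
  m <- rbind(c(1, 1, 2), c(1, 2, 3), c(1, 2, 3))
  ranks <- t(apply(m, 1, rank))
  expected <- oracle_q_from_ranks(ranks) / (1 - 6 / (3 * 24))
  expect_equal(friedman_statistic(m)$statistic, expected, tolerance = 1e-12)
})

test_that("exact p-values equal the brute-force permutation oracle", {
  withr::with_seed(55, {
    designs <- list(
      matrix(stats::rnorm(6), 2, 3),     # 36 rank tables
      matrix(stats::rnorm(9), 3, 3),
      matrix(stats::rnorm(12), 4, 3),
      matrix(stats::rnorm(10), 5, 2),
      matrix(stats::rnorm(8), 2, 4)
    )
    for (m in designs) {
      st <- friedman_statistic(m)
      p_pkg <- friedman_pvalue(st$statistic, st$df, method = "exact",
                               n = st$n)
      p_bf <- oracle_exact_p(st$statistic, st$n, st$k)
      expect_equal(p_pkg, p_bf, tolerance = 1e-12)
    }
  })
  expect_error(friedman_pvalue(1, 3, method = "exact", n = 10), "chisq")
})

test_that("two-treatment designs reduce to sign-test behaviour", {
  # all 5 blocks agree on the order: the most extreme 5x2 table
  m <- cbind(1:5, (1:5) + 1)
  st <- friedman_statistic(m)
  expect_equal(st$statistic, 5)  # R = (5, 10)
  p <- friedman_pvalue(st$statistic, st$df, method = "exact", n = 5)
  expect_equal(p, 2 / 32)  # two one-sided extremes of 2^5 orderings
  expect_equal(p, oracle_exact_p(st$statistic, 5, 2), tolerance = 1e-12)
})

test_that("the statistic is invariant to within-block monotone transforms", {
  withr::with_seed(77, {
    m <- matrix(stats::rlnorm(15), 5, 3)
    q0 <- friedman_statistic(m)$statistic
    expect_equal(friedman_statistic(log(m))$statistic, q0)
    expect_equal(friedman_statistic(m^3)$statistic, q0)
    expect_equal(friedman_statistic(sweep(m, 1, 1:5, "*"))$statistic, q0)
  })
})

test_that("chi-square tail probabilities track the exact tail", {
  # the approximation is reliable in the rejection region; mid-distribution
  # the discrete exact law sits well above it on designs this small
  withr::with_seed(91, {
    for (i in 1:20) {
      m <- matrix(stats::rnorm(12), 4, 3)
      st <- friedman_statistic(m)
      pe <- friedman_pvalue(st$statistic, st$df, "exact", n = 4)
      pc <- friedman_pvalue(st$statistic, st$df, "chisq")
      if (pe <= 0.125) expect_lt(abs(pe - pc), 0.05)
    }
  })
  # spot checks at the decision boundary
  expect_lt(abs(friedman_pvalue(6, 2, "exact", n = 4) -
                  friedman_pvalue(6, 2, "chisq")), 0.05)
})

test_that("the tidy front-end accepts long data and supports tidy()/glance()", {
  d <- tidyr::expand_grid(block = paste0("b", 1:3),
                          treatment = c("t1", "t2", "t3"))
  d$value <- rep(c(1, 2, 3), times = 3)
  ft <- friedman_rank_test(d, value, treatment, block)
  expect_equal(ft$statistic, 6)
  expect_equal(ft$method, "exact")
  td <- tidy(ft)
  expect_equal(td$statistic, 6)
  expect_equal(glance(ft)$n_blocks, 3)
})

test_that("identical samples give null verdicts everywhere", {
  one <- c(Ca = "100", Fe = "10", Cd = "1")
  tbl <- dplyr::bind_rows(lapply(c("m1", "m2", "t1", "t2"), function(s) {
    dplyr::bind_rows(
      make_conc(as.list(one), sample_id = s, compartment = "raw"),
      make_conc(as.list(one), sample_id = s, compartment = "ash")
    )
  }))
  meta <- tibble::tibble(sample_id = c("m1", "m2", "t1", "t2"),
                         tobacco_type = c("maassel", "maassel",
                                          "traditional", "traditional"),
                         label = sample_id)
  v <- compare_conditions(tbl, meta)
  expect_equal(nrow(v), 4)  # 3 elements + total row
  expect_true(all(v$p_time == 1))
  expect_true(all(v$p_type == 1))
  expect_true(all(v$direction_time == "none"))
  expect_true(all(v$direction_type == "none"))
})

test_that("a planted 5x type effect is flagged traditional > maassel", {
  cfg <- simulate_config(seed = 314, type_effect = c(Na = 5))
  study <- simulate_hookah_study(cfg)
  v <- compare_conditions(study$concentrations, study$meta, alpha = 0.10)
  na_row <- dplyr::filter(v, element == "Na")
  expect_equal(na_row$direction_type, "traditional>maassel")
  expect_lte(na_row$p_type, 0.10)
})

test_that("undersized type groups are skipped with a warning", {
  cfg <- simulate_config(seed = 3, n_per_type = 2)
  study <- simulate_hookah_study(cfg)
  meta <- dplyr::filter(study$meta, sample_id != "traditional_02")
  conc <- dplyr::filter(study$concentrations,
                        sample_id %in% meta$sample_id)
  expect_warning(v <- compare_conditions(conc, meta), "fewer than 2")
  expect_true(all(is.na(v$p_type)))
  expect_false(all(is.na(v$p_time)))
})

test_that("the study fixture yields a full verdict table with a total row", {
  v <- compare_conditions(fixture_conc(), fixture_meta())
  expect_equal(nrow(v), 30)
  expect_equal(v$element[30], "Total concentration")
  expect_true(all(v$p_time >= 0 & v$p_time <= 1, na.rm = TRUE))
})
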