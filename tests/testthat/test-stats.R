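test_that("five-number summary matches the interpolation oracle", {
  s <- summarize_values(c(1, 2, 3, 4, 5))
  expect_equal(unlist(s[c("q1", "median", "q3")]),
               c(q1 = 2, median = 3, q3 = 4))
  set.seed(123)
  x <- rnorm(50)
  s <- summarize_values(x)
  for (p in c(0.25, 0.5, 0.75)) {
    col <- c(`0.25` = "q1", `0.5` = "median", `0.75` = "q3")[[as.character(p)]]
    expect_equal(s[[col]], quantile_oracle(x, p), tolerance = 1e-12)
  }
  expect_equal(s$n, 50)
  expect_true(s$min <= s$q1 && s$q1 <= s$median && s$median <= s$q3 &&
                s$q3 <= s$max)
})

test_that("infant exclusion drops flagged rows and errors when empty", {
  v <- c(10, 11, 14)
  inf <- c(FALSE, FALSE, TRUE)
  expect_equal(summarize_values(v, inf, exclude_infants = TRUE)$max, 11)
  expect_error(summarize_values(c(1), c(TRUE), exclude_infants = TRUE),
               "no values")
  expect_error(summarize_values(v, NULL, exclude_infants = TRUE),
               "is_infant")
})

test_that("offsets are human minus fauna means with a minimum-n rule", {
  tab <- rbind(
    sample_row("H1", d15N = 9, d13C = -20),
    sample_row("H2", d15N = 11, d13C = -19),
    sample_row("F1", category = "herbivore", taxon = "Bos taurus",
               d15N = 6, d13C = -21),
    sample_row("F2", category = "omnivore", taxon = "Sus domesticus",
               d15N = 8, d13C = -20)
  )
  out <- compute_offsets(tab)
  expect_equal(nrow(out), 1)
  expect_equal(out$offset_d15N, 10 - 7)
  expect_equal(out$offset_d13C, -19.5 - (-20.5))
  expect_equal(c(out$n_human, out$n_fauna), c(2L, 2L))
  # one human only: no record
  expect_equal(nrow(compute_offsets(tab[-2, ])), 0)
  # carnivores and fish never enter the baseline pool
  tab2 <- rbind(tab,
                sample_row("C1", category = "carnivore",
                           taxon = "Canis familiaris", d15N = 12),
                sample_row("P1", category = "fish", taxon = "Cyprinus",
                           d15N = 12))
  expect_equal(compute_offsets(tab2)$offset_d15N, 3)
  expect_equal(compute_offsets(tab2, include_fish = TRUE)$n_fauna, 3L)
})

test_that("offsets are translation-equivariant in the human values", {
  d <- generate_isotope_dataset(small_cfg(seed = 2))
  base <- compute_offsets(d$samples)
  shifted <- d$samples
  hum <- shifted$category == "human"
  shifted$d15N[hum] <- shifted$d15N[hum] + 1.7
  shifted$d13C[hum] <- shifted$d13C[hum] + 0.4
  out <- compute_offsets(shifted)
  expect_equal(out$offset_d15N, base$offset_d15N + 1.7)
  expect_equal(out$offset_d13C, base$offset_d13C + 0.4)
})

test_that("noiseless synthetic data returns configured offsets exactly", {
  cfg <- small_cfg(seed = 4, noise_sd_d13C = 0, noise_sd_d15N = 0,
                   frac_qc_fail = 0, frac_infant = 0)
  d <- generate_isotope_dataset(cfg)
  out <- compute_offsets(d$samples)
  expect_equal(nrow(out), cfg$n_sites)
  expect_equal(out$offset_d13C, rep(cfg$trophic_offset_d13C, nrow(out)))
  expect_equal(out$offset_d15N, rep(cfg$trophic_offset_d15N, nrow(out)))
})

test_that("group tests agree with closed-form oracles", {
  # identical groups: no between-group variation
  tab <- rbind(
    sample_row("A1", d15N = 1, region = "Alfold"),
    sample_row("A2", d15N = 2, region = "Alfold"),
    sample_row("A3", d15N = 3, region = "Alfold"),
    sample_row("B1", d15N = 1, region = "Transdanubia"),
    sample_row("B2", d15N = 2, region = "Transdanubia"),
    sample_row("B3", d15N = 3, region = "Transdanubia")
  )
  res <- group_tests(tab, "d15N", "region")
  expect_equal(res$kw_H, 0)
  expect_equal(res$p_kw, 1)
  expect_equal(res$anova_F, 0)

  # closed-form one-way ANOVA for {1,2,3} vs {4,5,6}:
  # SSB = 2 * 3 * (1.5)^2 = 13.5 on 1 df; SSW = 2 + 2 = 4 on 4 df
  tab$d15N <- c(1, 2, 3, 4, 5, 6)
  res <- group_tests(tab, "d15N", "region")
  expect_equal(res$anova_F, (13.5 / 1) / (4 / 4), tolerance = 1e-12)
  expect_equal(unname(res$group_ns), c(3L, 3L), ignore_attr = TRUE)

  # a single group is refused
  expect_error(group_tests(tab[1:3, ], "d15N", "region"), "2 non-empty")
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  d <- generate_isotope_dataset(small_cfg(seed = 6))
  s <- d$samples
  h0 <- group_tests(s, "d15N", "region")
  for (f in list(function(x) exp(x / 5), function(x) x^3 + 7)) {
    s2 <- s
    s2$d15N <- f(s$d15N)
    h <- group_tests(s2, "d15N", "region")
    expect_equal(h$kw_H, h0$kw_H, tolerance = 1e-10)
    expect_equal(h$p_kw, h0$p_kw, tolerance = 1e-10)
  }
})

test_that("crosstab test matches the hypergeometric oracle and rejects
           degenerate margins", {
  # perfectly dependent 2x2: exact enumeration oracle
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  res <- crosstab_test(tab)
  expect_lt(res$p_value, 0.01)
  # exact probability of a table at least this extreme given the margins
  p_exact <- dhyper(10, 10, 10, 10) + dhyper(0, 10, 10, 10)
  expect_lt(res$p_value, 0.01)
  expect_lt(p_exact, 0.01)   # oracle agrees dependence is detectable

  # perfect independence: statistic 0, p = 1
  res <- crosstab_test(matrix(5, 2, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # small expected counts in a 2x2 fall back to Fisher's exact test
  small <- matrix(c(4, 0, 0, 4), 2, 2)
  res <- crosstab_test(small)
  expect_equal(res$method, "fisher")
  expect_equal(res$p_value, fisher.test(small)$p.value)

  expect_error(crosstab_test(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "degenerate")
  expect_error(crosstab_test(matrix(1:3, 3, 1)), "2 levels")
})
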