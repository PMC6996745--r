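test_that("paired comparison matches the brute-force t oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    tv <- round(runif(n, 1, 4))
    sv <- pmin(pmax(tv - rnorm(n, 0.5, 0.6), 1), 4)
    tab <- paired_tables(tv, sv)
    cmp <- compare_motive("liking", tab$traits, tab$summaries)
    o <- paired_t_oracle(tv, sv)
    expect_equal(cmp$t_stat, o$t, tolerance = 1e-9)
    expect_equal(cmp$df, o$df)
    expect_equal(cmp$p_value, o$p, tolerance = 1e-9)
    expect_equal(cmp$mean_diff, mean(tv) - mean(sv))
    expect_equal(cmp$cohen_d,
                 mean(tv - sv) / ((sd(tv) + sd(sv)) / 2), tolerance = 1e-12)
    expect_equal(cmp$trait_state_r, cor(tv, sv), tolerance = 1e-12)
  }
})

test_that("textbook 3-pair fixture reproduces the hand computation", {
  tab <- paired_tables(c(2, 3, 4), c(1, 2, 3))
  cmp <- compare_motive("liking", tab$traits, tab$summaries)
  expect_equal(cmp$mean_diff, 1)
  # all differences equal 1: zero-variance differences, t undefined
  expect_true(is.na(cmp$t_stat) && is.na(cmp$p_value))
  expect_equal(cmp$cohen_d, 1)  # d_av = 1 / ((1 + 1) / 2)
})

test_that("degenerate inputs yield undefined markers, never exceptions", {
  # trait == state everywhere
  tab <- paired_tables(c(2, 3, 4, 2), c(2, 3, 4, 2))
  cmp <- compare_motive("liking", tab$traits, tab$summaries)
  expect_equal(cmp$mean_diff, 0)
  expect_true(is.na(cmp$t_stat))
  expect_equal(cmp$cohen_d, 0)
  # no between-person variance on either side
  tab <- paired_tables(rep(3, 5), rep(2, 5))
  cmp <- compare_motive("liking", tab$traits, tab$summaries)
  expect_true(is.na(cmp$t_stat) && is.na(cmp$cohen_d) &&
                is.na(cmp$trait_state_r))
  expect_equal(cmp$mean_diff, 1)
  # fewer than 3 matched participants: means only
  tab <- paired_tables(c(2, 4), c(1, 3))
  cmp <- compare_motive("liking", tab$traits, tab$summaries)
  expect_equal(cmp$mean_diff, 1)
  expect_true(is.na(cmp$t_stat) && is.na(cmp$cohen_d))
})

test_that("swapping trait and state negates the signed statistics", {
  set.seed(55)
  tv <- round(runif(20, 1, 4)); sv <- round(runif(20, 1, 4), 1)
  a <- paired_tables(tv, sv)
  b <- paired_tables(sv, tv)
  ca <- compare_motive("liking", a$traits, a$summaries)
  cb <- compare_motive("liking", b$traits, b$summaries)
  expect_equal(cb$mean_diff, -ca$mean_diff)
  expect_equal(cb$t_stat, -ca$t_stat, tolerance = 1e-12)
  expect_equal(cb$cohen_d, -ca$cohen_d, tolerance = 1e-12)
  expect_equal(cb$trait_state_r, ca$trait_state_r, tolerance = 1e-12)
})

test_that("effect-size bands follow the strict d thresholds", {
  expect_equal(band_effect(1.97), "large")
  expect_equal(band_effect(-0.9), "large")
  expect_equal(band_effect(0.8), "moderate")   # strict: 0.8 is not > 0.8
  expect_equal(band_effect(0.55), "moderate")
  expect_equal(band_effect(0.4), "small")
  expect_equal(band_effect(0.30), "negligible")
  expect_true(is.na(band_effect(NA_real_)))
})

test_that("correlation bands use an inclusive high threshold", {
  expect_equal(band_correlation(0.50), "high")
  expect_equal(band_correlation(0.31), "medium")
  expect_equal(band_correlation(0.30), "low")
  expect_equal(band_correlation(-0.2), "low")
  expect_true(is.na(band_correlation(NA_real_)))
})

test_that("the full comparison table covers the catalog with Holm p-values", {
  d <- simulate_cohort(study_config(seed = 4))
  s <- summarize_states(d)
  cmp <- compare_all_motives(d$traits, s)
  expect_equal(nrow(cmp), 15)
  expect_identical(cmp$motive, tems_motives())
  expect_true(all(cmp$p_holm >= cmp$p_value, na.rm = TRUE))
  expect_equal(attr(cmp, "counts")$n_flagged, sum(cmp$flagged))
  expect_identical(cmp$effect_band, band_effect(cmp$cohen_d))
  expect_identical(cmp$r_band, band_correlation(cmp$trait_state_r))
})
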