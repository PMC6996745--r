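test_that("double-entry ICC matches hand-computed closed-form values", {
  expect_equal(icc_double_entry(c(1, 2, 3), c(1, 2, 3)), 1.0)
  # m = 2, numerator -2, denominator 2
  expect_equal(icc_double_entry(c(1, 2, 3), c(3, 2, 1)), -1.0)
  # m = 3, numerator 4, denominator 6
  expect_equal(icc_double_entry(c(1, 2, 3, 4), c(2, 3, 4, 5)), 2 / 3)
  # both profiles constant at the same value: undefined, not an error
  expect_true(is.na(icc_double_entry(rep(2, 5), rep(2, 5))))
})

test_that("closed-form ICC equals the doubled-Pearson oracle on random pairs", {
  set.seed(42)
  for (i in 1:1000) {
    x <- runif(15, 1, 4)
    y <- runif(15, 1, 4)
    expect_equal(icc_double_entry(x, y), icc_doubled_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("shape similarity is the Pearson correlation of the profiles", {
  x <- c(1, 2, 3, 4)
  expect_equal(shape_similarity(x, x + 0.5), 1.0)
  # covariance 4/3 over sd products sqrt(5/3)*sqrt(5/3) = 0.8
  expect_equal(shape_similarity(x, c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(shape_similarity(rep(2, 4), x)))
})

test_that("scatter and elevation are signed trait-minus-state differences", {
  expect_equal(scatter_similarity(c(1, 3), c(2, 2)), 2.0)
  expect_equal(scatter_similarity(c(1, 3), c(1, 3)), 0.0)
  expect_equal(scatter_similarity(c(2, 2), c(1, 3)),
               -scatter_similarity(c(1, 3), c(2, 2)))
  x <- c(1, 2, 4)
  expect_equal(elevation_similarity(x, x), 0.0)
  expect_equal(elevation_similarity(x + 0.7, x), 0.7)
})

test_that("identical profiles are maximally similar on every index", {
  x <- c(3.5, 2, 1.5, 4, 2.5)
  s <- similarity_profile(x, x)
  expect_equal(s$icc_de, 1.0)
  expect_equal(s$shape_r, 1.0)
  expect_equal(s$scatter_var_d, 0.0)
  expect_equal(s$elevation_m_d, 0.0)
  expect_equal(s$variance_explained_pct, 100.0)
})

test_that("variance explained is the squared ICC on the percent scale", {
  set.seed(7)
  for (i in 1:20) {
    s <- similarity_profile(runif(15, 1, 4), runif(15, 1, 4))
    expect_equal(s$variance_explained_pct, s$icc_de^2 * 100,
                 tolerance = 1e-9)
  }
  # components go undefined independently
  s <- similarity_profile(rep(2, 5), rep(2, 5))
  expect_true(is.na(s$icc_de) && is.na(s$shape_r))
  expect_equal(s$scatter_var_d, 0)
  expect_equal(s$elevation_m_d, 0)
})

test_that("a pure elevation shift leaves shape intact but degrades the ICC", {
  x <- c(1, 1.5, 2, 2.5, 3, 2, 1, 3.5, 2.2, 1.8, 2.7, 1.2, 3.1, 2.9, 1.6)
  iccs <- vapply(c(0, 0.5, 1, 1.5, 2), function(cc) {
    expect_equal(elevation_similarity(x + cc, x), cc)
    expect_equal(shape_similarity(x + cc, x), 1.0)
    icc_double_entry(x + cc, x)
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))
  expect_true(all(abs(iccs) <= 1))
})

test_that("ICC equals shape r when means and variances match", {
  set.seed(13)
  for (i in 1:20) {
    x <- runif(15, 1, 4)
    y <- sample(x)  # same mean, same variance, different shape
    expect_equal(icc_double_entry(x, y), shape_similarity(x, y),
                 tolerance = 1e-10)
  }
})

test_that("a joint positive-scale affine map leaves ICC and shape unchanged", {
  set.seed(99)
  for (i in 1:50) {
    x <- runif(15, 1, 4); y <- runif(15, 1, 4)
    a <- runif(1, -2, 2); b <- runif(1, 0.1, 3)
    expect_equal(icc_double_entry(a + b * x, a + b * y),
                 icc_double_entry(x, y), tolerance = 1e-10)
    expect_equal(shape_similarity(a + b * x, a + b * y),
                 shape_similarity(x, y), tolerance = 1e-10)
  }
})

test_that("the group pair averages person means, not pooled events", {
  # participant a logs 1 event (all 2s), participant b logs 3 events (all 4s)
  tr <- make_traits(c("a", "b"), function(id) rep(if (id == "a") 1 else 3, 15))
  ev <- rbind(make_events("a", matrix(2, 1, 15)),
              make_events("b", matrix(4, 3, 15)))
  d <- cohort_dataset(tr, ev)
  s <- summarize_states(d)
  gp <- between_person_pair(d$traits, s, d$catalog)
  expect_equal(unname(gp$trait["liking"]), 2)     # (1 + 3) / 2
  expect_equal(unname(gp$state["liking"]), 3)     # (2 + 4) / 2, person means
  # brute-force event-pooled mean differs, establishing the convention
  pooled <- mean(d$events$liking)                 # (2 + 4 + 4 + 4) / 4 = 3.5
  expect_false(isTRUE(all.equal(unname(gp$state["liking"]), pooled)))
})

test_that("one participant's group pair is their own profile pair", {
  tr <- make_traits("a", function(id) rep(c(1, 2, 3), 5))
  ev <- make_events("a", rbind(rep(2, 15), rep(3, 15)))
  d <- cohort_dataset(tr, ev)
  s <- summarize_states(d)
  gp <- between_person_pair(d$traits, s, d$catalog)
  wp <- within_person_pairs(d$traits, s, d$catalog)
  expect_equal(gp$trait, wp[["a"]]$trait)
  expect_equal(gp$state, wp[["a"]]$state)
})

test_that("within-person pairs follow trait order and report exclusions", {
  d <- simulate_cohort(simulation_config(n_participants = 5, seed = 21))
  s <- summarize_states(d, min_events = 1)
  wp <- within_person_pairs(d$traits, s, d$catalog)
  expect_identical(names(wp), d$traits$participant_id)
  # drop one participant below threshold
  s2 <- s[s$participant_id != d$traits$participant_id[2], ]
  wp2 <- within_person_pairs(d$traits, s2, d$catalog)
  expect_identical(attr(wp2, "excluded"), d$traits$participant_id[2])
  expect_length(wp2, 4)
  expect_error(between_person_pair(d$traits, s2[0, ], d$catalog),
               "no participant")
})

test_that("the similarity table has a group row plus one row per participant", {
  d <- simulate_cohort(study_config(seed = 1))
  tab <- similarity_table(d)
  expect_equal(nrow(tab), 36)
  expect_equal(tab$level[1], "group")
  expect_true(all(abs(tab$icc_de) <= 1, na.rm = TRUE))
  expect_true(all(abs(tab$shape_r) <= 1, na.rm = TRUE))
})
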