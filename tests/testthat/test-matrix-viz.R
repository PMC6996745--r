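svg_row_labels <- function(svg) {
  m <- gregexpr('text-anchor="end">[^<]+<', svg)[[1]]
  labs <- regmatches(svg, gregexpr('text-anchor="end">[^<]+<', svg))[[1]]
  sub('<$', '', sub('^text-anchor="end">', '', labs))
}

test_that("cell encoding maps ratings, differences and variance as designed", {
  sc <- likert_scale()
  # the worked single-cell example: trait 4.00 vs state 2.40
  e <- encode_cell(4, 2.4, 1.49, sc, max_variance = 2.25)
  expect_equal(e$square_area_fraction, 1.6 / 3, tolerance = 1e-12)
  expect_equal(e$square_hue, "trait")
  expect_equal(e$trait_dash_y, 1)
  expect_equal(e$state_dash_y, 1.4 / 3, tolerance = 1e-12)

  # no difference, no square
  e0 <- encode_cell(3, 3, 0.2, sc, max_variance = 1)
  expect_equal(e0$square_area_fraction, 0)
  expect_equal(e0$square_hue, "none")

  # state higher -> state-dominant hue; shade saturates at max variance
  e1 <- encode_cell(1, 3, 5, sc, max_variance = 2.25)
  expect_equal(e1$square_hue, "state")
  expect_equal(e1$background_shade, 1)
  expect_true(is.na(encode_cell(2, 2, NA, sc, 1)$background_shade))

  # dash positions monotone in the rating; depth increasing with midpoint
  pos <- vapply(1:4, function(v) encode_cell(v, 1, 0, sc, 1)$trait_dash_y,
                numeric(1))
  expect_true(all(diff(pos) > 0))
  expect_equal(encode_cell(1, 1, 0, sc, 1)$square_depth, 0.25)
  expect_equal(encode_cell(4, 4, 0, sc, 1)$square_depth, 1)
})

test_that("distinct integer rating pairs get distinct encodings", {
  grid <- expand.grid(trait = 1:4, state = 1:4)
  keys <- apply(grid, 1, function(g) {
    e <- encode_cell(g["trait"], g["state"], 0.5, likert_scale(), 1)
    paste(e$trait_dash_y, e$state_dash_y, e$square_area_fraction,
          e$square_hue)
  })
  expect_equal(anyDuplicated(keys), 0)
})

test_that("square area grows strictly with the absolute difference", {
  af <- vapply(seq(0, 3, by = 0.5), function(d) {
    encode_cell(1 + d, 1, 0, likert_scale(), 1)$square_area_fraction
  }, numeric(1))
  expect_true(all(diff(af) > 0))
})

test_that("index lightness is light for similar, dark for dissimilar", {
  expect_equal(encode_index("overall", 1), 1)
  expect_equal(encode_index("overall", -1), 0)
  expect_equal(encode_index("shape", 0), 0.5)
  expect_equal(encode_index("elevation", 0), 1)
  expect_equal(encode_index("elevation", 3), 0)   # widest possible M_D
  expect_equal(encode_index("elevation", -1.5), 0.5)
  expect_equal(encode_index("scatter", 2.25), 0)  # max variance of 1-4 scale
  expect_true(is.na(encode_index("scatter", NA)))
})

test_that("rendering is deterministic and row-ordered by overall similarity", {
  d <- simulate_cohort(simulation_config(n_participants = 8, seed = 17))
  svg1 <- render_matrix(d)
  svg2 <- render_matrix(d)
  expect_identical(svg1, svg2)

  labs <- svg_row_labels(svg1)
  expect_equal(labs[1], "average")
  tab <- similarity_table(d)
  p <- tab[tab$level == "participant", ]
  expected <- p$label[order(-p$icc_de, p$label)]
  expect_identical(labs[-1], expected)
  # the ICC sequence down the rows is non-increasing
  expect_true(all(diff(p$icc_de[match(labs[-1], p$label)]) <= 1e-12))

  # alternative ordering key
  labs_id <- svg_row_labels(render_matrix(d, order_by = "id"))
  expect_identical(labs_id[-1], sort(p$label))
})

test_that("a cohort of n participants renders n + 1 rows", {
  d <- simulate_cohort(simulation_config(n_participants = 6, seed = 23))
  svg <- render_matrix(d)
  # one sparkline (2 polylines) per row
  n_poly <- length(gregexpr("<polyline", svg)[[1]])
  expect_equal(n_poly / 2, 7)
  expect_length(svg_row_labels(svg), 7)
})

test_that("file output is byte-stable", {
  d <- simulate_cohort(simulation_config(n_participants = 3, seed = 2))
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_matrix(d, file = f1)
  render_matrix(d, file = f2)
  expect_identical(readLines(f1), readLines(f2))
})
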