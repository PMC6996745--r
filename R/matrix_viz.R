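#' Visual encoding of one motive cell
#'
#' Maps one trait/state motive pair (plus the motive's within-person state
#' variance) to the graphical attributes of a data box in the person x
#' motive matrix: dash positions for the two ratings (0 = cell bottom at
#' the scale minimum, 1 = ceiling at the maximum), a colored
#' difference square whose *area* is proportional to |trait - state|,
#' a square color family indicating which assessment dominates (blue for
#' trait, orange for state), a color depth driven by how pronounced the
#' motive is (the trait/state midpoint, mapped from the scale to
#' [0.25, 1]), and a gray background shade proportional to the state
#' variance relative to `max_variance`.
#'
#' @param trait_value,state_value Ratings on `scale`.
#' @param state_variance Within-person sample variance of the state
#'   ratings; may be `NA` (single event), giving a white background.
#' @param scale A [likert_scale()].
#' @param max_variance Variance mapped to the darkest background.
#' @return A list: `trait_dash_y`, `state_dash_y`, `square_area_fraction`,
#'   `square_hue` (`"trait"`, `"state"` or `"none"`), `square_depth`,
#'   `background_shade` (`NA` when the variance is undefined).
#' @examples
#' encode_cell(4, 2.4, 1.49, likert_scale(), max_variance = 1.5)
#' @export
encode_cell <- function(trait_value, state_value, state_variance,
                        scale = likert_scale(), max_variance = 1) {
  rng <- scale$max_value - scale$min_value
  stopifnot(trait_value >= scale$min_value, trait_value <= scale$max_value,
            state_value >= scale$min_value, state_value <= scale$max_value,
            is.na(state_variance) || state_variance >= 0, max_variance > 0)
  pos <- function(v) (v - scale$min_value) / rng
  diff <- trait_value - state_value
  list(
    trait_dash_y = pos(trait_value),
    state_dash_y = pos(state_value),
    square_area_fraction = abs(diff) / rng,
    square_hue = if (diff > 0) "trait" else if (diff < 0) "state" else "none",
    square_depth = 0.25 +
      0.75 * (mean(c(trait_value, state_value)) - scale$min_value) / rng,
    background_shade = if (is.na(state_variance)) NA_real_ else
      min(state_variance / max_variance, 1))
}

#' Lightness encoding of a similarity-index cell
#'
#' Similarity-index columns are shaded so that lighter means more
#' similar. Correlation-type indices (`"shape"`, `"overall"`) map through
#' `(value + 1) / 2`; difference-type indices map through
#' `1 - min(|value| / range, 1)` with range 3 for `"elevation"` (the
#' widest possible mean difference on a 1-4 scale) and 2.25 for
#' `"scatter"` (the largest possible variance of a bounded 1-4 variable,
#' (4-1)^2 / 4).
#'
#' @param index_name One of `"shape"`, `"elevation"`, `"scatter"`,
#'   `"overall"`.
#' @param value The index value; `NA` gives `NA` (rendered hatched).
#' @return Lightness in `[0, 1]`.
#' @examples
#' encode_index("overall", 1)    # 1, lightest
#' encode_index("elevation", 0)  # 1
#' encode_index("elevation", 3)  # 0, darkest
#' @export
encode_index <- function(index_name, value) {
  index_name <- match.arg(index_name,
                          c("shape", "elevation", "scatter", "overall"))
  if (is.na(value)) return(NA_real_)
  if (index_name %in% c("shape", "overall")) {
    min(max((value + 1) / 2, 0), 1)
  } else {
    rng <- if (index_name == "elevation") 3 else 2.25
    1 - min(abs(value) / rng, 1)
  }
}

# -- SVG helpers --------------------------------------------------------

svg_num <- function(x) sprintf("%.2f", x)

gray_fill <- function(level) {
  v <- as.integer(round(255 * level))
  sprintf("rgb(%d,%d,%d)", v, v, v)
}

# mix a base color with white: depth 1 = full color, 0 = white
family_fill <- function(family, depth) {
  base <- switch(family, trait = c(31, 119, 180), state = c(255, 127, 14))
  v <- as.integer(round(255 + depth * (base - 255)))
  sprintf("rgb(%d,%d,%d)", v[1], v[2], v[3])
}

TRAIT_COL <- "rgb(31,119,180)"
STATE_COL <- "rgb(255,127,14)"

#' Render the person x motive data matrix as SVG
#'
#' Draws the full small-multiples matrix: one row for the "average
#' participant" (group profiles) followed by one row per participant.
#' Columns are (1) a profile sparkline of all 15 motives, (2) the average
#' of the 15 motives, (3-17) the 15 motive data boxes in catalog order,
#' each with trait/state dashes, a difference square and
#' variance-shaded background, and (18-21) the four similarity indices
#' shape r, elevation, scatter, and overall (double-entry ICC), shaded
#' light (similar) to dark (dissimilar). Participant rows are ordered by
#' the chosen key (default: descending overall similarity, ties broken by
#' ascending participant id). Output is plain-text SVG built with fixed
#' number formatting, so identical input yields byte-identical documents.
#'
#' @param dataset A [cohort_dataset()].
#' @param min_events Passed to [summarize_states()].
#' @param order_by Row-ordering key: `"overall"`, `"shape"`,
#'   `"elevation"`, `"scatter"` (similarity keys, descending; the
#'   difference-type keys order by their lightness encoding) or `"id"`
#'   (ascending participant id).
#' @param file Optional path; when given the SVG is written there.
#' @return The SVG document as a single character string (invisibly when
#'   `file` is given).
#' @examples
#' d <- simulate_cohort(simulation_config(n_participants = 3, seed = 4))
#' svg <- render_matrix(d)
#' substr(svg, 1, 60)
#' @export
render_matrix <- function(dataset, min_events = 1,
                          order_by = c("overall", "shape", "elevation",
                                       "scatter", "id"),
                          file = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  order_by <- match.arg(order_by)
  motives <- as.character(dataset$catalog)
  k <- length(motives)
  scale <- dataset$scale

  summaries <- summarize_states(dataset, min_events = min_events)
  sim <- similarity_table(dataset, min_events = min_events)
  gp <- between_person_pair(dataset$traits, summaries, dataset$catalog)
  wp <- within_person_pairs(dataset$traits, summaries, dataset$catalog)
  svm <- if (nrow(summaries)) state_var_matrix(summaries, motives) else NULL
  max_var <- (scale$max_value - scale$min_value)^2 / 4

  psim <- sim[sim$level == "participant", ]
  ids <- psim$label
  if (length(ids)) {
    key <- switch(order_by,
                  overall = psim$icc_de,
                  shape = psim$shape_r,
                  elevation = vapply(psim$elevation_m_d, encode_index,
                                     numeric(1), index_name = "elevation"),
                  scatter = vapply(psim$scatter_var_d, encode_index,
                                   numeric(1), index_name = "scatter"),
                  id = NULL)
    ids <- if (order_by == "id") sort(ids) else
      ids[order(-key, ids, na.last = TRUE)]
  }

  cw <- 26; ch <- 44; gap <- 2; label_w <- 64; spark_w <- 72
  header_h <- 74; legend_h <- 56
  ncol_total <- 2 + k + 4
  width <- label_w + spark_w + gap + (ncol_total - 1) * (cw + gap) + 8
  n_rows <- 1 + length(ids)
  height <- header_h + n_rows * (ch + gap) + legend_h

  out <- c(sprintf(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" ',
    'font-family="Helvetica,sans-serif">'), ceiling(width), height),
    '<rect width="100%" height="100%" fill="white"/>')

  col_x <- function(j) {
    # j = 1 sparkline; j = 2 average; 3..(k+2) motives; (k+3)..(k+6) indices
    if (j == 1) return(label_w)
    label_w + spark_w + gap + (j - 2) * (cw + gap)
  }
  col_w <- function(j) if (j == 1) spark_w else cw

  index_names <- c("shape", "elevation", "scatter", "overall")
  index_titles <- c("shape r", "elev. M_D", "scatter Var_D", "overall ICC")
  headers <- c("profile", "average", motives, index_titles)
  for (j in seq_along(headers)) {
    x <- col_x(j) + col_w(j) / 2
    out <- c(out, sprintf(
      '<text x="%s" y="%d" font-size="8" text-anchor="start" transform="rotate(-45 %s %d)">%s</text>',
      svg_num(x), header_h - 8, svg_num(x), header_h - 8, headers[j]))
  }

  draw_dash <- function(x, w, yfrac, y0, col) {
    y <- y0 + ch - 3 - yfrac * (ch - 6)
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="2"/>',
            svg_num(x + 2), svg_num(y), svg_num(x + w - 2), svg_num(y), col)
  }

  draw_cell <- function(x, y0, enc) {
    s <- character(0)
    bg <- if (is.na(enc$background_shade)) "white" else
      gray_fill(1 - 0.65 * enc$background_shade)
    s <- c(s, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="rgb(200,200,200)" stroke-width="0.5"/>',
      svg_num(x), svg_num(y0), svg_num(cw), svg_num(ch), bg))
    if (is.na(enc$background_shade)) {
      s <- c(s, sprintf(
        '<text x="%s" y="%s" font-size="6" text-anchor="middle" fill="rgb(150,150,150)">var?</text>',
        svg_num(x + cw / 2), svg_num(y0 + 7)))
    }
    if (enc$square_area_fraction > 0) {
      side <- sqrt(enc$square_area_fraction) * (cw - 4)
      ymid <- y0 + ch - 3 -
        (enc$trait_dash_y + enc$state_dash_y) / 2 * (ch - 6)
      s <- c(s, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        svg_num(x + (cw - side) / 2), svg_num(ymid - side / 2),
        svg_num(side), svg_num(side),
        family_fill(enc$square_hue, enc$square_depth)))
    }
    c(s,
      draw_dash(x, cw, enc$trait_dash_y, y0, TRAIT_COL),
      draw_dash(x, cw, enc$state_dash_y, y0, STATE_COL))
  }

  draw_sparkline <- function(x, y0, trait_vec, state_vec) {
    px <- x + 4 + (seq_len(k) - 1) / (k - 1) * (spark_w - 8)
    py <- function(v) y0 + ch - 3 -
      (v - scale$min_value) / (scale$max_value - scale$min_value) * (ch - 6)
    pts <- function(v) paste(sprintf("%s,%s", svg_num(px), svg_num(py(v))),
                             collapse = " ")
    c(sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="white" stroke="rgb(200,200,200)" stroke-width="0.5"/>',
              svg_num(x), svg_num(y0), svg_num(spark_w), svg_num(ch)),
      sprintf('<polyline points="%s" fill="none" stroke="%s" stroke-width="1"/>',
              pts(trait_vec), TRAIT_COL),
      sprintf('<polyline points="%s" fill="none" stroke="%s" stroke-width="1"/>',
              pts(state_vec), STATE_COL))
  }

  draw_index_cell <- function(x, y0, name, value) {
    l <- encode_index(name, value)
    if (is.na(l)) {
      c(sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="white" stroke="rgb(150,150,150)" stroke-width="0.5"/>',
                svg_num(x), svg_num(y0), svg_num(cw), svg_num(ch)),
        sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="rgb(150,150,150)" stroke-width="1"/>',
                svg_num(x), svg_num(y0), svg_num(x + cw), svg_num(y0 + ch)),
        sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="rgb(150,150,150)" stroke-width="1"/>',
                svg_num(x + cw), svg_num(y0), svg_num(x), svg_num(y0 + ch)))
    } else {
      txtcol <- if (l < 0.45) "white" else "rgb(40,40,40)"
      c(sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="rgb(150,150,150)" stroke-width="0.5"/>',
                svg_num(x), svg_num(y0), svg_num(cw), svg_num(ch),
                gray_fill(l)),
        sprintf('<text x="%s" y="%s" font-size="7" text-anchor="middle" fill="%s">%s</text>',
                svg_num(x + cw / 2), svg_num(y0 + ch / 2 + 2), txtcol,
                sprintf("%.2f", value)))
    }
  }

  draw_row <- function(y0, row_label, trait_vec, state_vec, var_vec,
                       sim_row) {
    s <- sprintf(
      '<text x="%d" y="%s" font-size="9" text-anchor="end">%s</text>',
      label_w - 6, svg_num(y0 + ch / 2 + 3), row_label)
    s <- c(s, draw_sparkline(col_x(1), y0, trait_vec, state_vec))
    avg_enc <- encode_cell(mean(trait_vec), mean(state_vec), NA_real_,
                           scale, max_var)
    avg_enc$background_shade <- 0  # plain background for the average box
    s <- c(s, draw_cell(col_x(2), y0, avg_enc))
    for (j in seq_len(k)) {
      enc <- encode_cell(trait_vec[j], state_vec[j], var_vec[j], scale,
                         max_var)
      s <- c(s, draw_cell(col_x(2 + j), y0, enc))
    }
    vals <- c(sim_row$shape_r, sim_row$elevation_m_d,
              sim_row$scatter_var_d, sim_row$icc_de)
    for (j in seq_len(4)) {
      s <- c(s, draw_index_cell(col_x(2 + k + j), y0, index_names[j],
                                vals[j]))
    }
    s
  }

  if (length(ids) == 0 && is.null(svm)) {
    out <- c(out, sprintf(
      '<text x="%d" y="%d" font-size="10" fill="rgb(180,0,0)">No participants to display.</text>',
      label_w, header_h + 20))
  } else {
    y <- header_h
    gsim <- sim[sim$level == "group", ]
    gvar <- colMeans(svm, na.rm = TRUE)
    out <- c(out, draw_row(y, "average", gp$trait, gp$state, gvar, gsim))
    for (id in ids) {
      y <- y + ch + gap
      p <- wp[[id]]
      out <- c(out, draw_row(y, id, p$trait, p$state, svm[id, ],
                             psim[psim$label == id, ]))
    }
  }

  ly <- height - legend_h + 16
  out <- c(out,
    sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="%s" stroke-width="2"/>',
            label_w, ly, label_w + 18, ly, TRAIT_COL),
    sprintf('<text x="%d" y="%d" font-size="8">trait rating</text>',
            label_w + 22, ly + 3),
    sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="%s" stroke-width="2"/>',
            label_w + 90, ly, label_w + 108, ly, STATE_COL),
    sprintf('<text x="%d" y="%d" font-size="8">state mean</text>',
            label_w + 112, ly + 3),
    sprintf(paste0('<text x="%d" y="%d" font-size="8">square area = |trait - state|',
                   ' (blue: trait higher, orange: state higher); ',
                   'gray background = state variance; ',
                   'index columns: light = similar</text>'),
            label_w, ly + 16),
    '</svg>')

  doc <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}
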