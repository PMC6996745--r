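#' The 15 basic eating motives of the single-item TEMS
#'
#' Returns the ordered identifiers of the 15 basic eating motives of The
#' Eating Motivation Survey (TEMS), in the conventional rank order. This
#' ordering is the profile axis used by every analysis and plot in the
#' package.
#'
#' @return A character vector of length 15.
#' @examples
#' tems_motives()
#' @export
tems_motives <- function() {
  c("liking", "habit", "need_and_hunger", "health", "convenience",
    "pleasure", "traditional_eating", "natural_concerns", "sociability",
    "price", "visual_appeal", "weight_control", "affect_regulation",
    "social_norms", "social_image")
}

#' Motive catalog
#'
#' An ordered set of motive identifiers defining the profile axis. The
#' default is the 15 single-item TEMS motives; a custom catalog may be
#' supplied for other instruments, but identifiers must be unique,
#' non-empty, whitespace-free tokens.
#'
#' @param motives Character vector of motive identifiers.
#' @return A character vector with class `motive_catalog`.
#' @examples
#' motive_catalog()
#' length(motive_catalog())
#' @export
motive_catalog <- function(motives = tems_motives()) {
  motives <- as.character(motives)
  if (length(motives) < 2) {
    stop("a motive catalog needs at least 2 motives", call. = FALSE)
  }
  if (anyDuplicated(motives)) {
    stop("motive identifiers must be unique; duplicated: ",
         paste(unique(motives[duplicated(motives)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(motives)) || any(grepl("\\s", motives))) {
    stop("motive identifiers must be non-empty, whitespace-free tokens",
         call. = FALSE)
  }
  structure(motives, class = "motive_catalog")
}

#' Likert rating scale
#'
#' Bounds of the response scale. The study design modeled here uses a
#' 4-point agreement scale, 1 = "strongly disagree" to 4 = "strongly agree".
#'
#' @param min_value Lower scale bound.
#' @param max_value Upper scale bound.
#' @return A list with elements `min_value` and `max_value`, class
#'   `likert_scale`.
#' @examples
#' likert_scale()
#' @export
likert_scale <- function(min_value = 1, max_value = 4) {
  min_value <- as.numeric(min_value)
  max_value <- as.numeric(max_value)
  if (!is.finite(min_value) || !is.finite(max_value) || min_value >= max_value) {
    stop("likert_scale requires finite min_value < max_value", call. = FALSE)
  }
  structure(list(min_value = min_value, max_value = max_value),
            class = "likert_scale")
}

#' @export
print.likert_scale <- function(x, ...) {
  cat(sprintf("<likert_scale [%g, %g]>\n", x$min_value, x$max_value))
  invisible(x)
}

#' Meal-type categories
#'
#' The closed set of participant-identified meal types used to classify
#' eating occasions.
#'
#' @return Character vector of the five meal-type tokens.
#' @export
meal_types <- function() {
  c("breakfast", "lunch", "afternoon_tea", "snack", "dinner")
}
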