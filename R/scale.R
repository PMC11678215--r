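#' Declare a discrete rating scale
#'
#' A rating scale is the set of consecutive integer scores participants may
#' give, e.g. the 5-point hedonic scale (1 = dislike very much, 3 = not sure,
#' 5 = like very much) or an 11-point 0--10 scale.
#'
#' @param min_score integer, lowest admissible score.
#' @param max_score integer, highest admissible score; must exceed `min_score`.
#' @param name optional short label, e.g. `"5-point hedonic"`.
#' @return An object of class `rating_scale` with fields `name`, `min_score`,
#'   `max_score` and `n_points`.
#' @export
#' @examples
#' rating_scale(1, 5, "5-point hedonic")
#' rating_scale(0, 10)
rating_scale <- function(min_score, max_score, name = NULL) {
  if (!is_count(abs(min_score)) && min_score != trunc(min_score))
    abort_mascore("min_score must be an integer", "mascore_invalid_scale")
  if (min_score != trunc(min_score) || max_score != trunc(max_score))
    abort_mascore("scale bounds must be integers", "mascore_invalid_scale")
  min_score <- as.integer(min_score)
  max_score <- as.integer(max_score)
  if (max_score <= min_score)
    abort_mascore("max_score must exceed min_score (need at least 2 points)",
                  "mascore_invalid_scale")
  structure(
    list(
      name = name %||% sprintf("%d-point", max_score - min_score + 1L),
      min_score = min_score,
      max_score = max_score,
      n_points = max_score - min_score + 1L
    ),
    class = "rating_scale"
  )
}

#' @export
print.rating_scale <- function(x, ...) {
  cat(sprintf("<rating_scale> %s: integers %d..%d (%d points)\n",
              x$name, x$min_score, x$max_score, x$n_points))
  invisible(x)
}

scale_scores <- function(scale) seq.int(scale$min_score, scale$max_score)

#' Check scores against a rating scale
#'
#' @param scores numeric vector (may contain `NA` for absent responses).
#' @param scale a [rating_scale()].
#' @return `TRUE` invisibly; signals a validation error naming the offending
#'   values otherwise.
#' @keywords internal
assert_on_scale <- function(scores, scale) {
  ok <- is.na(scores) |
    (scores == trunc(scores) & scores >= scale$min_score & scores <= scale$max_score)
  if (!all(ok)) {
    bad <- unique(scores[!ok])
    abort_mascore(
      sprintf("score(s) %s outside the %s scale [%d, %d]",
              paste(bad, collapse = ", "), scale$name,
              scale$min_score, scale$max_score),
      "mascore_score_out_of_scale"
    )
  }
  invisible(TRUE)
}

#' Declare a passives score range
#'
#' The passives range is the inclusive interval of scores classed as neither
#' promoter nor detractor. Scores strictly above `high` are promoters; scores
#' strictly below `low` are detractors. It is the calibrated quantity of the
#' MAS method.
#'
#' @param low,high inclusive integer bounds, `low <= high`. A singleton range
#'   (e.g. the optimum 3 on the 5-point scale) has `low == high`.
#' @param scale optional [rating_scale()]; when supplied the range is checked
#'   to lie within the scale.
#' @return An object of class `passives_range`.
#' @export
#' @examples
#' passives_range(3, 3)
#' passives_range(2, 4, rating_scale(1, 5))
passives_range <- function(low, high = low, scale = NULL) {
  if (low != trunc(low) || high != trunc(high))
    abort_mascore("passives bounds must be integers", "mascore_invalid_range")
  low <- as.integer(low); high <- as.integer(high)
  if (high < low)
    abort_mascore("passives range requires low <= high", "mascore_invalid_range")
  if (!is.null(scale)) {
    if (low < scale$min_score || high > scale$max_score)
      abort_mascore(
        sprintf("passives range %d-%d not contained in scale [%d, %d]",
                low, high, scale$min_score, scale$max_score),
        "mascore_invalid_range"
      )
  }
  structure(list(low = low, high = high), class = "passives_range")
}

#' @export
print.passives_range <- function(x, ...) {
  cat(sprintf("<passives_range> %s\n", format_range(x)))
  invisible(x)
}

#' @export
format.passives_range <- function(x, ...) format_range(x)

format_range <- function(r) {
  if (r$low == r$high) as.character(r$low) else sprintf("%d-%d", r$low, r$high)
}

#' Parse a passives range from text
#'
#' Accepts the notation used throughout reports and on the command line:
#' `"a-b"` for an inclusive interval and a bare `"a"` for the singleton.
#'
#' @param text character scalar, e.g. `"2-3"` or `"3"`.
#' @param scale optional [rating_scale()] for containment checking.
#' @return A [passives_range()].
#' @export
#' @examples
#' parse_range("2-4")
#' parse_range("3")
parse_range <- function(text, scale = NULL) {
  text <- trimws(text)
  m <- regmatches(text, regexec("^(-?[0-9]+)(?:-([0-9]+))?$", text))[[1]]
  if (length(m) == 0)
    abort_mascore(sprintf("cannot parse passives range '%s'", text),
                  "mascore_invalid_range")
  low <- as.integer(m[2])
  high <- if (m[3] == "") low else as.integer(m[3])
  passives_range(low, high, scale)
}
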