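#' Declare a study design
#'
#' Captures the structure of one taste-assessment study: the rating scale the
#' taste scores live on, how willingness to take the medicine again was asked
#' (binary yes/no, a forced choice among the study's formulations, or a second
#' rating scale), and the formulations under comparison.
#'
#' @param study_id character label, e.g. `"study2"`.
#' @param scale a [rating_scale()] for the taste (and rating-mode willingness)
#'   scores.
#' @param willingness_mode one of `"binary"`, `"forced_choice"`, `"rating"`.
#' @param formulations character vector of formulation labels.
#' @param k_alternatives number of alternatives in a forced choice; must equal
#'   `length(formulations)` and is only meaningful in forced-choice mode. The
#'   neutral point of the forced-choice WTMS is `100 / k_alternatives`.
#' @return An object of class `study_design`.
#' @export
#' @examples
#' study_design("study2", rating_scale(1, 5), "binary", c("TRM TMT", "TRM LQD"))
study_design <- function(study_id, scale, willingness_mode, formulations,
                         k_alternatives = NULL) {
  stopifnot(inherits(scale, "rating_scale"))
  willingness_mode <- match.arg(willingness_mode,
                                c("binary", "forced_choice", "rating"))
  formulations <- as.character(formulations)
  if (length(formulations) < 1 || anyDuplicated(formulations))
    abort_mascore("formulations must be a non-empty set of unique labels",
                  "mascore_invalid_design")
  if (willingness_mode == "forced_choice") {
    k_alternatives <- as.integer(k_alternatives %||% length(formulations))
    if (k_alternatives < 2)
      abort_mascore("forced choice requires at least 2 alternatives",
                    "mascore_invalid_design")
    if (k_alternatives != length(formulations))
      abort_mascore("k_alternatives must equal the number of formulations",
                    "mascore_invalid_design")
  } else {
    k_alternatives <- NULL
  }
  structure(
    list(study_id = as.character(study_id), scale = scale,
         willingness_mode = willingness_mode,
         k_alternatives = k_alternatives, formulations = formulations),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %s: %s willingness, scale %d..%d, formulations: %s\n",
              x$study_id, x$willingness_mode, x$scale$min_score,
              x$scale$max_score, paste(x$formulations, collapse = ", ")))
  invisible(x)
}

#' Read a study design from JSON
#'
#' The JSON object carries `study_id`, a `scale` object (`name`, `min_score`,
#' `max_score`), `willingness_mode`, `formulations`, and (forced choice only)
#' `k_alternatives`.
#'
#' @param path path to a JSON file.
#' @return A [study_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path))
    abort_mascore(sprintf("design file '%s' does not exist", path),
                  "mascore_io_error")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("study_id", "scale", "willingness_mode", "formulations"))
    if (is.null(j[[field]]))
      abort_mascore(sprintf("design file '%s' lacks field '%s'", path, field),
                    "mascore_schema_error")
  sc <- rating_scale(j$scale$min_score, j$scale$max_score, j$scale$name)
  study_design(j$study_id, sc, j$willingness_mode, j$formulations,
               k_alternatives = j$k_alternatives)
}

#' Write a study design to JSON
#'
#' Inverse of [read_design()]: `read_design(write_design(d, p))` reproduces
#' `d` field for field.
#'
#' @param design a [study_design()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  j <- list(
    study_id = design$study_id,
    scale = list(name = design$scale$name,
                 min_score = design$scale$min_score,
                 max_score = design$scale$max_score),
    willingness_mode = design$willingness_mode,
    formulations = design$formulations
  )
  if (!is.null(design$k_alternatives)) j$k_alternatives <- design$k_alternatives
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
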