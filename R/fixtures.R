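fixture_cache <- new.env(parent = emptyenv())

#' Bundled reference study datasets
#'
#' Loads the four taste-assessment study datasets shipped with the package.
#' These are synthetic reconstructions, not trial records: willingness
#' responses (yes counts, forced-choice votes) match the published
#' per-formulation tallies exactly, taste-score distributions on the 5-point
#' studies are canonical [reconstruct_counts()] solutions (the
#' lexicographically smallest count vector consistent with the published
#' n, median, mean, and all four published MAS values), and the
#' paediatric studies carry age labels matching the published age-stratum
#' sizes. Study 4's 11-point distributions are underdetermined by its
#' published summaries; the bundled ones are a documented canonical choice
#' consistent with the published n, medians, means, and MAS values.
#'
#' @details The keys are `study1` (midazolam TMT vs LQD, binary willingness),
#'   `study2` (tramadol TMT vs LQD, binary), `study3` (three flucloxacillin
#'   formulations, 3-way forced choice), `study4` (prednisolone sodium
#'   phosphate TMT vs LQD on a 0--10 scale, 2-way forced choice plus an
#'   11-point willingness rating), and `study4_rating` (the same records with
#'   the design re-declared as rating-mode willingness, for MAS-style scoring
#'   of the willingness ratings).
#'
#' @return Named list of [response_dataset()]s.
#' @export
#' @examples
#' fx <- study_fixtures()
#' score_study(fx$study2, passives_range(3))
study_fixtures <- function() {
  if (!is.null(fixture_cache$fixtures)) return(fixture_cache$fixtures)
  load1 <- function(id) {
    design <- read_design(fixture_path(paste0(id, ".json")))
    read_responses(fixture_path(paste0(id, ".csv")), design)
  }
  fx <- list(study1 = load1("study1"), study2 = load1("study2"),
             study3 = load1("study3"), study4 = load1("study4"))
  rating_design <- read_design(fixture_path("study4_rating.json"))
  recs <- fx$study4$records
  recs$willing_choice <- NA_character_
  fx$study4_rating <- response_dataset(rating_design, recs)
  fixture_cache$fixtures <- fx
  fx
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mascore")
  if (p == "")
    abort_mascore(sprintf("bundled fixture '%s' not found", file),
                  "mascore_io_error")
  p
}

#' Published summary constraints for the 5-point studies
#'
#' The per-formulation summary constraints that the bundled 5-point-scale
#' fixtures are reconstructed from: cohort size, median, mean, the four
#' published MAS values by passives range, and the published category-share
#' statements under the singleton range 3 (taste-masked tablets attract a
#' displayed promoter share of at least 48 percent; liquid comparators a
#' displayed detractor share above 70 percent). Exposed so the
#' reconstruction can be replayed and audited.
#'
#' @return Named list (one entry per formulation) of
#'   [summary_constraints()].
#' @export
fixture_constraints <- function() {
  sc <- rating_scale(1, 5, "5-point hedonic")
  tmt_share <- list(list(range = "3", category = "promoters", min_pct = 48))
  lqd_share <- list(list(range = "3", category = "detractors", min_pct = 71))
  list(
    "MDZ TMT" = summary_constraints(74, sc, median = 3, mean = 3.19,
      mas_by_range = c("2-3" = 27, "2-4" = 0, "3" = 19, "3-4" = -8),
      share_bounds = tmt_share),
    "MDZ LQD" = summary_constraints(70, sc, median = 1, mean = 1.71,
      mas_by_range = c("2-3" = -50, "2-4" = -54, "3" = -74, "3-4" = -79),
      share_bounds = lqd_share),
    "TRM TMT" = summary_constraints(68, sc, median = 4, mean = 3.69,
      mas_by_range = c("2-3" = 50, "2-4" = 28, "3" = 41, "3-4" = 19),
      share_bounds = tmt_share),
    "TRM LQD" = summary_constraints(71, sc, median = 2, mean = 2.00,
      mas_by_range = c("2-3" = -34, "2-4" = -41, "3" = -59, "3-4" = -66),
      share_bounds = lqd_share),
    "FLX TMT1" = summary_constraints(21, sc, median = 4, mean = 3.52,
      mas_by_range = c("2-3" = 62, "2-4" = 14, "3" = 38, "3-4" = -10),
      share_bounds = tmt_share),
    "FLX TMT2" = summary_constraints(21, sc, median = 3, mean = 3.19,
      mas_by_range = c("2-3" = 33, "2-4" = 0, "3" = 19, "3-4" = -14),
      share_bounds = tmt_share),
    "FLX LQD" = summary_constraints(21, sc, median = 2, mean = 2.10,
      mas_by_range = c("2-3" = -24, "2-4" = -33, "3" = -57, "3-4" = -67),
      share_bounds = lqd_share)
  )
}
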