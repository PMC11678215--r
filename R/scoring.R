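#' Categorise taste scores into promoters, passives, and detractors
#'
#' Scores strictly above the passives range are promoters, scores strictly
#' below it are detractors, scores inside it (inclusive) are passives.
#' `NA` scores are dropped before counting.
#'
#' @param scores integer vector of scores on `scale` (`NA` allowed).
#' @param scale a [rating_scale()].
#' @param passives a [passives_range()] contained in `scale`.
#' @return A list of class `category_counts` with fields `promoters`,
#'   `passives`, `detractors`, and `n` (their sum).
#' @export
#' @examples
#' sc <- rating_scale(1, 5)
#' categorize(c(1, 3, 3, 4, 4), sc, passives_range(3))
categorize <- function(scores, scale, passives) {
  stopifnot(inherits(scale, "rating_scale"), inherits(passives, "passives_range"))
  passives_range(passives$low, passives$high, scale)  # containment check
  assert_on_scale(scores, scale)
  s <- scores[!is.na(scores)]
  counts <- list(
    promoters = sum(s > passives$high),
    passives = sum(s >= passives$low & s <= passives$high),
    detractors = sum(s < passives$low)
  )
  counts$n <- counts$promoters + counts$passives + counts$detractors
  structure(counts, class = "category_counts")
}

#' @export
print.category_counts <- function(x, ...) {
  cat(sprintf("<category_counts> promoters %d, passives %d, detractors %d (n = %d)\n",
              x$promoters, x$passives, x$detractors, x$n))
  invisible(x)
}

#' Medicine Acceptability Score from category counts
#'
#' The MAS is the percentage of promoters minus the percentage of detractors,
#' ranging from -100 (all detractors) to +100 (all promoters). In `"paper"`
#' mode the difference is rounded once, at the end, half away from zero:
#' `round(100 * (P - D) / n)`. This single final rounding is the convention
#' under which all published 5-point-scale MAS values are reproduced;
#' rounding the two percentages separately before subtracting gives
#' occasionally different values (e.g. -75 instead of -74 at
#' (P - D) = -52, n = 70).
#'
#' @param counts a `category_counts` object from [categorize()].
#' @param mode `"paper"` (integer output, the reporting convention) or
#'   `"exact"` (unrounded).
#' @return A number in `[-100, 100]`.
#' @export
#' @examples
#' sc <- rating_scale(1, 5)
#' mas(categorize(c(1, 3, 3, 4, 4), sc, passives_range(3)))
mas <- function(counts, mode = c("paper", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "category_counts"))
  if (counts$n == 0)
    abort_mascore("MAS undefined: no scoreable responses (n = 0)",
                  "mascore_undefined_score")
  value <- 100 * (counts$promoters - counts$detractors) / counts$n
  if (mode == "paper") round_half_away(value) else value
}

#' Willingness-to-Take-Medicine Score, binary design
#'
#' For yes/no willingness questions the neutral no-preference point is a 50%
#' affirmative rate; the WTMS is the signed deviation of the affirmative
#' percentage from 50. In `"paper"` mode the affirmative percentage is rounded
#' half away from zero to an integer before subtracting 50.
#'
#' @param affirmative count of yes answers.
#' @param n count of willingness responses (yes + no).
#' @param mode `"paper"` or `"exact"`.
#' @return A number in `[-50, 50]`.
#' @export
#' @examples
#' wtms_binary(53, 68)  # 78% yes -> +28
wtms_binary <- function(affirmative, n, mode = c("paper", "exact")) {
  mode <- match.arg(mode)
  if (!is_count(n) || n == 0)
    abort_mascore("WTMS undefined: no willingness responses (n = 0)",
                  "mascore_undefined_score")
  if (!is_count(affirmative) || affirmative > n)
    abort_mascore("affirmative count must satisfy 0 <= affirmative <= n",
                  "mascore_invalid_argument")
  pct <- 100 * affirmative / n
  if (mode == "paper") round_half_away(pct) - 50 else pct - 50
}

#' Willingness-to-Take-Medicine Score, k-alternative forced choice
#'
#' When each participant votes for exactly one of `k` formulations, the
#' neutral no-preference point is an even split, `100 / k` percent (50% for
#' two alternatives, 33% for three). The WTMS is the deviation of a
#' formulation's vote share from that neutral point. In `"paper"` mode the
#' vote percentage and the neutral point are rounded to integers separately,
#' then subtracted (so k = 3 uses a neutral point of 33, and 1 vote of 21
#' gives 5 - 33 = -28).
#'
#' @param votes count of votes received by the formulation.
#' @param n count of participants who cast a vote.
#' @param k number of alternatives (>= 2).
#' @param mode `"paper"` or `"exact"`.
#' @return A number in `[-100/k, 100 - 100/k]` (exact mode).
#' @export
#' @examples
#' wtms_choice(11, 21, k = 3)  # 52% vs neutral 33 -> +19
wtms_choice <- function(votes, n, k, mode = c("paper", "exact")) {
  mode <- match.arg(mode)
  if (!is_count(n) || n == 0)
    abort_mascore("WTMS undefined: no votes cast (n = 0)",
                  "mascore_undefined_score")
  if (!is_count(k) || k < 2)
    abort_mascore("forced choice requires k >= 2", "mascore_invalid_argument")
  if (!is_count(votes) || votes > n)
    abort_mascore("votes must satisfy 0 <= votes <= n",
                  "mascore_invalid_argument")
  pct <- 100 * votes / n
  neutral <- 100 / k
  if (mode == "paper") round_half_away(pct) - round_half_away(neutral)
  else pct - neutral
}

#' Score every formulation in a study
#'
#' Computes, per formulation, the MAS from taste scores and the WTMS
#' dispatched on the study's willingness mode: binary designs use
#' [wtms_binary()] on the yes counts; forced-choice designs use
#' [wtms_choice()] with `k = design$k_alternatives`, counting one vote per
#' participant; rating designs compute an MAS-style score on the willingness
#' ratings with the same passives range. Records with an absent taste score
#' are excluded from the MAS denominator, and records (or participants)
#' without a willingness response from the WTMS denominator; exclusions are
#' reported via `message()`.
#'
#' @param dataset a [response_dataset()].
#' @param passives a [passives_range()] on the dataset's scale.
#' @param mode `"paper"` or `"exact"`.
#' @return A data frame of class `score_table` with one row per formulation:
#'   `formulation_id`, `mas`, `wtms`, `n_mas`, `n_wtms`, `promoters`,
#'   `passives`, `detractors`, `mode`. Formulations with no scoreable
#'   records get `NA` scores (flagged, not an error).
#' @export
score_study <- function(dataset, passives, mode = c("paper", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "response_dataset"),
            inherits(passives, "passives_range"))
  design <- dataset$design
  recs <- dataset$records
  passives_range(passives$low, passives$high, design$scale)

  n_excl_taste <- sum(is.na(recs$taste_score))
  if (n_excl_taste > 0 && design$willingness_mode != "rating")
    message(sprintf("score_study[%s]: %d record(s) without taste_score excluded from MAS",
                    design$study_id, n_excl_taste))

  rows <- lapply(design$formulations, function(f) {
    sub <- recs[recs$formulation_id == f, ]
    taste <- sub$taste_score[!is.na(sub$taste_score)]
    if (length(taste) > 0) {
      cc <- categorize(taste, design$scale, passives)
      mas_val <- mas(cc, mode)
    } else {
      cc <- list(promoters = 0L, passives = 0L, detractors = 0L)
      mas_val <- NA_real_
    }
    w <- switch(design$willingness_mode,
      binary = {
        wb <- sub$willing_binary[!is.na(sub$willing_binary)]
        if (length(wb) > 0)
          list(wtms = wtms_binary(sum(wb), length(wb), mode), n = length(wb))
        else list(wtms = NA_real_, n = 0L)
      },
      forced_choice = {
        voted <- recs[!is.na(recs$willing_choice),
                      c("participant_id", "willing_choice")]
        voted <- unique(voted)
        dup <- duplicated(voted$participant_id)
        if (any(dup))
          abort_mascore("participant(s) with conflicting forced-choice votes",
                        "mascore_validation_error")
        n_voters <- nrow(voted)
        if (n_voters > 0)
          list(wtms = wtms_choice(sum(voted$willing_choice == f), n_voters,
                                  design$k_alternatives, mode),
               n = n_voters)
        else list(wtms = NA_real_, n = 0L)
      },
      rating = {
        ws <- sub$willing_score[!is.na(sub$willing_score)]
        if (length(ws) > 0)
          list(wtms = mas(categorize(ws, design$scale, passives), mode),
               n = length(ws))
        else list(wtms = NA_real_, n = 0L)
      }
    )
    data.frame(formulation_id = f, mas = mas_val, wtms = w$wtms,
               n_mas = length(taste), n_wtms = w$n,
               promoters = cc$promoters, passives = cc$passives,
               detractors = cc$detractors, mode = mode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Write a score table to CSV or JSON
#'
#' @param scores a `score_table` from [score_study()].
#' @param path output path; format chosen by extension (`.json` for JSON,
#'   anything else CSV).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "score_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(scores), path, auto_unbox = FALSE,
                         digits = NA, na = "null", pretty = TRUE)
  } else {
    utils::write.csv(as.data.frame(scores), path, row.names = FALSE, na = "")
  }
  invisible(path)
}
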