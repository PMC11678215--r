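as_dataset_list <- function(x) {
  if (inherits(x, "response_dataset")) x <- list(x)
  if (!length(x) || !all(vapply(x, inherits, logical(1), "response_dataset")))
    abort_mascore("expected a response_dataset or a list of them",
                  "mascore_invalid_argument")
  scales <- unique(vapply(x, function(d)
    paste(d$design$scale$min_score, d$design$scale$max_score), character(1)))
  if (length(scales) > 1)
    abort_mascore("all datasets in a calibration must share one rating scale",
                  "mascore_invalid_argument")
  x
}

#' Calibration settings for passives-range selection
#'
#' @param candidate_ranges list of [passives_range()]s to sweep (or character
#'   vector parseable by [parse_range()]). The canonical candidate set for a
#'   5-point scale is `c("2-3", "2-4", "3", "3-4")`.
#' @param concordance_subset `"positive_wtms"` (default) restricts the
#'   rank-concordance comparison to formulations with WTMS > 0; `"all"` uses
#'   every formulation.
#' @param sign_filter apply the sign-concordance filter before ranking
#'   (default `TRUE`).
#' @param zero_fails_sign should MAS == 0 against a nonzero WTMS fail the
#'   sign filter (default `TRUE`)?
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(candidate_ranges = c("2-3", "2-4", "3", "3-4"),
                               concordance_subset = c("positive_wtms", "all"),
                               sign_filter = TRUE, zero_fails_sign = TRUE) {
  concordance_subset <- match.arg(concordance_subset)
  if (is.character(candidate_ranges))
    candidate_ranges <- lapply(candidate_ranges, parse_range)
  if (!length(candidate_ranges) ||
      !all(vapply(candidate_ranges, inherits, logical(1), "passives_range")))
    abort_mascore("candidate_ranges must be a non-empty list of passives ranges",
                  "mascore_invalid_config")
  structure(
    list(candidate_ranges = candidate_ranges,
         concordance_subset = concordance_subset,
         sign_filter = sign_filter, zero_fails_sign = zero_fails_sign),
    class = "calibration_config"
  )
}

#' MAS of every formulation under every candidate passives range
#'
#' @param datasets a [response_dataset()] or list of them sharing one rating
#'   scale (formulations are concatenated across datasets).
#' @param candidates list of [passives_range()]s (or characters for
#'   [parse_range()]).
#' @param mode `"paper"` or `"exact"`.
#' @return Numeric matrix, rows named by formulation, columns by candidate
#'   range; entries are `NA` for formulations without scoreable records.
#' @export
mas_matrix <- function(datasets, candidates, mode = c("paper", "exact")) {
  mode <- match.arg(mode)
  datasets <- as_dataset_list(datasets)
  if (is.character(candidates)) candidates <- lapply(candidates, parse_range)
  cols <- lapply(candidates, function(r) {
    tabs <- lapply(datasets, score_study, passives = r, mode = mode)
    do.call(rbind, tabs)$mas
  })
  forms <- unlist(lapply(datasets, function(d) d$design$formulations))
  if (anyDuplicated(forms))
    abort_mascore("formulation labels must be unique across datasets",
                  "mascore_invalid_argument")
  m <- do.call(cbind, cols)
  dimnames(m) <- list(forms, vapply(candidates, format_range, character(1)))
  m
}

wtms_vector <- function(datasets, mode = "paper") {
  datasets <- as_dataset_list(datasets)
  scale <- datasets[[1]]$design$scale
  mid <- passives_range(round((scale$min_score + scale$max_score) / 2))
  tab <- do.call(rbind, lapply(datasets, score_study, passives = mid, mode = mode))
  stats::setNames(tab$wtms, tab$formulation_id)
}

#' Sign concordance between MAS and WTMS vectors
#'
#' A candidate passives range is sign-concordant when every formulation with
#' a nonzero WTMS has an MAS of the same sign. With `zero_fails = TRUE`
#' (default) an MAS of exactly 0 against a nonzero WTMS also fails: a range
#' that neutralises a formulation the willingness data clearly ranks is
#' considered uninformative.
#'
#' @param mas_vector,wtms_vector named numeric vectors aligned on
#'   formulation ids.
#' @param zero_fails logical.
#' @return A list with `pass` (logical) and `detail`, a per-formulation
#'   logical vector.
#' @export
sign_concordance <- function(mas_vector, wtms_vector, zero_fails = TRUE) {
  if (is.null(names(mas_vector)) || is.null(names(wtms_vector)) ||
      !setequal(names(mas_vector), names(wtms_vector)))
    abort_mascore("MAS and WTMS vectors must be named by the same formulations",
                  "mascore_alignment_error")
  wtms_vector <- wtms_vector[names(mas_vector)]
  detail <- vapply(seq_along(mas_vector), function(i) {
    m <- mas_vector[i]; w <- wtms_vector[i]
    if (is.na(m) || is.na(w)) return(NA)
    if (w == 0) return(TRUE)
    if (m == 0) return(!zero_fails)
    sign(m) == sign(w)
  }, logical(1))
  names(detail) <- names(mas_vector)
  list(pass = all(detail %in% TRUE), detail = detail)
}

#' Rank concordance (Kendall tau-b) between MAS and WTMS
#'
#' Formalises "the MAS ranking most closely matches the WTMS ranking" as
#' Kendall's tau-b, the tie-corrected rank correlation, optionally restricted
#' to the formulations with positive WTMS.
#'
#' @param mas_vector,wtms_vector named numeric vectors aligned on
#'   formulation ids.
#' @param subset `"all"` or `"positive_wtms"`.
#' @return tau-b in `[-1, 1]`.
#' @export
rank_concordance <- function(mas_vector, wtms_vector,
                             subset = c("all", "positive_wtms")) {
  subset <- match.arg(subset)
  if (is.null(names(mas_vector)) || is.null(names(wtms_vector)) ||
      !setequal(names(mas_vector), names(wtms_vector)))
    abort_mascore("MAS and WTMS vectors must be named by the same formulations",
                  "mascore_alignment_error")
  wtms_vector <- wtms_vector[names(mas_vector)]
  keep <- !is.na(mas_vector) & !is.na(wtms_vector)
  if (subset == "positive_wtms") keep <- keep & wtms_vector > 0
  x <- mas_vector[keep]; y <- wtms_vector[keep]
  if (length(x) < 2)
    abort_mascore("rank concordance undefined on fewer than 2 formulations",
                  "mascore_undefined_score")
  stats::cor(x, y, method = "kendall")
}

#' Select the optimal passives range against WTMS
#'
#' Sweeps the candidate passives ranges, computes the MAS matrix and the WTMS
#' vector, drops candidates failing sign concordance (when the filter is
#' enabled), and selects the survivor with the highest rank concordance on
#' the configured subset. Ties break deterministically to the narrower range,
#' then the lower midpoint.
#'
#' @param datasets a [response_dataset()] or list of them on one scale.
#' @param config a [calibration_config()].
#' @param mode `"paper"` or `"exact"`.
#' @return An object of class `calibration_result`: `mas_matrix`,
#'   `wtms_vector`, `survivors` (character range labels), `concordance`
#'   (named numeric over survivors), `selected` (a [passives_range()] or
#'   `NULL` when no candidate survives), and `audit`, a per-candidate data
#'   frame of filter outcomes and failure reasons.
#' @export
select_passives_range <- function(datasets, config = calibration_config(),
                                  mode = c("paper", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "calibration_config"))
  datasets <- as_dataset_list(datasets)
  candidates <- config$candidate_ranges
  labels <- vapply(candidates, format_range, character(1))
  m <- mas_matrix(datasets, candidates, mode)
  w <- wtms_vector(datasets, mode)
  if (any(is.na(w)))
    abort_mascore("WTMS not computable for every formulation",
                  "mascore_undefined_score")

  widths <- vapply(candidates, function(r) r$high - r$low, numeric(1))
  mids <- vapply(candidates, function(r) (r$high + r$low) / 2, numeric(1))

  audit <- data.frame(range = labels, width = widths, midpoint = mids,
                      sign_pass = NA, concordance = NA_real_,
                      reason = "", stringsAsFactors = FALSE)
  mas_col <- function(i) stats::setNames(m[, i], rownames(m))
  for (i in seq_along(candidates)) {
    sc <- sign_concordance(mas_col(i), w, zero_fails = config$zero_fails_sign)
    audit$sign_pass[i] <- sc$pass
    if (!sc$pass)
      audit$reason[i] <- sprintf(
        "sign discordance: %s",
        paste(names(sc$detail)[!(sc$detail %in% TRUE)], collapse = ", "))
  }
  surv <- if (config$sign_filter) which(audit$sign_pass) else seq_along(candidates)
  for (i in surv)
    audit$concordance[i] <- tryCatch(
      rank_concordance(mas_col(i), w, subset = config$concordance_subset),
      mascore_error = function(e) NA_real_)
  if (length(surv) == 0) {
    selected <- NULL
  } else {
    # max concordance; ties -> narrower range, then lower midpoint
    conc <- audit$concordance[surv]
    conc[is.na(conc)] <- -Inf
    ord <- surv[order(-conc, widths[surv], mids[surv])]
    selected <- candidates[[ord[1]]]
  }
  structure(
    list(mas_matrix = m, wtms_vector = w,
         survivors = labels[surv],
         concordance = stats::setNames(audit$concordance[surv], labels[surv]),
         selected = selected, audit = audit, mode = mode,
         subset = config$concordance_subset),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat("MAS matrix:\n"); print(x$mas_matrix)
  cat("WTMS:\n"); print(x$wtms_vector)
  cat(sprintf("survivors: %s\n",
              if (length(x$survivors)) paste(x$survivors, collapse = ", ") else "(none)"))
  if (length(x$concordance))
    cat(sprintf("tau-b (%s): %s\n", x$subset,
                paste(sprintf("%s=%.3f", names(x$concordance), x$concordance),
                      collapse = ", ")))
  cat(sprintf("selected: %s\n",
              if (is.null(x$selected)) "(no selection)" else format_range(x$selected)))
  invisible(x)
}

#' Export a calibration result
#'
#' @param result a `calibration_result`.
#' @param path output path; `.json` writes the full result (matrix,
#'   survivors, concordances, selection, audit trail), anything else writes
#'   the MAS matrix as CSV.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(
      mas_matrix = as.data.frame(result$mas_matrix),
      formulations = rownames(result$mas_matrix),
      wtms = as.list(result$wtms_vector),
      survivors = result$survivors,
      concordance = as.list(result$concordance),
      selected = if (is.null(result$selected)) NULL
                 else format_range(result$selected),
      audit = result$audit, mode = result$mode, subset = result$subset
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.csv(cbind(formulation_id = rownames(result$mas_matrix),
                           as.data.frame(result$mas_matrix)),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Transpose a passives range between rating scales
#'
#' Maps a passives range calibrated on one rating scale onto another. The
#' default `"paper"` rule multiplies the range centre by `factor` (default 2),
#' rounds it, and takes `centre +/- halfwidth` (default 1), clipped to the
#' target scale: the 5-point optimum 3 becomes centre 6 and range 5--7 on an
#' 11-point 0--10 scale. The `"affine"` rule instead maps each bound linearly
#' from the source to the target scale span (the 5-point 3 centres on 5 of
#' 0--10) before widening by `halfwidth`; it is the principled alternative but
#' not the published convention.
#'
#' @param range a [passives_range()] on `source`.
#' @param source,target [rating_scale()]s.
#' @param rule `"paper"` or `"affine"`.
#' @param factor multiplier for the range centre (`"paper"` rule).
#' @param halfwidth half-width, in target-scale units, of the transposed
#'   range around its centre.
#' @return A [passives_range()] on `target`.
#' @export
#' @examples
#' transpose_range(passives_range(3), rating_scale(1, 5), rating_scale(0, 10))
transpose_range <- function(range, source, target, rule = c("paper", "affine"),
                            factor = 2, halfwidth = 1) {
  rule <- match.arg(rule)
  stopifnot(inherits(range, "passives_range"),
            inherits(source, "rating_scale"), inherits(target, "rating_scale"))
  passives_range(range$low, range$high, source)
  if (halfwidth < 0 || halfwidth != trunc(halfwidth))
    abort_mascore("halfwidth must be a non-negative integer",
                  "mascore_invalid_argument")
  if (rule == "paper") {
    centre <- round_half_away((range$low + range$high) / 2 * factor)
    low <- centre - halfwidth
    high <- centre + halfwidth
  } else {
    map <- function(b) target$min_score +
      (b - source$min_score) *
        (target$max_score - target$min_score) /
        (source$max_score - source$min_score)
    low <- round_half_away(map(range$low)) - halfwidth
    high <- round_half_away(map(range$high)) + halfwidth
  }
  low <- max(low, target$min_score)
  high <- min(high, target$max_score)
  if (high < low)
    abort_mascore("transposed range is empty after clipping to the target scale",
                  "mascore_invalid_range")
  passives_range(low, high, target)
}
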