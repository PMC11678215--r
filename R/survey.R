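RECORD_COLS <- c("study_id", "participant_id", "formulation_id", "age_years",
                 "taste_score", "willing_binary", "willing_choice",
                 "willing_score")

#' Construct a validated response dataset
#'
#' Bundles a [study_design()] with a data frame of per-participant responses.
#' One row is one participant's responses for one formulation. Absent
#' responses are `NA`; they are retained in the dataset but excluded from the
#' relevant score denominators at scoring time.
#'
#' @param design a [study_design()].
#' @param records data frame with columns `participant_id` and
#'   `formulation_id` (mandatory) and any of `study_id`, `age_years`,
#'   `taste_score`, `willing_binary` (logical), `willing_choice`
#'   (formulation label voted for), `willing_score`.
#' @return An object of class `response_dataset`.
#' @export
response_dataset <- function(design, records) {
  stopifnot(inherits(design, "study_design"))
  records <- as.data.frame(records)
  for (col in c("participant_id", "formulation_id"))
    if (is.null(records[[col]]))
      abort_mascore(sprintf("records lack mandatory column '%s'", col),
                    "mascore_schema_error")
  for (col in RECORD_COLS) if (is.null(records[[col]])) {
    fill <- switch(col,
      study_id = design$study_id,
      willing_binary = NA,
      willing_choice = NA_character_,
      NA_real_)
    records[[col]] <- rep(fill, length.out = nrow(records))
  }
  records <- records[RECORD_COLS]
  records$participant_id <- as.character(records$participant_id)
  records$formulation_id <- as.character(records$formulation_id)
  records$study_id <- as.character(records$study_id)
  records$willing_binary <- as.logical(records$willing_binary)
  records$willing_choice <- as.character(records$willing_choice)
  validate_records(design, records)
  structure(list(design = design, records = records),
            class = "response_dataset")
}

validate_records <- function(design, records) {
  bad_form <- setdiff(unique(records$formulation_id), design$formulations)
  if (length(bad_form))
    abort_mascore(
      sprintf("formulation(s) not declared in design: %s",
              paste(bad_form, collapse = ", ")),
      "mascore_validation_error"
    )
  if (nrow(records)) {
    bad <- !is.na(records$taste_score) &
      (records$taste_score != trunc(records$taste_score) |
       records$taste_score < design$scale$min_score |
       records$taste_score > design$scale$max_score)
    if (any(bad))
      abort_mascore(
        sprintf("taste_score outside scale [%d, %d] in row(s) %s",
                design$scale$min_score, design$scale$max_score,
                paste(which(bad), collapse = ", ")),
        "mascore_validation_error"
      )
    if (design$willingness_mode == "rating") {
      bad_w <- !is.na(records$willing_score) &
        (records$willing_score != trunc(records$willing_score) |
         records$willing_score < design$scale$min_score |
         records$willing_score > design$scale$max_score)
      if (any(bad_w))
        abort_mascore(
          sprintf("willing_score outside scale [%d, %d] in row(s) %s",
                  design$scale$min_score, design$scale$max_score,
                  paste(which(bad_w), collapse = ", ")),
          "mascore_validation_error"
        )
    }
    dup <- duplicated(records[c("participant_id", "formulation_id")])
    if (any(dup))
      abort_mascore(
        sprintf("duplicate (participant_id, formulation_id) in row(s) %s",
                paste(which(dup), collapse = ", ")),
        "mascore_validation_error"
      )
    # willingness fields must match the declared design family
    if (design$willingness_mode != "binary" && any(!is.na(records$willing_binary)))
      abort_mascore("willing_binary present but design is not binary",
                    "mascore_validation_error")
    if (design$willingness_mode != "forced_choice" &&
        any(!is.na(records$willing_choice)))
      abort_mascore("willing_choice present but design is not forced choice",
                    "mascore_validation_error")
    if (design$willingness_mode == "forced_choice") {
      bad_c <- setdiff(stats::na.omit(unique(records$willing_choice)),
                       design$formulations)
      if (length(bad_c))
        abort_mascore(
          sprintf("willing_choice vote(s) for undeclared formulation: %s",
                  paste(bad_c, collapse = ", ")),
          "mascore_validation_error"
        )
    }
    if (any(!is.na(records$age_years) & records$age_years < 0))
      abort_mascore("age_years must be non-negative", "mascore_validation_error")
  }
  invisible(TRUE)
}

#' @export
print.response_dataset <- function(x, ...) {
  cat(sprintf("<response_dataset> %s: %d records, %d formulations\n",
              x$design$study_id, nrow(x$records), length(x$design$formulations)))
  invisible(x)
}

#' Read per-participant responses from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row naming at least
#' `participant_id` and `formulation_id`; empty cells mean absent responses.
#' `willing_binary` cells are written/read as `yes`/`no`.
#'
#' @param path path to a CSV file.
#' @param design the [study_design()] the responses belong to.
#' @return A validated [response_dataset()]; row order is preserved.
#' @export
read_responses <- function(path, design) {
  if (!file.exists(path))
    abort_mascore(sprintf("response file '%s' does not exist", path),
                  "mascore_io_error")
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "", check.names = FALSE)
  for (col in c("participant_id", "formulation_id"))
    if (is.null(raw[[col]]))
      abort_mascore(sprintf("'%s' lacks mandatory column '%s'", path, col),
                    "mascore_schema_error")
  recs <- data.frame(
    participant_id = raw$participant_id,
    formulation_id = raw$formulation_id,
    stringsAsFactors = FALSE
  )
  if (!is.null(raw$study_id)) recs$study_id <- raw$study_id
  if (!is.null(raw$age_years)) recs$age_years <- as.numeric(raw$age_years)
  if (!is.null(raw$taste_score)) recs$taste_score <- as.numeric(raw$taste_score)
  if (!is.null(raw$willing_binary))
    recs$willing_binary <- parse_yes_no(raw$willing_binary, path)
  if (!is.null(raw$willing_choice)) recs$willing_choice <- raw$willing_choice
  if (!is.null(raw$willing_score))
    recs$willing_score <- as.numeric(raw$willing_score)
  response_dataset(design, recs)
}

parse_yes_no <- function(x, path) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("yes", "y", "true", "1")] <- TRUE
  out[lx %in% c("no", "n", "false", "0")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    abort_mascore(
      sprintf("'%s': unparseable willing_binary value(s) in row(s) %s",
              path, paste(which(bad), collapse = ", ")),
      "mascore_validation_error"
    )
  out
}

#' Write responses to CSV
#'
#' Inverse of [read_responses()]: the written file round-trips field for
#' field (absent values as empty cells, `willing_binary` as `yes`/`no`).
#'
#' @param dataset a [response_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(dataset, path) {
  stopifnot(inherits(dataset, "response_dataset"))
  out <- dataset$records
  out$willing_binary <- ifelse(is.na(out$willing_binary), NA,
                               ifelse(out$willing_binary, "yes", "no"))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    abort_mascore(sprintf("cannot write responses to '%s'", path),
                  "mascore_io_error")
  invisible(path)
}

#' Split a cohort into young and mature age groups
#'
#' Partitions the records at an inclusive age cutoff: the young group holds
#' records with `age_years <= cutoff_years`, the mature group those with
#' `age_years > cutoff_years`. Records without a recorded age are excluded
#' from both groups and counted in the returned report.
#'
#' @param dataset a [response_dataset()].
#' @param cutoff_years positive number; the default 6 separates young
#'   (<= 6 years) from mature (> 6 years) participants.
#' @return A list with elements `young` and `mature` (both
#'   [response_dataset()]s) and `n_excluded`, the number of ageless records.
#' @export
stratify_by_age <- function(dataset, cutoff_years = 6) {
  stopifnot(inherits(dataset, "response_dataset"))
  if (!is.numeric(cutoff_years) || cutoff_years <= 0)
    abort_mascore("cutoff_years must be positive", "mascore_invalid_argument")
  age <- dataset$records$age_years
  if (all(is.na(age)))
    abort_mascore("no record carries an age; stratification impossible",
                  "mascore_no_ages")
  young <- !is.na(age) & age <= cutoff_years
  mature <- !is.na(age) & age > cutoff_years
  n_excluded <- sum(is.na(age))
  if (n_excluded > 0)
    message(sprintf("stratify_by_age: %d record(s) without age excluded",
                    n_excluded))
  list(
    young = response_dataset(dataset$design, dataset$records[young, ]),
    mature = response_dataset(dataset$design, dataset$records[mature, ]),
    n_excluded = n_excluded
  )
}
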