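#' Render a human- and machine-readable acceptability report
#'
#' Writes a per-formulation breakdown — promoter/passive/detractor
#' percentages, MAS, WTMS and the denominators behind them — as a CSV plus a
#' plain-text report, appending the calibration audit trail when a
#' [select_passives_range()] result is supplied.
#'
#' @param score_tables a `score_table` from [score_study()] or a list of
#'   them.
#' @param calibration optional `calibration_result`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"mas_report"`).
#' @return Named character vector of the files written (`breakdown`,
#'   `report`), invisibly.
#' @export
render_report <- function(score_tables, calibration = NULL, dir = ".",
                          prefix = "mas_report") {
  if (inherits(score_tables, "score_table")) score_tables <- list(score_tables)
  if (!length(score_tables) ||
      !all(vapply(score_tables, inherits, logical(1), "score_table")))
    abort_mascore("score_tables must be one or more score_table objects",
                  "mascore_invalid_argument")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  breakdown <- do.call(rbind, lapply(score_tables, function(tab) {
    n_cat <- tab$promoters + tab$passives + tab$detractors
    pct <- function(x) ifelse(n_cat > 0, 100 * x / n_cat, NA_real_)
    data.frame(
      formulation_id = tab$formulation_id,
      pct_promoters = pct(tab$promoters),
      pct_passives = pct(tab$passives),
      pct_detractors = pct(tab$detractors),
      mas = tab$mas, wtms = tab$wtms,
      n_mas = tab$n_mas, n_wtms = tab$n_wtms, mode = tab$mode,
      stringsAsFactors = FALSE)
  }))
  csv_path <- file.path(dir, paste0(prefix, "_breakdown.csv"))
  utils::write.csv(breakdown, csv_path, row.names = FALSE, na = "")

  txt_path <- file.path(dir, paste0(prefix, ".txt"))
  con <- file(txt_path, "w")
  on.exit(close(con))
  writeLines(c("Medicine Acceptability Score report",
               strrep("=", 35), ""), con)
  fmt <- "%-12s %10s %9s %11s %6s %6s"
  writeLines(sprintf(fmt, "formulation", "promoters%", "passives%",
                     "detractors%", "MAS", "WTMS"), con)
  for (i in seq_len(nrow(breakdown))) {
    b <- breakdown[i, ]
    writeLines(sprintf(fmt, b$formulation_id,
                       sprintf("%.1f", b$pct_promoters),
                       sprintf("%.1f", b$pct_passives),
                       sprintf("%.1f", b$pct_detractors),
                       format(b$mas), format(b$wtms)), con)
  }
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "calibration_result"))
    writeLines(c("", "Passives-range calibration", strrep("-", 26)), con)
    writeLines(utils::capture.output(print(calibration$audit)), con)
    writeLines(sprintf("selected passives range: %s",
                       if (is.null(calibration$selected)) "(no selection)"
                       else format_range(calibration$selected)), con)
  }
  invisible(c(breakdown = csv_path, report = txt_path))
}
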