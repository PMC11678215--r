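#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves moving away from zero
#' (so 0.5 -> 1 and -0.5 -> -1), unlike [base::round()]'s round-half-even.
#' All published score arithmetic in this package uses this convention.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == trunc(x)
}

abort_mascore <- function(msg, class) {
  stop(structure(
    class = c(class, "mascore_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
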