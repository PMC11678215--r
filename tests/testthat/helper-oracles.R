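# Independent brute-force oracles and small builders shared across tests.

scale5 <- rating_scale(1, 5, "5-point hedonic")

# per-record classify-and-average MAS, independent of categorize()/mas()
mas_brute <- function(scores, passives, mode = "exact") {
  contrib <- vapply(scores, function(s) {
    if (s > passives$high) 1 else if (s < passives$low) -1 else 0
  }, numeric(1))
  v <- 100 * mean(contrib)
  if (mode == "paper") sign(v) * floor(abs(v) + 0.5) else v
}

# Kendall tau-b by exhaustive pair enumeration
tau_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0) tx <- tx + 1
    if (dy == 0) ty <- ty + 1
    if (dx != 0 && dy != 0) {
      if (dx == dy) conc <- conc + 1 else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

make_binary_dataset <- function(scores, yes, formulation = "F1",
                                study_id = "s", ages = NULL) {
  design <- study_design(study_id, scale5, "binary", formulation)
  response_dataset(design, data.frame(
    participant_id = paste0("p", seq_along(scores)),
    formulation_id = formulation,
    age_years = if (is.null(ages)) NA_real_ else ages,
    taste_score = scores,
    willing_binary = yes))
}

random_binary_dataset <- function(n = 30) {
  make_binary_dataset(sample(1:5, n, replace = TRUE),
                      sample(c(TRUE, FALSE), n, replace = TRUE))
}

fixtures123 <- function() {
  fx <- suppressMessages(study_fixtures())
  fx[c("study1", "study2", "study3")]
}
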