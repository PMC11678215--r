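#' Declare summary constraints for count reconstruction
#'
#' Describes everything a published summary table states about one
#' formulation's score distribution: the sample size, optionally the median,
#' the mean (to its printed decimals), the standard deviation (n-1 divisor,
#' printed decimals), and any number of published MAS values keyed by the
#' passives range they were computed with. [reconstruct_counts()] finds every
#' integer count vector consistent with all of them.
#'
#' Printed decimals are honoured through inclusive rounding intervals: a mean
#' printed as 3.69 admits any true mean in `[3.685, 3.695]`, so no assumption
#' is made about the publisher's rounding rule.
#'
#' @param n total count of scores.
#' @param scale a [rating_scale()].
#' @param median printed median (integer), or `NULL`. For even `n` both
#'   middle order statistics must equal it.
#' @param mean,sd printed mean / SD, or `NULL`.
#' @param mean_digits,sd_digits decimals the mean / SD were printed to.
#' @param mas_by_range named list/vector of published integer MAS values, the
#'   names parseable by [parse_range()] (e.g. `c("2-3" = 50, "3-4" = 19)`).
#' @param share_bounds optional list of published category-share statements,
#'   each a list with `range` (passives range text), `category`
#'   (`"promoters"` or `"detractors"`), and `min_pct`: the category's share,
#'   as the displayed integer percentage (rounded half away from zero), must
#'   be at least `min_pct`. Captures claims such as "attracting at least 48
#'   percent promoters" as reconstruction constraints.
#' @return An object of class `summary_constraints`.
#' @export
summary_constraints <- function(n, scale, median = NULL, mean = NULL,
                                mean_digits = 2, sd = NULL, sd_digits = 2,
                                mas_by_range = NULL, share_bounds = NULL) {
  stopifnot(inherits(scale, "rating_scale"), is_count(n), n >= 1)
  if (is.null(median) && is.null(mean) && is.null(sd) &&
      !length(mas_by_range) && !length(share_bounds))
    abort_mascore("at least one constraint must be supplied",
                  "mascore_invalid_config")
  if (length(share_bounds)) {
    for (b in share_bounds) {
      if (!is.list(b) || is.null(b$range) || is.null(b$min_pct) ||
          !identical(b$category %in% c("promoters", "detractors"), TRUE))
        abort_mascore(paste("each share bound needs fields range, category",
                            "(promoters/detractors), and min_pct"),
                      "mascore_invalid_config")
      parse_range(b$range, scale)
    }
  }
  if (!is.null(median) && median != trunc(median))
    abort_mascore("median constraints must be printed integers",
                  "mascore_invalid_config")
  ranges <- NULL
  if (length(mas_by_range)) {
    if (is.null(names(mas_by_range)) || any(names(mas_by_range) == ""))
      abort_mascore("mas_by_range must be named by passives ranges",
                    "mascore_invalid_config")
    ranges <- lapply(names(mas_by_range), parse_range, scale = scale)
  }
  structure(
    list(n = as.integer(n), scale = scale, median = median,
         mean = mean, mean_digits = mean_digits,
         sd = sd, sd_digits = sd_digits,
         mas_values = as.numeric(mas_by_range), mas_ranges = ranges,
         share_bounds = share_bounds),
    class = "summary_constraints"
  )
}

# integer count differences d with round(100 d / n) == printed value,
# under half-away-from-zero rounding; contiguous by monotonicity
feasible_differences <- function(printed, n) {
  d <- seq.int(-n, n)
  d[round_half_away(100 * d / n) == printed]
}

#' Reconstruct score distributions from summary statistics
#'
#' Exhaustively enumerates every integer count vector over the scale's
#' scores, summing to `n`, that satisfies all supplied constraints: printed
#' median, mean and SD within their inclusive rounding intervals, and every
#' published MAS value under the single-final-rounding convention. A
#' depth-first search over the count cells with interval pruning on the score
#' total and on the promoter-minus-detractor differences keeps the search
#' tractable at the study sizes involved.
#'
#' Because rounding maps an interval of count differences to each printed
#' MAS, several published values jointly can force the exact promoter,
#' passive and detractor tallies even when the full distribution stays
#' underdetermined; the returned set makes such forcing checkable.
#'
#' @param constraints a [summary_constraints()] with `n <= 200`.
#' @return Integer matrix, one row per feasible count vector (possibly zero
#'   rows), columns named by score, rows in lexicographic order.
#' @export
#' @examples
#' sc <- rating_scale(1, 5)
#' # five scores with mean 3 and median 3
#' reconstruct_counts(summary_constraints(5, sc, median = 3, mean = 3,
#'                                        mean_digits = 0))
reconstruct_counts <- function(constraints) {
  stopifnot(inherits(constraints, "summary_constraints"))
  n <- constraints$n
  if (n > 200)
    abort_mascore(paste("exhaustive reconstruction is limited to n <= 200;",
                        "larger cohorts need a constraint-propagation approach"),
                  "mascore_search_bound")
  scores <- scale_scores(constraints$scale)
  m <- length(scores)

  # score-total interval from the printed mean
  t_bounds <- c(n * scores[1], n * scores[m])
  if (!is.null(constraints$mean)) {
    half <- 0.5 * 10^(-constraints$mean_digits)
    t_bounds <- c(max(t_bounds[1], ceiling(n * (constraints$mean - half) - 1e-9)),
                  min(t_bounds[2], floor(n * (constraints$mean + half) + 1e-9)))
  }

  # per published MAS value: weight vector and feasible difference interval
  forms <- list()
  if (length(constraints$mas_values)) {
    for (i in seq_along(constraints$mas_values)) {
      r <- constraints$mas_ranges[[i]]
      w <- ifelse(scores > r$high, 1L, ifelse(scores < r$low, -1L, 0L))
      D <- feasible_differences(constraints$mas_values[i], n)
      if (!length(D)) return(empty_counts(scores))
      forms[[i]] <- list(w = w, dlo = min(D), dhi = max(D))
    }
  }

  sols <- vector("list", 64)
  n_sol <- 0L

  share_checks <- lapply(constraints$share_bounds, function(b) {
    r <- parse_range(b$range, constraints$scale)
    keep <- if (b$category == "promoters") scores > r$high else scores < r$low
    list(keep = keep, min_pct = b$min_pct)
  })

  check_leaf <- function(counts) {
    if (!is.null(constraints$median) && !median_ok(counts, scores, constraints$median))
      return(FALSE)
    for (chk in share_checks) {
      pct <- round_half_away(100 * sum(counts[chk$keep]) / n)
      if (pct < chk$min_pct) return(FALSE)
    }
    if (!is.null(constraints$sd)) {
      tt <- sum(counts * scores)
      ss <- sum(counts * scores^2)
      if (n < 2) return(FALSE)
      s_hat <- sqrt(max(0, (ss - tt^2 / n) / (n - 1)))
      half <- 0.5 * 10^(-constraints$sd_digits)
      if (s_hat < constraints$sd - half - 1e-9 ||
          s_hat > constraints$sd + half + 1e-9) return(FALSE)
    }
    TRUE
  }

  recurse <- function(j, counts, remaining, total, dvals) {
    if (j == m) {
      counts[m] <- remaining
      total <- total + remaining * scores[m]
      if (total < t_bounds[1] || total > t_bounds[2]) return()
      for (i in seq_along(forms)) {
        d <- dvals[i] + remaining * forms[[i]]$w[m]
        if (d < forms[[i]]$dlo || d > forms[[i]]$dhi) return()
      }
      if (!check_leaf(counts)) return()
      n_sol <<- n_sol + 1L
      if (n_sol > length(sols)) length(sols) <<- 2L * length(sols)
      sols[[n_sol]] <<- counts
      return()
    }
    lo_s <- scores[j + 1]; hi_s <- scores[m]
    for (cj in 0:remaining) {
      counts[j] <- cj
      rem <- remaining - cj
      tot <- total + cj * scores[j]
      # score-total pruning: the max achievable total falls as cj grows
      if (tot + rem * hi_s < t_bounds[1]) break
      if (tot + rem * lo_s > t_bounds[2]) next
      ok <- TRUE
      dv <- dvals
      for (i in seq_along(forms)) {
        f <- forms[[i]]
        dv[i] <- dvals[i] + cj * f$w[j]
        wr <- f$w[(j + 1):m]
        if (dv[i] + rem * min(wr) > f$dhi || dv[i] + rem * max(wr) < f$dlo) {
          ok <- FALSE
          break
        }
      }
      if (ok) recurse(j + 1L, counts, rem, tot, dv)
    }
  }

  recurse(1L, integer(m), n, 0,
          if (length(forms)) numeric(length(forms)) else numeric(0))
  if (n_sol == 0) return(empty_counts(scores))
  out <- do.call(rbind, sols[seq_len(n_sol)])
  colnames(out) <- as.character(scores)
  out
}

empty_counts <- function(scores) {
  matrix(integer(0), nrow = 0, ncol = length(scores),
         dimnames = list(NULL, as.character(scores)))
}

median_ok <- function(counts, scores, med) {
  n <- sum(counts)
  cum <- cumsum(counts)
  stat <- function(k) scores[which(cum >= k)[1]]
  if (n %% 2 == 1) {
    stat((n + 1) / 2) == med
  } else {
    stat(n / 2) == med && stat(n / 2 + 1) == med
  }
}

#' Expand a count vector into individual scores
#'
#' @param counts integer vector of per-score counts (one row of a
#'   [reconstruct_counts()] result).
#' @param scale the [rating_scale()] the counts live on.
#' @return Integer vector of `sum(counts)` scores in ascending order.
#' @export
counts_to_scores <- function(counts, scale) {
  scores <- scale_scores(scale)
  stopifnot(length(counts) == length(scores))
  rep(scores, counts)
}

#' Parameters for the synthetic cohort simulator
#'
#' The simulator draws, for each participant and formulation, a latent liking
#' on a continuous scale: `latent ~ Normal(mu[formulation], sigma)`. The
#' observed taste score is the latent value discretised through strictly
#' increasing thresholds onto the design's rating scale. Willingness follows
#' the declared link: binary designs answer yes with probability
#' `plogis(link_a + link_b * latent)`; forced-choice designs vote for the
#' formulation maximising `latent + choice_noise * Gumbel` (the standard
#' discrete-choice construction); rating designs discretise
#' `link_a + link_b * latent + Normal(0, sigma)` through the same thresholds.
#'
#' The defaults emulate the binary-willingness paediatric study arms this
#' package's fixtures mirror: one taste-masked tablet with mildly positive
#' latent liking against a clearly disliked liquid comparator, 70
#' participants per formulation on a 5-point scale, and a positive
#' liking-to-willingness link.
#'
#' @param design a [study_design()]; mu must name all its formulations.
#' @param n participants per formulation (single-evaluation designs) or
#'   total participants (repeated-measures forced-choice/rating designs).
#' @param mu named numeric, latent mean liking per formulation.
#' @param sigma latent liking spread (> 0).
#' @param thresholds strictly increasing cut points, length
#'   `scale$n_points - 1`.
#' @param link_a,link_b willingness link intercept and slope.
#' @param choice_noise Gumbel noise scale for forced choice (> 0).
#' @param seed integer seed; identical parameters and seed reproduce the
#'   dataset exactly.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(design = NULL, n = 70,
                       mu = c(TMT = 0.5, LQD = -1.3),
                       sigma = 1, thresholds = NULL,
                       link_a = 0.3, link_b = 1.2,
                       choice_noise = 1, seed = 1L) {
  if (is.null(design))
    design <- study_design("simulated", rating_scale(1, 5, "5-point hedonic"),
                           "binary", names(mu))
  stopifnot(inherits(design, "study_design"))
  if (is.null(thresholds)) {
    k <- design$scale$n_points - 1L
    thresholds <- stats::qnorm(seq_len(k) / (k + 1)) * 1.3
  }
  if (sigma <= 0)
    abort_mascore("sigma must be positive", "mascore_invalid_config")
  if (length(thresholds) != design$scale$n_points - 1L ||
      any(diff(thresholds) <= 0))
    abort_mascore("thresholds must be strictly increasing with one cut per scale boundary",
                  "mascore_invalid_config")
  if (!setequal(names(mu), design$formulations))
    abort_mascore("mu must name exactly the design's formulations",
                  "mascore_invalid_config")
  if (!is_count(n) || n < 1)
    abort_mascore("n must be a positive integer", "mascore_invalid_config")
  if (choice_noise <= 0)
    abort_mascore("choice_noise must be positive", "mascore_invalid_config")
  structure(
    list(design = design, n = as.integer(n), mu = mu[design$formulations],
         sigma = sigma, thresholds = thresholds,
         link_a = link_a, link_b = link_b, choice_noise = choice_noise,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

rgumbel <- function(n) -log(-log(stats::runif(n)))

#' Simulate a synthetic taste-assessment cohort
#'
#' Draws a full response dataset from the latent-liking model described in
#' [sim_params()]. Single-evaluation (binary) designs simulate `n`
#' independent participants per formulation; repeated-measures
#' (forced-choice and rating) designs simulate `n` participants each
#' evaluating every formulation.
#'
#' @param params a [sim_params()].
#' @return A [response_dataset()]; identical `params` (including `seed`)
#'   yield identical datasets.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  design <- params$design
  scale <- design$scale
  set.seed(params$seed)
  cuts <- c(-Inf, params$thresholds, Inf)
  discretise <- function(latent)
    scale_scores(scale)[findInterval(latent, cuts, rightmost.closed = TRUE)]

  if (design$willingness_mode == "binary") {
    recs <- do.call(rbind, lapply(design$formulations, function(f) {
      latent <- stats::rnorm(params$n, params$mu[[f]], params$sigma)
      yes <- stats::runif(params$n) <
        stats::plogis(params$link_a + params$link_b * latent)
      data.frame(
        participant_id = paste0(gsub("\\s+", "_", f), "_", seq_len(params$n)),
        formulation_id = f,
        taste_score = discretise(latent),
        willing_binary = yes,
        stringsAsFactors = FALSE)
    }))
  } else {
    k <- length(design$formulations)
    latent <- matrix(stats::rnorm(params$n * k,
                                  mean = rep(params$mu[design$formulations],
                                             each = params$n),
                                  sd = params$sigma),
                     nrow = params$n, ncol = k,
                     dimnames = list(NULL, design$formulations))
    recs <- do.call(rbind, lapply(seq_len(k), function(j) {
      data.frame(
        participant_id = paste0("P", seq_len(params$n)),
        formulation_id = design$formulations[j],
        taste_score = discretise(latent[, j]),
        stringsAsFactors = FALSE)
    }))
    if (design$willingness_mode == "forced_choice") {
      util <- latent + params$choice_noise *
        matrix(rgumbel(params$n * k), nrow = params$n)
      vote <- design$formulations[max.col(util, ties.method = "first")]
      recs$willing_choice <- rep(vote, k)
    } else {
      wl <- params$link_a + params$link_b * latent +
        matrix(stats::rnorm(params$n * k, 0, params$sigma), nrow = params$n)
      ws <- matrix(discretise(wl), nrow = params$n)
      recs$willing_score <- as.vector(ws)
    }
  }
  response_dataset(design, recs)
}
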