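test_that("categorize splits scores around the passives range", {
  cases <- list(
    list(scores = c(1, 3, 3, 4, 4), passives = c(3, 3), expect = c(2, 2, 1)),
    list(scores = c(1, 3, 3, 4, 4), passives = c(2, 4), expect = c(0, 4, 1)),
    list(scores = c(3, 3, 3), passives = c(2, 4), expect = c(0, 3, 0)),
    list(scores = integer(0), passives = c(3, 3), expect = c(0, 0, 0))
  )
  for (cs in cases) {
    cc <- categorize(cs$scores, scale5, passives_range(cs$passives[1], cs$passives[2]))
    expect_equal(c(cc$promoters, cc$passives, cc$detractors), cs$expect)
    expect_equal(cc$n, length(cs$scores))
  }
})

test_that("mas matches the per-record brute-force oracle on random inputs", {
  set.seed(42)
  for (i in 1:50) {
    scores <- sample(1:5, sample(1:40, 1), replace = TRUE)
    p <- sort(sample(1:5, 2, replace = TRUE))
    passives <- passives_range(p[1], p[2])
    cc <- categorize(scores, scale5, passives)
    expect_equal(mas(cc, "exact"), mas_brute(scores, passives, "exact"))
    expect_equal(mas(cc, "paper"), mas_brute(scores, passives, "paper"))
    expect_true(abs(mas(cc, "paper") - mas(cc, "exact")) <= 0.5)
  }
})

test_that("mas hits its bounds at all-promoter and all-detractor inputs", {
  p3 <- passives_range(3)
  expect_equal(mas(categorize(rep(5, 7), scale5, p3)), 100)
  expect_equal(mas(categorize(rep(1, 7), scale5, p3)), -100)
  expect_equal(mas(categorize(rep(3, 7), scale5, p3)), 0)
  expect_equal(mas(categorize(c(1, 3, 3, 4, 4), scale5, p3)), 20)
  expect_error(mas(categorize(integer(0), scale5, p3)),
               class = "mascore_undefined_score")
})

test_that("paper-mode MAS rounds once on the final difference", {
  # count difference -52 over n = 70: -74.29 exact; a round-then-subtract
  # convention would give round(4.29) - round(78.57) = 4 - 79 = -75 instead
  cc <- categorize(c(rep(5, 3), rep(2, 17), rep(1, 38), rep(3, 12)),
                   scale5, passives_range(3))
  expect_equal(cc$promoters - cc$detractors, -52)
  expect_equal(mas(cc, "paper"), -74)
  expect_equal(mas(cc, "exact"), 100 * (-52) / 70)
})

test_that("binary WTMS deviates from the 50 percent neutral point", {
  expect_equal(wtms_binary(53, 68), 28)
  expect_equal(wtms_binary(45, 74), 11)
  expect_equal(wtms_binary(10, 20), 0)
  expect_equal(wtms_binary(0, 10), -50)
  expect_equal(wtms_binary(10, 10), 50)
  expect_equal(wtms_binary(45, 74, mode = "exact"), 100 * 45 / 74 - 50)
  expect_error(wtms_binary(5, 0), class = "mascore_undefined_score")
  expect_error(wtms_binary(11, 10), class = "mascore_invalid_argument")
})

test_that("forced-choice WTMS rounds share and neutral point separately", {
  expect_equal(wtms_choice(1, 21, 3), -28)   # exact -28.57 would round to -29
  expect_equal(wtms_choice(11, 21, 3), 19)
  expect_equal(wtms_choice(9, 21, 3), 10)
  expect_equal(wtms_choice(14, 25, 2), 6)
  for (k in 2:5) expect_equal(wtms_choice(12, 12, k), 100 - round_half_away(100 / k))
  expect_error(wtms_choice(1, 0, 3), class = "mascore_undefined_score")
  expect_error(wtms_choice(1, 5, 1), class = "mascore_invalid_argument")
})

test_that("forced-choice WTMS sums to zero over the alternatives (exact mode)", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(5:60, 1)
    votes <- as.vector(stats::rmultinom(1, n, runif(k)))
    total <- sum(vapply(votes, wtms_choice, numeric(1), n = n, k = k,
                        mode = "exact"))
    expect_equal(total, 0)
  }
})

test_that("widening the passives range moves MAS monotonically", {
  set.seed(11)
  for (i in 1:30) {
    scores <- sample(1:5, sample(5:50, 1), replace = TRUE)
    for (mode in c("paper", "exact")) {
      m <- function(lo, hi)
        mas(categorize(scores, scale5, passives_range(lo, hi)), mode)
      # absorbing detractors raises MAS; absorbing promoters lowers it
      expect_true(m(2, 3) >= m(3, 3))
      expect_true(m(3, 3) >= m(3, 4))
      expect_true(m(2, 3) >= m(2, 4))
      expect_true(m(2, 4) >= m(3, 4))
    }
  }
})

test_that("score_study dispatches WTMS on the willingness mode", {
  fx <- suppressMessages(study_fixtures())
  t2 <- score_study(fx$study2, passives_range(3))
  expect_equal(t2$wtms[t2$formulation_id == "TRM TMT"], 28)
  expect_equal(t2$n_wtms, c(68, 71))
  t3 <- score_study(fx$study3, passives_range(3))
  expect_equal(t3$wtms, c(19, 10, -28))
  t4r <- score_study(fx$study4_rating, passives_range(5, 7))
  expect_equal(t4r$wtms, c(40, 12))  # MAS-style scoring of willingness ratings
  expect_equal(t4r$mas, c(32, 0))
})

test_that("score_study flags unscoreable formulations instead of failing", {
  design <- study_design("s", scale5, "binary", c("A", "B"))
  ds <- response_dataset(design, data.frame(
    participant_id = c("p1", "p2"), formulation_id = "A",
    taste_score = c(3, 3), willing_binary = c(TRUE, FALSE)))
  tab <- score_study(ds, passives_range(3))
  expect_equal(tab$mas, c(0, NA))
  expect_equal(tab$wtms, c(0, NA))
  expect_equal(tab$n_mas, c(2L, 0L))
})

test_that("records missing a response drop out of that denominator only", {
  ds <- make_binary_dataset(c(1, NA, 5, 5), c(NA, TRUE, TRUE, FALSE))
  tab <- suppressMessages(score_study(ds, passives_range(3)))
  expect_equal(tab$n_mas, 3L)   # NA taste excluded
  expect_equal(tab$n_wtms, 3L)  # NA willingness excluded
  expect_equal(tab$mas, round_half_away(100 * (2 - 1) / 3))
})

test_that("same-seed simulated cohorts score identically", {
  params <- sim_params(n = 60, seed = 123)
  a <- score_study(simulate_cohort(params), passives_range(3))
  b <- score_study(simulate_cohort(params), passives_range(3))
  expect_identical(a, b)
})
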