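test_that("mas_matrix columns agree with score_study and obey monotonicity", {
  s123 <- fixtures123()
  m <- suppressMessages(mas_matrix(s123, c("2-3", "2-4", "3", "3-4")))
  expect_equal(dim(m), c(7L, 4L))
  # single candidate column equals the score_study output
  one <- suppressMessages(mas_matrix(s123$study2, list(passives_range(3))))
  t2 <- suppressMessages(score_study(s123$study2, passives_range(3)))
  expect_equal(as.vector(one), t2$mas)
  # widening monotonicity holds column-wise for every formulation
  expect_true(all(m[, "2-3"] >= m[, "3"]))
  expect_true(all(m[, "3"] >= m[, "3-4"]))
  expect_true(all(m[, "2-3"] >= m[, "2-4"]))
  expect_true(all(m[, "2-4"] >= m[, "3-4"]))
})

test_that("sign concordance applies the zero-fails rule", {
  w <- c(A = 28, B = 19, C = 11, D = 10, E = -13, F = -16, G = -28)
  m24 <- c(A = 28, B = 14, C = 0, D = 0, E = -54, F = -41, G = -33)
  m3 <- c(A = 41, B = 38, C = 19, D = 19, E = -74, F = -59, G = -57)
  expect_false(sign_concordance(m24, w)$pass)
  expect_equal(unname(which(!sign_concordance(m24, w)$detail)), c(3L, 4L))
  expect_true(sign_concordance(m24, w, zero_fails = FALSE)$pass)
  expect_true(sign_concordance(m3, w)$pass)
  expect_true(sign_concordance(w, w)$pass)
  expect_error(sign_concordance(c(A = 1), c(B = 1)),
               class = "mascore_alignment_error")
})

test_that("rank concordance is Kendall tau-b (brute-force pair oracle)", {
  w <- c(A = 28, B = 19, C = 11, D = 10)
  expect_equal(rank_concordance(c(A = 41, B = 38, C = 19, D = 19), w),
               5 / sqrt(30))
  expect_equal(rank_concordance(c(A = 50, B = 62, C = 27, D = 33), w), 1 / 3)
  expect_equal(rank_concordance(w, w), 1)
  set.seed(5)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    x <- stats::setNames(sample(-5:5, n, replace = TRUE), paste0("f", 1:n))
    y <- stats::setNames(sample(-5:5, n, replace = TRUE), paste0("f", 1:n))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(rank_concordance(x, y), tau_brute(x, y))
  }
  expect_error(rank_concordance(c(A = 1, B = 2), c(A = 5, B = -1),
                                subset = "positive_wtms"),
               class = "mascore_undefined_score")
})

test_that("passives-range selection reproduces the reference calibration", {
  res <- suppressMessages(select_passives_range(fixtures123()))
  expect_setequal(res$survivors, c("2-3", "3"))
  expect_equal(unname(res$concordance["3"]), 5 / sqrt(30))
  expect_equal(unname(res$concordance["2-3"]), 1 / 3)
  expect_equal(c(res$selected$low, res$selected$high), c(3L, 3L))
  # invariant to candidate ordering
  res2 <- suppressMessages(select_passives_range(
    fixtures123(), calibration_config(c("3-4", "3", "2-4", "2-3"))))
  expect_equal(format(res2$selected), "3")
})

test_that("selection tie-breaks and degenerate cases are deterministic", {
  ds <- make_binary_dataset(c(1, 5, 5, 4), c(TRUE, TRUE, TRUE, FALSE))
  # single candidate surviving -> selected even though tau is undefined (one formulation)
  res <- select_passives_range(ds, calibration_config("3"))
  expect_equal(format(res$selected), "3")
  expect_true(is.na(res$concordance["3"]))
  # identical concordance -> narrower range wins
  two <- list(make_binary_dataset(c(5, 5, 4, 1), c(TRUE, TRUE, TRUE, FALSE), "A"),
              make_binary_dataset(c(5, 4, 3, 1), c(TRUE, TRUE, FALSE, FALSE), "B"))
  res2 <- select_passives_range(two, calibration_config(c("2-3", "3")))
  expect_setequal(res2$survivors, c("2-3", "3"))
  expect_equal(format(res2$selected), "3")
  # no survivor -> explicit no-selection with reasons
  anti <- make_binary_dataset(c(1, 1, 2), c(TRUE, TRUE, TRUE))
  res3 <- select_passives_range(anti, calibration_config(c("2-3", "3")))
  expect_null(res3$selected)
  expect_length(res3$survivors, 0)
  expect_true(all(nzchar(res3$audit$reason)))
})

test_that("range transposition follows the x2 centre rule and clips", {
  sc11 <- rating_scale(0, 10)
  out <- transpose_range(passives_range(3), scale5, sc11)
  expect_equal(c(out$low, out$high), c(5L, 7L))
  # identity under factor 1, halfwidth 0
  same <- transpose_range(passives_range(3), scale5, scale5,
                          factor = 1, halfwidth = 0)
  expect_equal(c(same$low, same$high), c(3L, 3L))
  # affine rule centres on the proportional point instead
  aff <- transpose_range(passives_range(3), scale5, sc11, rule = "affine")
  expect_equal(c(aff$low, aff$high), c(4L, 6L))
  # clipping at the target boundary
  clipped <- transpose_range(passives_range(5), scale5, sc11)
  expect_equal(c(clipped$low, clipped$high), c(9L, 10L))
})
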