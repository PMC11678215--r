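test_that("reconstruction agrees with a full independent enumeration (tiny n)", {
  sc3 <- rating_scale(1, 3)
  n <- 6
  # oracle: enumerate every composition of n over 3 cells directly
  grid <- expand.grid(c1 = 0:n, c2 = 0:n)
  grid <- grid[grid$c1 + grid$c2 <= n, ]
  grid$c3 <- n - grid$c1 - grid$c2
  oracle_keep <- apply(grid, 1, function(cc) {
    scores <- rep(1:3, cc)
    mean_ok <- abs(mean(scores) - 2.0) <= 0.05 + 1e-9
    mas_val <- round_half_away(100 * (cc[3] - cc[1]) / n)
    med <- sort(scores)
    med_ok <- med[n / 2] == 2 && med[n / 2 + 1] == 2
    mean_ok && med_ok && mas_val == 0
  })
  oracle <- as.matrix(grid[oracle_keep, c("c1", "c2", "c3")])
  got <- reconstruct_counts(summary_constraints(
    n, sc3, median = 2, mean = 2.0, mean_digits = 1,
    mas_by_range = c("2" = 0)))
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(unname(got[order(got[, 1], got[, 2]), ]),
               unname(oracle[order(oracle[, 1], oracle[, 2]), ]))
  # lexicographic ordering of the returned set
  expect_true(all(diff(got[, 1]) >= 0))
})

test_that("published MAS triples force category tallies in the reconstruction", {
  sc <- rating_scale(1, 5)
  # n = 70 liquid arm: three published MAS values pin all three differences
  sols <- reconstruct_counts(summary_constraints(
    70, sc, mas_by_range = c("2-3" = -50, "2-4" = -54, "3-4" = -79)))
  expect_gt(nrow(sols), 0)
  d23 <- sols[, "4"] + sols[, "5"] - sols[, "1"]
  d24 <- sols[, "5"] - sols[, "1"]
  d34 <- sols[, "5"] - sols[, "1"] - sols[, "2"]
  expect_true(all(d23 == -35))
  expect_true(all(d24 == -38))
  expect_true(all(d34 == -55))
  expect_true(all(sols[, "2"] == 17))
  # n = 68 tablet arm: forced c2 and c4
  sols2 <- reconstruct_counts(summary_constraints(
    68, sc, mas_by_range = c("2-3" = 50, "2-4" = 28, "3-4" = 19)))
  expect_gt(nrow(sols2), 0)
  expect_true(all(sols2[, "2"] == 6))
  expect_true(all(sols2[, "4"] == 15))
})

test_that("contradictory constraints yield an empty feasible set", {
  sc <- rating_scale(1, 5)
  out <- reconstruct_counts(summary_constraints(5, sc, median = 1, mean = 5.0,
                                                mean_digits = 1))
  expect_equal(nrow(out), 0L)
  expect_error(reconstruct_counts(summary_constraints(201, sc, median = 3)),
               class = "mascore_search_bound")
})

test_that("reconstructed vectors verify their constraints through the scorer", {
  cons <- fixture_constraints()
  for (form in c("TRM TMT", "FLX LQD")) {
    cc <- cons[[form]]
    sols <- reconstruct_counts(cc)
    expect_gt(nrow(sols), 0)
    for (r in seq_len(nrow(sols))) {
      scores <- counts_to_scores(sols[r, ], cc$scale)
      expect_equal(length(scores), cc$n)
      expect_equal(stats::median(scores), cc$median)
      expect_true(abs(mean(scores) - cc$mean) <= 0.005 + 1e-9)
      for (i in seq_along(cc$mas_values)) {
        got <- mas(categorize(scores, cc$scale, cc$mas_ranges[[i]]), "paper")
        expect_equal(got, cc$mas_values[i])
      }
    }
  }
})

test_that("simulator is seed-deterministic and validates parameters", {
  p <- sim_params(n = 40, seed = 9)
  expect_identical(simulate_cohort(p), simulate_cohort(p))
  expect_error(sim_params(sigma = 0), class = "mascore_invalid_config")
  expect_error(sim_params(thresholds = c(0, 0, 1, 2)),
               class = "mascore_invalid_config")
  d2 <- study_design("s", rating_scale(1, 5), "binary", c("A", "B"))
  expect_error(sim_params(design = d2, mu = c(X = 1, Y = 0)),
               class = "mascore_invalid_config")
})

test_that("a flat willingness link gives WTMS near zero", {
  p <- sim_params(n = 10000, link_a = 0, link_b = 0, seed = 31)
  tab <- score_study(simulate_cohort(p), passives_range(3), mode = "exact")
  se <- 100 * sqrt(0.25 / 10000)
  expect_true(all(abs(tab$wtms) <= 3 * se))
})

test_that("higher latent liking propagates to higher MAS and WTMS", {
  p <- sim_params(n = 10000, seed = 17)
  tab <- score_study(simulate_cohort(p), passives_range(3), mode = "exact")
  expect_gt(tab$mas[tab$formulation_id == "TMT"],
            tab$mas[tab$formulation_id == "LQD"])
  expect_gt(tab$wtms[tab$formulation_id == "TMT"],
            tab$wtms[tab$formulation_id == "LQD"])
})

test_that("empirical MAS matches the analytic value implied by the model", {
  p <- sim_params(n = 10000, seed = 23)
  tab <- score_study(simulate_cohort(p), passives_range(3), mode = "exact")
  for (f in c("TMT", "LQD")) {
    mu <- p$mu[[f]]
    p_det <- stats::pnorm((p$thresholds[2] - mu) / p$sigma)
    p_pro <- 1 - stats::pnorm((p$thresholds[3] - mu) / p$sigma)
    analytic <- 100 * (p_pro - p_det)
    se <- 100 * sqrt((p_pro + p_det - (p_pro - p_det)^2) / p$n)
    expect_true(abs(tab$mas[tab$formulation_id == f] - analytic) <= 3 * se,
                info = f)
  }
})

test_that("forced-choice and rating simulators produce valid datasets", {
  d <- study_design("sim3", rating_scale(1, 5), "forced_choice",
                    c("A", "B", "C"))
  p <- sim_params(design = d, n = 50, mu = c(A = 1, B = 0, C = -1), seed = 3)
  ds <- simulate_cohort(p)
  expect_equal(nrow(ds$records), 150L)
  tab <- score_study(ds, passives_range(3), mode = "exact")
  expect_equal(sum(tab$wtms), 0)  # vote-share conservation
  dr <- study_design("sim4", rating_scale(0, 10), "rating", c("A", "B"))
  pr <- sim_params(design = dr, n = 30, mu = c(A = 1, B = -1), seed = 4)
  dsr <- simulate_cohort(pr)
  expect_true(all(dsr$records$willing_score %in% 0:10))
})
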