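test_that("degenerate and malformed inputs are rejected or saturate cleanly", {
  all_succ <- data.frame(saturation = c(0.1, 0.2, 0.4),
                         successes = c(5L, 5L, 5L), trials = c(5L, 5L, 5L))
  fit <- fit_modelfree(all_succ)
  expect_true(all(fit$p_hat >= 0.999))

  expect_error(fit_modelfree(data.frame(saturation = 0.1, successes = 1L,
                                        trials = 2L)), "unfittable")
  expect_error(fit_modelfree(data.frame(saturation = c(0.1, 0.2),
                                        successes = c(0L, 0L),
                                        trials = c(0L, 0L))), "empty-data")
  expect_error(fit_modelfree(data.frame(saturation = c(0.1, 0.2),
                                        successes = c(3L, 1L),
                                        trials = c(2L, 2L))), "format-error")
})

test_that("the large-bandwidth limit reproduces a global logistic regression", {
  set.seed(21)
  sat <- 0.9 * 0.5^(0:7)
  x <- log10(sat)
  p_true <- plogis(4 + 6 * x)
  n <- rep(30L, length(sat))
  k <- rbinom(length(sat), n, p_true)
  d <- data.frame(saturation = sat, successes = k, trials = n)

  fit <- fit_modelfree(d, fit_params(bandwidth = 60))
  g <- glm(cbind(k, n - k) ~ x, family = binomial)
  p_glm <- plogis(coef(g)[1] + coef(g)[2] * fit$grid_log10)
  expect_lt(max(abs(fit$p_hat - p_glm)), 1e-3)
})

test_that("the fit recovers a known logistic psychometric function", {
  # logit-linear truth: the degree-1 local fit is unbiased at any bandwidth
  set.seed(22)
  sat <- 0.9 * 0.5^(0:6)
  x <- log10(sat)
  p_true <- plogis(3.5 + 4 * x)
  n <- rep(500L, length(sat))
  k <- rbinom(length(sat), n, p_true)
  fit <- fit_modelfree(data.frame(saturation = sat, successes = k, trials = n))
  truth <- plogis(3.5 + 4 * fit$grid_log10)
  expect_lt(max(abs(fit$p_hat - truth)), 0.05)

  # threshold matches the analytic inverse within one grid step
  th <- threshold_at(fit, 0.5)
  analytic <- 10^((qlogis(0.5) - 3.5) / 4)
  step <- diff(fit$grid_log10[1:2])
  expect_lt(abs(log10(th$threshold) - log10(analytic)), 3 * step + 0.05)
  expect_identical(th$flag, "ok")
})

test_that("threshold extraction handles steps, chance-level curves and floors", {
  # step-shaped curve rising at the midpoint of the grid
  p_step <- c(rep(0.05, 100), rep(0.95, 101))
  fit <- synthetic_fit(p_step)
  th <- threshold_at(fit, 0.21)
  expect_identical(th$flag, "ok")
  expect_lt(abs(log10(th$threshold) - fit$grid_log10[100]),
            2 * diff(fit$grid_log10[1:2]))

  # chance-level performance never reaches 0.21: ceiling, unresolved
  flat <- synthetic_fit(rep(1 / 11, 201))
  th_flat <- threshold_at(flat, 0.21)
  expect_identical(th_flat$flag, "unresolved")
  expect_equal(th_flat$threshold, 0.9)

  # curve already above the level everywhere: floor at the grid minimum
  high <- synthetic_fit(rep(0.8, 201), grid_min = 0.01)
  th_high <- threshold_at(high, 0.21)
  expect_identical(th_high$flag, "floor")
  expect_equal(th_high$threshold, 0.01)

  # multiple crossings: the largest one wins
  wavy <- synthetic_fit(c(rep(0.05, 50), rep(0.5, 50), rep(0.1, 50),
                          rep(0.9, 51)))
  th_wavy <- threshold_at(wavy, 0.21)
  expect_gt(log10(th_wavy$threshold), wavy$grid_log10[149])

  expect_error(threshold_at(fit, 1.2), "invalid-level")
})

test_that("staircase sessions recover known observer thresholds", {
  # true thresholds from the independent closed-form oracle; 30 seeded
  # replicates spread over three target thresholds (the full 100-replicate
  # recovery check runs with the acceptance properties)
  targets <- c(0.05, 0.1, 0.2)
  rel_err <- c()
  for (j in seq_along(targets)) {
    r_star <- true_threshold_oracle(1, level = 0.21)
    sigma <- targets[j] / r_star
    for (i in 1:10) {
      s <- run_session(normal_observer(sigma), seed = 7000 + 100 * j + i)
      th <- session_thresholds(s)
      rel_err <- c(rel_err, abs(th$thresholds - targets[j]) / targets[j])
    }
  }
  expect_lt(median(rel_err), 0.30)
})

test_that("fit-parameter search returns the best-separating pair", {
  cohort <- simulate_cohort(7, prevalence = 3 / 7,
                            type_mix = c(deuteranomalous = 0, protanomalous = 0,
                                         deuteranope = 0.5, protanope = 0.5),
                            seed = 31)
  truth <- vapply(cohort$participants, `[[`, character(1), "truth")
  ids <- vapply(cohort$participants, `[[`, character(1), "id")
  pooled <- pool_cohort_observations(cohort)
  bw <- c(0.4, 0.7, 1.2)
  lv <- c(0.15, 0.21, 0.35)
  best <- optimize_fit_params(pooled, cvd_ids = ids[truth == "CVD"],
                              control_ids = ids[truth == "normal"],
                              bandwidths = bw, levels = lv, grid_size = 101L)
  expect_gt(attr(best, "objective"), 0)

  # exhaustively re-score every candidate pair: none beats the winner
  score <- function(h, level) {
    ratios <- vapply(pooled, function(per_axis) {
      th <- vapply(cvd_axes(), function(ax) {
        f <- fit_modelfree(per_axis[[ax]],
                           fit_params(bandwidth = h, grid_size = 101L))
        threshold_at(f, level)$threshold
      }, numeric(1))
      threshold_ratio(th)
    }, numeric(1))
    min(ratios[truth == "normal"]) - max(ratios[truth == "CVD"])
  }
  objs <- outer(bw, lv, Vectorize(score))
  expect_equal(attr(best, "objective"), max(objs), tolerance = 1e-12)

  # a single candidate pair is returned unchanged
  single <- optimize_fit_params(pooled, ids[truth == "CVD"],
                                ids[truth == "normal"],
                                bandwidths = 0.7, levels = 0.21,
                                grid_size = 101L)
  expect_equal(single$bandwidth, 0.7)
  expect_equal(single$level, 0.21)
})
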