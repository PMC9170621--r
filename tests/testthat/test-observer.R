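test_that("observer construction enforces the model's invariants", {
  expect_error(observer_model("normal",
                              c(protan = 0.05, deutan = 0.05, tritan = Inf)),
               "sigma_tritan must be finite")
  expect_error(normal_observer(lapse = 0.5), "lapse")
  expect_error(observer_model("normal",
                              c(protan = -1, deutan = 0.05, tritan = 0.05)),
               "invalid-observer")
})

test_that("a blind observer taps each target at exactly chance 1/11", {
  blind <- observer_model("deuteranope",
                          sigma = c(protan = Inf, deutan = Inf, tritan = 1e12))
  set.seed(51)
  tr <- make_trial(c(protan = 0.9, deutan = 0.9, tritan = 0.9))
  taps <- replicate(6000, tap_choice(tr, blind))
  for (ax in cvd_axes()) {
    expect_gt(binom.test(sum(taps == ax), length(taps), 1 / 11)$p.value, 0.001)
  }
  expect_gt(binom.test(sum(taps == "distractor"), length(taps), 8 / 11)$p.value,
            0.001)
})

test_that("tap rates match the closed-form choice probability at s = sigma", {
  obs <- normal_observer(0.3)
  set.seed(52)
  tr <- make_trial(c(protan = 0.3, deutan = 0.3, tritan = 0.3))
  taps <- replicate(8000, tap_choice(tr, obs))
  d <- 1 - exp(-1)                       # detection at s = sigma, beta = 2
  p_own <- d * (1 - (1 - d)^3) / (3 * d) + (1 - d)^3 / 11
  phat <- mean(taps == "protan")
  expect_lt(abs(phat - p_own), 4 * sqrt(p_own * (1 - p_own) / 8000))
})

test_that("a hypersensitive axis is always tapped and lapses are uniform", {
  sharp <- observer_model("normal",
                          sigma = c(protan = 1e-9, deutan = 1e9, tritan = 1e9))
  set.seed(53)
  tr <- make_trial(c(protan = 0.5, deutan = 0.5, tritan = 0.5))
  expect_true(all(replicate(200, tap_choice(tr, sharp)) == "protan"))

  lapser <- observer_model("normal",
                           sigma = c(protan = 1e-9, deutan = 1e9, tritan = 1e9),
                           lapse = 0.4)
  taps <- replicate(4000, tap_choice(tr, lapser))
  # lapses send ~0.4 * 10/11 of taps away from the detected target
  expect_gt(binom.test(sum(taps != "protan"), length(taps), 0.4 * 10 / 11)$p.value,
            0.001)
})

test_that("sessions terminate for normal observers and pin deficient axes at the cap", {
  s <- run_session(normal_observer(0.04), seed = 61)
  expect_true(s$complete)
  expect_lt(length(s$log), 1000L)

  deut <- deuteranope_observer()
  sd_ <- run_session(deut, seed = 62)
  tr <- session_trials(sd_)
  expect_gt(mean(tr$sat_deutan == 0.9, na.rm = TRUE), 0.5)
  th <- session_thresholds(sd_)
  expect_identical(th$flags[["deutan"]], "unresolved")
  expect_equal(th$thresholds[["deutan"]], 0.9)
  expect_lt(threshold_ratio(th$thresholds), 0.59)
})

test_that("dichromats classify as CVD across seeds with wide margin", {
  for (i in 1:12) {
    obs <- if (i %% 2) deuteranope_observer(0.05, lapse = 0.05) else
      observer_model("protanope",
                     sigma = c(protan = Inf, deutan = 0.6, tritan = 0.05),
                     lapse = 0.08)
    s <- run_session(obs, seed = 700 + i)
    th <- session_thresholds(s)
    expect_lt(threshold_ratio(th$thresholds), 0.59)
  }
})

test_that("normal observers produce threshold ratios concentrated around one", {
  # honest dispersion of the 70-observation pipeline: the ratio spread is
  # dominated by threshold-estimation noise (sd of log10 ratio ~0.18)
  cohort <- simulate_cohort(30, prevalence = 0, seed = 71)
  ev <- suppressWarnings(evaluate_cohort(cohort))
  r <- ev$results$ratio
  expect_gt(median(r), 0.8)
  expect_lt(median(r), 1.45)
  expect_gte(mean(r >= 0.6 & r <= 1.8), 0.8)
})

test_that("cohort simulation respects prevalence, type mix and replayability", {
  co <- simulate_cohort(200, prevalence = 0, seed = 81)
  expect_true(all(vapply(co$participants, `[[`, character(1), "truth") ==
                    "normal"))
  expect_true(all(vapply(co$participants, `[[`, integer(1),
                         "ishihara_errors") == 0L))

  co2 <- simulate_cohort(60, prevalence = 1, seed = 82)
  types <- vapply(co2$participants, function(p) p$observer$type, character(1))
  expect_true(all(types != "normal"))
  expect_true(all(vapply(co2$participants, `[[`, integer(1),
                         "ishihara_errors") >= 3L))
  for (p in co2$participants) {
    sig <- p$observer$sigma
    expect_true(is.finite(sig[["tritan"]]))
    if (p$observer$type %in% c("protanope", "deuteranope")) {
      expect_true(any(!is.finite(sig)))
    }
  }
  # bit-identical replay
  co3 <- simulate_cohort(60, prevalence = 1, seed = 82)
  expect_identical(co2, co3)
})

test_that("lapses move raw thresholds but leave the ratio comparatively stable", {
  obs <- normal_observer(0.05)
  reps <- lapply(1:8, function(i) {
    lapse_invariance_check(obs, c(0, 0.3), seed = 900 + i)
  })
  shift_t <- unlist(lapply(reps, function(r) {
    c(r$t_protan[2] / r$t_protan[1], r$t_deutan[2] / r$t_deutan[1],
      r$t_tritan[2] / r$t_tritan[1])
  }))
  shift_r <- vapply(reps, function(r) r$ratio[2] / r$ratio[1], numeric(1))
  # raw thresholds rise with the lapse rate; the ratio's location barely moves
  expect_gt(median(shift_t), 1)
  expect_lt(abs(log10(median(shift_r))), abs(log10(median(shift_t))))

  expect_error(lapse_invariance_check(obs, c(0, 0.5), seed = 1),
               "invalid-observer")
})
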