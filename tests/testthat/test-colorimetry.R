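test_that("MacLeod-Boynton coordinates are the cone ratios, and invert", {
  x <- mb_from_cones(2, 1, 0.03)
  expect_equal(x$l, 2 / 3)
  expect_equal(x$s, 0.01)
  expect_equal(x$lum, 3)

  x <- mb_from_cones(0.5, 0.5, 0)
  expect_equal(x$l, 0.5)
  expect_equal(x$s, 0)
  expect_equal(x$lum, 1)

  set.seed(11)
  for (i in 1:100) {
    cones <- c(runif(1, 0.1, 2), runif(1, 0.1, 2), runif(1, 0, 0.5))
    back <- cones_from_mb(mb_from_cones(cones[1], cones[2], cones[3]))
    expect_equal(unname(back), cones, tolerance = 1e-12)
  }

  expect_error(mb_from_cones(0, 0, 0.1), "invalid-cone-excitation")
  expect_error(cones_from_mb(mb_chromaticity(0.5, 0.1)),
               "underdetermined-conversion")
})

test_that("gamma encoding follows the power law and decode inverts encode", {
  p <- device_profile(
    model_id = "identity-gamma2",
    rgb_to_lms = diag(3),
    gamma = c(2, 2, 2),
    white = list(lum = 0.5),
    axis_endpoints = list(protan = list(l = 0.6160, s = 0.0186),
                          deutan = list(l = 0.6160, s = 0.0157),
                          tritan = list(l = 0.6553, s = 0.0033))
  )
  # square-root law: linear 0.25 encodes to 0.5 under gamma 2
  expect_equal(unname(rgb_from_cones(c(0.25, 0.25, 0.25), p)),
               rep(0.5, 3))
  for (v in seq(0.05, 0.95, by = 0.1)) {
    cones <- c(v, v / 2, v / 3)
    expect_equal(unname(cones_from_rgb(rgb_from_cones(cones, p), p)),
                 cones, tolerance = 1e-12)
  }
  expect_error(rgb_from_cones(c(2, 0.5, 0.5), p), "gamut-violation")
})

test_that("identity-matrix unit-gamma profile renders cones verbatim", {
  p <- device_profile(
    model_id = "identity", rgb_to_lms = diag(3), gamma = c(1, 1, 1),
    white = list(lum = 0.5),
    axis_endpoints = list(protan = list(l = 0.6160, s = 0.0186),
                          deutan = list(l = 0.6160, s = 0.0157),
                          tritan = list(l = 0.6553, s = 0.0033))
  )
  expect_equal(unname(rgb_from_cones(c(0.2, 0.3, 0.1), p)), c(0.2, 0.3, 0.1))
})

test_that("confusion-line targets interpolate affinely from white to endpoint", {
  p <- default_device_profile()
  w <- p$white
  for (ax in cvd_axes()) {
    at0 <- target_chromaticity(ax, 0, p)
    expect_equal(c(at0$l, at0$s), c(w$l, w$s))
  }
  ep <- target_chromaticity("protan", 1, p)
  expect_equal(c(ep$l, ep$s), c(0.6160, 0.0186))

  half <- target_chromaticity("tritan", 0.5, p)
  expect_equal(half$l, w$l)            # tritan confusion lines are vertical
  expect_equal(half$s, (w$s + 0.0033) / 2)

  # exact affinity in saturation
  for (ax in cvd_axes()) {
    e1 <- target_chromaticity(ax, 1, p)
    for (t in c(0.1, 0.37, 0.9)) {
      ch <- target_chromaticity(ax, t, p)
      expect_equal(ch$l - w$l, t * (e1$l - w$l), tolerance = 1e-14)
      expect_equal(ch$s - w$s, t * (e1$s - w$s), tolerance = 1e-14)
    }
  }
  expect_error(target_chromaticity("protan", 1.2, p), "invalid-saturation")
})

test_that("default profile white point lies on both red-green confusion lines", {
  p <- default_device_profile()
  expect_equal(p$white$l, 0.6553)
  # protan line through (0.6160, 0.0186) and copunctal (1, 0)
  s_protan_line <- 0.0186 * (1 - p$white$l) / (1 - 0.6160)
  # deutan line through (0.6160, 0.0157) and the origin
  s_deutan_line <- 0.0157 * p$white$l / 0.6160
  expect_lt(abs(p$white$s - s_protan_line), 2e-5)
  expect_lt(abs(p$white$s - s_deutan_line), 2e-5)
})

test_that("maximum in-gamut saturation matches a brute-force scan and is monotone in luminance", {
  p <- default_device_profile()
  for (ax in cvd_axes()) {
    t_hat <- max_in_gamut_saturation(ax, p, t_max = 2)
    if (t_hat < 2) {
      # brute force: linear RGB is affine in t, scan t at 1e-5 steps
      ts <- seq(0, 2, by = 1e-5)
      w <- p$white
      ep <- p$axis_endpoints[[ax]]
      l <- w$l + ts * (ep$l - w$l)
      s <- w$s + ts * (ep$s - w$s)
      lms <- rbind(l, 1 - l, s) * w$lum
      rgb <- p$lms_to_rgb %*% lms
      ok <- colSums(rgb >= -1e-9 & rgb <= 1 + 1e-9) == 3L
      t_brute <- ts[max(which(ok))]
      expect_lt(abs(t_hat - t_brute), 1e-4)
    }
    # doubling luminance near the gamut ceiling never increases the result
    hi <- max_in_gamut_saturation(ax, p, lum = 0.48)
    expect_lte(max_in_gamut_saturation(ax, p, lum = 0.96), hi + 1e-9)
  }
  expect_error(max_in_gamut_saturation("protan", p, lum = 1e6),
               "invalid-profile")
})

test_that("dichromat luminance signal is linear in saturation and reproduces the closed forms", {
  p <- default_device_profile()
  expect_identical(dichromat_luminance_signal("tritan", 0.9, p, "protanope"), 0)
  # protanope sees M; protan target at 0.9 raises M by ~10% of background
  expect_equal(dichromat_luminance_signal("protan", 0.9, p, "protanope"),
               0.9 * (0.6553 - 0.6160) / (1 - 0.6553), tolerance = 1e-10)
  expect_equal(dichromat_luminance_signal("protan", 0.9, p, "deuteranope"),
               -0.9 * (0.6553 - 0.6160) / 0.6553, tolerance = 1e-10)
  for (ty in c("protanope", "deuteranope")) {
    expect_equal(dichromat_luminance_signal("deutan", 0, p, ty), 0)
    s1 <- dichromat_luminance_signal("deutan", 1, p, ty)
    for (t in c(0.2, 0.5, 0.8)) {
      expect_equal(dichromat_luminance_signal("deutan", t, p, ty), t * s1,
                   tolerance = 1e-12)
    }
  }
  expect_equal(max_dichromat_luminance_cue(0.9, p), 0.102611,
               tolerance = 1e-5)
})

test_that("calibration audit reports zero residual cues for an identical profile", {
  p <- default_device_profile()
  rep0 <- audit_calibration_error(p, p, "protan", 0.9)
  expect_lt(rep0$residual_lum_cue, 1e-10)
  expect_lt(abs(rep0$residual_tritan_fraction), 1e-10)
})

test_that("calibration audit agrees with direct two-profile recomputation", {
  p <- default_device_profile()
  set.seed(7)
  for (i in 1:5) {
    m2 <- p$rgb_to_lms * (1 + matrix(runif(9, -0.01, 0.01), 3, 3))
    p2 <- device_profile("perturbed", m2, p$gamma,
                         list(l = p$white$l, s = p$white$s, lum = p$white$lum),
                         lapply(p$axis_endpoints, function(e) list(l = e$l, s = e$s)))
    rep1 <- audit_calibration_error(p, p2, "deutan", 0.9)
    # independent path: algebraic composition of the two calibrations
    view <- function(chrom) {
      lin <- solve(p$rgb_to_lms) %*% cones_from_mb(chrom)
      lms <- m2 %*% lin
      c(l = lms[1] / (lms[1] + lms[2]), s = lms[3] / (lms[1] + lms[2]))
    }
    tgt <- view(target_chromaticity("deutan", 0.9, p))
    wht <- view(p$white)
    expect_equal(rep1$displayed_target$l, unname(tgt["l"]), tolerance = 1e-10)
    expect_equal(rep1$displayed_white$s, unname(wht["s"]), tolerance = 1e-10)
    # 1% matrix errors leave the residual tritan cue far below the 16% noise
    expect_lt(abs(rep1$residual_tritan_fraction), 0.16)
  }
})
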