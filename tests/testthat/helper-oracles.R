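# Shared helpers: small observer constructors and an independent
# closed-form oracle for the session-measured psychometric function.

normal_observer <- function(sigma = 0.05, lapse = 0, beta = 2) {
  observer_model("normal",
                 sigma = c(protan = sigma, deutan = sigma, tritan = sigma),
                 beta = beta, lapse = lapse)
}

deuteranope_observer <- function(base = 0.05, neighbor_mult = 12, lapse = 0) {
  observer_model("deuteranope",
                 sigma = c(protan = base * neighbor_mult, deutan = Inf,
                           tritan = base),
                 lapse = lapse)
}

# Closed-form oracle for the probability measured by the pooling rule
# (own-target tap, conditional on the trial resolving by own tap or
# distractor tap), for an observer with equal detection probability e on
# the two other axes and d on the axis of interest, 3 targets + 8
# distractors:
#   own tap:     d * E[1/(1+Bin(2,e))] + (1-d)(1-e)^2 / 11
#   distractor:  (1-d)(1-e)^2 * 8/11
# Trials tapped on another axis's target are excluded by the pooling rule.
measured_p_oracle <- function(d, e) {
  E1 <- (1 - (1 - e)^3) / (3 * e)  # E[1/(1+K)], K ~ Bin(2, e)
  A <- d * E1
  B <- (1 - d) * (1 - e)^2 / 11
  (A + B) / (A + 9 * B)
}

# The staircase equilibrates where the measured success probability makes
# the expected log-saturation step zero: p log(0.5) + (1-p) log(1.5) = 0.
staircase_equilibrium_p <- function(down = 0.5, up = 1.5) {
  log(up) / (log(up) - log(down))
}

# True threshold of a symmetric-sigma observer at a given performance
# level: detection at the level's crossing, with the other two axes at
# their self-consistent staircase equilibrium detection rate.
true_threshold_oracle <- function(sigma, level = 0.21, beta = 2) {
  p_eq <- staircase_equilibrium_p()
  d_star <- stats::uniroot(function(e) measured_p_oracle(e, e) - p_eq,
                           c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  d_th <- stats::uniroot(function(d) measured_p_oracle(d, d_star) - level,
                         c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  sigma * (-log(1 - d_th))^(1 / beta)
}

# synthetic psychometric_fit object with a prescribed curve, for testing
# threshold extraction in isolation
synthetic_fit <- function(p_hat, grid_min = 0.005, grid_max = 0.9,
                          level = 0.21) {
  gl <- seq(log10(grid_min), log10(grid_max), length.out = length(p_hat))
  structure(list(grid = 10^gl, grid_log10 = gl, p_hat = p_hat,
                 bandwidth = 0.70, level = level, axis = NA_character_,
                 data = NULL),
            class = "psychometric_fit")
}
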