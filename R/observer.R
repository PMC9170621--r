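#' Parametric simulated observer
#'
#' A simulated participant taps items according to a simple detection
#' model: each active target is independently detected with probability
#' `1 - exp(-(s/sigma)^beta)` (a Weibull-style psychometric function of the
#' target's saturation `s`; `sigma = Inf` means the axis is never
#' detected), one detected target is tapped uniformly at random, and if
#' nothing is detected a tap lands uniformly on one of the 11 items. With
#' probability `lapse` the observer instead taps uniformly at random
#' regardless of the stimulus — a non-visual error that depresses
#' performance on all axes equally.
#'
#' @param type label: `"normal"`, `"protanomalous"`, `"deuteranomalous"`,
#'   `"protanope"` or `"deuteranope"`. Purely descriptive; behaviour is
#'   fully determined by `sigma`, `beta` and `lapse`.
#' @param sigma named positive sensitivity scales (saturation units) for
#'   `protan`, `deutan`, `tritan`; `Inf` allowed on the red-green axes.
#'   The tritan scale must be finite (congenital tritan deficiencies are
#'   extremely rare and are not modelled).
#' @param beta psychometric slope exponent, positive; default 2.
#' @param lapse lapse probability in `[0, 0.5)`.
#' @return An object of class `"observer_model"`.
#' @export
observer_model <- function(type = c("normal", "protanomalous", "deuteranomalous",
                                    "protanope", "deuteranope"),
                           sigma, beta = 2, lapse = 0) {
  type <- match.arg(type)
  stopifnot(all(cvd_axes() %in% names(sigma)))
  sigma <- stats::setNames(as.numeric(sigma[cvd_axes()]), cvd_axes())
  if (any(is.na(sigma)) || any(sigma <= 0)) {
    stop("invalid-observer: sigma must be positive (Inf allowed on red-green axes)")
  }
  if (!is.finite(sigma[["tritan"]])) {
    stop("invalid-observer: sigma_tritan must be finite")
  }
  if (!is.finite(beta) || beta <= 0) stop("invalid-observer: beta must be positive")
  if (!is.finite(lapse) || lapse < 0 || lapse >= 0.5) {
    stop("invalid-observer: lapse must lie in [0, 0.5)")
  }
  structure(list(type = type, sigma = sigma, beta = beta, lapse = lapse),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf("Simulated observer (%s): sigma %s, beta %.2g, lapse %.3f\n",
              x$type,
              paste(sprintf("%s=%.3g", names(x$sigma), x$sigma), collapse = " "),
              x$beta, x$lapse))
  invisible(x)
}

#' Simulated tap on one trial
#'
#' @param trial a [make_trial()] stimulus.
#' @param obs an [observer_model()].
#' @return `"protan"`, `"deutan"`, `"tritan"` or `"distractor"` — the role
#'   of the tapped item. Draws from the current RNG stream.
#' @export
tap_choice <- function(trial, obs) {
  stopifnot(inherits(trial, "trial_stimulus"), inherits(obs, "observer_model"))
  roles <- trial$items$role
  if (stats::runif(1) < obs$lapse) {
    return(roles[sample.int(length(roles), 1L)])
  }
  target_axes <- names(trial$active)[trial$active]
  if (length(target_axes)) {
    s <- trial$saturations[target_axes]
    p_det <- 1 - exp(-(s / obs$sigma[target_axes])^obs$beta)
    p_det[!is.finite(obs$sigma[target_axes])] <- 0
    detected <- target_axes[stats::runif(length(p_det)) < p_det]
    if (length(detected)) {
      return(detected[sample.int(length(detected), 1L)])
    }
  }
  roles[sample.int(length(roles), 1L)]
}

#' Run a full simulated staircase session
#'
#' Loops stimulus assembly, the observer's tap, and the staircase update
#' until both staircase sets complete. Deterministic given the seed.
#'
#' @param obs an [observer_model()].
#' @param seed integer seed for the session's RNG stream (stimulus noise,
#'   item order and observer choices all flow from it).
#' @param cfg an [engine_config()].
#' @param profile a [device_profile()].
#' @param max_trials guard against non-terminating sessions.
#' @return A completed `"cvd_session"`.
#' @export
run_session <- function(obs, seed = NULL, cfg = engine_config(),
                        profile = default_device_profile(),
                        max_trials = 10000L) {
  noise <- noise_config(cfg$lum_noise, cfg$tritan_noise)
  .with_seed(seed, {
    session <- init_session(seed = seed, cfg = cfg)
    while (!session$complete) {
      trial <- make_trial(session$saturation, active = session$active,
                          cfg = noise, profile = profile)
      session <- apply_tap(session, tap_choice(trial, obs))
      if (length(session$log) > max_trials) {
        stop("nonterminating-session: exceeded ", max_trials, " trials")
      }
    }
    session
  })
}

#' Simulate a screening cohort
#'
#' Draws `n` observers. Each is CVD with probability `prevalence`; CVD
#' observers get a deficiency type from `type_mix` (default mix echoes the
#' predominance of deutan deficiencies: 50% deuteranomalous, 25%
#' protanomalous, 15% deuteranope, 10% protanope). Every observer draws one
#' base sensitivity scale, uniform in `base_sigma_range`, applied to all
#' three axes — performance differences between axes then reflect the
#' deficiency alone, while overall sensitivity and the common lapse rate
#' (uniform in `lapse_range`) vary between children. Anomalous trichromats
#' multiply the affected red-green axis by uniform `anomalous_mult` and the
#' neighbouring red-green axis by uniform `anomalous_neighbor_mult` (the
#' two red-green confusion lines are close together in colour space, so a
#' deficit on one degrades the other); dichromats have an infinite scale on
#' the affected axis and multiply the neighbour by
#' `dichromat_neighbor_mult`. Reference-test error counts are emulated as 0
#' for normals and 3 plus a Poisson(3) draw for CVD observers.
#'
#' Every observer's tritan scale is additionally multiplied by
#' `tritan_sigma_factor` (default 1.2). A unit of tritan saturation (a
#' fraction of that axis's own maximum in-gamut excursion) is somewhat
#' harder to detect than a unit of red-green saturation; the default is
#' calibrated so that the full pipeline reproduces the location of the
#' control group's threshold-ratio distribution reported for the reference
#' cohorts (mean minimum tritan:red-green ratio near 1.08). Tritan
#' discrimination itself remains intact for every simulated observer.
#'
#' @param n cohort size.
#' @param prevalence CVD prevalence; default 0.08.
#' @param type_mix named probabilities over the four CVD types; must sum
#'   to 1.
#' @param seed integer seed; participants also receive derived per-session
#'   seeds so the whole cohort replays identically.
#' @param base_sigma_range,lapse_range,anomalous_mult,
#'   anomalous_neighbor_mult,dichromat_neighbor_mult parameter ranges as
#'   described above.
#' @param tritan_sigma_factor population tritan:red-green sensitivity-scale
#'   ratio applied to every observer.
#' @param beta psychometric slope exponent shared by all observers.
#' @return An object of class `"simulated_cohort"`: list with
#'   `participants` (each a list `id`, `observer`, `truth`
#'   (`"CVD"`/`"normal"`), `ishihara_errors`, `session_seed`),
#'   `prevalence`, `seed`.
#' @export
simulate_cohort <- function(n, prevalence = 0.08,
                            type_mix = c(deuteranomalous = 0.50,
                                         protanomalous = 0.25,
                                         deuteranope = 0.15,
                                         protanope = 0.10),
                            seed = NULL,
                            base_sigma_range = c(0.03, 0.08),
                            lapse_range = c(0, 0.1),
                            anomalous_mult = c(5, 20),
                            anomalous_neighbor_mult = c(2, 6),
                            dichromat_neighbor_mult = c(8, 30),
                            tritan_sigma_factor = 1.2,
                            beta = 2) {
  stopifnot(n > 0, prevalence >= 0, prevalence <= 1)
  if (abs(sum(type_mix) - 1) > 1e-8) {
    stop("invalid-mix: type_mix must sum to 1")
  }
  .with_seed(seed, {
    is_cvd <- stats::runif(n) < prevalence
    participants <- lapply(seq_len(n), function(i) {
      type <- if (is_cvd[i]) {
        sample(names(type_mix), 1L, prob = type_mix)
      } else "normal"
      obs <- .draw_observer(type, base_sigma_range, lapse_range,
                            anomalous_mult, anomalous_neighbor_mult,
                            dichromat_neighbor_mult, tritan_sigma_factor,
                            beta)
      list(
        id = sprintf("P%03d", i),
        observer = obs,
        truth = if (is_cvd[i]) "CVD" else "normal",
        ishihara_errors = if (is_cvd[i]) 3L + stats::rpois(1L, 3) else 0L,
        session_seed = if (is.null(seed)) NULL else .child_seed(seed, i)
      )
    })
    structure(list(participants = participants, prevalence = prevalence,
                   seed = seed),
              class = "simulated_cohort")
  })
}

.draw_observer <- function(type, base_sigma_range, lapse_range,
                           anomalous_mult, anomalous_neighbor_mult,
                           dichromat_neighbor_mult, tritan_sigma_factor,
                           beta) {
  base <- stats::runif(1, base_sigma_range[1], base_sigma_range[2])
  sigma <- stats::setNames(rep(base, 3L), cvd_axes())
  sigma["tritan"] <- sigma["tritan"] * tritan_sigma_factor
  affected <- switch(type,
                     protanomalous = , protanope = "protan",
                     deuteranomalous = , deuteranope = "deutan",
                     NULL)
  neighbor <- switch(type,
                     protanomalous = , protanope = "deutan",
                     deuteranomalous = , deuteranope = "protan",
                     NULL)
  if (type %in% c("protanomalous", "deuteranomalous")) {
    sigma[affected] <- sigma[affected] *
      stats::runif(1, anomalous_mult[1], anomalous_mult[2])
    sigma[neighbor] <- sigma[neighbor] *
      stats::runif(1, anomalous_neighbor_mult[1], anomalous_neighbor_mult[2])
  } else if (type %in% c("protanope", "deuteranope")) {
    sigma[affected] <- Inf
    sigma[neighbor] <- sigma[neighbor] *
      stats::runif(1, dichromat_neighbor_mult[1], dichromat_neighbor_mult[2])
  }
  observer_model(type = type, sigma = sigma, beta = beta,
                 lapse = stats::runif(1, lapse_range[1], lapse_range[2]))
}

#' @export
print.simulated_cohort <- function(x, ...) {
  truth <- vapply(x$participants, `[[`, character(1), "truth")
  cat(sprintf("Simulated cohort: %d participants (%d CVD, %d normal), prevalence %.2f\n",
              length(truth), sum(truth == "CVD"), sum(truth == "normal"),
              x$prevalence))
  invisible(x)
}

#' Ratio stability under lapse-rate changes
#'
#' Runs the full session-fit-ratio pipeline for the same sensitivity
#' profile at several lapse rates. Raw thresholds rise with the lapse rate
#' (lapses depress performance everywhere), but because they rise on all
#' three axes together the threshold ratio stays comparatively stable —
#' the property that motivates classifying on the ratio rather than on raw
#' thresholds.
#'
#' @param obs an [observer_model()] providing the sigma profile; its own
#'   lapse value is ignored.
#' @param lapse_values lapse rates to probe, each in `[0, 0.5)`.
#' @param seed integer seed (one derived session seed per lapse value).
#' @param params a [fit_params()].
#' @param cfg an [engine_config()].
#' @return Data frame with one row per lapse value: `lapse`, `t_protan`,
#'   `t_deutan`, `t_tritan`, `ratio`.
#' @export
lapse_invariance_check <- function(obs, lapse_values, seed = NULL,
                                   params = fit_params(),
                                   cfg = engine_config()) {
  rows <- lapply(seq_along(lapse_values), function(i) {
    o <- observer_model(obs$type, obs$sigma, obs$beta, lapse_values[i])
    sess <- run_session(o, seed = if (is.null(seed)) NULL else .child_seed(seed, i),
                        cfg = cfg)
    th <- session_thresholds(sess, params = params, cfg = cfg)
    data.frame(lapse = lapse_values[i],
               t_protan = th$thresholds[["protan"]],
               t_deutan = th$thresholds[["deutan"]],
               t_tritan = th$thresholds[["tritan"]],
               ratio = threshold_ratio(th$thresholds))
  })
  do.call(rbind, rows)
}
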