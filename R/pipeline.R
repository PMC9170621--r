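#' Per-axis thresholds of a completed session
#'
#' Pools each axis's observations across both staircase sets, fits the
#' model-free psychometric function, and reads off the threshold at the
#' configured performance level. Ceiling-flagged (unresolved) thresholds
#' enter downstream ratios at the 0.9 ceiling; floor-flagged ones at the
#' lowest tested level.
#'
#' An axis whose observations all sit at a single saturation level (which
#' can happen when a dichromat's staircase never leaves the ceiling) cannot
#' be fitted; it is resolved directly: observed success rate below the
#' performance level gives the ceiling with flag `"unresolved"`, at or
#' above it the tested level itself with flag `"floor"`.
#'
#' @param session a completed session (from [run_session()] or replayed
#'   from a log).
#' @param params a [fit_params()].
#' @param cfg an [engine_config()] (supplies the validity floor and the
#'   saturation ceiling).
#' @return List with `thresholds` (named numeric), `flags` (named
#'   character), `fits` (named list; `NULL` for degenerate axes).
#' @export
session_thresholds <- function(session, params = fit_params(),
                               cfg = if (!is.null(session$cfg)) session$cfg
                                     else engine_config()) {
  ths <- flags <- stats::setNames(vector("list", 3L), cvd_axes())
  fits <- stats::setNames(vector("list", 3L), cvd_axes())
  for (ax in cvd_axes()) {
    data <- pool_observations(session, ax, min_trials = cfg$min_valid_trials)
    if (length(unique(signif(data$saturation, 12))) < 2L) {
      rate <- sum(data$successes) / sum(data$trials)
      if (rate < params$level) {
        ths[[ax]] <- cfg$start_saturation
        flags[[ax]] <- "unresolved"
      } else {
        ths[[ax]] <- data$saturation[1]
        flags[[ax]] <- "floor"
      }
    } else {
      fit <- fit_modelfree(data, params, grid_max = cfg$start_saturation,
                           axis = ax)
      th <- threshold_at(fit)
      fits[[ax]] <- fit
      ths[[ax]] <- th$threshold
      flags[[ax]] <- th$flag
    }
  }
  list(thresholds = unlist(ths), flags = unlist(flags), fits = fits)
}

#' Run a simulated cohort through the full screening pipeline
#'
#' For every participant: run a complete staircase session, pool
#' observations, fit the model-free psychometric functions, compute the
#' tritan:red-green threshold ratio, and classify at the criterion. The
#' resulting labels are scored against the cohort's ground truth (and the
#' emulated reference-test grouping is reported alongside).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param params a [fit_params()].
#' @param criterion threshold-ratio criterion; default from `cfg`.
#' @param cfg an [engine_config()].
#' @param profile a [device_profile()].
#' @param progress print a dot per participant (useful for large cohorts).
#' @return List with `results` (data frame: `id`, `truth`,
#'   `ishihara_errors`, `reference_group`, `t_protan`, `t_deutan`,
#'   `t_tritan`, `flag_protan`, `flag_deutan`, `flag_tritan`, `ratio`,
#'   `label`, `n_trials`) and `metrics` (from [confusion_metrics()],
#'   scored against ground truth).
#' @export
evaluate_cohort <- function(cohort, params = fit_params(),
                            criterion = cfg$criterion,
                            cfg = engine_config(),
                            profile = default_device_profile(),
                            progress = FALSE) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  rows <- lapply(cohort$participants, function(p) {
    sess <- run_session(p$observer, seed = p$session_seed, cfg = cfg,
                        profile = profile)
    th <- session_thresholds(sess, params = params, cfg = cfg)
    ratio <- threshold_ratio(th$thresholds)
    if (progress) cat(".")
    data.frame(
      id = p$id, truth = p$truth,
      ishihara_errors = p$ishihara_errors,
      reference_group = ishihara_group(p$ishihara_errors),
      t_protan = th$thresholds[["protan"]],
      t_deutan = th$thresholds[["deutan"]],
      t_tritan = th$thresholds[["tritan"]],
      flag_protan = th$flags[["protan"]],
      flag_deutan = th$flags[["deutan"]],
      flag_tritan = th$flags[["tritan"]],
      ratio = ratio,
      label = classify_ratio(ratio, criterion),
      n_trials = length(sess$log),
      stringsAsFactors = FALSE
    )
  })
  if (progress) cat("\n")
  results <- do.call(rbind, rows)
  list(results = results,
       metrics = confusion_metrics(results$label, results$truth))
}

#' Pool a cohort's observations for parameter optimisation
#'
#' Runs every participant's session and returns the pooled per-axis
#' observation tables keyed by participant id, the shape
#' [optimize_fit_params()] consumes.
#'
#' @inheritParams evaluate_cohort
#' @return Named list (participant id) of named lists (axis) of pooled
#'   observation data frames.
#' @export
pool_cohort_observations <- function(cohort, cfg = engine_config(),
                                     profile = default_device_profile()) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  out <- lapply(cohort$participants, function(p) {
    sess <- run_session(p$observer, seed = p$session_seed, cfg = cfg,
                        profile = profile)
    stats::setNames(lapply(cvd_axes(), function(ax) {
      pool_observations(sess, ax, min_trials = cfg$min_valid_trials)
    }), cvd_axes())
  })
  names(out) <- vapply(cohort$participants, `[[`, character(1), "id")
  out
}
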