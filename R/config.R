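#' Engine configuration
#'
#' All tunable constants of the screening engine with their reference
#' defaults: the staircase geometry (start saturation 0.9, down/up
#' multipliers 0.5 and 1.5, 35 update events per staircase per set, two
#' sets), the 40-trial validity floor, the trial composition (8 achromatic
#' distractors alongside the targets), the masking-noise amplitudes
#' (luminance +/-20%, tritan +/-16%), the psychometric fit parameters
#' (bandwidth 0.70 in log10-saturation units, performance level 0.21), the
#' classification criterion ratio 0.59, and the assumed population CVD
#' prevalence 0.08.
#'
#' @param start_saturation initial staircase saturation.
#' @param down_factor multiplier applied to an axis after its target is
#'   tapped.
#' @param up_factor multiplier applied to all active axes after a
#'   distractor is tapped (capped at `start_saturation`).
#' @param set_quota update events per staircase per set.
#' @param n_sets number of sequential staircase sets.
#' @param min_valid_trials minimum trials for a session to count.
#' @param n_distractors distractors shown when all axes are active.
#' @param lum_noise half-range of the luminance noise.
#' @param tritan_noise binary tritan noise amplitude.
#' @param bandwidth model-free fit bandwidth (log10-saturation units).
#' @param level performance level defining the threshold.
#' @param criterion threshold-ratio criterion separating CVD from normal.
#' @param prevalence assumed CVD prevalence for cohort simulation.
#' @return An object of class `"engine_config"` (a named list).
#' @export
engine_config <- function(start_saturation = 0.9,
                          down_factor = 0.5,
                          up_factor = 1.5,
                          set_quota = 35L,
                          n_sets = 2L,
                          min_valid_trials = 40L,
                          n_distractors = 8L,
                          lum_noise = 0.20,
                          tritan_noise = 0.16,
                          bandwidth = 0.70,
                          level = 0.21,
                          criterion = 0.59,
                          prevalence = 0.08) {
  cfg <- list(
    start_saturation = start_saturation, down_factor = down_factor,
    up_factor = up_factor, set_quota = as.integer(set_quota),
    n_sets = as.integer(n_sets),
    min_valid_trials = as.integer(min_valid_trials),
    n_distractors = as.integer(n_distractors),
    lum_noise = lum_noise, tritan_noise = tritan_noise,
    bandwidth = bandwidth, level = level, criterion = criterion,
    prevalence = prevalence
  )
  stopifnot(cfg$start_saturation > 0, cfg$start_saturation <= 1,
            cfg$down_factor > 0, cfg$down_factor < 1, cfg$up_factor > 1,
            cfg$set_quota > 0, cfg$n_sets >= 1, cfg$level > 0, cfg$level < 1,
            cfg$bandwidth > 0, cfg$criterion > 0, cfg$prevalence >= 0,
            cfg$prevalence <= 1)
  structure(cfg, class = "engine_config")
}

#' Read or write an engine configuration as JSON
#'
#' Unknown fields in the file are rejected so that typos do not silently
#' fall back to defaults; missing fields take their defaults.
#'
#' @param path file path.
#' @return `read_engine_config` returns an [engine_config()];
#'   `write_engine_config` invisibly returns `path`.
#' @export
read_engine_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(engine_config))
  extra <- setdiff(names(j), known)
  if (length(extra)) {
    stop("format-error: unknown engine_config field(s): ",
         paste(extra, collapse = ", "))
  }
  do.call(engine_config, j)
}

#' @rdname read_engine_config
#' @param cfg an [engine_config()].
#' @export
write_engine_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "engine_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# run code with the global RNG seeded, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a bounded child seed from a base seed and a stream index
.child_seed <- function(seed, k) {
  (as.numeric(seed) * 69069 + 12345 * as.numeric(k)) %% 2147483587 + 1
}
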