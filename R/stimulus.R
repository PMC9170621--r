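#' Masking-noise configuration
#'
#' Two noise sources mask the residual cues a colour-deficient observer
#' could otherwise exploit: item luminances are drawn uniformly from a band
#' of +/- `lum_half_range` around the mean (default 20%, comfortably above
#' the ~10% maximum dichromat luminance cue of the red-green targets), and
#' every item's `s` coordinate is shifted by binary tritan noise of
#' +/- `tritan_amplitude` times the background `s` (default 16%, above the
#' ~8% maximum tritan leakage of the red-green targets).
#'
#' @param lum_half_range half-range of the uniform luminance noise, as a
#'   fraction of the mean luminance; in (0, 1).
#' @param tritan_amplitude binary tritan noise amplitude, as a fraction of
#'   the background `s`; in (0, 1).
#' @return An object of class `"noise_config"`.
#' @export
noise_config <- function(lum_half_range = 0.20, tritan_amplitude = 0.16) {
  stopifnot(lum_half_range > 0, lum_half_range < 1,
            tritan_amplitude > 0, tritan_amplitude < 1)
  structure(list(lum_half_range = lum_half_range,
                 tritan_amplitude = tritan_amplitude),
            class = "noise_config")
}

.n_items <- 11L

#' Assemble one trial of the tapping task
#'
#' A trial shows 11 items: one target per active confusion axis and
#' achromatic distractors filling the remaining slots (8 distractors when
#' all three axes are active; an inactive axis is replaced by an extra
#' distractor). Each item independently receives a uniform luminance draw
#' in `[1 - lum_half_range, 1 + lum_half_range]` times the mean and an
#' equiprobable binary tritan shift of `+/- tritan_amplitude * s_white`.
#' Item positions are a uniform random permutation of the 11 slots.
#'
#' Noise draws that would push an item out of the device gamut are redrawn
#' (up to 100 times), then clipped with a warning; with the default profile
#' at background luminance this never triggers.
#'
#' @param saturations named numeric with entries `protan`, `deutan`,
#'   `tritan`: the target saturation of each axis. Active axes must lie in
#'   (0, 0.9].
#' @param active named logical with the same names; inactive axes are shown
#'   as distractors.
#' @param cfg a [noise_config()].
#' @param profile a [device_profile()].
#' @return An object of class `"trial_stimulus"`: a list with `items`
#'   (data frame: `role`, `l`, `s_nominal`, `tritan_sign`, `s`, `lum_frac`,
#'   `position`), `saturations` (NA for inactive axes), `active`, `cfg`.
#' @export
make_trial <- function(saturations,
                       active = c(protan = TRUE, deutan = TRUE, tritan = TRUE),
                       cfg = noise_config(),
                       profile = default_device_profile()) {
  axes <- cvd_axes()
  stopifnot(all(axes %in% names(active)))
  active <- as.logical(active[axes])
  names(active) <- axes
  sat <- rep(NA_real_, 3L)
  names(sat) <- axes
  sat[names(saturations)] <- as.numeric(saturations)
  if (any(active & (!is.finite(sat) | sat <= 0))) {
    stop("invalid-saturation: every active axis needs a saturation in (0, 0.9]")
  }
  if (any(active & sat > 0.9 + 1e-12)) {
    stop("saturation-overflow: active saturation exceeds the 0.9 ceiling")
  }
  sat[!active] <- NA_real_

  w <- profile$white
  roles <- c(axes[active], rep("distractor", .n_items - sum(active)))
  l <- s_nom <- numeric(.n_items)
  for (i in seq_along(roles)) {
    if (roles[i] == "distractor") {
      l[i] <- w$l; s_nom[i] <- w$s
    } else {
      ch <- target_chromaticity(roles[i], sat[[roles[i]]], profile)
      l[i] <- ch$l; s_nom[i] <- ch$s
    }
  }

  draw <- function(n) {
    list(lum = stats::runif(n, 1 - cfg$lum_half_range, 1 + cfg$lum_half_range),
         sign = sample(c(-1, 1), n, replace = TRUE))
  }
  d <- draw(.n_items)
  lum_frac <- d$lum
  sign <- d$sign
  s_noisy <- s_nom + sign * cfg$tritan_amplitude * w$s

  # gamut audit on the noisy items, vectorised over the trial
  lin_of <- function(lf, sn) {
    lum <- lf * w$lum
    cones <- rbind(l * lum, (1 - l) * lum, sn * lum)
    profile$lms_to_rgb %*% cones
  }
  bad <- function(lin) {
    apply(lin < -.gamut_tol | lin > 1 + .gamut_tol, 2, any)
  }
  viol <- bad(lin_of(lum_frac, s_noisy))
  tries <- 0L
  while (any(viol) && tries < 100L) {
    idx <- which(viol)
    rd <- draw(length(idx))
    lum_frac[idx] <- rd$lum
    sign[idx] <- rd$sign
    s_noisy[idx] <- s_nom[idx] + sign[idx] * cfg$tritan_amplitude * w$s
    viol <- bad(lin_of(lum_frac, s_noisy))
    tries <- tries + 1L
  }
  if (any(viol)) {
    warning("gamut-clip: ", sum(viol),
            " item(s) remained out of gamut after 100 redraws; clipping")
  }

  items <- data.frame(
    role = roles,
    l = l,
    s_nominal = s_nom,
    tritan_sign = sign,
    s = pmax(s_noisy, 0),
    lum_frac = lum_frac,
    position = sample.int(.n_items),
    stringsAsFactors = FALSE
  )
  structure(list(items = items, saturations = sat, active = active, cfg = cfg),
            class = "trial_stimulus")
}

#' @export
print.trial_stimulus <- function(x, ...) {
  tg <- x$items$role != "distractor"
  cat(sprintf("Trial: %d targets (%s), %d distractors\n", sum(tg),
              paste(x$items$role[tg], collapse = ", "), sum(!tg)))
  sat <- x$saturations[!is.na(x$saturations)]
  if (length(sat)) {
    cat("  saturations:",
        paste(sprintf("%s=%.4f", names(sat), sat), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Residual cues a dichromat can see in a trial
#'
#' For each item, reports the chromatic luminance cue (the
#' [dichromat_luminance_signal()] implied by the item's `l` coordinate),
#' the luminance noise draw, and the total relative luminance the named
#' dichromat experiences: `lum_frac * (1 + chromatic cue) - 1`. On a
#' properly masked trial the target totals are statistically buried in the
#' distractor totals.
#'
#' @param trial a [make_trial()] result.
#' @param profile the [device_profile()] used to build the trial.
#' @param type `"protanope"` or `"deuteranope"`.
#' @return Data frame with columns `role`, `chromatic_cue`, `lum_frac`,
#'   `total_cue`.
#' @export
dichromat_visible_cue <- function(trial, profile = default_device_profile(),
                                  type = c("protanope", "deuteranope")) {
  type <- match.arg(type)
  l_w <- profile$white$l
  l_i <- trial$items$l
  chrom <- if (type == "protanope") (l_w - l_i) / (1 - l_w) else (l_i - l_w) / l_w
  data.frame(
    role = trial$items$role,
    chromatic_cue = chrom,
    lum_frac = trial$items$lum_frac,
    total_cue = trial$items$lum_frac * (1 + chrom) - 1,
    stringsAsFactors = FALSE
  )
}
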