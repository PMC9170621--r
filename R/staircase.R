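#' Start a new adaptive-staircase session
#'
#' A session runs three interleaved staircases, one per confusion axis, each
#' starting at the top tested saturation (0.9 by default). Tapping a target
#' halves that axis's saturation; tapping a distractor multiplies every
#' active axis's saturation by 1.5 (capped at the start saturation). Each
#' of those events is one update for the staircase(s) concerned. A
#' staircase that accumulates 35 updates within the current set deactivates
#' (its target is replaced by a distractor); when all three reach 35 the
#' next set begins with counts reset and saturations carried over, and the
#' session completes at the end of the second set.
#'
#' @param seed integer recorded in the session for provenance (the session
#'   controller itself draws no random numbers; randomness lives in the
#'   stimulus and observer layers).
#' @param cfg an [engine_config()].
#' @return An object of class `"cvd_session"`: a list with `saturation`,
#'   `update_count`, `active` (named by axis), `set_index`, `complete`,
#'   `log` (list of trial records), `seed`, `cfg`.
#' @export
init_session <- function(seed = NULL, cfg = engine_config()) {
  axes <- cvd_axes()
  structure(list(
    saturation = stats::setNames(rep(cfg$start_saturation, 3L), axes),
    update_count = stats::setNames(rep(0L, 3L), axes),
    active = stats::setNames(rep(TRUE, 3L), axes),
    set_index = 1L,
    complete = FALSE,
    log = list(),
    seed = seed,
    cfg = cfg
  ), class = "cvd_session")
}

#' @export
print.cvd_session <- function(x, ...) {
  cat(sprintf("Staircase session: %d trials, set %d, %s\n",
              length(x$log), x$set_index,
              if (x$complete) "complete" else "in progress"))
  cat("  saturation:",
      paste(sprintf("%s=%.4f", names(x$saturation), x$saturation),
            collapse = ", "), "\n")
  cat("  updates this set:",
      paste(sprintf("%s=%d", names(x$update_count), x$update_count),
            collapse = ", "), "\n")
  invisible(x)
}

#' Apply one tap to a session
#'
#' Records the trial (the presented per-axis saturations, with `NA` for
#' deactivated axes, and what was tapped) and advances the staircase state.
#'
#' @param session a [init_session()] object.
#' @param tapped `"protan"`, `"deutan"`, `"tritan"` or `"distractor"`.
#' @return The updated session.
#' @export
apply_tap <- function(session, tapped) {
  stopifnot(inherits(session, "cvd_session"))
  tapped <- match.arg(tapped, c(cvd_axes(), "distractor"))
  if (session$complete) {
    stop("protocol-violation: session is already complete")
  }
  if (tapped != "distractor" && !session$active[[tapped]]) {
    stop("protocol-violation: tap on inactive axis ", tapped)
  }
  cfg <- session$cfg
  presented <- ifelse(session$active, session$saturation, NA_real_)
  names(presented) <- names(session$saturation)
  session$log[[length(session$log) + 1L]] <- list(
    trial_index = length(session$log) + 1L,
    set_index = session$set_index,
    saturation = presented,
    tapped = tapped
  )

  if (tapped == "distractor") {
    up <- session$active
    session$saturation[up] <- pmin(session$saturation[up] * cfg$up_factor,
                                   cfg$start_saturation)
    session$update_count[up] <- session$update_count[up] + 1L
  } else {
    session$saturation[[tapped]] <- session$saturation[[tapped]] * cfg$down_factor
    session$update_count[[tapped]] <- session$update_count[[tapped]] + 1L
  }
  session$active <- session$active & session$update_count < cfg$set_quota

  if (all(session$update_count >= cfg$set_quota)) {
    if (session$set_index < cfg$n_sets) {
      session$set_index <- session$set_index + 1L
      session$update_count[] <- 0L
      session$active[] <- TRUE
    } else {
      session$complete <- TRUE
      session$active[] <- FALSE
    }
  }
  session
}

#' Trial log of a session as a data frame
#'
#' @param session a [init_session()] session (possibly read back from CSV).
#' @return Data frame with columns `trial_index`, `set_index`,
#'   `sat_protan`, `sat_deutan`, `sat_tritan` (NA when the axis was
#'   inactive) and `tapped`.
#' @export
session_trials <- function(session) {
  if (!length(session$log)) {
    return(data.frame(trial_index = integer(), set_index = integer(),
                      sat_protan = numeric(), sat_deutan = numeric(),
                      sat_tritan = numeric(), tapped = character(),
                      stringsAsFactors = FALSE))
  }
  sat <- t(vapply(session$log, `[[`, numeric(3L), "saturation"))
  data.frame(
    trial_index = vapply(session$log, `[[`, integer(1L), "trial_index"),
    set_index = vapply(session$log, `[[`, integer(1L), "set_index"),
    sat_protan = sat[, "protan"],
    sat_deutan = sat[, "deutan"],
    sat_tritan = sat[, "tritan"],
    tapped = vapply(session$log, `[[`, character(1L), "tapped"),
    stringsAsFactors = FALSE
  )
}

#' Per-axis update events of a session
#'
#' Counts, per axis and per set, the update events (own-target taps plus
#' distractor taps while the axis was active). In a complete session each
#' axis shows exactly the set quota (35) in each set.
#'
#' @inheritParams session_trials
#' @return Data frame with columns `set_index`, `axis`, `updates`.
#' @export
session_update_counts <- function(session) {
  tr <- session_trials(session)
  out <- expand.grid(set_index = sort(unique(tr$set_index)),
                     axis = cvd_axes(), stringsAsFactors = FALSE)
  out$updates <- mapply(function(set, ax) {
    sat <- tr[[paste0("sat_", ax)]]
    sub <- tr$set_index == set
    sum(sub & (tr$tapped == ax | (tr$tapped == "distractor" & !is.na(sat))))
  }, out$set_index, out$axis)
  out[order(out$set_index, match(out$axis, cvd_axes())), ]
}

#' Pool an axis's Bernoulli observations across both staircase sets
#'
#' Every trial on which the axis was updated contributes one Bernoulli
#' observation at the saturation presented on that trial: a success if the
#' axis's own target was tapped, a failure if a distractor was tapped.
#' Trials resolved by tapping a different axis's target contribute nothing
#' for this axis. Observations from both sets are aggregated per distinct
#' saturation level.
#'
#' @inheritParams session_trials
#' @param axis one of the confusion axes.
#' @param min_trials validity floor; sessions with fewer trials are
#'   rejected (`insufficient-data`). Defaults to the session config's
#'   `min_valid_trials` (40), or 40 when the session carries no config.
#' @return Data frame with columns `saturation`, `successes`, `trials`,
#'   sorted by saturation.
#' @export
pool_observations <- function(session, axis, min_trials = NULL) {
  axis <- .check_axis(axis)
  if (is.null(min_trials)) {
    min_trials <- if (!is.null(session$cfg)) session$cfg$min_valid_trials else 40L
  }
  tr <- session_trials(session)
  if (nrow(tr) < min_trials) {
    stop("insufficient-data: session has ", nrow(tr),
         " trials, fewer than the ", min_trials, "-trial validity floor")
  }
  sat <- tr[[paste0("sat_", axis)]]
  updated <- tr$tapped == axis | (tr$tapped == "distractor" & !is.na(sat))
  sat <- sat[updated]
  success <- tr$tapped[updated] == axis
  key <- signif(sat, 12)
  agg <- tapply(success, key, function(z) c(sum(z), length(z)))
  levels <- as.numeric(names(agg))
  m <- do.call(rbind, agg)
  out <- data.frame(saturation = levels, successes = as.integer(m[, 1]),
                    trials = as.integer(m[, 2]))
  out[order(out$saturation), , drop = FALSE]
}
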