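#' Model-free fit parameters
#'
#' @param bandwidth Gaussian kernel bandwidth of the local-linear fit, in
#'   log10-saturation units. The staircase levels are geometric (factor 0.5
#'   spacing, 0.301 log10 units), so the default 0.70 smooths over roughly
#'   two to three adjacent levels.
#' @param level performance level (probability of tapping the axis's own
#'   target) at which the threshold is read off; default 0.21, above the
#'   1/11 chance rate.
#' @param grid_size number of evaluation points on the log10-saturation
#'   grid.
#' @param link link function of the local polynomial; only `"logit"` is
#'   implemented.
#' @return An object of class `"fit_params"`.
#' @export
fit_params <- function(bandwidth = 0.70, level = 0.21, grid_size = 201L,
                       link = "logit") {
  stopifnot(bandwidth > 0, level > 0, level < 1, grid_size >= 2L)
  link <- match.arg(link, "logit")
  structure(list(bandwidth = bandwidth, level = level,
                 grid_size = as.integer(grid_size), link = link),
            class = "fit_params")
}

.p_clamp <- 1e-6
.eta_cap <- stats::qlogis(1 - 1e-6)

# kernel-weighted degree-1 local logistic likelihood, maximised by
# Fisher scoring at a single evaluation point; returns the local intercept
.local_logit_intercept <- function(xc, k, n, w) {
  a <- stats::qlogis(min(max((sum(w * k) + 0.5) / (sum(w * n) + 1), .p_clamp),
                         1 - .p_clamp))
  b <- 0
  for (iter in 1:100) {
    eta <- pmin(pmax(a + b * xc, -30), 30)
    p <- stats::plogis(eta)
    res <- w * (k - n * p)
    wt <- w * n * p * (1 - p)
    g1 <- sum(res)
    g2 <- sum(res * xc)
    h11 <- sum(wt)
    h12 <- sum(wt * xc)
    h22 <- sum(wt * xc * xc)
    ridge <- 1e-10 * max(h11, 1e-10)
    h11 <- h11 + ridge
    h22 <- h22 + ridge
    det <- h11 * h22 - h12 * h12
    da <- (h22 * g1 - h12 * g2) / det
    db <- (h11 * g2 - h12 * g1) / det
    # damp steps so complete-separation neighbourhoods walk to the cap
    da <- sign(da) * min(abs(da), 5)
    db <- sign(db) * min(abs(db), 5)
    a <- min(max(a + da, -.eta_cap), .eta_cap)
    b <- min(max(b + db, -100), 100)
    if (max(abs(da), abs(db)) < 1e-9) break
  }
  a
}

#' Model-free psychometric function fit
#'
#' Estimates the probability of tapping an axis's own target as a function
#' of log10 saturation by local-linear kernel logistic regression: at each
#' point of an evaluation grid, a degree-1 polynomial on the logit scale is
#' fitted by maximising the Gaussian-kernel-weighted binomial
#' log-likelihood, and the fitted probability is the inverse logit of the
#' local intercept. No parametric shape is imposed on the curve as a whole.
#' Degenerate all-success or all-failure neighbourhoods are handled by
#' clamping fitted probabilities to `[1e-6, 1 - 1e-6]`.
#'
#' @param data data frame with columns `saturation`, `successes`, `trials`
#'   (one row per distinct tested level), e.g. from [pool_observations()].
#' @param params a [fit_params()].
#' @param grid_max upper end of the evaluation grid on the saturation scale
#'   (default 0.9, the top tested level).
#' @param axis optional axis label stored in the fit.
#' @return An object of class `"psychometric_fit"`: a list with `grid`
#'   (saturations), `grid_log10`, `p_hat`, `bandwidth`, `level`, `axis`,
#'   `data`.
#' @export
fit_modelfree <- function(data, params = fit_params(), grid_max = 0.9,
                          axis = NA_character_) {
  stopifnot(all(c("saturation", "successes", "trials") %in% names(data)))
  data <- data[data$trials > 0, , drop = FALSE]
  if (nrow(data) == 0L || sum(data$trials) == 0L) {
    stop("empty-data: no observations with trials > 0")
  }
  if (any(data$successes < 0) || any(data$successes > data$trials)) {
    stop("format-error: successes must lie in [0, trials]")
  }
  if (length(unique(signif(data$saturation, 12))) < 2L) {
    stop("unfittable: fewer than 2 distinct saturation levels")
  }
  x <- log10(data$saturation)
  k <- data$successes
  n <- data$trials
  h <- params$bandwidth
  lo <- min(x)
  hi <- max(max(x), log10(grid_max))
  grid_log10 <- seq(lo, hi, length.out = params$grid_size)
  p_hat <- vapply(grid_log10, function(g) {
    w <- exp(-0.5 * ((x - g) / h)^2)
    stats::plogis(.local_logit_intercept(x - g, k, n, w))
  }, numeric(1))
  p_hat <- pmin(pmax(p_hat, .p_clamp), 1 - .p_clamp)
  structure(list(grid = 10^grid_log10, grid_log10 = grid_log10, p_hat = p_hat,
                 bandwidth = h, level = params$level, axis = axis,
                 data = data),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  th <- threshold_at(x)
  cat(sprintf("Model-free psychometric fit%s: bandwidth %.2f, %d grid points\n",
              if (is.na(x$axis)) "" else paste0(" (", x$axis, ")"),
              x$bandwidth, length(x$grid)))
  cat(sprintf("  threshold at level %.2f: %.4f (%s)\n",
              x$level, th$threshold, th$flag))
  invisible(x)
}

#' Threshold of a fitted psychometric function
#'
#' Reads off the saturation at which the fitted curve crosses the stated
#' performance level from below, taking the largest such crossing and
#' interpolating linearly (on the log10 grid) between grid points. A curve
#' that never reaches the level within the tested range returns the 0.9
#' ceiling with flag `"unresolved"`; a curve already above the level at the
#' grid minimum with no later upward crossing returns the grid minimum with
#' flag `"floor"`.
#'
#' @param fit a [fit_modelfree()] result.
#' @param level performance level in (0, 1); defaults to the fit's level.
#' @return List with `threshold`, `flag` (`"ok"`, `"unresolved"` or
#'   `"floor"`) and `level`.
#' @export
threshold_at <- function(fit, level = fit$level) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!is.finite(level) || level <= 0 || level >= 1) {
    stop("invalid-level: performance level must lie in (0, 1)")
  }
  p <- fit$p_hat
  m <- length(p)
  cross <- which(p[-m] < level & p[-1] >= level)
  if (length(cross)) {
    j <- max(cross)
    xg <- fit$grid_log10
    xt <- xg[j] + (level - p[j]) / (p[j + 1] - p[j]) * (xg[j + 1] - xg[j])
    list(threshold = 10^xt, flag = "ok", level = level)
  } else if (p[1] >= level) {
    list(threshold = fit$grid[1], flag = "floor", level = level)
  } else {
    list(threshold = max(fit$grid), flag = "unresolved", level = level)
  }
}

#' Grid search for the fit parameters that best separate the groups
#'
#' For every candidate (bandwidth, level) pair, fits every participant,
#' computes each participant's threshold ratio, and scores the pair by the
#' separation margin `min(control ratios) - max(CVD ratios)`. Returns the
#' argmax pair; ties are broken in favour of the smaller bandwidth, then
#' the lower level. A participant unfittable at some bandwidth makes that
#' pair's objective `-Inf` (with a message) rather than an error.
#'
#' @param pooled named list (by participant id) of named lists (by axis) of
#'   pooled observation data frames, as from [pool_observations()].
#' @param cvd_ids,control_ids participant ids of the two reference groups.
#' @param bandwidths,levels candidate grids; defaults are bandwidth 0.10 to
#'   2.00 in steps of 0.05 and level 0.05 to 0.50 in steps of 0.01.
#' @param grid_size evaluation grid size passed to [fit_modelfree()].
#' @return A [fit_params()] carrying the winning pair, with the achieved
#'   separation margin in attribute `"objective"`.
#' @export
optimize_fit_params <- function(pooled, cvd_ids, control_ids,
                                bandwidths = seq(0.10, 2.00, by = 0.05),
                                levels = seq(0.05, 0.50, by = 0.01),
                                grid_size = 201L) {
  stopifnot(length(cvd_ids) > 0, length(control_ids) > 0)
  ids <- c(cvd_ids, control_ids)
  if (!all(ids %in% names(pooled))) {
    stop("format-error: pooled data missing for id(s): ",
         paste(setdiff(ids, names(pooled)), collapse = ", "))
  }
  best <- list(objective = -Inf, bandwidth = NA_real_, level = NA_real_)
  for (h in sort(bandwidths)) {
    fits <- lapply(pooled[ids], function(per_axis) {
      tryCatch(
        lapply(cvd_axes(), function(ax) {
          fit_modelfree(per_axis[[ax]],
                        fit_params(bandwidth = h, grid_size = grid_size),
                        axis = ax)
        }),
        error = function(e) NULL
      )
    })
    if (any(vapply(fits, is.null, logical(1)))) {
      message("optimize_fit_params: unfittable participant(s) at bandwidth ",
              h, "; candidate pairs at this bandwidth scored -Inf")
      next
    }
    for (lv in sort(levels)) {
      ratios <- vapply(fits, function(f3) {
        th <- vapply(f3, function(f) .threshold_value(threshold_at(f, lv)),
                     numeric(1))
        names(th) <- cvd_axes()
        threshold_ratio(th)
      }, numeric(1))
      obj <- min(ratios[control_ids]) - max(ratios[cvd_ids])
      if (obj > best$objective) {
        best <- list(objective = obj, bandwidth = h, level = lv)
      }
    }
  }
  if (!is.finite(best$objective)) {
    stop("unfittable: no candidate pair produced fits for every participant")
  }
  out <- fit_params(bandwidth = best$bandwidth, level = best$level,
                    grid_size = grid_size)
  attr(out, "objective") <- best$objective
  out
}

# numeric threshold entering ratios: unresolved curves use the 0.9 ceiling,
# floor-flagged curves the grid minimum (both already stored in $threshold)
.threshold_value <- function(th) th$threshold

#' Export a psychometric fit as JSON
#'
#' @param fit a [fit_modelfree()] result.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "psychometric_fit"))
  th <- threshold_at(fit)
  jsonlite::write_json(list(
    axis = fit$axis, bandwidth = fit$bandwidth, level = fit$level,
    grid = fit$grid, p_hat = fit$p_hat,
    threshold = th$threshold, flag = th$flag
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
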