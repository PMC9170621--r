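#' MacLeod-Boynton chromaticity
#'
#' Constructs a chromaticity in the MacLeod-Boynton diagram, the cone-based
#' chromaticity space with abscissa `l = L/(L+M)` and ordinate `s = S/(L+M)`
#' at constant luminance `L+M`. Tritan confusion lines are vertical in this
#' space; protan and deutan confusion lines converge on their copunctal
#' points at `(l, s) = (1, 0)` and `(0, 0)` respectively.
#'
#' @param l L-cone fraction `L/(L+M)`, strictly inside (0, 1).
#' @param s S-cone ordinate `S/(L+M)`, nonnegative. The s-axis scaling is
#'   treated as profile-relative; no normalisation convention is imposed.
#' @param lum luminance proxy `L+M` in arbitrary linear units, or `NA` when
#'   the chromaticity is luminance-free.
#' @return An object of class `"mb_chromaticity"`: a named list with
#'   elements `l`, `s`, `lum`.
#' @seealso [mb_from_cones()], [cones_from_mb()]
#' @export
mb_chromaticity <- function(l, s, lum = NA_real_) {
  stopifnot(is.numeric(l), length(l) == 1L, is.numeric(s), length(s) == 1L)
  if (!(l > 0 && l < 1)) {
    stop("invalid-chromaticity: l must lie strictly inside (0, 1), got ", l)
  }
  if (s < 0) stop("invalid-chromaticity: s must be nonnegative, got ", s)
  if (!is.na(lum) && lum <= 0) {
    stop("invalid-chromaticity: lum must be positive when present")
  }
  structure(list(l = as.numeric(l), s = as.numeric(s), lum = as.numeric(lum)),
            class = "mb_chromaticity")
}

#' @export
print.mb_chromaticity <- function(x, ...) {
  cat(sprintf("MB chromaticity: l = %.4f, s = %.4f%s\n", x$l, x$s,
              if (is.na(x$lum)) "" else sprintf(", lum = %.4g", x$lum)))
  invisible(x)
}

#' The three dichromatic confusion axes
#'
#' @return Character vector `c("protan", "deutan", "tritan")`.
#' @export
cvd_axes <- function() c("protan", "deutan", "tritan")

.check_axis <- function(axis) {
  axis <- match.arg(axis, cvd_axes())
  axis
}

# s-coordinate of the white point implied by the printed red-green endpoints:
# the intersection of the protan confusion line (through the protan endpoint
# and the protan copunctal point (1, 0)) with the deutan confusion line
# (through the deutan endpoint and the origin).
.derive_white <- function(endpoints) {
  pe <- endpoints$protan
  de <- endpoints$deutan
  a <- pe$s / (1 - pe$l)     # protan line: s = a * (1 - l)
  b <- de$s / de$l           # deutan line: s = b * l
  l_star <- a / (a + b)
  list(l = l_star, s = b * l_star)
}

#' Device calibration profile
#'
#' A calibration state for one display model: the linear RGB to cone
#' excitation (LMS) transform, per-channel gamma exponents, the background
#' white point, and the chromaticities of the maximum in-gamut saturation
#' (saturation 1.0) on each confusion axis.
#'
#' If `white` omits `l` it defaults to the tritan endpoint's `l` (tritan
#' confusion lines are vertical, so tritan targets share the white point's
#' `l`). If `white` omits `s` it is recomputed at load as the intersection
#' of the protan and deutan confusion lines through the stored endpoints;
#' an explicitly supplied `s` wins.
#'
#' @param model_id character label for the display model.
#' @param rgb_to_lms invertible 3x3 matrix mapping linear RGB to LMS.
#' @param gamma three positive per-channel gamma exponents, each in (0.5, 5).
#' @param white list with `lum` (required) and optionally `l`, `s`.
#' @param axis_endpoints named list `protan`/`deutan`/`tritan`, each a list
#'   with `l` and `s`: the chromaticity at saturation 1.0 on that axis.
#' @return An object of class `"device_profile"`.
#' @export
device_profile <- function(model_id, rgb_to_lms, gamma, white, axis_endpoints) {
  rgb_to_lms <- as.matrix(rgb_to_lms)
  stopifnot(all(dim(rgb_to_lms) == c(3L, 3L)), length(gamma) == 3L)
  dimnames(rgb_to_lms) <- list(c("L", "M", "S"), c("R", "G", "B"))
  if (abs(det(rgb_to_lms)) < 1e-12) {
    stop("invalid-profile: rgb_to_lms matrix is singular")
  }
  if (any(gamma <= 0.5) || any(gamma >= 5)) {
    stop("invalid-profile: gamma exponents must lie in (0.5, 5)")
  }
  for (ax in cvd_axes()) {
    ep <- axis_endpoints[[ax]]
    if (is.null(ep) || is.null(ep$l) || is.null(ep$s)) {
      stop("invalid-profile: missing endpoint for axis ", ax)
    }
  }
  if (is.null(white[["lum"]]) || !is.finite(white[["lum"]]) || white[["lum"]] <= 0) {
    stop("invalid-profile: white point requires a positive lum")
  }
  derived <- .derive_white(axis_endpoints)
  l_w <- if (!is.null(white[["l"]])) white[["l"]] else axis_endpoints$tritan$l
  s_w <- if (!is.null(white[["s"]])) white[["s"]] else derived$s
  if (abs(axis_endpoints$tritan$l - l_w) > 1e-6) {
    stop("invalid-profile: tritan endpoint l (", axis_endpoints$tritan$l,
         ") must equal white l (", l_w, "): tritan confusion lines are vertical")
  }
  structure(list(
    model_id = as.character(model_id),
    rgb_to_lms = rgb_to_lms,
    lms_to_rgb = solve(rgb_to_lms),
    gamma = as.numeric(gamma),
    white = mb_chromaticity(l_w, s_w, white[["lum"]]),
    axis_endpoints = lapply(axis_endpoints[cvd_axes()],
                            function(e) mb_chromaticity(e$l, e$s))
  ), class = "device_profile")
}

#' @export
print.device_profile <- function(x, ...) {
  cat("Device calibration profile:", x$model_id, "\n")
  cat(sprintf("  white: l = %.4f, s = %.4f, lum = %.3g\n",
              x$white$l, x$white$s, x$white$lum))
  cat(sprintf("  gamma: %.2f %.2f %.2f\n", x$gamma[1], x$gamma[2], x$gamma[3]))
  for (ax in cvd_axes()) {
    ep <- x$axis_endpoints[[ax]]
    cat(sprintf("  %s endpoint (sat 1.0): l = %.4f, s = %.4f\n", ax, ep$l, ep$s))
  }
  invisible(x)
}

#' Default device profile
#'
#' A synthetic calibration profile for a generic tablet display. The axis
#' endpoints are the maximum in-gamut saturation chromaticities of the
#' reference calibration (protan l = 0.6160, s = 0.0186; deutan l = 0.6160,
#' s = 0.0157; tritan l = 0.6553, s = 0.0033); the white point is derived
#' from them (l from the tritan axis, s from the red-green confusion-line
#' intersection). The RGB-to-LMS matrix is a synthetic engineering matrix: a
#' row-normalised Hunt-Pointer-Estevez-style transform rescaled so that
#' equal-RGB grey maps exactly onto the derived white chromaticity. The
#' background luminance is set to half the display maximum so that the
#' +/-20% luminance noise never clips.
#'
#' @return A [device_profile()].
#' @export
default_device_profile <- function() {
  endpoints <- list(
    protan = list(l = 0.6160, s = 0.0186),
    deutan = list(l = 0.6160, s = 0.0157),
    tritan = list(l = 0.6553, s = 0.0033)
  )
  w <- .derive_white(endpoints)
  l_w <- endpoints$tritan$l
  # HPE-style cone weights, rows normalised to sum 1, then scaled so grey
  # (R=G=B=v) yields L+M = v and chromaticity exactly (l_w, s_w)
  hpe <- rbind(c(0.3139, 0.6395, 0.0466),
               c(0.1516, 0.7482, 0.0870),
               c(0.0177, 0.1095, 0.8729))
  hpe <- hpe / rowSums(hpe)
  m <- diag(c(l_w, 1 - l_w, w$s)) %*% hpe
  dimnames(m) <- list(c("L", "M", "S"), c("R", "G", "B"))
  device_profile(
    model_id = "synthetic-default",
    rgb_to_lms = m,
    gamma = c(2.2, 2.2, 2.2),
    white = list(lum = 0.5),
    axis_endpoints = endpoints
  )
}

#' Read or write a device profile as JSON
#'
#' The JSON layout is `{model_id, rgb_to_lms: [[..]x3], gamma: [g_r,g_g,g_b],
#' white: {l, s, lum}, endpoints: {protan: {l,s}, deutan: {l,s},
#' tritan: {l,s}}}`. `white$l`/`white$s` may be omitted and are then derived
#' from the endpoints at load.
#'
#' @param path file path.
#' @return `read_device_profile` returns a [device_profile()];
#'   `write_device_profile` invisibly returns `path`.
#' @export
read_device_profile <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("model_id", "rgb_to_lms", "gamma", "white", "endpoints")) {
    if (is.null(j[[f]])) {
      stop("format-error: device profile JSON missing field '", f, "' in ", path)
    }
  }
  device_profile(
    model_id = j$model_id,
    rgb_to_lms = matrix(unlist(j$rgb_to_lms), 3L, 3L, byrow = !is.matrix(j$rgb_to_lms)),
    gamma = j$gamma,
    white = as.list(j$white),
    axis_endpoints = lapply(j$endpoints, as.list)
  )
}

#' @rdname read_device_profile
#' @param profile a [device_profile()].
#' @export
write_device_profile <- function(profile, path) {
  stopifnot(inherits(profile, "device_profile"))
  j <- list(
    model_id = profile$model_id,
    rgb_to_lms = unclass(profile$rgb_to_lms),
    gamma = profile$gamma,
    white = list(l = profile$white$l, s = profile$white$s, lum = profile$white$lum),
    endpoints = lapply(profile$axis_endpoints, function(e) list(l = e$l, s = e$s))
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
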