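#' Convert cone excitations to MacLeod-Boynton chromaticity
#'
#' @param L,M,S nonnegative cone excitations in arbitrary linear units;
#'   `L + M` must be positive.
#' @return An [mb_chromaticity()] with `l = L/(L+M)`, `s = S/(L+M)` and
#'   `lum = L+M`.
#' @examples
#' mb_from_cones(2, 1, 0.03)  # l = 2/3, s = 0.01, lum = 3
#' @export
mb_from_cones <- function(L, M, S) {
  if (length(L) == 3L && missing(M)) { S <- L[3]; M <- L[2]; L <- L[1] }
  lum <- L + M
  if (!is.finite(lum) || lum <= 0) {
    stop("invalid-cone-excitation: L + M must be positive")
  }
  mb_chromaticity(L / lum, S / lum, lum)
}

#' Convert MacLeod-Boynton chromaticity to cone excitations
#'
#' The inverse of [mb_from_cones()]; requires a luminance to fix the scale.
#'
#' @param x an [mb_chromaticity()] with `lum` present.
#' @return Numeric vector `c(L, M, S)`.
#' @export
cones_from_mb <- function(x) {
  stopifnot(inherits(x, "mb_chromaticity"))
  if (is.na(x$lum)) {
    stop("underdetermined-conversion: chromaticity carries no luminance")
  }
  c(L = x$l * x$lum, M = (1 - x$l) * x$lum, S = x$s * x$lum)
}

.gamut_tol <- 1e-9

.linear_rgb_from_cones <- function(cones, profile) {
  as.numeric(profile$lms_to_rgb %*% cones)
}

.in_gamut <- function(linear_rgb) {
  all(linear_rgb >= -.gamut_tol & linear_rgb <= 1 + .gamut_tol)
}

#' Render cone excitations as gamma-encoded device RGB
#'
#' Maps LMS through the profile's inverse calibration matrix to linear RGB
#' and applies per-channel gamma encoding `v = linear^(1/gamma)`.
#'
#' @param cones numeric `c(L, M, S)`.
#' @param profile a [device_profile()].
#' @param on_gamut what to do when a linear channel falls outside `[0, 1]`:
#'   `"error"` (default) signals a gamut violation, `"clip"` clamps.
#' @return Gamma-encoded RGB triple in `[0, 1]`.
#' @export
rgb_from_cones <- function(cones, profile, on_gamut = c("error", "clip")) {
  on_gamut <- match.arg(on_gamut)
  lin <- .linear_rgb_from_cones(cones, profile)
  if (!.in_gamut(lin)) {
    if (on_gamut == "error") {
      stop(sprintf("gamut-violation: linear RGB (%.4f, %.4f, %.4f) outside [0,1]",
                   lin[1], lin[2], lin[3]))
    }
    lin <- pmin(pmax(lin, 0), 1)
  }
  lin <- pmin(pmax(lin, 0), 1)
  stats::setNames(lin^(1 / profile$gamma), c("R", "G", "B"))
}

#' Decode gamma-encoded device RGB back to cone excitations
#'
#' @param rgb gamma-encoded RGB triple in `[0, 1]`.
#' @inheritParams rgb_from_cones
#' @return Numeric `c(L, M, S)`.
#' @export
cones_from_rgb <- function(rgb, profile) {
  stopifnot(length(rgb) == 3L, all(rgb >= 0), all(rgb <= 1))
  lin <- rgb^profile$gamma
  stats::setNames(as.numeric(profile$rgb_to_lms %*% lin), c("L", "M", "S"))
}

#' Chromaticity of a confusion-line target at a given saturation
#'
#' Targets lie on the straight line from the background white point to the
#' axis endpoint (the maximum in-gamut chromaticity, saturation 1.0);
#' saturation interpolates linearly in both `l` and `s`.
#'
#' @param axis one of `"protan"`, `"deutan"`, `"tritan"`.
#' @param saturation unitless in `[0, 1]`, fraction of the maximum in-gamut
#'   excursion on that axis.
#' @param profile a [device_profile()].
#' @param lum luminance of the returned chromaticity (default: the
#'   background luminance).
#' @return An [mb_chromaticity()].
#' @export
target_chromaticity <- function(axis, saturation, profile = default_device_profile(),
                                lum = profile$white$lum) {
  axis <- .check_axis(axis)
  if (!is.finite(saturation) || saturation < 0 || saturation > 1) {
    stop("invalid-saturation: saturation must lie in [0, 1], got ", saturation)
  }
  w <- profile$white
  ep <- profile$axis_endpoints[[axis]]
  mb_chromaticity(w$l + saturation * (ep$l - w$l),
                  w$s + saturation * (ep$s - w$s),
                  lum)
}

# chromaticity along the axis ray, allowing t outside [0, 1] (internal,
# used by the gamut search)
.axis_chromaticity_raw <- function(axis, t, profile) {
  w <- profile$white
  ep <- profile$axis_endpoints[[axis]]
  c(l = w$l + t * (ep$l - w$l), s = w$s + t * (ep$s - w$s))
}

#' Maximum in-gamut saturation along a confusion axis
#'
#' Finds the largest multiple `t` of the stored axis excursion at which the
#' target, rendered at luminance `lum`, still converts to linear RGB inside
#' `[0, 1]^3`. Because linear RGB is affine in `t`, the in-gamut set is an
#' interval containing `t = 0` and a bisection search is exact up to the
#' stated tolerance. Values above 1 indicate headroom beyond the stored
#' endpoint (e.g. at lower luminance).
#'
#' @inheritParams target_chromaticity
#' @param tol search tolerance on `t` (default `1e-6`).
#' @param t_max upper bound of the search interval (default 2).
#' @return Unitless saturation multiple.
#' @export
max_in_gamut_saturation <- function(axis, profile = default_device_profile(),
                                    lum = profile$white$lum, tol = 1e-6,
                                    t_max = 2) {
  axis <- .check_axis(axis)
  in_gamut_at <- function(t) {
    ch <- .axis_chromaticity_raw(axis, t, profile)
    if (ch["l"] <= 0 || ch["l"] >= 1 || ch["s"] < 0) return(FALSE)
    cones <- c(ch["l"], 1 - ch["l"], ch["s"]) * lum
    .in_gamut(.linear_rgb_from_cones(cones, profile))
  }
  if (!in_gamut_at(0)) {
    stop("invalid-profile: the white point itself is out of gamut at lum ", lum)
  }
  if (in_gamut_at(t_max)) return(t_max)
  lo <- 0
  hi <- t_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (in_gamut_at(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Luminance signal a dichromat receives from a red-green target
#'
#' Stimuli are nominally isoluminant (constant `L + M`), but a dichromat's
#' luminance channel is driven by a single remaining cone class: for a
#' protanope luminance is proportional to M, for a deuteranope to L. A
#' red-green target therefore carries a residual luminance cue relative to
#' the background, which the engine masks with luminance noise.
#'
#' @inheritParams target_chromaticity
#' @param type `"protanope"` or `"deuteranope"`.
#' @return Signed fraction: the relative change in the dichromat's luminance
#'   signal for the target versus the background. Exactly 0 on the tritan
#'   axis (its confusion line is vertical: `l` does not change).
#' @examples
#' # maximum red-green cue at the top tested saturation, default profile
#' dichromat_luminance_signal("protan", 0.9, type = "protanope")
#' @export
dichromat_luminance_signal <- function(axis, saturation,
                                       profile = default_device_profile(),
                                       type = c("protanope", "deuteranope")) {
  axis <- .check_axis(axis)
  type <- match.arg(type)
  if (axis == "tritan") return(0)
  l_w <- profile$white$l
  l_t <- target_chromaticity(axis, saturation, profile)$l
  if (type == "protanope") (l_w - l_t) / (1 - l_w) else (l_t - l_w) / l_w
}

#' Maximum dichromat luminance cue of the red-green targets
#'
#' Convenience audit: the largest absolute [dichromat_luminance_signal()]
#' over both dichromat types and both red-green axes at the stated
#' saturation. With the default profile and the top tested saturation 0.9
#' this is about 0.10 (10% of background luminance), which motivates the
#' +/-20% luminance noise.
#'
#' @inheritParams target_chromaticity
#' @return Nonnegative fraction.
#' @export
max_dichromat_luminance_cue <- function(saturation = 0.9,
                                        profile = default_device_profile()) {
  max(abs(vapply(c("protan", "deutan"), function(ax) {
    vapply(c("protanope", "deuteranope"), function(ty) {
      dichromat_luminance_signal(ax, saturation, profile, ty)
    }, numeric(1))
  }, numeric(2))))
}

#' Audit residual cues introduced by calibration error
#'
#' Renders a confusion-line target under a nominal profile, then interprets
#' the resulting device RGB through a perturbed profile (as a mis-calibrated
#' display would show it), and reports the residual cues beyond those the
#' nominal stimulus intends: the extra dichromat luminance cue and the extra
#' s-axis (tritan) displacement as a fraction of the displayed background
#' `s`. Used to check that the masking-noise amplitudes dominate plausible
#' calibration errors.
#'
#' @param p_nominal,p_perturbed [device_profile()]s sharing a gamut.
#' @inheritParams target_chromaticity
#' @return List with `residual_lum_cue` (max absolute extra dichromat
#'   luminance cue over both dichromat types), `residual_tritan_fraction`
#'   (signed extra s displacement / displayed background s), and the
#'   displayed target and white chromaticities.
#' @export
audit_calibration_error <- function(p_nominal, p_perturbed, axis, saturation) {
  axis <- .check_axis(axis)
  displayed <- function(chrom) {
    rgb <- rgb_from_cones(cones_from_mb(chrom), p_nominal, on_gamut = "clip")
    cones <- cones_from_rgb(rgb, p_perturbed)
    mb_from_cones(cones[1], cones[2], cones[3])
  }
  tgt_nom <- target_chromaticity(axis, saturation, p_nominal)
  w_nom <- p_nominal$white
  tgt_disp <- displayed(tgt_nom)
  w_disp <- displayed(w_nom)

  cue_of <- function(l_t, l_w, type) {
    if (type == "protanope") (l_w - l_t) / (1 - l_w) else (l_t - l_w) / l_w
  }
  extra_cue <- vapply(c("protanope", "deuteranope"), function(ty) {
    cue_of(tgt_disp$l, w_disp$l, ty) - cue_of(tgt_nom$l, w_nom$l, ty)
  }, numeric(1))
  tritan_disp <- (tgt_disp$s - w_disp$s) / w_disp$s
  tritan_nom <- (tgt_nom$s - w_nom$s) / w_nom$s
  list(
    residual_lum_cue = max(abs(extra_cue)),
    residual_lum_cue_by_type = extra_cue,
    residual_tritan_fraction = tritan_disp - tritan_nom,
    displayed_target = tgt_disp,
    displayed_white = w_disp
  )
}
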