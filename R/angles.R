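# Conversion of the acetabular axis to anteversion/inclination under the
# anatomic, radiographic, and operative definitions (Murray's three
# conventions), and conversions between the definitions.
#
# Canonical axis components are (l, a, s) = (outward-lateral, anterior,
# superior) in the intrinsic pelvic frame, after side normalization
# (l >= 0).  For a cup with anatomic anteversion AA and inclination AI:
#   l = sin AI cos AA,  a = sin AI sin AA,  s = -cos AI.
# The definitions then read:
#   anatomic:     AI = acos(-s),      AA = atan2(a, l)
#   radiographic: RA = asin(a),       RI = atan2(l, -s)
#   operative:    OI = asin(l),       OA = atan2(a, -s)
# which imply the closed-form identities
#   sin RA = sin AA sin AI,  tan RI = tan AI cos AA,
#   tan OA = tan AI sin AA,  sin OI = sin AI cos AA.

ANGLE_DEFINITIONS <- c("anatomic", "radiographic", "operative")

#' Orientation angles of an acetabular axis
#'
#' @param anteversion,inclination angles in degrees.
#' @param definition one of `"anatomic"`, `"radiographic"`, `"operative"`.
#' @param side `"left"` or `"right"` (optional, for labelling).
#' @return object of class `orientation_angles`.
#' @export
orientation_angles <- function(anteversion, inclination,
                               definition = ANGLE_DEFINITIONS, side = NA_character_) {
  definition <- match.arg(definition)
  if (inclination < 0 || inclination > 90)
    stop("inclination must lie in [0, 90] degrees")
  if (anteversion <= -90 || anteversion >= 90)
    stop("anteversion must lie in (-90, 90) degrees")
  structure(list(anteversion = anteversion, inclination = inclination,
                 definition = definition, side = side),
            class = "orientation_angles")
}

#' @export
print.orientation_angles <- function(x, ...) {
  cat(sprintf("<orientation_angles> %s%s: anteversion %.2f deg, inclination %.2f deg\n",
              x$definition, if (is.na(x$side)) "" else paste0(" (", x$side, ")"),
              x$anteversion, x$inclination))
  invisible(x)
}

#' Convert an acetabular axis to orientation angles
#'
#' @param axis unit 3-vector `(l, a, s)` = (outward-lateral, anterior,
#'   superior components) with `l >= 0`, e.g. from [make_axis()], or an
#'   `acetabular_axis` object.
#' @param definition angle definition to report.
#' @param side side label carried through to the result.
#' @return an [orientation_angles()].
#' @export
axis_to_angles <- function(axis, definition = ANGLE_DEFINITIONS, side = NA_character_) {
  definition <- match.arg(definition)
  if (inherits(axis, "acetabular_axis")) {
    if (is.na(side)) side <- axis$side
    axis <- axis$direction
  }
  axis <- as.numeric(axis)
  if (abs(vnorm(axis) - 1) > 1e-6) stop("axis must be a unit vector")
  l <- axis[1]; a <- axis[2]; s <- axis[3]
  clamp1 <- function(x) max(-1, min(1, x))
  degen_av <- function(y, x) {
    if (abs(x) < 1e-15 && abs(y) < 1e-15) {
      warning("anteversion undefined for this axis; reporting 0")
      0
    } else rad2deg(atan2(y, x))
  }
  res <- switch(definition,
    anatomic = c(av = degen_av(a, l), inc = rad2deg(acos(clamp1(-s)))),
    radiographic = c(av = rad2deg(asin(clamp1(a))), inc = degen_av(l, -s)),
    operative = c(av = degen_av(a, -s), inc = rad2deg(asin(clamp1(l)))))
  orientation_angles(unname(res["av"]), unname(res["inc"]), definition, side)
}

#' Reconstruct the unit acetabular axis from orientation angles
#'
#' Inverse of [axis_to_angles()]: the unique unit axis with outward
#' lateral component `l >= 0` and superior component `s <= 0`
#' reproducing the given angles.
#'
#' @param definition angle definition of the inputs.
#' @param anteversion,inclination angles in degrees.
#' @return unit 3-vector `(l, a, s)`.
#' @export
angles_to_axis <- function(definition = ANGLE_DEFINITIONS, anteversion, inclination) {
  definition <- match.arg(definition)
  if (inclination < 0 || inclination > 90)
    stop("inclination must lie in [0, 90] degrees")
  if (anteversion <= -90 || anteversion >= 90)
    stop("anteversion must lie in (-90, 90) degrees")
  if (inclination == 0 && anteversion != 0)
    stop("anteversion is unidentifiable at zero inclination")
  av <- deg2rad(anteversion); inc <- deg2rad(inclination)
  ax <- switch(definition,
    anatomic = c(sin(inc) * cos(av), sin(inc) * sin(av), -cos(inc)),
    radiographic = c(cos(av) * sin(inc), sin(av), -cos(av) * cos(inc)),
    operative = c(sin(inc), cos(inc) * sin(av), -cos(inc) * cos(av)))
  unitize(ax)
}

#' Convert orientation angles between definitions
#'
#' Reconstructs the unit axis from the source definition and re-reads it
#' in the target definition; equal to the closed-form identities
#' `sin RA = sin AA sin AI`, `tan RI = tan AI cos AA`,
#' `tan OA = tan AI sin AA`, `sin OI = sin AI cos AA`.
#'
#' @param definition_from,definition_to angle definitions.
#' @param anteversion,inclination source angles, degrees.
#' @return named numeric vector `c(anteversion, inclination)` in the
#'   target definition, degrees.
#' @export
convert_angles <- function(definition_from, anteversion, inclination, definition_to) {
  ax <- angles_to_axis(definition_from, anteversion, inclination)
  out <- axis_to_angles(ax, definition_to)
  c(anteversion = unname(out$anteversion), inclination = unname(out$inclination))
}

#' Bilateral (left minus right) orientation difference
#'
#' @param left,right [orientation_angles()] under the same definition.
#' @return named vector `c(d_anteversion, d_inclination)`, degrees.
#' @export
bilateral_difference <- function(left, right) {
  stopifnot(inherits(left, "orientation_angles"),
            inherits(right, "orientation_angles"))
  if (!identical(left$definition, right$definition))
    stop("left and right angles use different definitions")
  c(d_anteversion = unname(left$anteversion - right$anteversion),
    d_inclination = unname(left$inclination - right$inclination))
}
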