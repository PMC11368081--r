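#' Default four-segment anthropometric parameter table
#'
#' Segmental parameters for the planar four-segment jumper model (foot,
#' shank, thigh and HAT, i.e. head-arms-trunk). The model stands on a
#' single leg carrying the whole body mass, so the per-limb mass fractions
#' of the standard segmental tables (Winter's) are doubled: foot
#' 2 x 0.0145 = 0.029, shank 2 x 0.0465 = 0.093, thigh 2 x 0.100 = 0.200,
#' and HAT takes the remainder, 0.678. Mass fractions sum to exactly 1.
#'
#' Length fractions are fractions of stature; for the foot the fraction
#' (0.152) is the foot length, for shank and thigh the segment lengths,
#' and for HAT the remainder of stature above the hip. `com_fraction`
#' locates the segment centre of mass along the segment: for the foot,
#' along the tiptoe-to-ankle line measured from the tiptoe (midpoint,
#' 0.5); for shank and thigh, from the proximal joint (Winter's 0.433);
#' for HAT, from the hip (0.626).
#'
#' Only the foot parameters affect the takeoff-landing centre of mass
#' difference: all segments above the foot translate rigidly when the
#' ankle plantarflexes about the tiptoe pivot, so their length and CoM
#' fractions cancel from any CoM *difference* (they set the absolute
#' standing CoM height only).
#'
#' @return A tibble with columns `segment`, `length_fraction`,
#'   `mass_fraction`, `com_fraction`, one row each for `"foot"`,
#'   `"shank"`, `"thigh"` and `"HAT"`.
#' @examples
#' segment_parameters()
#' sum(segment_parameters()$mass_fraction) # exactly 1
#' @export
segment_parameters <- function() {
  tibble::tibble(
    segment         = c("foot", "shank", "thigh", "HAT"),
    length_fraction = c(0.152, 0.246, 0.245, 1 - 0.039 - 0.246 - 0.245),
    mass_fraction   = c(0.029, 0.093, 0.200, 0.678),
    com_fraction    = c(0.5, 0.433, 0.433, 0.626)
  )
}

validate_segments <- function(segments) {
  if (!is.data.frame(segments)) {
    stop("`segments` must be a data frame of segment parameters", call. = FALSE)
  }
  required <- c("segment", "length_fraction", "mass_fraction", "com_fraction")
  missing <- setdiff(required, names(segments))
  if (length(missing) > 0) {
    stop("`segments` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  expected <- c("foot", "shank", "thigh", "HAT")
  if (nrow(segments) != 4L || !setequal(segments$segment, expected)) {
    stop("`segments` must contain exactly the four segments: ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  fracs <- c(segments$length_fraction, segments$mass_fraction,
             segments$com_fraction)
  if (any(!is.finite(fracs)) || any(fracs <= 0) || any(fracs > 1)) {
    stop("all segment fractions must lie in (0, 1]", call. = FALSE)
  }
  mass_sum <- sum(segments$mass_fraction)
  if (abs(mass_sum - 1) > 1e-9) {
    stop(sprintf(
      "segment mass fractions must sum to 1 (got %.12f)", mass_sum),
      call. = FALSE)
  }
  invisible(segments)
}

# Fixed geometric fractions of stature: lateral-malleolus (ankle) height in
# standing, foot length, and the tiptoe-to-ankle horizontal distance as a
# share of foot length.
ANKLE_HEIGHT_FRACTION <- 0.039
FOOT_LENGTH_FRACTION <- 0.152
TOE_ANKLE_SHARE_OF_FOOT <- 0.787

#' Natural foot angle relative to the ground in standing
#'
#' The angle beta of the straight tiptoe-to-ankle (lateral malleolus) line
#' above the floor in quiet standing: `atan(0.039 H / (0.152 x 0.787 H))`.
#' Stature cancels, so beta is the same for every body (about 18.06
#' degrees). Ankle plantarflexion angles are measured on top of this
#' natural inclination.
#'
#' @return The foot angle in degrees (scalar).
#' @examples
#' foot_angle() # ~18.06
#' @export
foot_angle <- function() {
  atan2(ANKLE_HEIGHT_FRACTION,
        FOOT_LENGTH_FRACTION * TOE_ANKLE_SHARE_OF_FOOT) * 180 / pi
}

#' Tiptoe-to-ankle distance from stature or foot length
#'
#' Converts an anthropometric measurement into the straight-line
#' tiptoe-to-lateral-malleolus distance `l_at` used by the anthropometric
#' centre-of-mass correction. From stature `H` the exact expression is
#' `l_at = sqrt((0.039 H)^2 + (0.152 x 0.787 H)^2)` (about `0.126 H`);
#' from foot length `L` it is `l_at = L x sqrt(0.787^2 + (0.039/0.152)^2)`.
#' Exactly one of the two inputs must be supplied.
#'
#' @param stature Stature in metres, or `NULL`.
#' @param foot_length Foot length in metres, or `NULL`.
#' @return Tiptoe-to-ankle distance in metres.
#' @examples
#' ankle_toe_length(stature = 1.75)
#' ankle_toe_length(foot_length = 0.266)
#' @export
ankle_toe_length <- function(stature = NULL, foot_length = NULL) {
  if (is.null(stature) == is.null(foot_length)) {
    stop("supply exactly one of `stature` or `foot_length`", call. = FALSE)
  }
  if (!is.null(stature)) {
    if (any(!is.finite(stature)) || any(stature <= 0)) {
      stop("`stature` must be positive and finite", call. = FALSE)
    }
    sqrt((ANKLE_HEIGHT_FRACTION * stature)^2 +
           (FOOT_LENGTH_FRACTION * TOE_ANKLE_SHARE_OF_FOOT * stature)^2)
  } else {
    if (any(!is.finite(foot_length)) || any(foot_length <= 0)) {
      stop("`foot_length` must be positive and finite", call. = FALSE)
    }
    foot_length * sqrt(TOE_ANKLE_SHARE_OF_FOOT^2 +
                         (ANKLE_HEIGHT_FRACTION / FOOT_LENGTH_FRACTION)^2)
  }
}

#' Build a stature-scaled four-segment body model
#'
#' Scales the segmental parameter table to a given stature and derives the
#' foot geometry needed by the tiptoe-pivot kinematic chain: foot length
#' (0.152 H), standing ankle height (0.039 H), the tiptoe-to-ankle
#' horizontal distance (78.7% of foot length), the straight tiptoe-to-ankle
#' distance `l_at` (computed from the exact square-root expression, not the
#' rounded 0.126 coefficient) and the natural foot angle beta.
#'
#' @param stature Stature H in metres; must lie in (0.5, 3), a sanity
#'   range bracketing all adult human statures.
#' @param segments Segment parameter table, as from
#'   [segment_parameters()]; overrides are validated (fractions in (0, 1],
#'   mass fractions summing to 1).
#' @param g Gravitational acceleration in m/s^2 (default 9.81); carried on
#'   the model for downstream flight computations.
#' @return An object of class `body_model`: a list with fields `stature`,
#'   `g`, `segments` (the fraction table plus absolute `length` in
#'   metres), `foot_length`, `ankle_height`, `toe_ankle_horizontal`,
#'   `ankle_toe_length` and `foot_angle` (degrees).
#' @examples
#' m <- body_model(1.75)
#' m$ankle_toe_length / m$stature # ~0.1258, rounds to 0.126
#' @export
body_model <- function(stature, segments = segment_parameters(), g = 9.81) {
  if (length(stature) != 1L || !is.finite(stature)) {
    stop("`stature` must be a single finite number", call. = FALSE)
  }
  if (stature <= 0.5 || stature >= 3.0) {
    stop(sprintf(
      "`stature` = %g m is outside the supported range (0.5, 3) m", stature),
      call. = FALSE)
  }
  if (length(g) != 1L || !is.finite(g) || g <= 0) {
    stop("`g` must be a single positive number", call. = FALSE)
  }
  validate_segments(segments)
  segments <- segments[match(c("foot", "shank", "thigh", "HAT"),
                             segments$segment), ]
  segments$length <- segments$length_fraction * stature

  structure(
    list(
      stature = stature,
      g = g,
      segments = tibble::as_tibble(segments),
      foot_length = FOOT_LENGTH_FRACTION * stature,
      ankle_height = ANKLE_HEIGHT_FRACTION * stature,
      toe_ankle_horizontal =
        FOOT_LENGTH_FRACTION * TOE_ANKLE_SHARE_OF_FOOT * stature,
      ankle_toe_length = ankle_toe_length(stature = stature),
      foot_angle = foot_angle()
    ),
    class = "body_model"
  )
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("<body_model> stature %.3f m, g = %.5g m/s^2\n", x$stature, x$g))
  cat(sprintf(
    "  foot %.4f m, ankle height %.4f m, tiptoe-ankle %.4f m (%.4f horiz.)\n",
    x$foot_length, x$ankle_height, x$ankle_toe_length,
    x$toe_ankle_horizontal))
  cat(sprintf("  natural foot angle %.2f deg\n", x$foot_angle))
  print(x$segments)
  invisible(x)
}
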