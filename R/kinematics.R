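check_angle <- function(alpha, name = "alpha") {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 90)) {
    stop(sprintf("`%s` must lie in [0, 90] degrees", name), call. = FALSE)
  }
  invisible(alpha)
}

deg2rad <- function(x) x * pi / 180

#' Vertical rise of the ankle with plantarflexion
#'
#' When the foot plantarflexes by `alpha` degrees about the tiptoe pivot,
#' the ankle (lateral malleolus) rises from its standing height by
#' `l_at * (sin(alpha + beta) - sin(beta))`, where `l_at` is the straight
#' tiptoe-to-ankle distance and beta the natural foot angle in standing.
#' At `alpha = 0` (foot flat) the rise is zero; the rise increases
#' strictly with `alpha` up to `90 - beta` degrees.
#'
#' @param model A [body_model()].
#' @param alpha Plantarflexion angle(s) in degrees, in \[0, 90\];
#'   0 means foot flat on the floor.
#' @return Vertical rise(s) of the ankle above standing, in metres.
#' @examples
#' ankle_raise(body_model(1.75), 40)
#' @export
ankle_raise <- function(model, alpha) {
  stopifnot(inherits(model, "body_model"))
  check_angle(alpha)
  beta <- deg2rad(model$foot_angle)
  model$ankle_toe_length * (sin(deg2rad(alpha) + beta) - sin(beta))
}

# CoM rise per unit ankle rise: segments above the foot translate rigidly
# (weight 1 - m_foot); the foot CoM, a point part-way along the rotating
# toe-ankle line, rises by its line fraction of the ankle rise.
com_rise_factor <- function(segments) {
  foot <- segments[segments$segment == "foot", ]
  1 - foot$mass_fraction * (1 - foot$com_fraction)
}

standing_com_height <- function(model) {
  s <- model$segments
  len <- stats::setNames(s$length, s$segment)
  com <- stats::setNames(s$com_fraction, s$segment)
  mass <- stats::setNames(s$mass_fraction, s$segment)
  ankle <- model$ankle_height
  knee <- ankle + len[["shank"]]
  hip <- knee + len[["thigh"]]
  z <- c(
    foot  = com[["foot"]] * ankle,
    shank = knee - com[["shank"]] * len[["shank"]],
    thigh = hip - com[["thigh"]] * len[["thigh"]],
    HAT   = hip + com[["HAT"]] * len[["HAT"]]
  )
  sum(mass[names(z)] * z)
}

#' Whole-body centre of mass height at a given ankle angle
#'
#' Mass-weighted height of the four segment centres of mass in the
#' extended (knee and hip straight) posture with the ankle plantarflexed
#' by `alpha` about the tiptoe pivot. The foot centre of mass rotates with
#' the tiptoe-to-ankle line; every segment above the foot translates
#' rigidly upward by the ankle rise.
#'
#' @inheritParams ankle_raise
#' @return Centre of mass height(s) above the floor, in metres.
#' @examples
#' m <- body_model(1.75)
#' com_height(m, 40) - com_height(m, 0) # CoM rise on tiptoes
#' @export
com_height <- function(model, alpha) {
  stopifnot(inherits(model, "body_model"))
  check_angle(alpha)
  standing_com_height(model) +
    com_rise_factor(model$segments) * ankle_raise(model, alpha)
}

#' Centre of mass difference between landing and takeoff
#'
#' The signed difference `h_diff = h_landing - h_takeoff` between the
#' whole-body centre of mass heights in the landing and takeoff postures.
#' A flatter (more dorsiflexed) landing puts the centre of mass lower
#' than at takeoff, so `h_diff` is negative; this signed convention is
#' what the ballistic flight equations consume. Differences depend only
#' on the foot parameters: all above-foot segments translate rigidly, so
#' their lengths and CoM locations cancel.
#'
#' @param model A [body_model()].
#' @param alpha_takeoff,alpha_landing Ankle plantarflexion at takeoff and
#'   landing, degrees in \[0, 90\]; vectors are recycled to a common
#'   length.
#' @return A tibble with columns `alpha_takeoff`, `alpha_landing`,
#'   `h_takeoff`, `h_landing` (CoM heights, m) and `h_diff` (m, signed).
#' @examples
#' com_difference(body_model(1.71), alpha_takeoff = 40, alpha_landing = 0)
#' @export
com_difference <- function(model, alpha_takeoff, alpha_landing) {
  stopifnot(inherits(model, "body_model"))
  check_angle(alpha_takeoff, "alpha_takeoff")
  check_angle(alpha_landing, "alpha_landing")
  h_to <- com_height(model, alpha_takeoff)
  h_l <- com_height(model, alpha_landing)
  tibble::tibble(
    alpha_takeoff = alpha_takeoff,
    alpha_landing = alpha_landing,
    h_takeoff = h_to,
    h_landing = h_l,
    h_diff = h_l - h_to
  )
}

#' Anthropometric estimate of the takeoff-landing CoM drop
#'
#' Field-usable approximation of the centre of mass change from ankle
#' position alone:
#' `l_at * (sin(alpha_takeoff + beta) - sin(alpha_landing + beta))`.
#' This is the difference in ankle rise between the two postures — it
#' treats the whole body as riding on the ankle, ignoring the small foot
#' mass whose CoM rises only half as far. Note the orientation: it is
#' *positive* when the takeoff is more plantarflexed than the landing,
#' i.e. opposite in sign to [com_difference()]'s `h_diff`.
#'
#' @param x A [body_model()], or a numeric tiptoe-to-ankle distance
#'   `l_at` in metres (as from [ankle_toe_length()]).
#' @param alpha_takeoff,alpha_landing Ankle plantarflexion at takeoff and
#'   landing, degrees in \[0, 90\].
#' @return Estimated CoM drop(s) in metres, positive for a flatter
#'   landing.
#' @examples
#' anthro_hdiff(body_model(1.71), 40, 20)
#' anthro_hdiff(ankle_toe_length(stature = 1.71), 40, 20) # identical
#' @export
anthro_hdiff <- function(x, alpha_takeoff, alpha_landing) {
  check_angle(alpha_takeoff, "alpha_takeoff")
  check_angle(alpha_landing, "alpha_landing")
  if (inherits(x, "body_model")) {
    l_at <- x$ankle_toe_length
  } else if (is.numeric(x) && all(is.finite(x)) && all(x > 0)) {
    l_at <- x
  } else {
    stop("`x` must be a body_model or a positive ankle-toe distance in metres",
         call. = FALSE)
  }
  beta <- deg2rad(foot_angle())
  l_at * (sin(deg2rad(alpha_takeoff) + beta) -
            sin(deg2rad(alpha_landing) + beta))
}
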