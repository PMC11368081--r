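check_g <- function(g) {
  if (any(!is.finite(g)) || any(g <= 0)) {
    stop("`g` must be positive and finite", call. = FALSE)
  }
  invisible(g)
}

#' Ballistic flight quantities of a true jump
#'
#' For a jump of true height `h` (the centre of mass rise above takeoff),
#' constant-acceleration kinematics give the ascending time
#' `t_a = sqrt(2 h / g)`, the true flight time `FT_true = 2 t_a` (takeoff
#' and landing CoM heights equal) and the takeoff velocity `V_to = g t_a`.
#' All are vectorized over `h`.
#'
#' @param jump_height True jump height(s) h in metres, >= 0.
#' @param g Gravitational acceleration, m/s^2.
#' @return Time in seconds ([ascending_time()], [true_flight_time()]) or
#'   velocity in m/s ([takeoff_velocity()]).
#' @examples
#' ascending_time(0.30)
#' true_flight_time(0.30) # twice the ascending time
#' takeoff_velocity(0.30)^2 / (2 * 9.81) # recovers 0.30
#' @export
ascending_time <- function(jump_height, g = 9.81) {
  check_g(g)
  if (any(!is.finite(jump_height)) || any(jump_height < 0)) {
    stop("`jump_height` must be non-negative", call. = FALSE)
  }
  sqrt(2 * jump_height / g)
}

#' @rdname ascending_time
#' @export
true_flight_time <- function(jump_height, g = 9.81) {
  2 * ascending_time(jump_height, g)
}

#' @rdname ascending_time
#' @export
takeoff_velocity <- function(jump_height, g = 9.81) {
  g * ascending_time(jump_height, g)
}

#' Measured flight time under a takeoff-landing CoM difference
#'
#' Time in the air of a projectile leaving with vertical velocity `V_to`
#' and landing when its centre of mass has moved `h_diff` above (positive)
#' or below (negative) its takeoff height:
#' `FT = (V_to + sqrt(V_to^2 - 2 g h_diff)) / g`.
#' With `h_diff = 0` this reduces to the true flight time `2 V_to / g`;
#' a negative `h_diff` (flatter landing) lengthens the measured flight
#' time, which is what inflates flight-time height estimates.
#'
#' @param takeoff_velocity Vertical takeoff velocity(ies), m/s, >= 0.
#' @param h_diff Signed landing-minus-takeoff CoM difference(s), metres
#'   (negative for a flatter landing).
#' @param g Gravitational acceleration, m/s^2.
#' @return Measured flight time(s) in seconds.
#' @examples
#' v <- takeoff_velocity(0.30)
#' measured_flight_time(v, h_diff = -0.05) # longer than true_flight_time(0.30)
#' @export
measured_flight_time <- function(takeoff_velocity, h_diff, g = 9.81) {
  check_g(g)
  if (any(!is.finite(takeoff_velocity)) || any(takeoff_velocity < 0)) {
    stop("`takeoff_velocity` must be non-negative", call. = FALSE)
  }
  radicand <- takeoff_velocity^2 - 2 * g * h_diff
  if (any(radicand < 0)) {
    stop("unreachable landing height: h_diff exceeds the jump apex",
         call. = FALSE)
  }
  ft <- (takeoff_velocity + sqrt(radicand)) / g
  # exact algebraic reduction at h_diff = 0 (avoids the sqrt(v^2) ulp)
  zero <- h_diff == 0
  if (any(zero)) {
    ft[zero] <- (2 * takeoff_velocity / g)[zero]
  }
  ft
}

#' Flight-time estimate of jump height
#'
#' The flight-time method's height estimate `h_hat = g FT^2 / 8`, exact
#' when takeoff and landing CoM heights coincide.
#'
#' @param flight_time Measured flight time(s), seconds, >= 0.
#' @param g Gravitational acceleration, m/s^2.
#' @return Estimated jump height(s) in metres.
#' @examples
#' estimated_height(true_flight_time(0.30)) # 0.30
#' @export
estimated_height <- function(flight_time, g = 9.81) {
  check_g(g)
  if (any(!is.finite(flight_time)) || any(flight_time < 0)) {
    stop("`flight_time` must be non-negative", call. = FALSE)
  }
  flight_time^2 * g / 8
}

#' Percentage error of a height estimate
#'
#' Signed percentage error `(h_hat - h) / h * 100` of an estimated jump
#' height against the true height.
#'
#' @param estimated Estimated height(s), metres.
#' @param true_height True height(s), metres, > 0.
#' @return Signed percentage error(s), on the 0-100 scale.
#' @examples
#' height_error(0.15, 0.10) # 50
#' @export
height_error <- function(estimated, true_height) {
  if (any(!is.finite(true_height)) || any(true_height <= 0)) {
    stop("`true_height` must be positive (percentage error is undefined at 0)",
         call. = FALSE)
  }
  (estimated - true_height) / true_height * 100
}

#' Closed-form flight-time height estimate
#'
#' Algebraic composition of the ballistic pipeline: substituting the
#' takeoff velocity and measured flight time into `g FT^2 / 8` gives
#' `h_hat = (sqrt(h) + sqrt(h - h_diff))^2 / 4`, in which g cancels.
#' The percentage error of the flight-time method therefore does not
#' depend on the value of g.
#'
#' @param jump_height True jump height(s) h, metres, >= 0.
#' @param h_diff Signed landing-minus-takeoff CoM difference(s), metres;
#'   must satisfy `h_diff <= h`.
#' @return Estimated height(s) in metres.
#' @examples
#' estimated_height_closed_form(0.10, -0.1325) # ~0.1594
#' @export
estimated_height_closed_form <- function(jump_height, h_diff) {
  if (any(!is.finite(jump_height)) || any(jump_height < 0)) {
    stop("`jump_height` must be non-negative", call. = FALSE)
  }
  if (any(jump_height - h_diff < 0)) {
    stop("unreachable landing height: h_diff exceeds the jump height",
         call. = FALSE)
  }
  est <- (sqrt(jump_height) + sqrt(jump_height - h_diff))^2 / 4
  # exact reduction h_hat = h at h_diff = 0
  zero <- h_diff == 0
  if (any(zero)) {
    est[zero] <- rep_len(jump_height, length(est))[zero]
  }
  est
}

#' Recover the true jump height from a measured flight time
#'
#' Exact inversion of [measured_flight_time()]: given the measured flight
#' time and the signed landing-minus-takeoff CoM difference, the
#' ascending time is `t_a = FT/2 + h_diff/(g FT)` and the true height is
#' `h = g t_a^2 / 2`. A flatter landing (negative `h_diff`) yields a
#' smaller recovered height than the naive `g FT^2 / 8`.
#'
#' @param flight_time Measured flight time(s) FT, seconds, > 0.
#' @param h_diff Signed landing-minus-takeoff CoM difference(s), metres
#'   (negative for a flatter landing), as from [com_difference()].
#' @param g Gravitational acceleration, m/s^2.
#' @param details If `TRUE`, return a tibble with the decomposition
#'   (`ft`, `ft_true`, `t_diff = ft - ft_true`, `jump_height`) instead of
#'   the bare height.
#' @return Recovered true height(s) in metres, or a tibble when
#'   `details = TRUE`.
#' @examples
#' ft <- measured_flight_time(takeoff_velocity(0.30), -0.05)
#' true_height_from_flight(ft, -0.05) # 0.30
#' @export
true_height_from_flight <- function(flight_time, h_diff, g = 9.81,
                                    details = FALSE) {
  check_g(g)
  if (any(!is.finite(flight_time)) || any(flight_time <= 0)) {
    stop("`flight_time` must be positive", call. = FALSE)
  }
  t_a <- flight_time / 2 + h_diff / (g * flight_time)
  if (any(t_a < 0)) {
    stop("h_diff inconsistent with FT: recovered ascending time is negative",
         call. = FALSE)
  }
  h <- g * t_a^2 / 2
  # exact reduction to the plain flight-time estimate at h_diff = 0
  zero <- h_diff == 0
  if (any(zero)) {
    h[zero] <- (rep_len(flight_time, length(h))^2 * g / 8)[zero]
  }
  if (!details) {
    return(h)
  }
  ft_true <- 2 * t_a
  tibble::tibble(
    ft = flight_time,
    ft_true = ft_true,
    t_diff = flight_time - ft_true,
    jump_height = h
  )
}

#' Anthropometrically corrected jump height
#'
#' The correction equation of the flight-time method: from the measured
#' flight time and the anthropometric CoM-drop estimate
#' ([anthro_hdiff()], positive for a flatter landing),
#' `h_c = (g FT / 2 - hdiff_hat / FT)^2 / (2 g)`.
#' With `hdiff_hat = 0` this is the ordinary estimate `g FT^2 / 8`; a
#' positive `hdiff_hat` shrinks the estimate toward the true height.
#' Internally this is [true_height_from_flight()] with the sign of
#' `hdiff_hat` flipped to the signed landing-minus-takeoff convention.
#'
#' @param flight_time Measured flight time(s) FT, seconds, > 0.
#' @param hdiff_hat Anthropometric CoM drop estimate(s), metres,
#'   positive when takeoff is more plantarflexed than landing.
#' @param g Gravitational acceleration, m/s^2.
#' @return A tibble with columns `ft`, `hdiff_hat` and `h_corrected`
#'   (metres).
#' @examples
#' hd <- anthro_hdiff(body_model(1.984), 40, 0)
#' ft <- measured_flight_time(takeoff_velocity(0.10), -0.1325)
#' corrected_height(ft, hd) # ~0.099, vs naive estimated_height(ft) ~0.159
#' @export
corrected_height <- function(flight_time, hdiff_hat, g = 9.81) {
  h_c <- true_height_from_flight(flight_time, -hdiff_hat, g)
  tibble::tibble(
    ft = flight_time,
    hdiff_hat = hdiff_hat,
    h_corrected = h_c
  )
}
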