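#' Factorial grid of simulated jump conditions
#'
#' Enumerates the full factorial of statures, ankle-position changes and
#' true jump heights. The defaults reproduce the reference simulation
#' design: 100 statures evenly spaced from 1.435 m (3 SD below the female
#' average) to 1.984 m (3 SD above the male average), takeoff
#' plantarflexion fixed at 40 degrees, landing angle reduced by a change
#' of 0-40 degrees in 1-degree steps (0 = identical posture, 40 = flat
#' foot landing), and jump heights 0.10-0.40 m — 16,400 conditions.
#'
#' Rows are ordered deterministically: stature outermost, then change,
#' then jump height innermost.
#'
#' @param stature_min,stature_max Stature range in metres (inclusive).
#' @param stature_count Number of evenly spaced statures.
#' @param takeoff_angle Ankle plantarflexion at takeoff, degrees.
#' @param ankle_changes Ankle-position changes between takeoff and
#'   landing, degrees; the landing angle is `takeoff_angle - change` and
#'   must stay non-negative.
#' @param jump_heights True jump heights, metres.
#' @return A tibble of conditions with columns `stature_m`,
#'   `change_deg`, `jump_height_m`, `alpha_takeoff_deg`,
#'   `alpha_landing_deg`.
#' @examples
#' nrow(jump_grid()) # 16400
#' jump_grid(stature_count = 2, ankle_changes = c(0, 20), jump_heights = 0.3)
#' @export
jump_grid <- function(stature_min = 1.435, stature_max = 1.984,
                      stature_count = 100, takeoff_angle = 40,
                      ankle_changes = 0:40,
                      jump_heights = c(0.10, 0.20, 0.30, 0.40)) {
  if (!is.finite(stature_min) || !is.finite(stature_max) ||
      stature_min <= 0 || stature_max < stature_min) {
    stop("invalid stature range", call. = FALSE)
  }
  if (!is.finite(stature_count) || stature_count < 1) {
    stop("`stature_count` must be at least 1", call. = FALSE)
  }
  if (length(ankle_changes) == 0 || length(jump_heights) == 0) {
    stop("`ankle_changes` and `jump_heights` must be non-empty", call. = FALSE)
  }
  check_angle(takeoff_angle, "takeoff_angle")
  if (any(ankle_changes < 0) || any(ankle_changes > takeoff_angle)) {
    stop("`ankle_changes` must lie in [0, takeoff_angle]", call. = FALSE)
  }
  if (any(!is.finite(jump_heights)) || any(jump_heights <= 0)) {
    stop("`jump_heights` must be positive", call. = FALSE)
  }
  statures <- if (stature_count == 1) {
    stature_min
  } else {
    seq(stature_min, stature_max, length.out = stature_count)
  }
  tidyr::expand_grid(
    stature_m = statures,
    change_deg = as.numeric(ankle_changes),
    jump_height_m = as.numeric(jump_heights)
  ) |>
    dplyr::mutate(
      alpha_takeoff_deg = as.numeric(takeoff_angle),
      alpha_landing_deg = as.numeric(takeoff_angle) - .data$change_deg
    ) |>
    dplyr::relocate("stature_m", "change_deg", "jump_height_m")
}

#' Simulate the flight-time height estimate for a table of jumps
#'
#' For each row (stature, true jump height, takeoff and landing ankle
#' angles) the four-segment body model gives the signed takeoff-landing
#' centre of mass difference; the ballistic flight equations give the
#' measured flight time, the flight-time height estimate and its
#' percentage error; and the anthropometric correction gives the
#' recovered height. All quantities are closed-form, so the result is
#' fully deterministic.
#'
#' @param conditions A data frame with columns `stature_m`,
#'   `jump_height_m`, `alpha_takeoff_deg`, `alpha_landing_deg` (and
#'   optionally `change_deg`), as produced by [jump_grid()].
#' @param segments Segment parameter table, as from
#'   [segment_parameters()].
#' @param g Gravitational acceleration, m/s^2.
#' @return A `jump_sim` tibble: the input conditions plus `h_diff_m`
#'   (signed CoM difference), `hdiff_hat_m` (anthropometric estimate),
#'   `v_to_ms`, `ft_true_s`, `ft_s`, `t_diff_s`, `h_est_m`,
#'   `h_error_pct` and `h_corrected_m`.
#' @examples
#' jump_grid(stature_count = 3) |> simulate_jumps()
#' @export
simulate_jumps <- function(conditions, segments = segment_parameters(),
                           g = 9.81) {
  if (!is.data.frame(conditions)) {
    stop("`conditions` must be a data frame", call. = FALSE)
  }
  required <- c("stature_m", "jump_height_m",
                "alpha_takeoff_deg", "alpha_landing_deg")
  missing <- setdiff(required, names(conditions))
  if (length(missing) > 0) {
    stop("`conditions` is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_segments(segments)
  check_g(g)
  check_angle(conditions$alpha_takeoff_deg, "alpha_takeoff_deg")
  check_angle(conditions$alpha_landing_deg, "alpha_landing_deg")
  if (any(conditions$jump_height_m <= 0)) {
    stop("`jump_height_m` must be positive", call. = FALSE)
  }

  beta <- deg2rad(foot_angle())
  rise_factor <- com_rise_factor(segments)

  out <- tibble::as_tibble(conditions)
  if (!"change_deg" %in% names(out)) {
    out$change_deg <- out$alpha_takeoff_deg - out$alpha_landing_deg
  }
  l_at <- ankle_toe_length(stature = out$stature_m)
  raise_to <- l_at * (sin(deg2rad(out$alpha_takeoff_deg) + beta) - sin(beta))
  raise_land <- l_at * (sin(deg2rad(out$alpha_landing_deg) + beta) - sin(beta))

  out$h_diff_m <- rise_factor * (raise_land - raise_to)
  out$hdiff_hat_m <- raise_to - raise_land
  out$v_to_ms <- takeoff_velocity(out$jump_height_m, g)
  out$ft_true_s <- true_flight_time(out$jump_height_m, g)
  out$ft_s <- measured_flight_time(out$v_to_ms, out$h_diff_m, g)
  out$h_est_m <- estimated_height(out$ft_s, g)
  # unchanged posture reduces exactly: FT = FT_true, h_hat = h
  zero <- out$h_diff_m == 0
  out$ft_s[zero] <- out$ft_true_s[zero]
  out$h_est_m[zero] <- out$jump_height_m[zero]
  out$t_diff_s <- out$ft_s - out$ft_true_s
  out$h_error_pct <- height_error(out$h_est_m, out$jump_height_m)
  out$h_corrected_m <- corrected_height(out$ft_s, out$hdiff_hat_m,
                                        g)$h_corrected

  out <- dplyr::relocate(out, dplyr::all_of(GRID_COLUMNS))
  new_jump_sim(out, g = g)
}

new_jump_sim <- function(x, g) {
  structure(
    x,
    g = g,
    class = c("jump_sim", class(tibble::tibble()))
  )
}

#' Simulate a single jump condition
#'
#' Convenience scalar wrapper around [simulate_jumps()] for one
#' (stature, jump height, takeoff angle, landing angle) condition.
#'
#' @param stature Stature in metres.
#' @param jump_height True jump height in metres.
#' @param alpha_takeoff,alpha_landing Ankle plantarflexion at takeoff and
#'   landing, degrees.
#' @inheritParams simulate_jumps
#' @return A one-row `jump_sim` tibble (see [simulate_jumps()]).
#' @examples
#' simulate_jump(1.984, 0.10, 40, 0) # the worst-case tall/low jump
#' @export
simulate_jump <- function(stature, jump_height, alpha_takeoff, alpha_landing,
                          segments = segment_parameters(), g = 9.81) {
  simulate_jumps(
    tibble::tibble(
      stature_m = stature,
      jump_height_m = jump_height,
      alpha_takeoff_deg = alpha_takeoff,
      alpha_landing_deg = alpha_landing,
      change_deg = alpha_takeoff - alpha_landing
    ),
    segments = segments, g = g
  )
}

#' Worst-case estimation error in a simulation table
#'
#' @param sim A `jump_sim` tibble from [simulate_jumps()].
#' @return The row of `sim` with the largest `h_error_pct`, as a one-row
#'   tibble.
#' @examples
#' jump_grid(stature_count = 5) |> simulate_jumps() |> max_error()
#' @export
max_error <- function(sim) {
  stopifnot(is.data.frame(sim), "h_error_pct" %in% names(sim))
  dplyr::slice_max(tibble::as_tibble(sim), .data$h_error_pct,
                   n = 1, with_ties = FALSE)
}

#' Estimation error at a grid condition
#'
#' Looks up the simulated row nearest to the requested stature with the
#' given jump height and ankle-position change (both matched exactly up
#' to floating point).
#'
#' @param sim A `jump_sim` tibble from [simulate_jumps()].
#' @param stature Stature in metres (nearest grid node is used).
#' @param jump_height True jump height in metres.
#' @param change Ankle-position change in degrees.
#' @return The matching row as a one-row tibble.
#' @examples
#' jump_grid() |> simulate_jumps() |> error_at(1.71, 0.30, 40)
#' @export
error_at <- function(sim, stature, jump_height, change) {
  stopifnot(is.data.frame(sim))
  hits <- dplyr::filter(
    tibble::as_tibble(sim),
    abs(.data$jump_height_m - jump_height) < 1e-9,
    abs(.data$change_deg - change) < 1e-9
  )
  if (nrow(hits) == 0) {
    stop("no simulated condition matches the requested jump height and change",
         call. = FALSE)
  }
  dplyr::slice_min(hits, abs(.data$stature_m - stature),
                   n = 1, with_ties = FALSE)
}

#' Validate the anthropometric correction by regression
#'
#' Ordinary least-squares fit of the corrected height on the true height
#' over the simulated jumps at or below `h_max` (the jumps most prone to
#' error). A successful correction puts every point on the identity line:
#' slope 1, intercept 0, coefficient of determination 1.
#'
#' @param sim A `jump_sim` tibble from [simulate_jumps()].
#' @param h_max Only rows with true jump height <= `h_max` (metres) enter
#'   the regression.
#' @return A `correction_validation` object with fields `n`, `slope`,
#'   `intercept`, `r_squared`, `df_residual`, `h_max` and the underlying
#'   `lm` fit; supports [generics::tidy()], [generics::glance()],
#'   `print()` and [ggplot2::autoplot()].
#' @examples
#' jump_grid(stature_count = 10) |>
#'   simulate_jumps() |>
#'   validate_correction(h_max = 0.20)
#' @export
validate_correction <- function(sim, h_max = 0.20) {
  stopifnot(is.data.frame(sim))
  required <- c("jump_height_m", "h_corrected_m")
  if (!all(required %in% names(sim))) {
    stop("`sim` must contain columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  rows <- dplyr::filter(tibble::as_tibble(sim),
                        .data$jump_height_m <= h_max + 1e-12)
  if (nrow(rows) < 3) {
    stop("fewer than 3 rows at or below h_max; cannot fit the regression",
         call. = FALSE)
  }
  fit <- stats::lm(h_corrected_m ~ jump_height_m, data = rows)
  structure(
    list(
      n = nrow(rows),
      slope = unname(stats::coef(fit)[["jump_height_m"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      r_squared = summary(fit)$r.squared,
      df_residual = fit$df.residual,
      h_max = h_max,
      fit = fit,
      data = rows
    ),
    class = "correction_validation"
  )
}

#' @export
print.correction_validation <- function(x, ...) {
  cat(sprintf(
    "<correction_validation> corrected vs true height, h <= %.2f m\n",
    x$h_max))
  cat(sprintf("  n = %d, slope = %.6f, intercept = %.6f m\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("  r^2 = %.6f (df = %d)\n", x$r_squared, x$df_residual))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname validate_correction
#' @param x A `correction_validation` object.
#' @param ... Unused, for generic consistency.
#' @export
tidy.correction_validation <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"],
    statistic = co[, "t value"],
    p.value = co[, "Pr(>|t|)"]
  )
}

#' @rdname validate_correction
#' @export
glance.correction_validation <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = unname(s$fstatistic["value"]),
    df = unname(s$fstatistic["numdf"]),
    df.residual = x$df_residual,
    nobs = x$n
  )
}
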