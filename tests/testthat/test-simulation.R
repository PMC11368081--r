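test_that("default grid enumerates the full factorial design", {
  g <- jump_grid()
  expect_equal(nrow(g), 16400L)
  expect_equal(dplyr::n_distinct(g$stature_m), 100L)
  expect_equal(g$stature_m[1], 1.435)
  expect_equal(g$stature_m[nrow(g)], 1.984)
  expect_equal(diff(unique(g$stature_m))[1], (1.984 - 1.435) / 99,
               tolerance = 1e-12)
  expect_setequal(unique(g$change_deg), 0:40)
  expect_setequal(unique(g$jump_height_m), c(0.10, 0.20, 0.30, 0.40))
  expect_true(all(g$alpha_landing_deg == 40 - g$change_deg))
  # deterministic order: stature outer, change middle, height inner
  expect_equal(g$jump_height_m[1:4], c(0.10, 0.20, 0.30, 0.40))
  expect_equal(g$change_deg[1:8], rep(c(0, 1), each = 4))
  expect_false(is.unsorted(g$stature_m))
})

test_that("degenerate and invalid grids are handled", {
  g1 <- jump_grid(stature_count = 1, ankle_changes = 0, jump_heights = 0.3)
  expect_equal(nrow(g1), 1L)
  expect_error(jump_grid(ankle_changes = numeric(0)), "non-empty")
  expect_error(jump_grid(jump_heights = numeric(0)), "non-empty")
  expect_error(jump_grid(jump_heights = -0.1), "positive")
  expect_error(jump_grid(ankle_changes = 50), "takeoff_angle")
  expect_error(jump_grid(stature_min = 2, stature_max = 1), "stature range")
})

test_that("simulated rows agree with the model-plus-flight pipeline", {
  sim <- jump_grid(stature_count = 4, ankle_changes = c(0, 10, 25, 40)) |>
    simulate_jumps()
  idx <- sample(nrow(sim), 20)
  for (i in idx) {
    row <- sim[i, ]
    m <- body_model(row$stature_m)
    cd <- com_difference(m, row$alpha_takeoff_deg, row$alpha_landing_deg)
    expect_equal(row$h_diff_m, cd$h_diff, tolerance = 1e-12)
    expect_equal(row$hdiff_hat_m,
                 anthro_hdiff(m, row$alpha_takeoff_deg, row$alpha_landing_deg),
                 tolerance = 1e-12)
    ft <- measured_flight_time(takeoff_velocity(row$jump_height_m),
                               cd$h_diff)
    expect_equal(row$ft_s, ft, tolerance = 1e-12)
    expect_equal(row$h_est_m, estimated_height(ft), tolerance = 1e-12)
    expect_equal(row$h_corrected_m,
                 corrected_height(ft, row$hdiff_hat_m)$h_corrected,
                 tolerance = 1e-12)
  }
  # closed-form identity holds on every row
  expect_equal(sim$h_est_m,
               estimated_height_closed_form(sim$jump_height_m, sim$h_diff_m),
               tolerance = 1e-12)
})

test_that("unchanged posture gives zero error and perfect correction", {
  sim <- jump_grid() |> simulate_jumps()
  zero <- dplyr::filter(sim, change_deg == 0)
  expect_equal(nrow(zero), 400L)
  expect_true(all(zero$h_error_pct == 0))
  expect_true(all(zero$t_diff_s == 0))
  expect_equal(zero$h_corrected_m, zero$jump_height_m, tolerance = 1e-12)
})

test_that("the error surface is monotone in stature, change and jump height", {
  sim <- jump_grid(stature_count = 10) |> simulate_jumps()
  by_h_change <- dplyr::group_by(sim, jump_height_m, change_deg) |>
    dplyr::filter(change_deg > 0) |>
    dplyr::arrange(stature_m, .by_group = TRUE) |>
    dplyr::summarise(mono = all(diff(h_error_pct) > 0), .groups = "drop")
  expect_true(all(by_h_change$mono))
  by_H_change <- dplyr::group_by(sim, stature_m, change_deg) |>
    dplyr::filter(change_deg > 0) |>
    dplyr::arrange(jump_height_m, .by_group = TRUE) |>
    dplyr::summarise(mono = all(diff(h_error_pct) < 0), .groups = "drop")
  expect_true(all(by_H_change$mono))
  by_H_h <- dplyr::group_by(sim, stature_m, jump_height_m) |>
    dplyr::arrange(change_deg, .by_group = TRUE) |>
    dplyr::summarise(mono = all(diff(h_error_pct) > 0), .groups = "drop")
  expect_true(all(by_H_h$mono))
})

test_that("correction always beats the raw estimate, to within 2 mm of truth", {
  sim <- jump_grid() |> simulate_jumps()
  changed <- dplyr::filter(sim, change_deg > 0)
  expect_true(all(abs(changed$h_corrected_m - changed$jump_height_m) <
                    abs(changed$h_est_m - changed$jump_height_m)))
  expect_lt(max(abs(sim$h_corrected_m - sim$jump_height_m)), 2e-3)
})

test_that("summary accessors find the worst case and grid nodes", {
  sim <- jump_grid() |> simulate_jumps()
  worst <- max_error(sim)
  expect_equal(worst$stature_m, 1.984)
  expect_equal(worst$jump_height_m, 0.10)
  expect_equal(worst$change_deg, 40)
  at <- error_at(sim, 1.71, 0.30, 20)
  expect_equal(at$change_deg, 20)
  expect_lt(abs(at$stature_m - 1.71), (1.984 - 1.435) / 99)
  expect_error(error_at(sim, 1.71, 0.55, 20), "no simulated condition")
})

test_that("correction validation regression reports the published frame", {
  sim <- jump_grid() |> simulate_jumps()
  v <- validate_correction(sim, h_max = 0.20)
  expect_equal(v$n, 8200L)
  expect_equal(v$df_residual, 8198L)
  expect_gte(v$r_squared, 0.999)
  expect_lte(v$r_squared, 1)
  expect_equal(v$slope, 1, tolerance = 0.01)
  expect_equal(v$intercept, 0, tolerance = 1e-3)
  # broom-style accessors
  td <- tidy(v)
  expect_equal(td$term, c("(Intercept)", "jump_height_m"))
  expect_equal(unname(td$estimate), c(v$intercept, v$slope),
               tolerance = 1e-12)
  gl <- glance(v)
  expect_equal(gl$nobs, 8200L)
  expect_equal(gl$df.residual, 8198L)
  expect_equal(gl$r.squared, v$r_squared)
})

test_that("correcting with the exact CoM difference is a perfect round trip", {
  sim <- jump_grid(stature_count = 5) |> simulate_jumps()
  exact <- dplyr::mutate(
    sim, h_corrected_m = true_height_from_flight(ft_s, h_diff_m))
  # summary.lm warns that the fit is "essentially perfect" — that is the point
  v <- suppressWarnings(validate_correction(exact, h_max = 0.20))
  expect_equal(v$slope, 1, tolerance = 1e-9)
  expect_equal(v$intercept, 0, tolerance = 1e-12)
  expect_equal(v$r_squared, 1, tolerance = 1e-12)
  expect_error(validate_correction(sim[1:2, ]), "fewer than 3")
})

test_that("autoplot methods return ggplot objects", {
  sim <- jump_grid(stature_count = 4) |> simulate_jumps()
  expect_s3_class(ggplot2::autoplot(sim), "ggplot")
  expect_s3_class(ggplot2::autoplot(validate_correction(sim)), "ggplot")
})
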