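# Independent oracles used across the suite.

# Brute-force whole-body CoM height: every segment CoM is an explicit 2D
# point; plantarflexion rotates the foot points about the tiptoe origin
# with a clockwise 2x2 rotation matrix (which raises the ankle), and all
# above-foot points translate rigidly with the ankle.
oracle_com_height <- function(stature, alpha_deg,
                              segments = segment_parameters()) {
  seg <- segments[match(c("foot", "shank", "thigh", "HAT"),
                        segments$segment), ]
  len <- seg$length_fraction * stature
  ankle_h <- 0.039 * stature
  toe_ankle_x <- 0.152 * 0.787 * stature

  ankle <- c(-toe_ankle_x, ankle_h)     # toe at the origin
  foot_com <- seg$com_fraction[1] * ankle
  knee_z <- ankle_h + len[2]
  hip_z <- knee_z + len[3]
  above <- rbind(
    shank = c(ankle[1], knee_z - seg$com_fraction[2] * len[2]),
    thigh = c(ankle[1], hip_z - seg$com_fraction[3] * len[3]),
    HAT   = c(ankle[1], hip_z + seg$com_fraction[4] * len[4])
  )

  a <- alpha_deg * pi / 180
  rot_cw <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), nrow = 2)
  ankle_new <- drop(rot_cw %*% ankle)
  foot_com_new <- drop(rot_cw %*% foot_com)
  shift <- ankle_new - ankle
  above_new <- sweep(above, 2, shift, "+")

  z <- c(foot_com_new[2], above_new[, 2])
  sum(seg$mass_fraction * z)
}

# Forward time-stepped point projectile: launch at v upward, detect the
# first downward crossing of height h_diff relative to takeoff.
oracle_flight_time <- function(v, h_diff, g = 9.81, dt = 1e-6) {
  t_max <- 2 * v / g + sqrt(2 * (abs(h_diff) + v^2 / (2 * g)) / g) + 0.2
  t <- seq(dt, t_max, by = dt)
  z <- v * t - g * t^2 / 2
  idx <- which(t > v / g & z <= h_diff)[1]
  stopifnot(!is.na(idx))
  t[idx]
}
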