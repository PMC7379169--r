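test_that("profile interpolates the swing anchors and reproduces the printed kinematic peaks", {
  an <- pecking_anchors()
  p <- build_pecking_profile(an)
  # displacement anchors through phase IV are interpolated exactly
  sw <- profile_eval(p, c(0, 0.060, 0.100, 0.150))
  expect_equal(sw$theta, c(0, -0.32, -0.58, -0.18), tolerance = 1e-12)
  expect_equal(sw$omega, c(0, -9.63, 0, 14.45), tolerance = 1e-12)
  expect_equal(sw$alpha, c(0, 0, 408.43, 0), tolerance = 1e-9)
  # peak velocity and peak deceleration over a fine grid
  k <- profile_eval(p, seq(0, 0.25, by = 1e-5))
  expect_equal(max(abs(k$omega)), 14.45, tolerance = 1e-6)
  expect_equal(max(abs(k$alpha)), 7056.73, tolerance = 1e-4)
  # exact pulse midpoint carries the anchor deceleration
  mid <- profile_eval(p, p$t_pulse + p$Tp / 2)
  expect_equal(abs(mid$alpha), 7056.73, tolerance = 1e-9)
  # pulse duration calibrated so the half-sine peak equals the anchor
  # deceleration: T = pi w / (2 a); displacement gained in the pulse w T / 2
  expect_equal(p$Tp, pi * 14.45 / (2 * 7056.73), tolerance = 1e-12)
  th_pulse <- profile_eval(p, p$t_impact)$theta - profile_eval(p, p$t_pulse)$theta
  expect_equal(th_pulse, 14.45 * p$Tp / 2, tolerance = 1e-9)
  # dwell: identically zero motion
  dw <- profile_eval(p, seq(0.161, 0.25, by = 1e-3))
  expect_true(all(dw$omega == 0) && all(dw$alpha == 0))
  expect_true(all(dw$theta == dw$theta[1]))
})

test_that("all-zero anchors produce an identically zero profile", {
  an <- pecking_anchors()
  an$theta <- an$omega <- an$alpha <- 0
  p <- build_pecking_profile(an)
  k <- profile_eval(p, seq(0, 0.25, by = 1e-3))
  expect_equal(max(abs(k$theta)), 0)
  expect_equal(max(abs(k$omega)), 0)
})

test_that("differentiating the displacement history recovers velocity and acceleration", {
  p <- build_pecking_profile()
  dt <- 1e-5
  tt <- seq(0, 0.25, by = dt)
  k <- profile_eval(p, tt)
  om_num <- diff(k$theta) / dt                       # midpoint velocities
  om_mid <- (k$omega[-1] + k$omega[-length(tt)]) / 2
  expect_lt(max(abs(om_num - om_mid)), 0.01 * max(abs(k$omega)))
  al_num <- diff(k$theta, differences = 2) / dt^2    # centred acceleration
  expect_lt(max(abs(al_num - k$alpha[2:(length(tt) - 1)])),
            0.01 * max(abs(k$alpha)))
})

test_that("anchor validation rejects disorder and oversized pulses", {
  an <- pecking_anchors()
  bad <- an; bad$t[2] <- 0.2
  expect_error(build_pecking_profile(bad))
  expect_error(build_pecking_profile(an, impact_pulse_duration = 0.02),
               "pulse longer")
})

test_that("frequency scaling doubles velocity and deceleration but not excursion", {
  p <- build_pecking_profile()
  p2 <- scale_frequency(p, 2)
  k1 <- profile_eval(p, seq(0, p$t_end, by = 1e-5))
  k2 <- profile_eval(p2, seq(0, p2$t_end, by = 1e-5))
  expect_equal(max(abs(k2$omega)), 2 * max(abs(k1$omega)), tolerance = 0.02)
  expect_equal(max(abs(k2$alpha)), 2 * 7056.73, tolerance = 0.02)
  expect_equal(max(abs(k2$theta)), max(abs(k1$theta)), tolerance = 1e-9)
  expect_equal(p2$Tp, p$Tp)                           # pulse duration fixed
  expect_identical(scale_frequency(p, 1), p)          # identity
})

test_that("multi-cycle trains are continuous, periodic, and at rest at junctions", {
  p <- build_pecking_profile()
  p2 <- repeat_cycles(p, 2)
  expect_equal(p2$cycle_duration, 0.5)
  Tc <- p2$cycle_duration / 2
  tt <- seq(0, Tc - 1e-4, by = 1e-4)
  k1 <- profile_eval(p2, tt)
  k2 <- profile_eval(p2, tt + Tc)
  # per-cycle displacement traces identical up to the junction offset
  expect_equal(k2$theta - k2$theta[1], k1$theta - k1$theta[1], tolerance = 1e-12)
  # junction continuity and rest
  jl <- profile_eval(p2, Tc - 1e-9); jr <- profile_eval(p2, Tc + 1e-9)
  expect_equal(jl$theta, jr$theta, tolerance = 1e-6)
  expect_equal(jl$omega, 0); expect_equal(jr$omega, 0, tolerance = 1e-3)
  expect_error(repeat_cycles(p, 2, dwell = -0.1), "negative dwell")
  expect_equal(repeat_cycles(p, 1)$cycle_duration, p$cycle_duration)
})

test_that("rigid-body CM kinematics follow v = omega r and the resultant formula", {
  p <- build_pecking_profile()
  # phase II: |omega| = 9.63 rad/s at the 0.117 m lever arm
  k <- rigid_cm_kinematics(p, 0.117, t = 0.060)
  expect_equal(k$speed, 9.63 * 0.117, tolerance = 1e-12)
  # tabulated simulated value 1.12 m/s within 2%
  expect_equal(k$speed, 1.12, tolerance = 0.02)
  # peak return velocity
  k4 <- rigid_cm_kinematics(p, 0.117, t = 0.150)
  expect_equal(k4$speed, 14.45 * 0.117, tolerance = 1e-12)
  # at rest: everything zero
  k0 <- rigid_cm_kinematics(p, 0.117, t = 0.0)
  expect_equal(k0$speed, 0); expect_equal(k0$a_resultant, 0)
  # resultant combines tangential and centripetal components
  kt <- rigid_cm_kinematics(p, 0.2, t = 0.08)
  kk <- profile_eval(p, 0.08)
  expect_equal(kt$a_resultant,
               sqrt((kk$alpha * 0.2)^2 + (kk$omega^2 * 0.2)^2))
})

test_that("profiles round-trip through CSV export", {
  p <- build_pecking_profile()
  f <- tempfile(fileext = ".csv")
  write_profile_csv(p, f)
  d <- read.csv(f)
  expect_equal(names(d), c("t", "theta"))
  expect_equal(d$theta, p$samples$theta)
})
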