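# Pecking-cycle drive reconstruction.
#
# The pecking cycle is reconstructed from six phase anchors
# (time, angular displacement, velocity, acceleration):
#   I   initial contact, at rest
#   II  halfway rotation (peak swing-away velocity)
#   III extreme end of swing, motion reverses
#   IV  just before impact (peak return velocity)
#   V   impact: half-sine deceleration pulse bringing the head to rest
#   VI  dwell: ~90 ms at rest
# Phases I-IV are quintic Hermite segments matching displacement,
# velocity and acceleration at every anchor; the impact is a half-sine
# angular-deceleration pulse whose duration is calibrated once so that
# its peak equals the phase-V anchor deceleration given the phase-IV
# velocity: T = pi * omega_IV / (2 * |alpha_V|).
#
# The published anchors are not mutually integrable between phases IV
# and V (the displacement step to zero would require velocities above
# the stated peak), so the profile interpolates the displacement anchors
# exactly through phase IV and honors the peak velocity and peak
# deceleration exactly; the post-impact dwell holds the small residual
# angle the pulse integral actually delivers.

#' Default pecking-cycle phase anchors
#'
#' The six-phase anchor table for the woodpecker pecking cycle: times in
#' seconds, angular displacement (rad), velocity (rad/s) and acceleration
#' (rad/s^2) of the drive reference point, plus the end of the dwell.
#'
#' @return data.frame with columns phase, t, theta, omega, alpha
#' @export
pecking_anchors <- function() {
  data.frame(
    phase = c("I", "II", "III", "IV", "V", "VI"),
    t     = c(0, 0.060, 0.100, 0.150, 0.160, 0.250),
    theta = c(0, -0.32, -0.58, -0.18, 0, 0),
    omega = c(0, -9.63, 0, 14.45, 0, 0),
    alpha = c(0, 0, 408.43, 0, -7056.73, 0)
  )
}

# quintic Hermite coefficients on s in [0,1] for (y,v,a) at both ends
quintic_coef <- function(t0, t1, y0, v0, a0, y1, v1, a1) {
  h <- t1 - t0
  M <- matrix(0, 6, 6)
  M[1, 1] <- 1; M[2, 2] <- 1; M[3, 3] <- 2
  M[4, ] <- 1
  M[5, ] <- 0:5
  M[6, ] <- c(0, 0, 2, 6, 12, 20)
  solve(M, c(y0, v0 * h, a0 * h^2, y1, v1 * h, a1 * h^2))
}

#' Build the pecking-cycle drive profile
#'
#' @param anchors anchor table as from [pecking_anchors()]; the phase-V
#'   and phase-VI rows define the impact and the dwell end
#' @param impact_pulse_duration half-sine deceleration pulse length, s;
#'   `NULL` (default) calibrates it so the pulse peak equals the phase-V
#'   anchor deceleration
#' @param sample_dt grid spacing of the exported sampled profile, s
#' @return object of class `pecking_profile` with the piecewise analytic
#'   definition, the sampled grid, cycle and dwell durations
#' @export
build_pecking_profile <- function(anchors = pecking_anchors(),
                                  impact_pulse_duration = NULL,
                                  sample_dt = 1e-4) {
  stopifnot(nrow(anchors) >= 2, all(diff(anchors$t) > 0))
  n <- nrow(anchors)
  t_impact <- anchors$t[n - 1]
  t_end <- anchors$t[n]
  omega_in <- anchors$omega[n - 2]         # velocity entering the pulse
  alpha_pk <- abs(anchors$alpha[n - 1])
  if (alpha_pk > 0 && abs(omega_in) > 0) {
    T_cal <- pi * abs(omega_in) / (2 * alpha_pk)
  } else T_cal <- 0
  Tp <- if (is.null(impact_pulse_duration)) T_cal else impact_pulse_duration
  t_swing_end <- anchors$t[n - 2]          # phase IV anchor time
  if (Tp > t_impact - t_swing_end)
    stop("impact pulse longer than the interval between phases IV and V")
  t_pulse <- t_impact - Tp                 # pulse start

  segs <- list()
  for (k in seq_len(n - 3)) {
    segs[[k]] <- list(
      t0 = anchors$t[k], t1 = anchors$t[k + 1],
      cf = quintic_coef(anchors$t[k], anchors$t[k + 1],
                        anchors$theta[k], anchors$omega[k], anchors$alpha[k],
                        anchors$theta[k + 1], anchors$omega[k + 1],
                        anchors$alpha[k + 1]))
  }
  theta_iv <- anchors$theta[n - 2]
  theta_pulse0 <- theta_iv + omega_in * (t_pulse - t_swing_end)
  theta_final <- theta_pulse0 + omega_in * Tp / 2

  prof <- structure(list(
    segs = segs,
    t_swing_end = t_swing_end, t_pulse = t_pulse, Tp = Tp,
    omega_in = omega_in, alpha_peak = if (Tp > 0) pi * abs(omega_in) / (2 * Tp) else 0,
    theta_iv = theta_iv, theta_pulse0 = theta_pulse0,
    theta_final = theta_final,
    t_impact = t_impact, t_end = t_end,
    cycle_duration = t_end, dwell_duration = t_end - t_impact,
    theta_offset = 0, n_cycles = 1L,
    sample_dt = sample_dt
  ), class = "pecking_profile")
  prof$samples <- profile_eval(prof, seq(0, t_end, by = sample_dt))
  prof
}

# evaluate one single-cycle profile (no offset/cycling) at times t
eval_single <- function(prof, t) {
  th <- om <- al <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti <= prof$t_swing_end) {
      seg <- NULL
      for (s in prof$segs) if (ti <= s$t1 + 1e-15) { seg <- s; break }
      if (is.null(seg)) seg <- prof$segs[[length(prof$segs)]]
      h <- seg$t1 - seg$t0
      s01 <- min(max((ti - seg$t0) / h, 0), 1)
      p <- s01^(0:5)
      th[i] <- sum(seg$cf * p)
      om[i] <- sum(seg$cf[2:6] * (1:5) * s01^(0:4)) / h
      al[i] <- sum(seg$cf[3:6] * c(2, 6, 12, 20) * s01^(0:3)) / h^2
    } else if (ti <= prof$t_pulse) {
      th[i] <- prof$theta_iv + prof$omega_in * (ti - prof$t_swing_end)
      om[i] <- prof$omega_in
      al[i] <- 0
    } else if (ti <= prof$t_impact && prof$Tp > 0) {
      s <- (ti - prof$t_pulse) / prof$Tp
      w0 <- prof$omega_in
      th[i] <- prof$theta_pulse0 +
        w0 * (prof$Tp / 2) * (s + sin(pi * s) / pi)
      om[i] <- w0 * (1 + cos(pi * s)) / 2
      al[i] <- -sign(w0) * prof$alpha_peak * sin(pi * s)
    } else {
      th[i] <- prof$theta_final; om[i] <- 0; al[i] <- 0
    }
  }
  data.frame(t = t, theta = th, omega = om, alpha = al)
}

#' Evaluate a pecking profile analytically
#'
#' Returns angular displacement, velocity and acceleration at arbitrary
#' times, handling multi-cycle trains (each later cycle is offset in
#' angle so that displacement is continuous at cycle junctions; both
#' sides of every junction are at rest).
#'
#' @param profile a `pecking_profile`
#' @param t times, s (vectorised)
#' @return data.frame with columns t, theta, omega, alpha
#' @export
profile_eval <- function(profile, t) {
  Tc <- profile$cycle_duration / profile$n_cycles
  cyc <- pmin(pmax(floor(t / Tc), 0), profile$n_cycles - 1)
  loc <- t - cyc * Tc
  out <- eval_single(profile, loc)
  out$theta <- out$theta + cyc * profile$theta_final + profile$theta_offset
  out$t <- t
  out
}

#' Repeat a pecking cycle into a multi-cycle train
#'
#' Concatenates `n_cycles` copies of the cycle; each cycle retains (or
#' overrides) its dwell, and the angular displacement is continuous at
#' junctions with both sides at rest.
#'
#' @param profile a single-cycle `pecking_profile`
#' @param n_cycles number of cycles (>= 1)
#' @param dwell per-cycle dwell duration, s (default: the profile's own)
#' @return a `pecking_profile` spanning `n_cycles` cycles
#' @export
repeat_cycles <- function(profile, n_cycles, dwell = NULL) {
  stopifnot(inherits(profile, "pecking_profile"), n_cycles >= 1)
  if (!is.null(dwell)) {
    if (dwell < 0) stop("negative dwell")
    profile$t_end <- profile$t_impact + dwell
    profile$dwell_duration <- dwell
  }
  if (profile$n_cycles != 1L) stop("profile is already a multi-cycle train")
  profile$n_cycles <- as.integer(n_cycles)
  profile$cycle_duration <- profile$t_end * n_cycles
  profile$samples <- profile_eval(profile,
                                  seq(0, profile$cycle_duration,
                                      by = profile$sample_dt))
  profile
}

#' Scale the pecking frequency of a profile
#'
#' Compresses the swing phases in time by `factor` (velocities scale by
#' `factor`) while holding the impact-pulse duration fixed, so the peak
#' deceleration scales by `factor` — doubling the pecking frequency
#' doubles the deceleration. The total angular excursion is unchanged.
#'
#' @param profile a single-cycle `pecking_profile`
#' @param factor frequency factor (> 0)
#' @return a `pecking_profile`
#' @export
scale_frequency <- function(profile, factor) {
  stopifnot(inherits(profile, "pecking_profile"), factor > 0)
  if (factor == 1) return(profile)
  if (profile$n_cycles != 1L) stop("scale frequency before repeating cycles")
  p <- profile
  # compress all swing timings; pulse duration fixed
  p$segs <- lapply(profile$segs, function(s) {
    s$t0 <- s$t0 / factor; s$t1 <- s$t1 / factor; s
  })
  p$t_swing_end <- profile$t_swing_end / factor
  p$t_pulse <- profile$t_pulse / factor
  if (p$t_pulse < p$t_swing_end)
    stop("compressed swing shorter than the impact pulse")
  p$Tp <- profile$Tp
  p$t_impact <- p$t_pulse + p$Tp
  p$omega_in <- profile$omega_in * factor
  p$alpha_peak <- pi * abs(p$omega_in) / (2 * p$Tp)
  p$theta_pulse0 <- p$theta_iv + p$omega_in * (p$t_pulse - p$t_swing_end)
  p$theta_final <- p$theta_pulse0 + p$omega_in * p$Tp / 2
  p$t_end <- p$t_impact + profile$dwell_duration
  p$cycle_duration <- p$t_end
  # velocity scaling of the quintic segments: y(t) = y0(factor * t) has
  # identical coefficients on the normalized segment variable
  p$samples <- profile_eval(p, seq(0, p$t_end, by = p$sample_dt))
  p
}

#' Rigid-body kinematics at the head centre of mass
#'
#' For a point at distance `lever_arm` from the rotation reference point:
#' speed `|omega| r`, tangential acceleration `alpha r`, centripetal
#' `omega^2 r`, resultant `sqrt(a_t^2 + a_c^2)`.
#'
#' @param profile a `pecking_profile`
#' @param lever_arm distance from reference point, m (> 0)
#' @param t times, s (default: the profile's sample grid)
#' @return data.frame with t, speed, a_tangential, a_centripetal, a_resultant
#' @export
rigid_cm_kinematics <- function(profile, lever_arm, t = profile$samples$t) {
  stopifnot(lever_arm > 0)
  k <- profile_eval(profile, t)
  data.frame(
    t = t,
    speed = abs(k$omega) * lever_arm,
    a_tangential = k$alpha * lever_arm,
    a_centripetal = k$omega^2 * lever_arm,
    a_resultant = sqrt((k$alpha * lever_arm)^2 + (k$omega^2 * lever_arm)^2)
  )
}
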