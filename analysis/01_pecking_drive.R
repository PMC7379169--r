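#!/usr/bin/env Rscript
# Reconstructs the pecking-cycle drive from the phase anchor table and
# records its kinematic checkpoints.
suppressMessages(library(peckmech))
dir.create("results", showWarnings = FALSE)

drive <- build_pecking_profile()
write_profile_csv(drive, "results/pecking_profile.csv")

k <- profile_eval(drive, seq(0, drive$t_end, by = 1e-5))
checks <- data.frame(
  quantity = c("theta at 100 ms (rad)", "peak |omega| (rad/s)",
               "peak |alpha| (rad/s^2)", "impact pulse duration (ms)",
               "CM speed at phase II, r = 0.117 m (m/s)"),
  value = c(profile_eval(drive, 0.100)$theta, max(abs(k$omega)),
            max(abs(k$alpha)), 1e3 * drive$Tp,
            rigid_cm_kinematics(drive, 0.117, t = 0.060)$speed))
write.csv(checks, "results/drive_checkpoints.csv", row.names = FALSE)
print(checks, row.names = FALSE)
cat("\nThe drive interpolates the swing displacement anchors exactly and",
    "carries the printed peak velocity and deceleration; the half-sine",
    "impact pulse is calibrated to", signif(1e3 * drive$Tp, 4), "ms.\n")
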