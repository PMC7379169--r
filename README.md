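# peckmech

Why don't woodpeckers get concussions? A pecking woodpecker decelerates
its head at about 7,000 rad/s² many thousand times a day — kinematics
that, applied to a human head, sit far beyond published brain-injury
thresholds. `peckmech` is a self-contained R implementation of a 2D
plane-strain explicit-dynamics finite-element pipeline for putting that
comparison on a quantitative footing: it builds simplified woodpecker
and human head models, drives both with the *same* pecking-cycle
rotation, and compares the resulting brain strain and stress fields,
injury-threshold exceedances, and the head-size scaling law that
connects the two species.

It is aimed at researchers in impact biomechanics and comparative
biomechanics who want a scriptable, fully inspectable desk-scale model
chain — every step from mesh generation to injury metrics is an exported
R function.

## What is inside

* **Geometry** — parametric five-region heads (woodpecker: beak, hyoid,
  skull, flesh, brain; human: skull, face, neck, subarachnoid space,
  brain) meshed quad-dominant with conforming region interfaces.
  Feature ablation (no hyoid / no beak) is a pure relabel on identical
  topology, so fields stay element-wise comparable.
* **Materials** — elastic tissue cards realised as finite-strain
  neo-Hookean solids, and a one-term Ogden brain
  (μ₀ = 2780 Pa, α = 6) with quasilinear-viscoelastic Prony relaxation
  μ(t) = μ₀[1 − Σᵢ gᵢ(1 − e^(−t/τᵢ))], g = (0.5663, 0.3246),
  τ ≈ 35 ms, μ∞ = 303.3 Pa.
* **Kinematics** — the six-phase pecking cycle rebuilt from anchor
  values (peak |ω| = 14.45 rad/s, peak |α| = 7056.73 rad/s², ~90 ms
  dwell), with frequency scaling and multi-cycle trains.
* **Solver** — explicit central differences, one-point reduced-
  integration quads with hourglass control, kinematic coupling of the
  head surface to the rotating reference point, penalty contact for the
  beak-impact validation, energy-balance bookkeeping, and an implicit
  Newmark oracle for cross-checking.
* **Fields & statistics** — maximum shear strain (MSS), maximum
  principal strain (MPS), von Mises stress (VM); Pearson r, regression
  slope and a 0–100 correlation score with the significance rule
  r < 0.90, m ∉ (0.9, 1.1), CS < 86; axonal-strain (13%, 18%) and
  shear-stress (7.8 kPa) injury thresholds assessed per phase.
* **Experiments** — baseline species comparison, geometry ablation,
  frequency study, two-cycle material-variant study, and the
  acceleration-scaling search (at what drive amplitude does a scaled
  human head match the woodpecker's brain stress?).

## A worked example

```r
library(peckmech)

# the pecking drive, rebuilt from the phase anchors
drive <- build_pecking_profile()
rigid_cm_kinematics(drive, lever_arm = 0.117, t = 0.060)$speed
#> [1] 1.12671             # head CM speed at mid-swing, m/s

# woodpecker model, full 250 ms cycle
wood <- build_simplified_woodpecker(element_size = 3e-3)
h <- run_simulation(wood, material_library(), drive, solver_config())
peak_report(h, "brain")
#>   metric         peak      time              phase
#> 1    MSS   0.10511289 0.1601904 deceleration-dwell
#> 2    MPS   0.05240772 0.1601876 deceleration-dwell
#> 3     VM 517.23049742 0.1601820 deceleration-dwell

assess_injury(h)
#> injury assessment (brain):
#>   axonal_strain_18   peak 0.05241  exceeded: FALSE (rotation FALSE, decel-dwell FALSE)
#>   axonal_strain_13   peak 0.05241  exceeded: FALSE (rotation FALSE, decel-dwell FALSE)
#>   shear_stress       peak 517.2    exceeded: FALSE (rotation FALSE, decel-dwell FALSE)
```

The woodpecker brain peaks at ~10% shear strain and ~0.5 kPa von Mises
stress, entirely during the deceleration-dwell phase, and never
approaches the 7.8 kPa shear-stress injury tolerance. The same drive
applied to the human model produces strains an order of magnitude
larger and exceeds the 13% axonal-strain threshold in both the rotation
and the deceleration phase.

The numbered scripts under `analysis/` run each study end to end and
write their tables under `results/`:

```sh
Rscript analysis/01_pecking_drive.R
Rscript analysis/02_baseline_comparison.R
# ... through 07_convergence.R
```

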