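# Shared simulation runs, computed lazily once per test session.
# Test meshes are deliberately coarse (desk-scale): peak ratios, phase
# attribution and comparison statistics are the quantities under test,
# not absolute converged field values.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

test_wood_mesh <- function() cached("wood_mesh",
  build_simplified_woodpecker(element_size = 3e-3))

test_human_mesh <- function() cached("human_mesh",
  build_simplified_human(element_size = 10e-3))

test_drive <- function() cached("drive", build_pecking_profile())

# full-cycle woodpecker run (rotation + deceleration + dwell)
wood_full_run <- function() cached("wood_full", {
  run_simulation(test_wood_mesh(), material_library(), test_drive(),
                 solver_config())
})

# full-cycle human run
human_full_run <- function() cached("human_full", {
  run_simulation(test_human_mesh(), material_library(), test_drive(),
                 solver_config())
})

ablation_study <- function() cached("ablation", {
  run_geometry_ablation(element_size = 3e-3)
})

frequency_study <- function() cached("frequency", {
  run_frequency_study(mesh = test_wood_mesh())
})

multicycle_study <- function() cached("multicycle", {
  run_multicycle_study(mesh = test_wood_mesh())
})

scaling_study <- function() cached("scaling", {
  run_scaling_study(sizes = c(1, 0.1),
                    wood_mesh = test_wood_mesh(),
                    human_base = test_human_mesh())
})

# small rotation drive for patch-level explicit/implicit comparisons
smooth_rotation <- function(theta_max, T) {
  function(t) theta_max * 0.5 * (1 - cos(2 * pi * pmin(t, T) / T))
}
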