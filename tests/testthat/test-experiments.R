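test_that("baseline comparison of a model against itself yields unit ratios", {
  m <- test_wood_mesh()
  bc <- run_baseline_comparison(wood_mesh = m, human_mesh = m,
                                window = c(0.155, 0.170))
  expect_equal(unname(bc$ratios), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(unname(bc$acm[1]), unname(bc$acm[2]), tolerance = 1e-12)
})

test_that("baseline comparison reports ratios consistent with the raw histories", {
  hw <- wood_full_run(); hh <- human_full_run()
  # brute-force recomputation from the saved runs
  rat <- max(peak_field(hh, "VM", "brain")) / max(peak_field(hw, "VM", "brain"))
  bc <- list(ratios = c(
    MSS = max(peak_field(hh, "MSS", "brain")) / max(peak_field(hw, "MSS", "brain")),
    MPS = max(peak_field(hh, "MPS", "brain")) / max(peak_field(hw, "MPS", "brain")),
    VM = rat))
  expect_true(all(bc$ratios > 1))          # human responds more strongly
  expect_gt(rat, bc$ratios["MSS"])         # stress amplifies more than strain
})

test_that("ablation fields are statistically indistinguishable; a shuffled control is not", {
  ab <- ablation_study()
  expect_gte(ab$stats$no_hyoid$r, 0.90)
  expect_gte(ab$stats$no_hyoid_no_beak$r, 0.90)
  expect_false(ab$stats$no_hyoid$significant_difference)
  expect_false(ab$stats$no_hyoid_no_beak$significant_difference)
  # base vs base: exact unity
  f0 <- peak_field(ab$base, "MSS", "brain")
  self <- compare_fields(f0, f0)
  expect_equal(self$r, 1)
  # permutation negative control breaks the correlation
  set.seed(123)
  ctrl <- compare_fields(f0, sample(f0))
  expect_true(ctrl$significant_difference)
})

test_that("frequency doubling roughly doubles brain response; the fields differ significantly", {
  fs <- frequency_study()
  expect_true(all(fs$pct_increase > 50))
  expect_true(fs$stats$significant_difference)    # slope far from unity
  # the drive itself doubles: peak deceleration of the scaled profile
  expect_equal(fs$scaled$drive$alpha_peak, 2 * fs$base$drive$alpha_peak,
               tolerance = 1e-12)
})

test_that("multi-cycle study: fast baseline relaxation, stiffer slow-relaxation variant", {
  mc <- multicycle_study()
  base <- mc$baseline; slow <- mc$tau10
  # baseline Prony card: second cycle within a few percent of the first
  expect_lt(abs(base$pct_diff), 3)
  expect_false(base$stats$significant_difference)
  # slower relaxation holds more residual stress at the end of the dwell
  expect_gt(slow$end_dwell_vm[1], base$end_dwell_vm[1])
  # dwell relaxes stress far below the cycle peak for the baseline card
  pk_vm <- max(peak_field(base$history, "VM", "brain"))
  expect_lt(base$end_dwell_vm[1], 0.25 * pk_vm)
})

test_that("peak brain stress decreases monotonically with head size under the identical drive", {
  lib <- material_library()
  d <- test_drive()
  m <- test_wood_mesh()
  win <- c(d$t_pulse - 2e-3, d$t_impact + 12e-3)
  vm <- vapply(c(1, 0.6, 0.3), function(f) {
    mf <- scale_head(m, f, lever_arm = m$lever_arm)
    h <- run_simulation(mf, lib, d, solver_config(window = win))
    max(peak_field(h, "VM", "brain"))
  }, numeric(1))
  expect_true(all(diff(vm) < 0))
})

test_that("scaling search against the model itself converges to unit amplitude and factor", {
  m <- test_wood_mesh()
  sc <- run_scaling_study(sizes = 1, wood_mesh = m, human_base = m,
                          tol = 0.02, max_iter = 10)
  expect_true(sc$converged)
  expect_equal(sc$amplitude, 1, tolerance = 0.1)
  expect_equal(sc$factor, 1, tolerance = 0.1)
})

test_that("experiment reports are deterministic under identical configuration", {
  lib <- material_library()
  d <- test_drive()
  m <- test_wood_mesh()
  cfg <- solver_config(window = c(d$t_pulse - 1e-3, d$t_impact + 5e-3))
  h1 <- run_simulation(m, lib, d, cfg)
  h2 <- run_simulation(m, lib, d, cfg)
  expect_identical(h1$peaks, h2$peaks)
  expect_identical(h1$energy, h2$energy)
})

test_that("scenario configs materialise meshes, variants and drives", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "geometry:",
    "  species: woodpecker",
    "  element_size: 0.003",
    "  include_hyoid: false",
    "materials:",
    "  variant: tau10",
    "drive:",
    "  frequency_factor: 2",
    "solver:",
    "  safety: 0.8"), f)
  cfg <- read_scenario_config(f)
  sc <- build_scenario(cfg)
  expect_false(any(sc$mesh$elem_region == "hyoid"))
  expect_equal(attr(sc$library, "variant"), "tau10")
  expect_equal(sc$library$brain$tau, c(0.35, 0.351))
  expect_equal(sc$drive$alpha_peak, 2 * 7056.73, tolerance = 1e-6)
  expect_equal(sc$solver_config$safety, 0.8)
})

test_that("user-supplied material cards override packaged defaults", {
  lib <- material_library_from_config(list(
    flesh = list(rho = 1100, E = 2e6, nu = 0.4),
    brain = list(rho = 1000, mu0 = 2000, alpha = 4,
                 g = list(0.3), tau = list(0.05))))
  expect_equal(lib$flesh$E, 2e6)
  expect_equal(lib$brain$alpha, 4)
  expect_equal(longterm_shear_modulus(lib$brain), 2000 * 0.7)
  # untouched regions keep the packaged values
  expect_equal(lib$hyoid$E, 3.72e9)
})
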