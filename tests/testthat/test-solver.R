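test_that("lumped mass: tributary values, exact totals, refinement invariance", {
  unit_lib <- structure(list(brain = elastic_card(1, 1, 0)),
                        class = "material_library")
  m1 <- patch_mesh(1, 1, 1, 1)
  expect_equal(assemble_lumped_mass(m1, unit_lib), rep(0.25, 4))
  m4 <- patch_mesh(4, 4, 1, 1)
  expect_equal(sum(assemble_lumped_mass(m4, unit_lib)), 1, tolerance = 1e-12)
  # real mesh: total mass equals sum rho * area exactly
  lib <- material_library()
  m <- test_wood_mesh()
  rho <- vapply(m$elem_region, function(rg)
    peckmech:::resolve_card(lib, rg)$rho, numeric(1))
  expect_equal(sum(assemble_lumped_mass(m, lib)), sum(rho * m$elem_area),
               tolerance = 1e-12)
  expect_error(assemble_lumped_mass(patch_mesh(1, 1, 1, 1, region = "fin"), lib),
               "no material card")
})

test_that("internal forces: zero at rest, zero under rigid rotation, patch-test tractions", {
  lib <- material_library()
  m <- patch_mesh(2, 2, 0.02, 0.02, region = "flesh")
  f0 <- internal_forces(m, m$nodes, lib)
  expect_lt(max(abs(f0$force)), 1e-10)
  expect_lt(max(abs(f0$stress)), 1e-8)
  # rigid 30-degree rotation
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  fr <- internal_forces(m, m$nodes %*% t(R), lib)
  mu <- lib$flesh$mu
  expect_lt(max(abs(fr$force)), 1e-6 * mu * sum(m$elem_area) / 0.01)
  # uniform-stretch patch: boundary tractions match the closed form
  F <- matrix(c(1.05, 0, 0, 0.98), 2)
  fs <- internal_forces(m, m$nodes %*% t(F), lib)
  sig <- neo_hookean_stress(lib$flesh, F)
  P <- det(F) * sig[1:2, 1:2] %*% t(solve(F))
  right <- which(abs(m$nodes[, 1] - 0.02) < 1e-12)
  # assembled internal force on the constrained right edge balances P e1 Ly
  expect_equal(sum(fs$force[right, 1]), -P[1, 1] * 0.02, tolerance = 0.01)
  # uniform stress everywhere (patch test)
  expect_equal(max(abs(sweep(fs$stress, 2,
                             c(sig[1, 1], sig[2, 2], sig[1, 2], sig[3, 3])))),
               0, tolerance = 1e-8 * mu)
})

test_that("implicit Newmark path runs and a rigid drive leaves a rigid patch strain-free", {
  lib <- material_library()
  m <- patch_mesh(2, 2, 0.02, 0.02, region = "brain")
  m$ref_point <- c(0.01, 0.01)
  # slow rigid rotation: the quasi-static patch follows rigidly, so the
  # implicit solution must carry (numerically) zero strain
  th_fun <- smooth_rotation(0.15, 0.01)
  imp <- newmark_implicit(m, lib, th_fun, t_end = 0.01, dt = 5e-4)
  expect_true(all(is.finite(imp$mss)))
  expect_lt(max(imp$mss), 1e-3)
})

test_that("explicit kernel matches the implicit Newmark oracle on a driven brain patch", {
  lib <- material_library()
  m <- patch_mesh(2, 2, 0.02, 0.02, region = "brain")
  m$ref_point <- c(0, 0)    # off-centre pivot; see below
  # a fast small rotation about the patch corner: the free centre node
  # must accelerate, and its inertial lag shears the soft brain elements
  T_rot <- 0.002; T_end <- 0.004
  th_fun <- smooth_rotation(5e-4, T_rot)
  mt <- peckmech:::material_table(m, lib)
  mass <- assemble_lumped_mass(m, lib)
  # matched physics for the scheme comparison: no viscous damping terms,
  # explicit step well below stability so both schemes are resolved
  nst <- 400L; dt <- T_end / nst
  res <- peckmech:::explicit_solve_cpp(
    m$nodes, m$quads - 1L, matrix(0L, 0, 3), mt$type, mt$par, mass,
    m$boundary_nodes - 1L, th_fun(dt * (0:nst)),
    m$ref_point[1], m$ref_point[2], dt, nst, 8L, 1L,
    0.05, 0, 0, FALSE, 0, 0, 0, 0, 0,
    matrix(0, nrow(m$nodes), 2), 0, integer(0), numeric(0))
  expect_equal(res$status, 0)
  mss_explicit <- max(res$peaks[, 1])
  expect_gt(mss_explicit, 1e-4)             # a real transient, not noise
  imp <- newmark_implicit(m, lib, th_fun, t_end = T_end, dt = T_end / 100)
  mss_implicit <- max(imp$mss)
  expect_equal(mss_explicit, mss_implicit, tolerance = 0.05)
})

test_that("rigid-drive fidelity: coupled nodes follow the analytic rotation to machine precision", {
  h <- wood_full_run()
  m <- h$mesh
  th_end <- profile_eval(h$drive, h$window[2])$theta -
    profile_eval(h$drive, h$window[1])$theta
  R <- matrix(c(cos(th_end), sin(th_end), -sin(th_end), cos(th_end)), 2)
  bn <- m$boundary_nodes
  expect_lt(max(abs(h$pos_final[bn, ] -
                    sweep(sweep(m$nodes[bn, ], 2, m$ref_point) %*% t(R),
                          2, m$ref_point, "+"))), 1e-12)
})

test_that("energy balance closes and hourglass work stays small in the pecking run", {
  h <- wood_full_run()
  expect_lte(energy_residual(h), 0.02)
  expect_lt(max(h$energy$W_hourglass), 0.05 * max(abs(h$energy$W_int)))
})

test_that("halving the time step changes peak brain MSS by under 2%", {
  lib <- material_library()
  m <- test_wood_mesh()
  d <- test_drive()
  win <- c(d$t_pulse - 2e-3, d$t_impact + 15e-3)
  h1 <- run_simulation(m, lib, d, solver_config(window = win, safety = 0.9))
  h2 <- run_simulation(m, lib, d, solver_config(window = win, safety = 0.45))
  expect_equal(max(peak_field(h2, "MSS", "brain")),
               max(peak_field(h1, "MSS", "brain")), tolerance = 0.02)
})

test_that("free flight conserves momentum and translates force-free", {
  lib <- material_library()
  m <- patch_mesh(3, 3, 0.03, 0.03, region = "flesh")
  mt <- peckmech:::material_table(m, lib)
  mass <- assemble_lumped_mass(m, lib)
  dt <- stable_time_step(m, lib, 0.9)
  nst <- 400L
  # non-uniform initial velocity (spin about the centre): internal forces
  # develop, but total momentum must be conserved without constraints
  om <- 50
  rel <- sweep(m$nodes, 2, c(0.015, 0.015))
  v0 <- cbind(-om * rel[, 2], om * rel[, 1]) + 0.5
  res <- peckmech:::explicit_solve_cpp(
    m$nodes, m$quads - 1L, matrix(0L, 0, 3), mt$type, mt$par, mass,
    integer(0), numeric(nst + 1), 0, 0, dt, nst, 100L, 5L,
    0.05, 0.02, 0.06, FALSE, 0, 0, 0, 0, 0, v0, 0,
    integer(0), numeric(0))
  expect_equal(res$status, 0)
  p0 <- colSums(mass * v0)
  p1 <- colSums(mass * res$vel_final)
  expect_lt(max(abs(p1 - p0)) / sqrt(sum(p0^2)), 1e-3)
  # pure translation: no forces, exact uniform motion
  v0t <- cbind(rep(1.3, nrow(m$nodes)), rep(-0.4, nrow(m$nodes)))
  rest <- peckmech:::explicit_solve_cpp(
    m$nodes, m$quads - 1L, matrix(0L, 0, 3), mt$type, mt$par, mass,
    integer(0), numeric(nst + 1), 0, 0, dt, nst, 100L, 5L,
    0.05, 0.02, 0.06, FALSE, 0, 0, 0, 0, 0, v0t, 0,
    integer(0), numeric(0))
  expect_equal(rest$pos_final,
               m$nodes + nst * dt * cbind(rep(1.3, nrow(m$nodes)),
                                          rep(-0.4, nrow(m$nodes))),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("beak impact: no force without approach speed, impulse-momentum balance, single pulse", {
  lib <- material_library()
  m <- build_simplified_woodpecker(element_size = 3e-3)
  z <- run_impact_validation(m, lib, impact_speed = 0, duration = 3e-4)
  expect_equal(max(abs(z$contact$force)), 0)
  r <- run_impact_validation(m, lib, impact_speed = 1.4, beak_angle = 79,
                             duration = 2.5e-3)
  f <- r$contact$force
  expect_gt(max(f), 0)
  # force rises from zero and returns to (near) zero after rebound
  expect_equal(f[1], 0)
  expect_lt(f[length(f)], 0.05 * max(f))
  # impulse equals the momentum change of the head
  impulse <- sum(f) * diff(r$contact$t[1:2])
  mass <- r$contact$mass
  dvx <- 1.4 - sum(mass * r$vel_final[, 1]) / sum(mass)
  expect_equal(impulse, sum(mass) * dvx, tolerance = 0.05)
  # single dominant pulse of about a millisecond at this coarse mesh
  t_on <- r$contact$t[f > 0.05 * max(f)]
  expect_lt(max(t_on) - min(t_on), 1.5e-3)
})

test_that("element inversion and instability are reported with context", {
  lib <- material_library()
  m <- patch_mesh(2, 2, 0.02, 0.02, region = "brain")
  m$ref_point <- c(0, 0)       # off-centre pivot so the drive is not rigid
  an <- pecking_anchors()
  d <- build_pecking_profile(an)
  # absurd amplitude forces inversion or instability quickly
  expect_error(
    run_simulation(m, lib, d,
                   solver_config(window = c(0.15, 0.2), amplitude = 2000)),
    "inversion|instability")
})
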