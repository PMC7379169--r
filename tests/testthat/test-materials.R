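brain_card <- function(...) {
  lib <- material_library(...)
  lib$brain
}

test_that("shear relaxation modulus reproduces the tabulated instantaneous and long-time moduli", {
  card <- brain_card()
  expect_equal(shear_relaxation_modulus(card, 0), 2780)
  expect_equal(longterm_shear_modulus(card), 303.3, tolerance = 1e-3)
  expect_equal(shear_relaxation_modulus(card, 100), 303.3, tolerance = 1e-3)
  # direct evaluation of the relaxation function at one decay time
  expect_equal(shear_relaxation_modulus(card, 0.035), 1215.373, tolerance = 1e-4)
  # strictly decreasing, bounded below by the equilibrium modulus
  tt <- seq(0, 0.5, by = 1e-3)
  mu <- shear_relaxation_modulus(card, tt)
  expect_true(all(diff(mu) < 0))
  expect_true(all(mu >= longterm_shear_modulus(card) - 1e-9))
  expect_error(shear_relaxation_modulus(card, -1), "t >= 0")
})

test_that("long-time modulus arithmetic and validity guards", {
  c1 <- ogden_qlv_card(1000, 1000, 2, g = 0.5, tau = 0.1)
  expect_equal(longterm_shear_modulus(c1), 500)
  c2 <- ogden_qlv_card(1000, 1000, 2, g = numeric(0), tau = numeric(0))
  expect_equal(longterm_shear_modulus(c2), 1000)
  expect_error(ogden_qlv_card(1000, 1000, 2, g = c(0.6, 0.4), tau = c(1, 1)),
               "sum of Prony moduli")
})

test_that("Ogden stress: identity, small-strain shear modulus, closed-form principal differences", {
  card <- brain_card()
  expect_equal(ogden_stress(card, diag(2)), matrix(0, 3, 3))
  # small simple shear: shear stress ~ mu0 * gamma
  g <- 0.01
  S <- ogden_stress(card, matrix(c(1, 0, g, 1), 2))
  expect_equal(S[1, 2], card$mu0 * g, tolerance = 0.02)
  # isochoric in-plane stretch (lam, 1/lam, 1): principal Cauchy stress
  # difference has the closed form (2 mu / alpha)(lam^a - lam^-a)
  lam <- 1.1
  S2 <- ogden_stress(card, diag(c(lam, 1 / lam)))
  closed <- (2 * card$mu0 / card$alpha) * (lam^card$alpha - lam^(-card$alpha))
  expect_equal(S2[1, 1] - S2[2, 2], closed, tolerance = 1e-10)
  expect_error(ogden_stress(card, diag(c(-1, 1))), "Jacobian")
})

test_that("Ogden and neo-Hookean stresses agree with numeric differentiation of the energy", {
  # independent oracle: Cauchy stress = J^-1 (dU/dF) F^T by finite differences
  card <- brain_card()
  U_ogden <- function(F) {
    J <- det(F)
    C <- t(F) %*% F
    lam <- sqrt(eigen(C, symmetric = TRUE)$values)
    lb <- c(lam, 1) * J^(-1 / 3)
    2 * card$mu0 / card$alpha^2 * sum(lb^card$alpha - 1) +
      card$K / 2 * (J - 1)^2
  }
  ec <- material_library()$flesh
  U_nh <- function(F) {
    J <- det(F)
    B <- F %*% t(F)
    trBb <- J^(-2 / 3) * (B[1, 1] + B[2, 2] + 1)
    ec$mu / 2 * (trBb - 3) + ec$K / 2 * (J - 1)^2
  }
  num_cauchy <- function(U, F) {
    P <- matrix(0, 2, 2)
    h <- 1e-7
    for (i in 1:2) for (j in 1:2) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (U(Fp) - U(Fm)) / (2 * h)
    }
    (P %*% t(F)) / det(F)
  }
  set.seed(42)
  for (k in 1:5) {
    F <- diag(2) + matrix(rnorm(4, sd = 0.08), 2)
    if (det(F) <= 0.2) next
    So <- ogden_stress(card, F)
    expect_equal(So[1:2, 1:2], num_cauchy(U_ogden, F), tolerance = 1e-4)
    Sn <- neo_hookean_stress(ec, F)
    expect_equal(Sn[1:2, 1:2] / ec$mu, num_cauchy(U_nh, F) / ec$mu,
                 tolerance = 1e-4)
  }
})

test_that("stresses are frame-indifferent under random rigid rotations", {
  card <- brain_card()
  ec <- material_library()$skull
  set.seed(7)
  F <- diag(2) + matrix(rnorm(4, sd = 0.1), 2)
  for (k in 1:8) {
    th <- runif(1, -pi, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    for (fun in list(function(f) ogden_stress(card, f),
                     function(f) neo_hookean_stress(ec, f))) {
      S0 <- fun(F)
      SR <- fun(R %*% F)
      rot <- matrix(0, 3, 3); rot[1:2, 1:2] <- R; rot[3, 3] <- 1
      expect_equal(SR, rot %*% S0 %*% t(rot), tolerance = 1e-9)
    }
    # rigid rotation alone produces zero stress
    expect_equal(max(abs(neo_hookean_stress(ec, R))), 0, tolerance = 1e-6 * ec$mu)
    expect_equal(max(abs(ogden_stress(card, R))), 0, tolerance = 1e-6 * card$mu0)
  }
})

test_that("QLV update relaxes a held shear to the equilibrium ratio and matches the analytic hereditary integral", {
  card <- brain_card()
  # instantaneous deviatoric stress held constant: sigma(t)/sigma(0+) = mu(t)/mu0
  S_inst <- c(1, -1, 0.5, 0)
  dt <- min(card$tau) / 100
  st <- NULL
  up <- qlv_update(card, S_inst, st, dt)   # step applied in the first increment
  expect_equal(up$S_dev, S_inst, tolerance = 0.01)   # t = 0+: instantaneous
  nstep <- round(0.5 / dt)
  for (i in seq_len(nstep)) up <- qlv_update(card, S_inst, up$state, dt)
  ratio <- up$S_dev[1] / S_inst[1]
  expect_equal(ratio, 303.3 / 2780, tolerance = 0.01)
  # analytic hereditary integral for a step at t=0: G(t) = mu(t)/mu0
  up2 <- qlv_update(card, S_inst, NULL, dt)
  nhold <- round(0.07 / dt)
  for (i in seq_len(nhold)) up2 <- qlv_update(card, S_inst, up2$state, dt)
  G_analytic <- shear_relaxation_modulus(card, 0.07 + dt) / card$mu0
  expect_equal(up2$S_dev[1] / S_inst[1], G_analytic, tolerance = 0.01)
  # zero strain history stays zero
  upz <- qlv_update(card, c(0, 0, 0, 0), NULL, dt)
  for (i in 1:50) upz <- qlv_update(card, c(0, 0, 0, 0), upz$state, dt)
  expect_equal(upz$S_dev, c(0, 0, 0, 0))
  # single-term card: step response proportional to 1 - g1 (1 - exp(-t/tau))
  c1 <- ogden_qlv_card(1000, 1000, 2, g = 0.4, tau = 0.02)
  u <- qlv_update(c1, 1, NULL, 1e-4)
  for (i in seq_len(2000)) u <- qlv_update(c1, 1, u$state, 1e-4)
  t_el <- 2001e-4
  expect_equal(u$S_dev, 1 - 0.4 * (1 - exp(-t_el / 0.02)), tolerance = 0.01)
})

test_that("dilatational wave speeds match the plane-strain P-wave formula", {
  lib <- material_library()
  expect_equal(dilatational_wave_speed(lib$hyoid), 2768.5, tolerance = 1e-3)
  expect_equal(dilatational_wave_speed(lib$flesh), 59.54, tolerance = 1e-3)
  expect_equal(dilatational_wave_speed(elastic_card(1, 1, 0)), 1)
  expect_error(dilatational_wave_speed(elastic_card(1, 1, 0.5 - 1e-16)),
               "unbounded")
  # brain: from instantaneous shear modulus and near-incompressible bulk
  b <- lib$brain
  expect_equal(dilatational_wave_speed(b),
               sqrt((b$K + 4 * b$mu0 / 3) / b$rho))
})

test_that("stable time step follows element length over wave speed", {
  lib <- material_library()
  # one unit element of a unit-wave-speed material: characteristic
  # length is area over the longest diagonal (the conservative explicit
  # stability measure), 1/sqrt(2) for a unit square
  unit_lib <- structure(list(flesh = elastic_card(1, 1, 0)),
                        class = "material_library")
  m1 <- patch_mesh(1, 1, 1, 1, region = "flesh")
  expect_equal(stable_time_step(m1, unit_lib, safety = 1), 1 / sqrt(2))
  expect_equal(stable_time_step(m1, unit_lib, safety = 0.4), 0.4 / sqrt(2))
  # coarsening by 5x grows dt by 5x
  m5 <- patch_mesh(1, 1, 5, 5, region = "flesh")
  expect_equal(stable_time_step(m5, unit_lib, 1),
               5 * stable_time_step(m1, unit_lib, 1))
  # a 0.2 mm hyoid element: dt of the order 1e-7 s
  mh <- patch_mesh(1, 1, 0.2e-3, 0.2e-3, region = "hyoid")
  dth <- stable_time_step(mh, lib, safety = 1)
  expect_equal(dth, 0.2e-3 / sqrt(2) / 2768.5, tolerance = 1e-3)
})
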