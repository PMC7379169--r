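# Constitutive models and the tissue property library.
#
# Two kinds of material card:
#   * elastic_card  -- hard/soft tissues (rho, E, nu), implemented as a
#     compressible neo-Hookean solid matched to (E, nu) so that the large
#     rigid rotations of the pecking swing generate no spurious stress.
#   * ogden_qlv_card -- brain tissue: one-term Ogden hyperelasticity with
#     quasilinear viscoelastic (Prony series) relaxation of the deviatoric
#     stress; volumetric response elastic and near-incompressible.

#' Linear-elastic tissue card
#'
#' Density, Young's modulus and Poisson's ratio for a hard or soft tissue.
#' At run time the card is realised as a compressible neo-Hookean solid
#' whose small-strain limit reproduces `E` and `nu` exactly, so rigid
#' rotation produces zero stress.
#'
#' @param rho density, kg/m^3
#' @param E Young's modulus, Pa
#' @param nu Poisson's ratio, in (-1, 0.5)
#' @return an object of class `elastic_card`
#' @export
elastic_card <- function(rho, E, nu) {
  stopifnot(rho > 0, E > 0, nu > -1, nu < 0.5)
  structure(list(rho = rho, E = E, nu = nu,
                 mu = E / (2 * (1 + nu)),
                 K = E / (3 * (1 - 2 * nu))),
            class = "elastic_card")
}

#' Ogden + quasilinear-viscoelastic brain card
#'
#' One-term Ogden strain energy
#' \deqn{U = \frac{2\mu_0}{\alpha^2}(\bar\lambda_1^\alpha +
#'       \bar\lambda_2^\alpha + \bar\lambda_3^\alpha - 3)}
#' with deviatoric principal stretches \eqn{\bar\lambda_i = \lambda_i J^{-1/3}},
#' and a Prony-series relaxation function
#' \deqn{\mu(t) = \mu_0 [1 - \sum_i g_i (1 - e^{-t/\tau_i})]}
#' applied to the deviatoric stress (quasilinear viscoelasticity). The
#' volumetric response is elastic, with bulk modulus implied by `nu_eff`.
#'
#' @param rho density, kg/m^3
#' @param mu0 instantaneous shear modulus, Pa
#' @param alpha Ogden exponent (dimensionless)
#' @param g Prony relative moduli (dimensionless), `sum(g) < 1`
#' @param tau Prony decay constants, s
#' @param nu_eff effective Poisson's ratio controlling near-incompressibility
#' @return an object of class `ogden_qlv_card`
#' @export
ogden_qlv_card <- function(rho, mu0, alpha, g, tau, nu_eff = 0.499) {
  stopifnot(rho > 0, mu0 > 0, length(g) == length(tau),
            all(tau > 0), all(g >= 0), nu_eff > 0, nu_eff < 0.5)
  if (sum(g) >= 1)
    stop("sum of Prony moduli g must be < 1 (long-time modulus would vanish)")
  structure(list(rho = rho, mu0 = mu0, alpha = alpha,
                 g = g, tau = tau, nu_eff = nu_eff,
                 # bulk modulus consistent with (mu0, nu_eff) small-strain elasticity
                 K = 2 * mu0 * (1 + nu_eff) / (3 * (1 - 2 * nu_eff))),
            class = "ogden_qlv_card")
}

#' Default tissue property library
#'
#' The packaged property set for both species. Woodpecker: beak, hyoid,
#' skull, flesh, brain. Human: skull, face, neck, subarachnoid space,
#' brain. The woodpecker and human brain cards are identical. `variant`
#' selects the Prony decay constants: `"baseline"` (tau ~ 35 ms) or
#' `"tau10"` with both decay constants scaled by 10 (slower relaxation).
#'
#' @param variant `"baseline"` or `"tau10"`
#' @param nu_eff near-incompressibility parameter for the brain
#' @return a named list of material cards, class `material_library`
#' @export
material_library <- function(variant = c("baseline", "tau10"), nu_eff = 0.499) {
  variant <- match.arg(variant)
  tau_scale <- if (variant == "tau10") 10 else 1
  brain <- ogden_qlv_card(rho = 1040, mu0 = 2780, alpha = 6.0,
                          g = c(0.5663, 0.3246),
                          tau = c(0.0350, 0.0351) * tau_scale,
                          nu_eff = nu_eff)
  structure(list(
    beak  = elastic_card(rho = 1456, E = 1e9,    nu = 0.3),
    hyoid = elastic_card(rho = 1040, E = 3.72e9, nu = 0.4),
    skull = elastic_card(rho = 1456, E = 0.31e9, nu = 0.4),
    flesh = elastic_card(rho = 1070, E = 1e6,    nu = 0.45),
    brain = brain,
    skull_h       = elastic_card(rho = 2070, E = 8e9,    nu = 0.22),
    face          = elastic_card(rho = 2000, E = 15e9,   nu = 0.22),
    neck          = elastic_card(rho = 1300, E = 1e9,    nu = 0.24),
    subarachnoid  = elastic_card(rho = 1133, E = 9.85e6, nu = 0.49),
    brain_h       = brain
  ), class = "material_library", variant = variant)
}

#' Resolve a mesh region label to a material card
#'
#' Human meshes use the region names `skull`, `face`, `neck`,
#' `subarachnoid`, `brain`; the human skull/brain resolve to the `_h`
#' cards when `species = "human"`.
#'
#' @param library a `material_library`
#' @param region region label
#' @param species `"woodpecker"` or `"human"`
#' @return a material card
#' @export
resolve_card <- function(library, region, species = "woodpecker") {
  key <- region
  if (species == "human" && region %in% c("skull", "brain"))
    key <- paste0(region, "_h")
  card <- library[[key]]
  if (is.null(card))
    stop("no material card for region '", region, "' (species ", species, ")")
  card
}

#' Shear relaxation modulus of a viscoelastic brain card
#'
#' Evaluates \eqn{\mu(t) = \mu_0[1 - \sum_i g_i(1 - e^{-t/\tau_i})]}.
#' Strictly decreasing in t, bounded below by the long-time modulus.
#'
#' @param card an `ogden_qlv_card`
#' @param t time, s (vectorised; `t >= 0`)
#' @return modulus, Pa
#' @export
shear_relaxation_modulus <- function(card, t) {
  stopifnot(inherits(card, "ogden_qlv_card"))
  if (any(t < 0)) stop("relaxation modulus requires t >= 0")
  vapply(t, function(ti)
    card$mu0 * (1 - sum(card$g * (1 - exp(-ti / card$tau)))), numeric(1))
}

#' Long-time (equilibrium) shear modulus
#'
#' The \eqn{t \to \infty} limit of the relaxation function,
#' \eqn{\mu_\infty = \mu_0 (1 - \sum_i g_i)}.
#'
#' @param card an `ogden_qlv_card`
#' @return modulus, Pa
#' @export
longterm_shear_modulus <- function(card) {
  stopifnot(inherits(card, "ogden_qlv_card"))
  gsum <- sum(card$g)
  if (gsum >= 1) stop("sum(g) >= 1: long-time modulus non-positive")
  card$mu0 * (1 - gsum)
}

# --- tensor helpers (2x2 in-plane, plane strain) ----------------------------

# eigen-decomposition of a symmetric 2x2 [a b; b c], closed form
sym2_eigen <- function(a, b, c) {
  tr <- a + c
  disc <- sqrt(((a - c) / 2)^2 + b^2)
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (abs(b) < 1e-300 * max(abs(a), abs(c), 1)) {
    if (a >= c) v1 <- c(1, 0) else v1 <- c(0, 1)
  } else {
    v1 <- c(l1 - c, b)
    v1 <- v1 / sqrt(sum(v1^2))
  }
  list(values = c(l1, l2), v1 = v1, v2 = c(-v1[2], v1[1]))
}

#' Instantaneous Ogden Cauchy stress (plane strain)
#'
#' Full finite-strain Cauchy stress of the one-term Ogden model at a given
#' in-plane deformation gradient, plane strain (\eqn{\lambda_3 = 1}),
#' including the elastic volumetric part `K (J - 1)`. Returns the 3x3
#' Cauchy stress (out-of-plane normal component included; out-of-plane
#' shears are zero).
#'
#' @param card an `ogden_qlv_card`
#' @param F 2x2 in-plane deformation gradient
#' @return 3x3 Cauchy stress, Pa
#' @export
ogden_stress <- function(card, F) {
  stopifnot(inherits(card, "ogden_qlv_card"), all(dim(F) == c(2, 2)))
  J <- F[1, 1] * F[2, 2] - F[1, 2] * F[2, 1]
  if (J <= 0) stop("non-positive Jacobian in Ogden stress evaluation")
  C <- t(F) %*% F
  eg <- sym2_eigen(C[1, 1], C[1, 2], C[2, 2])
  lam <- sqrt(pmax(eg$values, 0))          # in-plane principal stretches
  lam3 <- 1
  Jm13 <- J^(-1 / 3)
  lb <- c(lam * Jm13, lam3 * Jm13)         # deviatoric stretches
  a <- card$alpha
  pow <- lb^a
  dev <- (2 * card$mu0 / (a * J)) * (pow - mean(pow))
  # principal directions of C are Lagrangian; rotate to spatial via F
  # spatial principal directions: n_i = F N_i / lambda_i
  N1 <- eg$v1; N2 <- eg$v2
  n1 <- as.numeric(F %*% N1); n1 <- n1 / sqrt(sum(n1^2))
  n2 <- as.numeric(F %*% N2); n2 <- n2 / sqrt(sum(n2^2))
  Sdev2 <- dev[1] * (n1 %o% n1) + dev[2] * (n2 %o% n2)
  p <- card$K * (J - 1)
  S <- matrix(0, 3, 3)
  S[1:2, 1:2] <- Sdev2 + diag(p, 2)
  S[3, 3] <- dev[3] + p
  S
}

#' Finite-strain neo-Hookean Cauchy stress for elastic tissue cards
#'
#' Compressible neo-Hookean form whose small-strain limit reproduces
#' (E, nu): deviatoric part \eqn{(\mu/J)\,\mathrm{dev}(\bar B)}, volumetric
#' part \eqn{K(J-1)}. Plane strain; returns the 3x3 Cauchy stress.
#'
#' @param card an `elastic_card`
#' @param F 2x2 in-plane deformation gradient
#' @return 3x3 Cauchy stress, Pa
#' @export
neo_hookean_stress <- function(card, F) {
  stopifnot(inherits(card, "elastic_card"), all(dim(F) == c(2, 2)))
  J <- F[1, 1] * F[2, 2] - F[1, 2] * F[2, 1]
  if (J <= 0) stop("non-positive Jacobian in neo-Hookean stress evaluation")
  B <- F %*% t(F)
  Jm23 <- J^(-2 / 3)
  Bb <- matrix(0, 3, 3)
  Bb[1:2, 1:2] <- Jm23 * B
  Bb[3, 3] <- Jm23
  trBb <- Bb[1, 1] + Bb[2, 2] + Bb[3, 3]
  S <- (card$mu / J) * (Bb - diag(trBb / 3, 3))
  S + diag(card$K * (J - 1), 3)
}

#' Recursive quasilinear-viscoelastic stress update
#'
#' Hereditary-integral update of the deviatoric Ogden stress with the
#' Prony relaxation function, using the exponential recursion that is
#' exact for deviatoric stress varying linearly over a step:
#' \deqn{r_i^{n+1} = e^{-\Delta t/\tau_i} r_i^n +
#'   \frac{\tau_i}{\Delta t}(1 - e^{-\Delta t/\tau_i})\,(S^{n+1}-S^n)}
#' \deqn{\sigma_{dev} = (1-\textstyle\sum g_i) S^{n+1} + \sum_i g_i r_i^{n+1}}
#' The volumetric part is elastic and not relaxed. State is carried in the
#' unrotated (co-rotational) frame by the solver; at the pure material
#' level (this function) the frame is the caller's.
#'
#' @param card an `ogden_qlv_card`
#' @param S_new instantaneous deviatoric stress at the end of the step
#'   (any consistent tensor storage; here a numeric vector)
#' @param state list with `S_prev` and `r` (list over Prony terms), or
#'   `NULL` to initialise at zero deformation
#' @param dt time step, s (> 0)
#' @return list with `S_dev` (relaxed deviatoric stress) and `state`
#' @export
qlv_update <- function(card, S_new, state = NULL, dt) {
  stopifnot(inherits(card, "ogden_qlv_card"), dt > 0)
  n <- length(card$g)
  if (is.null(state))
    state <- list(S_prev = S_new * 0,
                  r = replicate(n, S_new * 0, simplify = FALSE))
  dS <- S_new - state$S_prev
  e <- exp(-dt / card$tau)
  fac <- (card$tau / dt) * (1 - e)
  r <- vector("list", n)
  acc <- (1 - sum(card$g)) * S_new
  for (i in seq_len(n)) {
    r[[i]] <- e[i] * state$r[[i]] + fac[i] * dS
    acc <- acc + card$g[i] * r[[i]]
  }
  list(S_dev = acc, state = list(S_prev = S_new, r = r))
}

#' Dilatational (P-) wave speed of a material card
#'
#' For elastic cards: \eqn{c_d = \sqrt{E(1-\nu) / ((1+\nu)(1-2\nu)\rho)}}.
#' For the brain card: computed from the instantaneous shear modulus and
#' the bulk modulus implied by `nu_eff`,
#' \eqn{c_d = \sqrt{(K + 4\mu_0/3)/\rho}}.
#'
#' @param card a material card
#' @return wave speed, m/s
#' @export
dilatational_wave_speed <- function(card) {
  if (inherits(card, "elastic_card")) {
    if (card$nu >= 0.5 - 1e-12) stop("nu -> 0.5: unbounded dilatational wave speed")
    sqrt(card$E * (1 - card$nu) / ((1 + card$nu) * (1 - 2 * card$nu) * card$rho))
  } else if (inherits(card, "ogden_qlv_card")) {
    sqrt((card$K + 4 * card$mu0 / 3) / card$rho)
  } else stop("unknown material card class")
}

#' Stable explicit time step of a mesh + material pairing
#'
#' `safety` times the minimum over elements of characteristic length over
#' dilatational wave speed. Characteristic length is element area divided
#' by the longest edge (a standard conservative choice for quads and
#' triangles).
#'
#' @param mesh a `mesh2d`
#' @param library a `material_library`
#' @param safety time-step safety factor in (0, 1]
#' @return stable time step, s
#' @export
stable_time_step <- function(mesh, library, safety = 1) {
  stopifnot(inherits(mesh, "mesh2d"), safety > 0, safety <= 1)
  ne <- n_elements(mesh)
  if (ne == 0) stop("empty mesh")
  len <- element_char_length(mesh)
  speeds <- vapply(unique(mesh$elem_region), function(rg)
    dilatational_wave_speed(resolve_card(library, rg, mesh$species)), numeric(1))
  names(speeds) <- unique(mesh$elem_region)
  safety * min(len / speeds[mesh$elem_region])
}

#' Build a material library from a configuration list
#'
#' Accepts a named list (typically a parsed YAML section) of material
#' card descriptions keyed by region name and returns a library usable
#' wherever [material_library()] is. Elastic cards need `rho`, `E`,
#' `nu`; viscoelastic brain cards need `rho`, `mu0`, `alpha`, `g`,
#' `tau` (and optionally `nu_eff`). Entries missing from the list fall
#' back to the packaged defaults, so a config may override a single
#' tissue.
#'
#' @param cards named list of card descriptions
#' @param base library supplying defaults for unlisted regions
#' @return a `material_library`
#' @export
material_library_from_config <- function(cards, base = material_library()) {
  out <- base
  for (nm in names(cards)) {
    cc <- cards[[nm]]
    out[[nm]] <- if (!is.null(cc$mu0)) {
      ogden_qlv_card(rho = cc$rho, mu0 = cc$mu0, alpha = cc$alpha,
                     g = unlist(cc$g), tau = unlist(cc$tau),
                     nu_eff = cc$nu_eff %||% 0.499)
    } else {
      elastic_card(rho = cc$rho, E = cc$E, nu = cc$nu)
    }
  }
  out
}
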