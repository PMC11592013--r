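#' Elastic constants for a bone phase
#'
#' Stores linear-elastic constants in the internal mm-N-s-tonne system.
#' Arguments are given in the units bone property tables print: GPa for the
#' modulus and g/cm^3 for density.
#'
#' @param E_gpa Young's modulus in GPa.
#' @param nu Poisson's ratio, in [0, 0.5).
#' @param rho_gcm3 mass density in g/cm^3.
#' @return an `oi_elastic` list with `E` (MPa), `nu`, `rho` (tonne/mm^3).
#' @export
elastic_constants <- function(E_gpa, nu, rho_gcm3) {
  stopifnot(E_gpa > 0, nu >= 0, nu < 0.5, rho_gcm3 > 0)
  structure(list(E = gpa_to_mpa(E_gpa), nu = nu, rho = gcm3_to_tmm3(rho_gcm3)),
            class = "oi_elastic")
}

#' Multilinear isotropic hardening curve
#'
#' Ordered (equivalent plastic strain, true stress) pairs. The curve must start
#' at zero plastic strain, be strictly increasing in strain and non-decreasing
#' in stress: softening enters only through the damage model, never through the
#' base curve. Beyond the last point the flow stress is held constant.
#'
#' @param eps_pl equivalent plastic strains (dimensionless), first must be 0.
#' @param sigma true stresses in MPa.
#' @return an `oi_hardening` object.
#' @export
hardening_curve <- function(eps_pl, sigma) {
  stopifnot(length(eps_pl) == length(sigma), length(eps_pl) >= 1)
  if (eps_pl[1] != 0) stop("hardening curve must start at eps_pl = 0")
  if (any(diff(eps_pl) <= 0)) stop("eps_pl must be strictly increasing")
  if (any(sigma <= 0)) stop("flow stress must be positive")
  if (any(diff(sigma) < 0)) stop("base hardening curve must be non-softening")
  structure(list(eps_pl = as.numeric(eps_pl), sigma = as.numeric(sigma)),
            class = "oi_hardening")
}

#' Cowper-Symonds strain-rate law
#'
#' Empirical rate hardening: the plastic strain rate and the dynamic
#' overstress factor R are linked by \eqn{\dot\varepsilon_{pl} = D (R-1)^n},
#' i.e. \eqn{R = 1 + (\dot\varepsilon_{pl}/D)^{1/n}}. The defaults are the
#' cortical-bone constants used throughout this package, D = 360.7 1/s and
#' n = 4.61. A disabled law always returns R = 1.
#'
#' @param D reference strain rate (1/s), > 0.
#' @param n rate exponent, > 0.
#' @param enabled logical; disabled laws are rate-independent.
#' @return an `oi_rate_law` object.
#' @export
rate_law <- function(D = 360.7, n = 4.61, enabled = TRUE) {
  stopifnot(D > 0, n > 0, is.logical(enabled))
  structure(list(D = D, n = n, enabled = enabled), class = "oi_rate_law")
}

#' Dynamic overstress factor R of a rate law
#'
#' @param law an [rate_law()] object.
#' @param eps_dot_pl equivalent plastic strain rate(s) in 1/s, >= 0.
#' @return R >= 1, vectorised over `eps_dot_pl`; exactly 1 when the law is
#'   disabled or the rate is zero.
#' @export
rate_factor <- function(law, eps_dot_pl) {
  if (any(eps_dot_pl < 0)) stop("negative strain rate")
  if (!law$enabled) return(rep(1, length(eps_dot_pl)))
  1 + (eps_dot_pl / law$D)^(1 / law$n)
}

#' Material card for one bone phase
#'
#' Bundles elasticity, hardening and rate dependence for either the cortical
#' or the trabecular phase. Trabecular bone is modelled rate-independent (its
#' failure is secondary to cortical failure), so trabecular cards must carry a
#' disabled rate law.
#'
#' @param name label.
#' @param elastic an [elastic_constants()] object.
#' @param hardening an [hardening_curve()] object.
#' @param rate a [rate_law()] object.
#' @param phase `"cortical"` or `"trabecular"`.
#' @return an `oi_material` object.
#' @export
material_card <- function(name, elastic, hardening, rate, phase) {
  phase <- match.arg(phase, c("cortical", "trabecular"))
  stopifnot(inherits(elastic, "oi_elastic"), inherits(hardening, "oi_hardening"),
            inherits(rate, "oi_rate_law"))
  if (phase == "trabecular" && rate$enabled)
    stop("trabecular cards must have the rate law disabled")
  structure(list(name = name, elastic = elastic, hardening = hardening,
                 rate = rate, phase = phase), class = "oi_material")
}

#' Default type II cortical bone card
#'
#' Elastic constants E = 13.7 GPa, nu = 0.3, rho = 2.12 g/cm^3 (Misch type II
#' cortical bone). The default hardening curve is a package calibration, not
#' tabulated literature data: quasi-static yield 110 MPa rising linearly to
#' 180 MPa at 2% plastic strain, flat beyond; the Cowper-Symonds law
#' (D = 360.7, n = 4.61) scales the whole curve.
#'
#' @param hardening optional replacement [hardening_curve()].
#' @export
cortical_card <- function(hardening = NULL) {
  if (is.null(hardening))
    hardening <- hardening_curve(c(0, 0.02), c(110, 180))
  material_card("cortical", elastic_constants(13.7, 0.3, 2.12),
                hardening, rate_law(360.7, 4.61, TRUE), "cortical")
}

#' Default type II trabecular (cancellous) bone card
#'
#' Elastic constants E = 5.5 GPa, nu = 0.3, rho = 2.12 g/cm^3. Default
#' hardening: 30 MPa yield, flat to 6% plastic strain (a package calibration).
#' Rate-independent by construction.
#'
#' @param hardening optional replacement [hardening_curve()].
#' @export
trabecular_card <- function(hardening = NULL) {
  if (is.null(hardening))
    hardening <- hardening_curve(c(0, 0.06), c(30, 30))
  material_card("trabecular", elastic_constants(5.5, 0.3, 2.12),
                hardening, rate_law(enabled = FALSE), "trabecular")
}

# internal: flatten a card for the C++ kernel
mat_to_kernel <- function(card) {
  list(E = card$elastic$E, nu = card$elastic$nu,
       hard_eps = card$hardening$eps_pl, hard_sig = card$hardening$sigma,
       cs_D = card$rate$D, cs_n = card$rate$n, cs_enabled = card$rate$enabled)
}

#' Rate-scaled flow stress
#'
#' Piecewise-linear interpolation of the hardening curve at `eps_pl` (clamped
#' at the last point), multiplied by the Cowper-Symonds factor at
#' `eps_dot_pl`. Trabecular cards return a rate-independent value.
#'
#' @param card a [material_card()].
#' @param eps_pl equivalent plastic strain(s), >= 0.
#' @param eps_dot_pl equivalent plastic strain rate(s) in 1/s.
#' @return flow stress in MPa.
#' @export
flow_stress <- function(card, eps_pl, eps_dot_pl = 0) {
  if (any(eps_pl < 0)) stop("negative plastic strain")
  h <- card$hardening
  if (length(h$eps_pl) == 0) stop("empty hardening curve")
  base <- if (length(h$eps_pl) == 1) rep(h$sigma, length(eps_pl)) else
    stats::approx(h$eps_pl, h$sigma, xout = pmin(eps_pl, max(h$eps_pl)),
                  rule = 2)$y
  base * rate_factor(card$rate, eps_dot_pl)
}

#' Incremental stress update (radial-return J2 plasticity)
#'
#' Integrates one strain increment: elastic trial, then radial return onto the
#' rate-scaled yield surface. The increment is given as a displacement-gradient
#' increment; its symmetric part is the strain increment and its skew part the
#' incremental spin, which rotates the stored stress (exact Rodrigues rotation,
#' so pure rigid rotations preserve the stress magnitude to round-off).
#'
#' @param card a [material_card()].
#' @param dgrad 3x3 displacement-increment gradient, or a symmetric 3x3 strain
#'   increment (then spin is zero).
#' @param state list with `stress` (Voigt 6-vector, order xx,yy,zz,xy,yz,xz,
#'   MPa) and `eps_pl`; defaults to a virgin state.
#' @param dt time increment in s, > 0 (sets the plastic strain rate seen by
#'   the rate law).
#' @return list with updated `stress`, `eps_pl`, `delta_eps_pl`, `eps_dot_pl`
#'   and the von Mises stress `q`.
#' @export
stress_update <- function(card, dgrad, state = NULL, dt = 1) {
  if (is.null(state)) state <- list(stress = numeric(6), eps_pl = 0)
  stopifnot(dt > 0)
  if (!all(is.finite(dgrad)) || !all(is.finite(state$stress)))
    stop("non-finite input to stress update")
  dgrad <- as.matrix(dgrad)
  stopifnot(identical(dim(dgrad), c(3L, 3L)))
  e <- 0.5 * (dgrad + t(dgrad))
  w <- 0.5 * (dgrad - t(dgrad))
  deps <- c(e[1, 1], e[2, 2], e[3, 3], e[1, 2], e[2, 3], e[1, 3])
  spin <- c(w[3, 2], w[1, 3], w[2, 1])
  cpp_point_stress_update(state$stress, state$eps_pl, deps, spin, dt,
                          mat_to_kernel(card))
}

#' Serialize / deserialize material cards
#'
#' Cards round-trip through a plain list (and hence YAML or JSON) using the
#' interface units: E in GPa, rho in g/cm^3.
#'
#' @param card a [material_card()].
#' @return `material_to_list`: a plain list; `material_from_list`: a card.
#' @export
material_to_list <- function(card) {
  list(name = card$name, phase = card$phase,
       E_GPa = mpa_to_gpa(card$elastic$E), nu = card$elastic$nu,
       rho_g_cm3 = tmm3_to_gcm3(card$elastic$rho),
       hardening = Map(c, card$hardening$eps_pl, card$hardening$sigma),
       cowper_symonds = list(D = card$rate$D, n = card$rate$n,
                             enabled = card$rate$enabled))
}

#' @rdname material_to_list
#' @param x a plain list as produced by `material_to_list` (e.g. from
#'   `yaml::read_yaml`).
#' @export
material_from_list <- function(x) {
  h <- do.call(rbind, lapply(x$hardening, as.numeric))
  material_card(x$name,
                elastic_constants(x$E_GPa, x$nu, x$rho_g_cm3),
                hardening_curve(h[, 1], h[, 2]),
                rate_law(x$cowper_symonds$D, x$cowper_symonds$n,
                         isTRUE(x$cowper_symonds$enabled)),
                x$phase)
}
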