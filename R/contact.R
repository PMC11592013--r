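# Skin-surrogate contact: exponential pressure-overclosure law against a
# rigid analytic cylinder, with regularised Coulomb friction.

#' Exponential pressure-overclosure contact law
#'
#' Transmits pressure before touching: the pressure rises exponentially from
#' 0 at clearance `c0` (the effective skin thickness) to `p0` at zero
#' clearance,
#' \deqn{p(c) = p_0 (e^{1 - c/c_0} - 1)/(e - 1), \quad 0 \le c < c_0,}
#' and continues linearly for penetration (c < 0) with the slope matched at
#' c = 0, keeping the contact stiffness bounded for the explicit integrator.
#'
#' @param c0 clearance (skin-surrogate thickness) in mm; default 1.5.
#' @param p0 pressure at zero clearance in N/mm^2; default 100.
#' @return an `oi_contact_law` object (the penetration slope in N/mm^3 is
#'   derived and stored).
#' @export
contact_law <- function(c0 = 1.5, p0 = 100) {
  stopifnot(c0 > 0, p0 > 0)
  slope <- p0 * exp(1) / ((exp(1) - 1) * c0)  # -dp/dc at c = 0
  structure(list(c0 = c0, p0 = p0, slope = slope), class = "oi_contact_law")
}

#' Contact pressure at a signed clearance
#'
#' @param law an [contact_law()].
#' @param clearance signed clearance(s) in mm (negative = penetration).
#' @return pressure(s) in N/mm^2; 0 for clearance >= c0, `p0` at 0,
#'   continuous and non-increasing in clearance.
#' @export
contact_pressure <- function(law, clearance) {
  p <- numeric(length(clearance))
  mid <- clearance >= 0 & clearance < law$c0
  p[mid] <- law$p0 * (exp(1 - clearance[mid] / law$c0) - 1) / (exp(1) - 1)
  pen <- clearance < 0
  p[pen] <- law$p0 - law$slope * clearance[pen]
  p
}

#' Contact potential energy density
#'
#' The energy per unit area stored in the (elastic) overclosure law at
#' clearance `c`: the integral of the pressure from `c` up to `c0`. Used by
#' the energy ledger.
#'
#' @param law an [contact_law()].
#' @param clearance signed clearance(s) in mm.
#' @return energy per area in mJ/mm^2.
#' @export
contact_potential <- function(law, clearance) {
  e1 <- exp(1) - 1
  P0 <- law$p0 * law$c0 * (exp(1) - 2) / e1    # stored energy at c = 0
  out <- numeric(length(clearance))
  mid <- clearance >= 0 & clearance < law$c0
  cm <- clearance[mid]
  out[mid] <- law$p0 / e1 * (law$c0 * exp(1 - cm / law$c0) + cm - 2 * law$c0)
  pen <- clearance < 0
  cp <- clearance[pen]
  out[pen] <- P0 - law$p0 * cp + 0.5 * law$slope * cp^2
  out
}

#' Regularised Coulomb friction model
#'
#' Tangential traction opposes relative sliding, capped at `mu` times the
#' normal pressure; the cap is reached linearly over the regularisation
#' velocity, avoiding stick-slip chatter in explicit stepping.
#'
#' @param mu friction coefficient, >= 0 (default 0.2, impactor on bone).
#' @param v_reg regularisation slip velocity in mm/s.
#' @return an `oi_friction` object.
#' @export
friction_model <- function(mu = 0.2, v_reg = 1) {
  stopifnot(mu >= 0, v_reg > 0)
  structure(list(mu = mu, v_reg = v_reg), class = "oi_friction")
}

#' Signed clearance and outward normal of the rigid cylinder
#'
#' Distance from points to the finite cylinder's surface (lateral surface
#' with end-cap handling): positive outside, negative inside; the normal is
#' the outward unit vector at the nearest surface point.
#'
#' @param impactor an [make_impactor()] object.
#' @param points n x 3 matrix of coordinates (mm).
#' @return list with `clearance` (n) and `normal` (n x 3).
#' @export
cylinder_clearance <- function(impactor, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (!all(is.finite(points))) stop("non-finite point coordinates")
  cpp_cylinder_clearance(points, impactor$origin, impactor$axis,
                         impactor$half_len, impactor$radius)
}

#' Resolve contact between surface nodes and the rigid impactor
#'
#' Node-to-analytic-surface contact: each surface node carries a tributary
#' area; its normal force is `pressure(clearance) * area` along the outward
#' cylinder normal, and the tangential force is regularised Coulomb friction
#' against the relative slip velocity, capped at `mu` times the normal force.
#' The impactor receives the exact opposite resultant (action-reaction to
#' round-off).
#'
#' @param points n x 3 current surface-node coordinates (mm).
#' @param velocities n x 3 surface-node velocities (mm/s).
#' @param areas tributary areas (mm^2), > 0 where contact may act.
#' @param impactor an [make_impactor()] (its `velocity` is used for slip).
#' @param law an [contact_law()].
#' @param friction an [friction_model()].
#' @param dt time increment (s), used for the friction-dissipation estimate
#'   and the stick stability clamp.
#' @param masses optional nodal masses (tonne). When given (dynamic runs),
#'   the tangential force is additionally capped at the impulse that would
#'   cancel the node's relative slip in one step, which keeps sticking nodes
#'   stable in explicit integration instead of chattering.
#' @return list with `force` (n x 3, on the nodes), `reaction` (3, on the
#'   impactor), `normal_force` (n), `dissipation` (mJ, >= 0) and
#'   `potential` (mJ stored in the overclosure law).
#' @export
resolve_contact <- function(points, velocities, areas, impactor, law,
                            friction, dt = 0, masses = NULL) {
  if (any(areas < 0)) stop("negative tributary area")
  cc <- cylinder_clearance(impactor, points)
  p <- contact_pressure(law, cc$clearance)
  fn <- p * areas
  act <- fn > 0
  n <- nrow(points)
  force <- matrix(0, n, 3)
  diss <- 0
  if (any(act)) {
    nm <- cc$normal[act, , drop = FALSE]
    fa <- fn[act] * nm
    if (friction$mu > 0) {
      vrel <- velocities[act, , drop = FALSE] -
        matrix(impactor$velocity, sum(act), 3, byrow = TRUE)
      vn <- rowSums(vrel * nm)
      vt <- vrel - vn * nm
      sp <- sqrt(rowSums(vt^2))
      ft <- friction$mu * fn[act] * pmin(1, sp / friction$v_reg)
      if (!is.null(masses) && dt > 0)
        ft <- pmin(ft, 0.5 * masses[act] * sp / dt)
      nz <- sp > 1e-12
      if (any(nz)) {
        dirt <- vt[nz, , drop = FALSE] / sp[nz]
        fa[nz, ] <- fa[nz, , drop = FALSE] - ft[nz] * dirt
        diss <- sum(ft[nz] * sp[nz]) * dt
      }
    }
    force[act, ] <- fa
  }
  pot <- sum(areas * contact_potential(law, cc$clearance))
  list(force = force, reaction = -colSums(force), normal_force = fn,
       dissipation = diss, potential = pot)
}
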