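# Single-element verification rig: displacement-controlled uniaxial tests of
# a material/damage card pair at prescribed strain rate, with lateral strains
# iterated to a uniaxial stress state. Used to measure apparent moduli,
# rate-scaled flow curves, onset strains and the dissipated fracture energy.

#' Displacement-controlled uniaxial test of a material point
#'
#' Drives a material point (one element of characteristic length `L_e`) in
#' uniaxial stress: the axial strain grows at the prescribed total strain
#' rate while the lateral strain is iterated each step until the lateral
#' stress vanishes. Damage initiation and fracture-energy softening are
#' applied through the damage card; the reported stress is the degraded
#' (observable) stress.
#'
#' @param card a [material_card()].
#' @param damage a [damage_card()], or `NULL` for plain plasticity.
#' @param eps_max final axial strain.
#' @param n_steps number of strain increments.
#' @param rate total axial strain rate in 1/s; 0 means quasi-static.
#' @param L_e element characteristic length in mm.
#' @return an `oi_uniaxial` list: `data` (data.frame with strain, stress_MPa,
#'   eps_pl, omega, d), `dissipation_per_area` (mJ/mm^2 dissipated after
#'   damage initiation, the fracture-energy measure) and `state`.
#' @export
uniaxial_test <- function(card, damage = NULL, eps_max = 0.001,
                          n_steps = 200, rate = 0, L_e = 1) {
  stopifnot(eps_max > 0, n_steps >= 1, rate >= 0, L_e > 0)
  de <- eps_max / n_steps
  dt <- if (rate > 0) de / rate else 1e9
  st <- list(stress = numeric(6), eps_pl = 0)
  ds <- damage_state(L_e)
  out <- data.frame(strain = numeric(n_steps + 1), stress_MPa = 0,
                    eps_pl = 0, omega = 0, d = 0)
  dissip <- 0
  dl_lat <- 0     # warm start for the lateral iteration
  for (i in seq_len(n_steps)) {
    # solve for the lateral strain increment that keeps sigma_lat = 0
    trial <- function(dlat) {
      g <- diag(c(de, dlat, dlat))
      stress_update(card, g, st, dt)
    }
    lo <- -de; hi <- de   # bracket for the lateral increment
    r <- trial(dl_lat)
    if (abs(r$stress[2]) > 1e-9 * card$elastic$E) {
      flo <- trial(lo)$stress[2]
      for (it in 1:60) {
        mid <- 0.5 * (lo + hi)
        fm <- trial(mid)$stress[2]
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      }
      dl_lat <- 0.5 * (lo + hi)
      r <- trial(dl_lat)
    }
    dpl <- r$delta_eps_pl
    st <- list(stress = r$stress, eps_pl = r$eps_pl)
    if (!is.null(damage) && isTRUE(damage$enabled) && dpl > 0 &&
        !ds$deleted) {
      d_old <- ds$d
      ds <- accumulate_initiation(ds, dpl, r$eps_dot_pl, damage,
                                  flow_stress_now = r$q)
      if (ds$omega >= 1) {
        ds <- evolve_damage(ds, dpl, damage$G)
        dmid <- 0.5 * (d_old + ds$d)
        dissip <- dissip + (1 - dmid) * r$q * dpl * L_e
        if (ds$d >= damage$deletion_threshold) ds$deleted <- TRUE
      }
    }
    obs <- apply_damage(st$stress, ds$d)
    if (ds$deleted) obs <- obs * 0
    out[i + 1, ] <- list(i * de, obs[1], st$eps_pl, ds$omega, ds$d)
  }
  structure(list(data = out, dissipation_per_area = dissip, state = st,
                 damage_state = ds), class = "oi_uniaxial")
}

#' Apparent Young's modulus from a single-element tension test
#'
#' Runs the displacement-controlled uniaxial rig far below yield and returns
#' the axial stress/strain slope in GPa.
#'
#' @param card a [material_card()].
#' @param strain probe strain (well below yield).
#' @export
apparent_modulus <- function(card, strain = 5e-5) {
  r <- uniaxial_test(card, damage = NULL, eps_max = strain, n_steps = 10)
  mpa_to_gpa(r$data$stress_MPa[nrow(r$data)] / strain)
}

#' Measure the damage-onset strain at a prescribed plastic strain rate
#'
#' Feeds constant-rate plastic strain increments to the initiation
#' accumulator and reports the equivalent plastic strain at which the
#' initiation measure crosses 1 (linear interpolation over the crossing
#' step, exact for a constant rate).
#'
#' @param damage a [damage_card()].
#' @param rate plastic strain rate in 1/s.
#' @param n_steps number of increments to resolve the crossing.
#' @export
measure_onset_strain <- function(damage, rate, n_steps = 400) {
  guess <- onset_strain(damage, rate)
  de <- 1.5 * guess / n_steps
  ds <- damage_state(1)
  eps <- 0
  for (i in seq_len(2 * n_steps)) {
    om0 <- ds$omega
    ds <- accumulate_initiation(ds, de, rate, damage, flow_stress_now = 1)
    eps <- eps + de
    if (ds$omega >= 1)
      return(eps - de + de * (1 - om0) / (ds$omega - om0))
  }
  NA_real_
}
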