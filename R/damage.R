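#' Ductile damage card
#'
#' Parameters for damage initiation and evolution of the cortical phase, plus
#' the trabecular strain cap. Initiation uses a rate-dependent onset-strain
#' table (equivalent plastic strain at the onset of damage vs. plastic strain
#' rate, at a single stress triaxiality); evolution dissipates a prescribed
#' fracture energy per unit cracked area through linear displacement-based
#' softening; elements are removed at a damage threshold.
#'
#' The default onset table is the type II cortical bone calibration used
#' throughout the package: onset strain 0.02 quasi-statically, falling to
#' 0.0024 at 1000 1/s, all at triaxiality 0.33 (uniaxial tension). The default
#' fracture energy is G = 1.54 mJ/mm^2. The trabecular phase is deleted at
#' twice the ~3% cortical failure strain, i.e. at 6% plastic strain.
#'
#' @param onset_table data.frame with columns `eps_onset`, `triaxiality`,
#'   `rate` (1/s), ordered by rate.
#' @param G fracture energy in mJ/mm^2, > 0.
#' @param trabecular_cap plastic strain at which trabecular elements are
#'   deleted (rate-independent).
#' @param deletion_threshold damage level d at which an element is removed;
#'   slightly below 1 to avoid a zero-stiffness singular tail.
#' @param rate_smoothing exponential smoothing factor applied to the per-step
#'   plastic strain rate before the onset-table lookup (1/steps).
#' @param enabled logical; a disabled card turns all damage off.
#' @return an `oi_damage_card` object.
#' @export
damage_card <- function(onset_table = default_onset_table(), G = 1.54,
                        trabecular_cap = 0.06, deletion_threshold = 0.99,
                        rate_smoothing = 0.1, enabled = TRUE) {
  stopifnot(is.data.frame(onset_table),
            all(c("eps_onset", "triaxiality", "rate") %in% names(onset_table)),
            nrow(onset_table) >= 1, G > 0, trabecular_cap > 0,
            deletion_threshold > 0, deletion_threshold <= 1)
  if (any(onset_table$eps_onset <= 0)) stop("onset strains must be positive")
  if (any(diff(onset_table$rate) <= 0)) stop("rates must be increasing")
  if (any(diff(onset_table$eps_onset) > 0))
    stop("onset strain must be non-increasing with rate")
  if (length(unique(onset_table$triaxiality)) != 1)
    stop("a single triaxiality value is supported")
  structure(list(onset_table = onset_table, G = G,
                 trabecular_cap = trabecular_cap,
                 deletion_threshold = deletion_threshold,
                 rate_smoothing = rate_smoothing, enabled = enabled),
            class = "oi_damage_card")
}

#' Default rate-dependent onset-strain table
#'
#' Onset equivalent plastic strain vs. plastic strain rate for type II
#' cortical bone at triaxiality 0.33 (uniaxial tension).
#' @export
default_onset_table <- function() {
  data.frame(
    eps_onset   = c(0.02, 0.02, 0.0175, 0.0149, 0.0123, 0.0072, 0.0024),
    triaxiality = 0.33,
    rate        = c(0, 0.01, 0.1, 1, 10, 100, 1000))
}

# internal: flatten for the C++ kernel
damage_to_kernel <- function(card) {
  list(table_rate = card$onset_table$rate, table_eps = card$onset_table$eps_onset,
       G = card$G, trabecular_cap = card$trabecular_cap,
       deletion_threshold = card$deletion_threshold,
       rate_smoothing = card$rate_smoothing, enabled = card$enabled)
}

#' Onset strain at a given plastic strain rate
#'
#' Piecewise-linear in log10(rate) between tabulated rates, clamped at both
#' ends; rates at or below the first nonzero tabulated rate return the
#' quasi-static value.
#'
#' @param card a [damage_card()].
#' @param eps_dot_pl plastic strain rate(s) in 1/s, >= 0.
#' @return onset equivalent plastic strain(s).
#' @export
onset_strain <- function(card, eps_dot_pl) {
  if (nrow(card$onset_table) == 0) stop("empty onset table")
  if (any(eps_dot_pl < 0)) stop("negative strain rate")
  vapply(eps_dot_pl, function(r)
    cpp_onset_strain(card$onset_table$rate, card$onset_table$eps_onset, r),
    numeric(1))
}

#' Fresh per-element damage state
#'
#' @param L_e element characteristic length in mm.
#' @return an `oi_damage_state` list with the initiation measure `omega`
#'   (the DUCTCRIT analogue), damage `d`, effective plastic displacement
#'   `u_pl` (mm), `sigma_y0_at_onset` (MPa), `deleted` flag and `L_e`.
#' @export
damage_state <- function(L_e = 1) {
  stopifnot(L_e > 0)
  structure(list(omega = 0, d = 0, u_pl = 0, sigma_y0_at_onset = 0,
                 deleted = FALSE, L_e = L_e), class = "oi_damage_state")
}

#' Accumulate the damage-initiation measure
#'
#' Adds `delta_eps_pl / onset_strain(rate)` to omega. Initiation is declared
#' when omega reaches 1; at that moment the current flow stress is recorded as
#' the softening anchor `sigma_y0_at_onset`.
#'
#' @param state an [damage_state()].
#' @param delta_eps_pl plastic strain increment, >= 0.
#' @param eps_dot_pl plastic strain rate in 1/s.
#' @param card a [damage_card()].
#' @param flow_stress_now current flow stress in MPa; required at the step
#'   where initiation occurs.
#' @return updated state.
#' @export
accumulate_initiation <- function(state, delta_eps_pl, eps_dot_pl, card,
                                  flow_stress_now = NULL) {
  stopifnot(delta_eps_pl >= 0)
  state$omega <- state$omega + delta_eps_pl / onset_strain(card, eps_dot_pl)
  if (state$omega >= 1 && state$sigma_y0_at_onset <= 0) {
    if (is.null(flow_stress_now))
      stop("flow_stress_now needed at the initiation step")
    state$sigma_y0_at_onset <- flow_stress_now
  }
  state
}

#' Evolve damage after initiation (fracture-energy softening)
#'
#' Linear softening in effective plastic displacement: `u_pl` grows by
#' `L_e * delta_eps_pl` and `d = min(1, u_pl / u_f)` with
#' `u_f = 2 G / sigma_y0_at_onset`, so that the stress-displacement triangle
#' dissipates exactly G per unit cracked area regardless of element size.
#'
#' @param state an initiated [damage_state()] (omega >= 1).
#' @param delta_eps_pl plastic strain increment, >= 0.
#' @param G fracture energy in mJ/mm^2.
#' @return updated state (damage is non-decreasing).
#' @export
evolve_damage <- function(state, delta_eps_pl, G) {
  stopifnot(delta_eps_pl >= 0, G > 0)
  if (state$omega < 1) stop("damage evolution before initiation")
  if (state$sigma_y0_at_onset <= 0) stop("invalid sigma_y0_at_onset")
  state$u_pl <- state$u_pl + state$L_e * delta_eps_pl
  u_f <- 2 * G / state$sigma_y0_at_onset
  state$d <- max(state$d, min(1, state$u_pl / u_f))
  state
}

#' Degrade a stress by the damage variable
#'
#' @param stress stress tensor (any numeric array) in MPa.
#' @param d damage in [0, 1].
#' @return `(1 - d) * stress`.
#' @export
apply_damage <- function(stress, d) {
  if (d < 0 || d > 1) stop("damage outside [0, 1]")
  (1 - d) * stress
}

#' Trabecular strain-cap failure check
#'
#' Trabecular elements are deleted when the equivalent plastic strain reaches
#' the cap (default 6%, twice the cortical failure strain); rate-independent.
#'
#' @param card a [damage_card()].
#' @param eps_pl equivalent plastic strain.
#' @param phase element phase; only `"trabecular"` is admissible.
#' @return logical deletion decision.
#' @export
trabecular_failure <- function(card, eps_pl, phase = "trabecular") {
  if (phase != "trabecular")
    stop("strain-cap failure applies to trabecular elements only")
  eps_pl >= card$trabecular_cap
}

#' Serialize / deserialize a damage card
#' @param card a [damage_card()].
#' @export
damage_to_list <- function(card) {
  list(onset_table = Map(c, card$onset_table$eps_onset,
                         card$onset_table$triaxiality, card$onset_table$rate),
       G_mJ_per_mm2 = card$G, trabecular_cap = card$trabecular_cap,
       deletion_threshold = card$deletion_threshold,
       rate_smoothing = card$rate_smoothing, enabled = card$enabled)
}

#' @rdname damage_to_list
#' @param x a plain list as produced by `damage_to_list`.
#' @export
damage_from_list <- function(x) {
  m <- do.call(rbind, lapply(x$onset_table, as.numeric))
  damage_card(data.frame(eps_onset = m[, 1], triaxiality = m[, 2],
                         rate = m[, 3]),
              G = x$G_mJ_per_mm2, trabecular_cap = x$trabecular_cap,
              deletion_threshold = x$deletion_threshold,
              rate_smoothing = x$rate_smoothing, enabled = isTRUE(x$enabled))
}
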