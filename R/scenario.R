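# Impact-scenario orchestration: explicit central-difference run of a
# deformable bone mesh struck by the rigid impactor, with energy ledger,
# force history, field snapshots and a fracture report.

#' Define an impact scenario
#'
#' @param mesh an [oi_mesh()] with a `fixed` node set (or `fixed_set = NULL`
#'   for a free body) and boundary surfaces.
#' @param impactor an [make_impactor()].
#' @param materials list with `cortical` and `trabecular` cards.
#' @param damage a [damage_card()].
#' @param law an [contact_law()].
#' @param friction an [friction_model()].
#' @param duration simulated time in s.
#' @param dt_target mass-scaling floor for the stable time increment (s):
#'   elements whose CFL limit is below this are mass-scaled up to it.
#' @param output_interval force/energy sampling interval (s).
#' @param snapshot_interval field snapshot interval (s).
#' @param mass_budget admissible added-mass fraction.
#' @param fixed_set name of the fixed node set, or `NULL`.
#' @return an `oi_scenario` object.
#' @export
impact_scenario <- function(mesh, impactor, materials = default_materials(),
                            damage = damage_card(), law = contact_law(),
                            friction = friction_model(),
                            duration = 0.02, dt_target = 1e-7,
                            output_interval = 1e-5,
                            snapshot_interval = 1e-3,
                            mass_budget = 0.01, fixed_set = "fixed") {
  stopifnot(duration > 0, dt_target > 0, output_interval > 0,
            mass_budget > 0, mass_budget <= 1)
  structure(list(mesh = mesh, impactor = impactor, materials = materials,
                 damage = damage, law = law, friction = friction,
                 duration = duration, dt_target = dt_target,
                 output_interval = output_interval,
                 snapshot_interval = snapshot_interval,
                 mass_budget = mass_budget, fixed_set = fixed_set),
            class = "oi_scenario")
}

#' Default cortical + trabecular material pair
#' @export
default_materials <- function() {
  list(cortical = cortical_card(), trabecular = trabecular_card())
}

#' The calibrated default impact scenario
#'
#' A 48 x 16 mm sandwich strip (1.5 mm cortical skins over a 1 mm trabecular
#' core, ~1.1 mm elements, ~2000 hexahedra) bridging a 28 mm cavity between
#' rigidly held abutments, struck at mid-span by the 200 mm x 40 mm diameter,
#' 2 kg cylinder. The cavity emulates thin facial bone spanning an air space
#' (the sinus) between buttresses; the abutments give the impactor something
#' to bear on once the span fails, as the surrounding face does. Calibrated
#' so that, with the fixed bone and contact parameters, a 5 km/h impact
#' produces local damage in the impact zone (crushed trabecular core,
#' cortical plasticity) without any through-thickness fracture path, impacts
#' at 15-20 km/h punch a through-thickness crush fracture under the
#' impactor, and peak filtered force and failed volume grow monotonically
#' with speed. A 5 ms impact runs in a few minutes on one CPU (use ~6 ms at
#' 5 km/h: momentum transfer is slower); pass `duration = 0.02` for a
#' full-length run.
#'
#' @param speed_kmh impact speed in km/h.
#' @param duration simulated time in s.
#' @param ... forwarded to [impact_scenario()].
#' @export
default_plate_scenario <- function(speed_kmh, duration = 5e-3, ...) {
  mesh <- make_layered_plate(plate_spec(
    span = 48, width = 16, cortical_thickness = 1.5, core_thickness = 1,
    elem_size = 1.1, support = "abutments", abutment_width = 10))
  ztop <- max(mesh$nodes[, 3])
  imp <- make_impactor(speed_kmh = speed_kmh, aim = c(0, 0, ztop))
  impact_scenario(mesh, imp, duration = duration, ...)
}

#' A slender-strut low-speed damage-initiation scenario
#'
#' A 100 x 8 mm two-edge-clamped sandwich strut (1.5 mm skins, 1 mm core).
#' In this slender, unbacked limit the structure escapes the load-spreading
#' skin surrogate by bending, and deep plastic hinges drive the cortical
#' ductile-initiation measure past 1 already at 5 km/h with no element
#' deleted -- the initiation-without-fracture regime. Used for low-speed
#' damage-initiation studies; the backed default scenario
#' ([default_plate_scenario()]) is the one with speed-monotone transmitted
#' force.
#'
#' @param speed_kmh impact speed in km/h.
#' @param duration simulated time in s (low speeds need ~8 ms).
#' @param ... forwarded to [impact_scenario()].
#' @export
strut_scenario <- function(speed_kmh, duration = 8e-3, ...) {
  mesh <- make_layered_plate(plate_spec(
    span = 100, width = 8, cortical_thickness = 1.5, core_thickness = 1,
    elem_size = 1, support = "two_edges"))
  ztop <- max(mesh$nodes[, 3])
  imp <- make_impactor(speed_kmh = speed_kmh, aim = c(0, 0, ztop))
  impact_scenario(mesh, imp, duration = duration, ...)
}

#' Run an impact scenario
#'
#' Explicit central-difference (leapfrog) integration: lumped mass with
#' selective mass scaling, incremental elastoplastic-damage internal forces,
#' node-to-cylinder contact through the pressure-overclosure law, a
#' free-flying rigid impactor, and an energy ledger closed at every output
#' frame. Deterministic for a given scenario. A divergence detector (kinetic
#' energy growing more than tenfold over 100 steps beyond the initial energy)
#' aborts the run, returning the history up to the last valid frame with a
#' warning.
#'
#' @param scn an [impact_scenario()].
#' @param verbose print progress.
#' @return an `oi_result` list: `history` (data.frame), `snapshots`,
#'   `fracture` ([extract_fracture_lines()] report), `model` (final state),
#'   `mass_report`, `dt`, `diverged`.
#' @export
run_scenario <- function(scn, verbose = FALSE) {
  mesh <- scn$mesh
  mats <- scn$materials
  n <- nrow(mesh$nodes)
  E <- length(mesh$nen)

  ms <- mass_scale(mesh, mats, scn$dt_target, scn$mass_budget)
  sd <- stable_dt(mesh, mats, safety_factor = 0.9, density_scale = ms$factor)
  dt <- sd$dt
  mass <- ms$masses

  model <- fem_model(mesh, mats, scn$damage)
  imp <- scn$impactor
  law <- scn$law
  fric <- scn$friction

  fixed <- if (is.null(scn$fixed_set)) integer(0) else
    mesh$node_sets[[scn$fixed_set]]

  ft <- mesh_face_table(mesh)
  fareas <- face_areas(mesh$nodes, ft)
  alive <- rep(TRUE, E)
  node_area <- surface_node_areas(mesh, ft, fareas, alive)
  snodes <- which(node_area > 0)

  disp <- matrix(0, n, 3)
  vh <- matrix(0, n, 3)          # half-step velocities
  x_imp <- imp$origin
  v_imp <- imp$velocity
  ke0_imp <- 0.5 * imp$mass * sum(v_imp^2)

  nsteps <- ceiling(scn$duration / dt)
  out_every <- max(1L, round(scn$output_interval / dt))
  snap_every <- max(1L, round(scn$snapshot_interval / dt))
  nrec <- floor(nsteps / out_every) + 1L

  hist <- data.frame(time_s = numeric(nrec), force_N = 0, force_axial_N = 0,
                     impactor_speed_mms = 0, ke_mesh = 0, ke_impactor = 0,
                     internal = 0, plastic = 0, damage_diss = 0,
                     friction_diss = 0, contact_pot = 0, erosion_diss = 0,
                     balance_resid = 0, n_deleted = 0)
  snapshots <- list()
  W_int <- W_pl <- W_dam <- W_fr <- W_eros <- 0
  # nodes exposed later by erosion arm for contact only once they are outside
  # the impactor, so no overclosure energy is injected from nothing
  armed <- rep(FALSE, n)
  armed[snodes] <- TRUE
  rec <- 0L
  ke_window <- 0
  diverged <- FALSE
  last_contact <- list(reaction = c(0, 0, 0), potential = 0)

  gp_elem <- rep(seq_len(E), model$pre$ngp)   # gp -> element map

  a_last <- matrix(0, n, 3)
  a_imp_last <- c(0, 0, 0)
  record <- function(step, reaction, pot) {
    rec <<- rec + 1L
    # time-centred velocities (leapfrog stores them at half steps)
    vc <- vh - a_last * (dt / 2)
    vi <- v_imp - a_imp_last * (dt / 2)
    ke_m <- 0.5 * sum(mass * rowSums(vc^2))
    ke_i <- 0.5 * imp$mass * sum(vi^2)
    resid <- ke_m + ke_i + W_int + W_fr + W_eros + pot - ke0_imp
    hist[rec, ] <<- list(step * dt, sqrt(sum(reaction^2)),
                         -sum(reaction * imp$approach),
                         sqrt(sum(vi^2)), ke_m, ke_i, W_int, W_pl, W_dam,
                         W_fr, pot, W_eros, resid, sum(!alive))
  }
  take_snapshot <- function(step) {
    sv <- matrix(model$stress, nrow = 6)
    vm_gp <- von_mises(t(sv))
    vm_el <- as.numeric(tapply(vm_gp, gp_elem, mean)) * (1 - model$dmg)
    vm_el[!alive] <- 0
    snapshots[[length(snapshots) + 1L]] <<- list(
      time_s = step * dt, displacement = disp + 0,
      von_mises_MPa = vm_el, ductcrit = model$omega + 0,
      damage = model$dmg + 0, deleted = as.integer(model$deleted),
      eps_pl = as.numeric(tapply(model$eps_pl, gp_elem, mean)))
  }

  record(0L, c(0, 0, 0), 0)
  take_snapshot(0L)

  for (step in seq_len(nsteps)) {
    du <- vh * dt
    disp <- disp + du
    x_imp <- x_imp + v_imp * dt
    imp$origin <- x_imp
    imp$velocity <- v_imp

    res <- internal_forces(model, du, dt)
    if (length(res$newly_deleted)) {
      pot_of <- function(ids, areas) {
        if (!length(ids)) return(0)
        p <- mesh$nodes[ids, , drop = FALSE] + disp[ids, , drop = FALSE]
        cl <- cylinder_clearance(imp, p)$clearance
        sum(areas[ids] * contact_potential(law, cl))
      }
      old_ids <- snodes[armed[snodes]]
      pot_old <- pot_of(old_ids, node_area)
      alive[res$newly_deleted] <- FALSE
      old_surface <- snodes
      node_area <- surface_node_areas(mesh, ft, fareas, alive)
      snodes <- which(node_area > 0)
      armed[setdiff(snodes, old_surface)] <- FALSE
      # the overclosure energy stored against eroded surface is destroyed
      W_eros <- W_eros + pot_old - pot_of(snodes[armed[snodes]], node_area)
    }
    W_int <- W_int + res$dW_int
    W_pl <- W_pl + res$dW_plastic
    W_dam <- W_dam + res$dW_damage

    disarmed <- snodes[!armed[snodes]]
    if (length(disarmed)) {
      p <- mesh$nodes[disarmed, , drop = FALSE] +
        disp[disarmed, , drop = FALSE]
      cl <- cylinder_clearance(imp, p)$clearance
      armed[disarmed[cl >= 0]] <- TRUE
    }
    sa <- snodes[armed[snodes]]
    pts <- mesh$nodes[sa, , drop = FALSE] + disp[sa, , drop = FALSE]
    ct <- resolve_contact(pts, vh[sa, , drop = FALSE], node_area[sa],
                          imp, law, fric, dt, masses = mass[sa])
    W_fr <- W_fr + ct$dissipation
    f <- -res$force
    f[sa, ] <- f[sa, ] + ct$force

    a <- f / mass
    if (length(fixed)) a[fixed, ] <- 0
    vh <- vh + a * dt
    if (length(fixed)) vh[fixed, ] <- 0
    a_imp <- ct$reaction / imp$mass
    v_imp <- v_imp + a_imp * dt
    a_last <- a
    a_imp_last <- a_imp
    last_contact <- ct

    if (step %% out_every == 0L) record(step, ct$reaction, ct$potential)
    if (step %% snap_every == 0L || step == nsteps) take_snapshot(step)

    if (step %% 100L == 0L) {
      ke_now <- 0.5 * sum(mass * rowSums(vh^2))
      if (ke_now > 10 * max(ke_window, 1e-12) &&
          ke_now > 2 * max(ke0_imp, 1e-9)) {
        warning(sprintf(
          "divergence detected at t = %.3e s (kinetic energy %.3e mJ); aborting",
          step * dt, ke_now))
        diverged <- TRUE
        break
      }
      ke_window <- ke_now
    }
  }

  hist <- hist[seq_len(rec), , drop = FALSE]
  hist$force_N_cfc180 <- sae_filter(hist$force_N,
                                    fs = 1 / scn$output_interval, cfc = 180)
  frac <- extract_fracture_lines(mesh, deleted = !alive, omega = model$omega,
                                 impactor = scn$impactor)
  structure(list(history = hist, snapshots = snapshots, fracture = frac,
                 model = model, mass_report = ms[c("scaled",
                                                   "added_mass_fraction")],
                 dt = dt, diverged = diverged,
                 final = list(displacement = disp, velocity = vh,
                              nodal_mass = mass,
                              impactor_velocity = v_imp,
                              impactor_position = x_imp),
                 scenario = scn), class = "oi_result")
}

#' @export
print.oi_result <- function(x, ...) {
  cat(sprintf(
    "<oi_result> %d frames, dt = %.3g s, peak force %.1f N (%.1f kgf), %d deleted\n",
    nrow(x$history), x$dt, max(x$history$force_N),
    n_to_kgf(max(x$history$force_N)), max(x$history$n_deleted)))
  invisible(x)
}
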