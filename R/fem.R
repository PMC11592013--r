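# Explicit solid-dynamics building blocks: lumped mass, stable time step,
# selective mass scaling, incremental internal forces, modal verification.

#' Lumped (row-sum) nodal masses
#'
#' Volume-weighted row-sum lumping of the consistent mass; the total equals
#' the exact integral of density over the mesh.
#'
#' @param mesh an [oi_mesh()].
#' @param materials list with `cortical` and `trabecular` [material_card()]s.
#' @param density_scale optional per-element mass-scaling factors (>= 1).
#' @return nodal masses in tonne (length = number of nodes).
#' @export
lumped_mass <- function(mesh, materials, density_scale = NULL) {
  rho <- elem_density(mesh, materials)
  if (!is.null(density_scale)) rho <- rho * density_scale
  pre <- mesh_precompute(mesh)
  cpp_lumped_mass(pre, mesh$conn, mesh$nen, rho, nrow(mesh$nodes))
}

#' Per-element and global stable time increments
#'
#' CFL estimate `L_e / c_d` with the dilatational wave speed
#' `c_d = sqrt(E (1 - nu) / ((1 + nu)(1 - 2 nu) rho))`. The global increment
#' applies the safety factor to the smallest element value.
#'
#' @param mesh an [oi_mesh()].
#' @param materials material list.
#' @param safety_factor multiplier on the CFL limit (default 0.9).
#' @param density_scale optional per-element mass-scaling factors.
#' @return list with `dt_elem` (s, per element), `dt` (s, global) and the
#'   wave speeds `c_d` (mm/s).
#' @export
stable_dt <- function(mesh, materials, safety_factor = 0.9,
                      density_scale = NULL) {
  rho <- elem_density(mesh, materials)
  if (!is.null(density_scale)) rho <- rho * density_scale
  E <- ifelse(mesh$phase == 1L, materials$cortical$elastic$E,
              materials$trabecular$elastic$E)
  nu <- ifelse(mesh$phase == 1L, materials$cortical$elastic$nu,
               materials$trabecular$elastic$nu)
  cd <- sqrt(E * (1 - nu) / ((1 + nu) * (1 - 2 * nu) * rho))
  Le <- mesh_precompute(mesh)$Lcfl
  dt_elem <- Le / cd
  list(dt_elem = dt_elem, dt = safety_factor * min(dt_elem), c_d = cd)
}

#' Selective mass scaling
#'
#' Elements whose stable increment falls below `dt_target` get their mass
#' multiplied by `(dt_target / dt_elem)^2` (the stable dt scales with the
#' square root of mass). Reports the affected elements and the added-mass
#' fraction, warning when it exceeds the budget (default 1% of model mass).
#'
#' @param mesh an [oi_mesh()].
#' @param materials material list.
#' @param dt_target desired stable time increment in s, > 0.
#' @param budget admissible added-mass fraction before a warning.
#' @return list with `factor` (per-element mass factors), `scaled` (element
#'   ids), `added_mass_fraction`, and `masses` (scaled lumped nodal masses).
#' @export
mass_scale <- function(mesh, materials, dt_target, budget = 0.01) {
  stopifnot(dt_target > 0)
  sd <- stable_dt(mesh, materials, safety_factor = 1)
  factor <- pmax(1, (dt_target / sd$dt_elem)^2)
  vol <- mesh_volumes(mesh)$vol
  rho <- elem_density(mesh, materials)
  m0 <- sum(vol * rho)
  added <- sum(vol * rho * (factor - 1)) / m0
  if (added > budget)
    warning(sprintf("mass scaling adds %.2f%% of model mass (budget %.2f%%)",
                    100 * added, 100 * budget))
  list(factor = factor, scaled = which(factor > 1),
       added_mass_fraction = added,
       masses = lumped_mass(mesh, materials, density_scale = factor))
}

#' Linear-elastic internal nodal forces
#'
#' Stateless small-strain assembly (mean-dilatation B-bar elements), used for
#' stiffness probing, modal analysis and as a verification surface. For the
#' full elastoplastic-damage path see [fem_model()] / [internal_forces()].
#'
#' @param mesh an [oi_mesh()].
#' @param materials material list.
#' @param disp N x 3 nodal displacement matrix (mm).
#' @return N x 3 nodal force matrix (N).
#' @export
elastic_internal_forces <- function(mesh, materials, disp) {
  pre <- mesh_precompute(mesh)
  E <- ifelse(mesh$phase == 1L, materials$cortical$elastic$E,
              materials$trabecular$elastic$E)
  nu <- ifelse(mesh$phase == 1L, materials$cortical$elastic$nu,
               materials$trabecular$elastic$nu)
  mu <- E / (2 * (1 + nu))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  cpp_elastic_forces(pre, mesh$conn, mesh$nen, as.matrix(disp), lam, mu)
}

#' Stateful finite-element model
#'
#' Bundles a mesh with its material and damage cards and the mutable solution
#' state (per-integration-point stress and plastic strain; per-element damage
#' variables and deletion flags). [internal_forces()] advances the state by
#' one displacement increment.
#'
#' @param mesh an [oi_mesh()].
#' @param materials list with `cortical` and `trabecular` cards.
#' @param damage a [damage_card()]; pass `damage_card(enabled = FALSE)` for
#'   plain plasticity.
#' @param elastic_only logical; skip plasticity and damage entirely.
#' @return an `oi_fem_model` environment.
#' @export
fem_model <- function(mesh, materials, damage = damage_card(),
                      elastic_only = FALSE) {
  m <- new.env(parent = emptyenv())
  m$mesh <- mesh
  m$pre <- mesh_precompute(mesh)
  m$materials <- materials
  m$damage <- damage
  m$mat_c <- mat_to_kernel(materials$cortical)
  m$mat_t <- mat_to_kernel(materials$trabecular)
  m$dam_k <- damage_to_kernel(damage)
  m$elastic_only <- elastic_only
  E <- length(mesh$nen)
  m$stress <- numeric(6 * m$pre$total_gp)
  m$eps_pl <- numeric(m$pre$total_gp)
  m$omega <- numeric(E)
  m$dmg <- numeric(E)
  m$u_pl <- numeric(E)
  m$sy0_onset <- numeric(E)
  m$rate_s <- numeric(E)
  m$deleted <- integer(E)
  class(m) <- "oi_fem_model"
  m
}

#' Incremental internal forces
#'
#' Advances every integration point by the displacement increment `du`
#' (radial-return plasticity with rate scaling, damage accumulation, element
#' deletion) and assembles nodal internal forces. Deleted elements contribute
#' nothing; the deletion flag never reverts.
#'
#' @param model an [fem_model()].
#' @param du N x 3 nodal displacement increment (mm).
#' @param dt time increment in s.
#' @return list with `force` (N x 3), energy increments `dW_int`,
#'   `dW_plastic`, `dW_damage` (mJ) and `newly_deleted` element ids.
#' @export
internal_forces <- function(model, du, dt = 1) {
  cpp_internal_forces_step(
    model$pre, model$mesh$conn, model$mesh$nen, model$mesh$phase,
    model$mat_c, model$mat_t, model$dam_k, as.matrix(du),
    nrow(model$mesh$nodes), dt,
    model$stress, model$eps_pl, model$omega, model$dmg, model$u_pl,
    model$sy0_onset, model$rate_s, model$deleted, model$elastic_only)
}

#' Natural frequencies of a (small) linear model
#'
#' Assembles the linear-elastic stiffness by probing [elastic_internal_forces()]
#' column by column (exact for a linear operator), pairs it with the lumped
#' mass, and solves the generalized symmetric eigenproblem densely. Intended
#' for verification-scale models (a few thousand DOF). An unconstrained model
#' reports its rigid-body modes as near-zero frequencies.
#'
#' @param mesh an [oi_mesh()].
#' @param materials material list.
#' @param fixed_set name of the fully fixed node set, or `NULL` for free-free.
#' @param k number of lowest frequencies to return.
#' @return frequencies in Hz, ascending.
#' @export
modal_frequencies <- function(mesh, materials, fixed_set = NULL, k = 6) {
  n <- nrow(mesh$nodes)
  fixed <- if (is.null(fixed_set)) integer(0) else mesh$node_sets[[fixed_set]]
  free_mask <- rep(TRUE, 3 * n)
  if (length(fixed)) free_mask[rep((fixed - 1) * 3, each = 3) + 1:3] <- FALSE
  free <- which(free_mask)
  nf <- length(free)
  if (nf > 6000) stop("modal analysis is meant for small verification models")
  pre <- mesh_precompute(mesh)
  E <- ifelse(mesh$phase == 1L, materials$cortical$elastic$E,
              materials$trabecular$elastic$E)
  nu <- ifelse(mesh$phase == 1L, materials$cortical$elastic$nu,
               materials$trabecular$elastic$nu)
  mu <- E / (2 * (1 + nu))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  K <- matrix(0, nf, nf)
  disp <- matrix(0, n, 3)
  for (j in seq_len(nf)) {
    dof <- free[j]
    disp[(dof - 1) %/% 3 + 1, (dof - 1) %% 3 + 1] <- 1
    f <- cpp_elastic_forces(pre, mesh$conn, mesh$nen, disp, lam, mu)
    K[, j] <- t(f)[free]                      # dof-major: (x,y,z) per node
    disp[(dof - 1) %/% 3 + 1, (dof - 1) %% 3 + 1] <- 0
  }
  K <- 0.5 * (K + t(K))
  mass <- lumped_mass(mesh, materials)
  mvec <- rep(mass, each = 3)[free]
  s <- 1 / sqrt(mvec)
  A <- K * tcrossprod(s)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  w2 <- sort(pmax(ev, 0))
  sqrt(w2[seq_len(min(k, nf))]) / (2 * pi)
}
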