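# Synthetic-geometry generator: parametric stand-ins for layered
# cortical/trabecular craniofacial bone (plates and arches), verification
# fixtures, and the rigid cylindrical impactor. All generation is
# deterministic given a spec; optional node jitter takes an explicit seed.

#' Specification of a layered bone plate
#'
#' A two-layer bone structure in the Misch type II sense: cortical skins
#' (1.5-2.0 mm thick) over a trabecular core, meshed with hexahedra near the
#' 1-1.5 mm element sizes typical of craniofacial impact models.
#'
#' @param span,width in-plane dimensions in mm.
#' @param cortical_thickness skin thickness in mm; must lie within
#'   `cortical_bounds`.
#' @param core_thickness trabecular core thickness in mm.
#' @param elem_size target element edge length in mm.
#' @param curvature_radius cylindrical bending radius in mm; `Inf` = flat.
#' @param support `"perimeter"` (all four side faces fixed), `"two_edges"`
#'   (the two faces normal to the span fixed), or `"abutments"` (the full
#'   volume within `abutment_width` of either span end held fixed -- a rigid
#'   socket the free span bridges, leaving a cavity under the centre).
#' @param abutment_width abutment depth in mm (only for
#'   `support = "abutments"`).
#' @param cortical_bounds admissible cortical thickness range (mm).
#' @param jitter relative node perturbation (fraction of `elem_size`); 0 by
#'   default. Interior nodes only; requires `jitter_seed`.
#' @param jitter_seed integer seed for the jitter.
#' @return an `oi_plate_spec` object.
#' @export
plate_spec <- function(span = 40, width = 40, cortical_thickness = 1.5,
                       core_thickness = 7, elem_size = 1.5,
                       curvature_radius = Inf,
                       support = c("perimeter", "two_edges", "abutments"),
                       abutment_width = 10,
                       cortical_bounds = c(1.5, 2.0),
                       jitter = 0, jitter_seed = 1L) {
  support <- match.arg(support)
  stopifnot(span > 0, width > 0, core_thickness > 0, elem_size > 0,
            curvature_radius > 0, jitter >= 0)
  if (support == "abutments")
    stopifnot(abutment_width > 0, abutment_width < span / 2)
  if (cortical_thickness < cortical_bounds[1] ||
      cortical_thickness > cortical_bounds[2])
    stop("cortical thickness outside the configured bounds [",
         cortical_bounds[1], ", ", cortical_bounds[2], "] mm")
  structure(list(span = span, width = width,
                 cortical_thickness = cortical_thickness,
                 core_thickness = core_thickness, elem_size = elem_size,
                 curvature_radius = curvature_radius, support = support,
                 abutment_width = abutment_width,
                 jitter = jitter, jitter_seed = as.integer(jitter_seed)),
            class = "oi_plate_spec")
}

# internal: structured hex grid of a sandwich block in [0,sx]x[0,sy] and
# stacked z layers; returns an oi_mesh with phase ids and standard sets.
sandwich_grid <- function(spec) {
  h <- spec$elem_size
  nx <- max(1L, round(spec$span / h))
  ny <- max(1L, round(spec$width / h))
  tc <- spec$cortical_thickness
  tt <- spec$core_thickness
  nzc <- max(1L, round(tc / h))
  nzt <- max(1L, round(tt / h))
  zc <- seq(0, tc, length.out = nzc + 1)
  zt <- tc + seq(0, tt, length.out = nzt + 1)[-1]
  z2 <- tc + tt + seq(0, tc, length.out = nzc + 1)[-1]
  zs <- c(zc, zt, z2)
  nz <- length(zs) - 1L
  layer_phase <- c(rep(1L, nzc), rep(2L, nzt), rep(1L, nzc))
  xs <- seq(0, spec$span, length.out = nx + 1)
  ys <- seq(0, spec$width, length.out = ny + 1)
  nid <- function(i, j, k)        # 1-based grid -> node index
    i + (nx + 1L) * ((j - 1L) + (ny + 1L) * (k - 1L))
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  colnames(nodes) <- NULL
  if (spec$jitter > 0) {
    set.seed(spec$jitter_seed)
    interior <- nodes[, 1] > 0 & nodes[, 1] < spec$span &
      nodes[, 2] > 0 & nodes[, 2] < spec$width &
      nodes[, 3] > 0 & nodes[, 3] < max(zs)
    nodes[interior, ] <- nodes[interior, ] +
      matrix(stats::runif(3 * sum(interior), -1, 1), ncol = 3) *
      spec$jitter * h
  }
  E <- nx * ny * nz
  conn <- matrix(0L, E, 8)
  phase <- integer(E)
  e <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    e <- e + 1L
    conn[e, ] <- c(nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k),
                   nid(i, j + 1L, k), nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                   nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
    phase[e] <- layer_phase[k]
  }
  ztop <- max(zs)
  idx <- seq_len(nrow(nodes))
  sets <- list(
    impact_face = idx[abs(nodes[, 3] - ztop) < 1e-9],
    back_face = idx[abs(nodes[, 3]) < 1e-9],
    edge_x0 = idx[abs(nodes[, 1]) < 1e-9],
    edge_x1 = idx[abs(nodes[, 1] - spec$span) < 1e-9],
    edge_y0 = idx[abs(nodes[, 2]) < 1e-9],
    edge_y1 = idx[abs(nodes[, 2] - spec$width) < 1e-9])
  sets$fixed <- switch(spec$support,
    perimeter = unique(c(sets$edge_x0, sets$edge_x1, sets$edge_y0,
                         sets$edge_y1)),
    two_edges = unique(c(sets$edge_x0, sets$edge_x1)),
    abutments = idx[nodes[, 1] <= spec$abutment_width + 1e-9 |
                      nodes[, 1] >= spec$span - spec$abutment_width - 1e-9])
  if (spec$support == "abutments") {
    sets$abutment_1 <- idx[nodes[, 1] <= spec$abutment_width + 1e-9]
    sets$abutment_2 <- idx[nodes[, 1] >= spec$span - spec$abutment_width - 1e-9]
  }
  list(nodes = nodes, conn = conn, nen = rep(8L, E), phase = phase,
       sets = sets, thickness = ztop)
}

#' Generate a layered cortical-trabecular plate mesh
#'
#' Conforming cortical/trabecular/cortical hexahedral sandwich, flat or bent
#' to a cylindrical radius, centred at the origin with the impact face on top
#' (z up at the centre). Provides `fixed` (supported edges), `impact_face`
#' and per-edge node sets.
#'
#' @param spec an [plate_spec()].
#' @return an [oi_mesh()].
#' @export
make_layered_plate <- function(spec) {
  g <- sandwich_grid(spec)
  nodes <- g$nodes
  # centre in-plane; thickness centred so the mid-surface passes through z = 0
  nodes[, 1] <- nodes[, 1] - spec$span / 2
  nodes[, 2] <- nodes[, 2] - spec$width / 2
  nodes[, 3] <- nodes[, 3] - g$thickness / 2
  if (is.finite(spec$curvature_radius)) {
    R <- spec$curvature_radius
    th <- nodes[, 1] / R
    r <- R + nodes[, 3]
    nodes <- cbind(r * sin(th), nodes[, 2], r * cos(th) - R)
  }
  oi_mesh(nodes, g$conn, g$nen, g$phase, g$sets)
}

#' Generate a synthetic zygoma-like arch
#'
#' A curved cortical-over-trabecular pillar spanning between two fixed
#' abutments, loaded laterally on its convex face: a structural stand-in for
#' the zygomatic arch bridging maxilla and temporal bone. Geometry is
#' synthetic (no anatomical drawing underlies it); the two-abutment support
#' and the curvature reproduce the bending-plus-crushing competition of the
#' real bone.
#'
#' @param span chord length between abutments (mm).
#' @param width arch width (mm).
#' @param cortical_thickness,core_thickness,elem_size as in [plate_spec()].
#' @param curvature_radius arch radius (mm).
#' @return an [oi_mesh()] with disjoint `abutment_1`/`abutment_2` sets, their
#'   union `fixed`, and an `impact_face` set on the convex face.
#' @export
make_zygoma_arch <- function(span = 50, width = 14, cortical_thickness = 1.5,
                             core_thickness = 6, elem_size = 1.4,
                             curvature_radius = 35) {
  spec <- plate_spec(span = span, width = width,
                     cortical_thickness = cortical_thickness,
                     core_thickness = core_thickness, elem_size = elem_size,
                     curvature_radius = curvature_radius,
                     support = "two_edges")
  m <- make_layered_plate(spec)
  m$node_sets$abutment_1 <- m$node_sets$edge_x0
  m$node_sets$abutment_2 <- m$node_sets$edge_x1
  m$node_sets$fixed <- unique(c(m$node_sets$abutment_1, m$node_sets$abutment_2))
  m
}

#' Single-element verification fixture
#'
#' One cubic hexahedron with face node sets for displacement-controlled
#' uniaxial and shear tests.
#'
#' @param phase `"cortical"` or `"trabecular"`.
#' @param size edge length in mm, > 0.
#' @return an [oi_mesh()] with sets `x0,x1,y0,y1,z0,z1`.
#' @export
make_single_element <- function(phase = "cortical", size = 1) {
  if (size <= 0) stop("element size must be positive")
  phase <- match.arg(phase, c("cortical", "trabecular"))
  nodes <- size * as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  colnames(nodes) <- NULL
  # grid order -> hex order (bottom ccw, then top)
  conn <- matrix(c(1L, 2L, 4L, 3L, 5L, 6L, 8L, 7L), 1)
  idx <- seq_len(8)
  sets <- list(x0 = idx[nodes[, 1] == 0], x1 = idx[nodes[, 1] == size],
               y0 = idx[nodes[, 2] == 0], y1 = idx[nodes[, 2] == size],
               z0 = idx[nodes[, 3] == 0], z1 = idx[nodes[, 3] == size])
  oi_mesh(nodes, conn, 8L, if (phase == "cortical") 1L else 2L, sets)
}

#' Build the rigid cylindrical impactor
#'
#' A steel cylinder (default 200 mm long, 40 mm diameter, 2 kg) approaching an
#' aim point at a given speed. The impactor is rigid and free-flying: it
#' carries the stated mass (an equivalent density is derived and reported)
#' and is decelerated only by the contact reaction.
#'
#' @param length cylinder length in mm.
#' @param diameter cylinder diameter in mm.
#' @param mass_kg mass in kg.
#' @param speed_kmh approach speed in km/h, >= 0.
#' @param aim aim point (mm) on the target surface.
#' @param approach unit approach direction (velocity direction).
#' @param axis cylinder axis direction (unit length enforced).
#' @param standoff initial gap between the cylinder surface and the aim point
#'   (mm); defaults to slightly more than the 1.5 mm skin-surrogate clearance
#'   so the history starts force-free.
#' @return an `oi_impactor` object.
#' @export
make_impactor <- function(length = 200, diameter = 40, mass_kg = 2,
                          speed_kmh = 0, aim = c(0, 0, 0),
                          approach = c(0, 0, -1), axis = c(0, 1, 0),
                          standoff = 1.7) {
  if (length <= 0 || diameter <= 0) stop("impactor dimensions must be positive")
  stopifnot(mass_kg > 0, speed_kmh >= 0)
  axis <- axis / sqrt(sum(axis^2))
  approach <- approach / sqrt(sum(approach^2))
  radius <- diameter / 2
  vol <- pi * radius^2 * length
  origin <- aim - approach * (radius + standoff)
  structure(list(length = length, half_len = length / 2, radius = radius,
                 mass = kg_to_tonne(mass_kg), mass_kg = mass_kg,
                 density_equiv = kg_to_tonne(mass_kg) / vol,
                 origin = as.numeric(origin), axis = as.numeric(axis),
                 velocity = kmh_to_mms(speed_kmh) * approach,
                 approach = approach),
            class = "oi_impactor")
}

#' @export
print.oi_impactor <- function(x, ...) {
  cat(sprintf(
    "<oi_impactor> L=%g mm, D=%g mm, m=%g kg, |v|=%.1f mm/s (rho_eq=%.3g t/mm^3)\n",
    x$length, 2 * x$radius, x$mass_kg, sqrt(sum(x$velocity^2)), x$density_equiv))
  invisible(x)
}
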