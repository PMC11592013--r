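# Mesh container: nodes (mm), first-order solid elements (4-node tets /
# 8-node hexes), per-element material phase, named node/element sets.

# local face connectivities (1-based), outward-oriented
.hex_faces <- list(c(1, 4, 3, 2), c(5, 6, 7, 8), c(1, 2, 6, 5),
                   c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
.tet_faces <- list(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))

#' Construct a finite-element mesh
#'
#' @param nodes N x 3 matrix of coordinates (mm).
#' @param conn E x 8 integer connectivity, 1-based; tetrahedra use the first 4
#'   columns (pad the rest with 0).
#' @param nen number of nodes per element (4 or 8), length E.
#' @param phase integer per element: 1 = cortical, 2 = trabecular.
#' @param node_sets named list of node index vectors.
#' @param elem_sets named list of element index vectors.
#' @return an `oi_mesh` object (validated: positive volumes, indices in
#'   range, every element phase defined).
#' @export
oi_mesh <- function(nodes, conn, nen, phase, node_sets = list(),
                    elem_sets = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  conn <- as.matrix(conn)
  storage.mode(conn) <- "integer"
  if (ncol(conn) < 8)
    conn <- cbind(conn, matrix(0L, nrow(conn), 8 - ncol(conn)))
  nen <- as.integer(nen)
  phase <- as.integer(phase)
  stopifnot(ncol(nodes) == 3, nrow(conn) == length(nen),
            length(phase) == length(nen), all(nen %in% c(4L, 8L)),
            all(phase %in% c(1L, 2L)))
  for (e in seq_along(nen)) {
    idx <- conn[e, seq_len(nen[e])]
    if (any(idx < 1L | idx > nrow(nodes)))
      stop("connectivity index out of range in element ", e)
  }
  m <- structure(list(nodes = nodes, conn = conn, nen = nen, phase = phase,
                      node_sets = node_sets, elem_sets = elem_sets),
                 class = "oi_mesh")
  # positive-volume / Jacobian validation happens in the precompute
  invisible(cpp_fem_precompute(m$nodes, m$conn, m$nen))
  m
}

#' @export
print.oi_mesh <- function(x, ...) {
  cat(sprintf("<oi_mesh> %d nodes, %d elements (%d hex, %d tet)\n",
              nrow(x$nodes), length(x$nen), sum(x$nen == 8), sum(x$nen == 4)))
  cat(" node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  invisible(x)
}

# internal: cached geometric precompute
mesh_precompute <- function(mesh) cpp_fem_precompute(mesh$nodes, mesh$conn, mesh$nen)

#' Element volumes and characteristic lengths
#' @param mesh an [oi_mesh()].
#' @return list with `vol` (mm^3) and `Le` (mm) per element.
#' @export
mesh_volumes <- function(mesh) {
  pre <- mesh_precompute(mesh)
  list(vol = pre$vol, Le = pre$Le)
}

# internal: density per element (tonne/mm^3) from a materials list
elem_density <- function(mesh, materials) {
  ifelse(mesh$phase == 1L, materials$cortical$elastic$rho,
         materials$trabecular$elastic$rho)
}

#' Total mesh mass
#' @param mesh an [oi_mesh()].
#' @param materials list with `cortical` and `trabecular` [material_card()]s.
#' @return mass in tonne.
#' @export
mesh_mass <- function(mesh, materials) {
  sum(mesh_volumes(mesh)$vol * elem_density(mesh, materials))
}

# ---------------------------------------------------------------------------
# face topology (used for contact surfaces and fracture components)

# internal: table of all element faces.
# Returns list(fnodes F x 4 (0-padded), nfn, e1, e2) where e2 = 0 for
# boundary faces.
mesh_face_table <- function(mesh) {
  E <- length(mesh$nen)
  rows <- vector("list", E)
  for (e in seq_len(E)) {
    loc <- if (mesh$nen[e] == 8L) .hex_faces else .tet_faces
    f <- t(vapply(loc, function(lf) {
      v <- mesh$conn[e, lf]
      c(v, rep(0L, 4 - length(v)))
    }, integer(4)))
    rows[[e]] <- cbind(f, e)
  }
  all <- do.call(rbind, rows)
  key <- apply(all[, 1:4, drop = FALSE], 1, function(v)
    paste(sort(v[v > 0]), collapse = "-"))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  F <- sum(first)
  e1 <- integer(F); e2 <- integer(F)
  ord <- seq_len(nrow(all))
  for (i in ord) {
    j <- idx[i]
    if (e1[j] == 0L) e1[j] <- all[i, 5] else e2[j] <- all[i, 5]
  }
  fn <- all[first, 1:4, drop = FALSE]
  list(fnodes = fn, nfn = rowSums(fn > 0), e1 = e1, e2 = e2)
}

# internal: face areas from reference coordinates
face_areas <- function(nodes, ft) {
  tri_area <- function(a, b, c) {
    u <- nodes[b, , drop = FALSE] - nodes[a, , drop = FALSE]
    v <- nodes[c, , drop = FALSE] - nodes[a, , drop = FALSE]
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  a <- tri_area(ft$fnodes[, 1], ft$fnodes[, 2], ft$fnodes[, 3])
  quad <- ft$nfn == 4
  if (any(quad))
    a[quad] <- a[quad] + tri_area(ft$fnodes[quad, 1], ft$fnodes[quad, 3],
                                  ft$fnodes[quad, 4])
  a
}

# internal: tributary node areas of the current exterior surface, given which
# elements are alive. A face is exposed when exactly one of its owners is
# alive (erosion exposes interior faces).
surface_node_areas <- function(mesh, ft, areas, alive) {
  a2 <- ft$e2 > 0L & xor(alive[ft$e1], alive[pmax(ft$e2, 1L)])
  act <- (ft$e2 == 0L & alive[ft$e1]) | a2
  n <- nrow(mesh$nodes)
  na <- numeric(n)
  if (!any(act)) return(na)
  fn <- ft$fnodes[act, , drop = FALSE]
  fa <- areas[act] / ft$nfn[act]
  idx <- as.vector(fn)
  w <- rep(fa, 4)
  sel <- idx > 0
  agg <- rowsum(w[sel], idx[sel])
  na[as.integer(rownames(agg))] <- agg[, 1]
  na
}

#' Tie two meshes by merging coincident interface nodes
#'
#' Concatenates two meshes and merges every node of `set_b` (in mesh `b`) with
#' the nearest node of `set_a` (in mesh `a`) within `tolerance`, snapping to
#' the master coordinates. A rigidly joined interface transmits motion exactly,
#' so rigid-body motion of the tied assembly produces zero internal force.
#'
#' @param a,b [oi_mesh()] objects.
#' @param set_a,set_b node-set names on `a` and `b` forming the interface.
#' @param tolerance pairing tolerance in mm.
#' @return the tied `oi_mesh`; node sets of `b` are suffixed with `"_b"`.
#' @export
merge_tie <- function(a, b, set_a = "tie", set_b = "tie", tolerance = 1e-6) {
  ia <- a$node_sets[[set_a]]
  ib <- b$node_sets[[set_b]]
  if (is.null(ia) || is.null(ib)) stop("missing tie node set")
  off <- nrow(a$nodes)
  # nearest master for each slave
  d2 <- outer(rowSums(b$nodes[ib, , drop = FALSE]^2),
              rowSums(a$nodes[ia, , drop = FALSE]^2), "+") -
    2 * b$nodes[ib, , drop = FALSE] %*% t(a$nodes[ia, , drop = FALSE])
  nearest <- apply(d2, 1, which.min)
  mind <- sqrt(pmax(0, d2[cbind(seq_along(ib), nearest)]))
  if (any(mind > tolerance))
    stop("unmatched slave node beyond tolerance (max distance ",
         format(max(mind)), " mm)")
  map <- seq_len(nrow(b$nodes)) + off
  map[ib] <- ia[nearest]
  keep <- setdiff(seq_len(nrow(b$nodes)), ib)
  # compress the surviving b nodes
  newid <- integer(nrow(b$nodes))
  newid[keep] <- off + seq_along(keep)
  map2 <- ifelse(seq_len(nrow(b$nodes)) %in% ib, map, newid[seq_len(nrow(b$nodes))])
  nodes <- rbind(a$nodes, b$nodes[keep, , drop = FALSE])
  connb <- b$conn
  pos <- connb > 0
  connb[pos] <- map2[connb[pos]]
  ns <- a$node_sets
  for (nm in names(b$node_sets))
    ns[[paste0(nm, "_b")]] <- unique(map2[b$node_sets[[nm]]])
  es <- a$elem_sets
  for (nm in names(b$elem_sets))
    es[[paste0(nm, "_b")]] <- b$elem_sets[[nm]] + length(a$nen)
  oi_mesh(nodes, rbind(a$conn, connb), c(a$nen, b$nen), c(a$phase, b$phase),
          ns, es)
}

#' Serialize a mesh to / from a plain list (JSON-compatible)
#' @param mesh an [oi_mesh()].
#' @export
mesh_to_list <- function(mesh) {
  list(nodes = unname(apply(mesh$nodes, 1, as.numeric, simplify = FALSE)),
       conn = unname(apply(mesh$conn, 1, as.integer, simplify = FALSE)),
       nen = mesh$nen, phase = mesh$phase,
       node_sets = mesh$node_sets, elem_sets = mesh$elem_sets)
}

#' @rdname mesh_to_list
#' @param x a list produced by `mesh_to_list` (e.g. parsed from JSON).
#' @export
mesh_from_list <- function(x) {
  oi_mesh(do.call(rbind, x$nodes), do.call(rbind, x$conn),
          unlist(x$nen), unlist(x$phase),
          lapply(x$node_sets, as.integer), lapply(x$elem_sets, as.integer))
}

#' Write / read the native JSON mesh container
#' @param mesh an [oi_mesh()].
#' @param path file path.
#' @export
write_mesh_json <- function(mesh, path) {
  jsonlite::write_json(mesh_to_list(mesh), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_mesh_json
#' @export
read_mesh_json <- function(path) mesh_from_list(jsonlite::read_json(path))
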