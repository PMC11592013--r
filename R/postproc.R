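# Post-processing: SAE J211 channel-class filtering, von Mises fields,
# nodal averaging, fracture-line extraction, file outputs.

#' SAE J211 channel-class filter
#'
#' Phaseless impact-test filtering: a 2-pole Butterworth at the channel-class
#' cutoff applied forward and backward (2 x 2 poles total), with
#' edge-reflected padding. Channel frequency class CFC maps to the -3 dB
#' cutoff as `f_c = CFC * 5/3` Hz, so CFC180 cuts at 300 Hz. DC gain is
#' exactly 1.
#'
#' @param x numeric signal, or a data.frame with a `time_s` column and the
#'   channel in the second column.
#' @param cfc channel frequency class (default 180).
#' @param fs sampling frequency in Hz (required when `x` is a vector).
#' @return the filtered signal (vector in, vector out; data.frame in,
#'   data.frame out with a `<channel>_cfc<cfc>` column appended).
#' @export
sae_filter <- function(x, cfc = 180, fs = NULL) {
  if (is.data.frame(x)) {
    t <- x$time_s
    if (is.null(t)) stop("data.frame input needs a time_s column")
    dt <- diff(t)
    fs <- 1 / stats::median(dt)
    chan <- setdiff(names(x), "time_s")[1]
    v <- x[[chan]]
    if (max(abs(dt - 1 / fs)) > 1e-6 / fs) {   # resample to uniform
      tu <- seq(t[1], t[length(t)], by = 1 / fs)
      v <- stats::approx(t, v, xout = tu, rule = 2)$y
    }
    x[[paste0(chan, "_cfc", cfc)]] <- sae_filter(v, cfc, fs)
    return(x)
  }
  stopifnot(!is.null(fs), fs > 0)
  fc <- cfc * 5 / 3
  if (fc >= fs / 2) stop("sampling rate too low for this channel class")
  n <- length(x)
  npad <- ceiling(fs / fc)
  if (n < 3) stop("history too short for the filter warm-up; pad the signal")
  npad <- min(n - 1, npad * 3)
  xp <- c(2 * x[1] - rev(x[2:(npad + 1)]), x,
          2 * x[n] - rev(x[(n - npad):(n - 1)]))
  bf <- signal::butter(2, fc / (fs / 2))
  y <- signal::filtfilt(bf, xp)
  y[(npad + 1):(npad + n)]
}

#' Von Mises equivalent stress
#'
#' @param stress a Voigt 6-vector (xx, yy, zz, xy, yz, xz), an n x 6 matrix
#'   of such rows, or a symmetric 3 x 3 matrix. Shear components are tensor
#'   components (not engineering).
#' @return scalar(s) in the stress units of the input.
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress) && all(dim(stress) == c(3, 3)))
    stress <- c(stress[1, 1], stress[2, 2], stress[3, 3],
                stress[1, 2], stress[2, 3], stress[1, 3])
  s <- if (is.matrix(stress)) stress else matrix(stress, nrow = 1)
  sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 + (s[, 3] - s[, 1])^2) +
         3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
}

#' Volume-weighted nodal averages of an element field
#'
#' Averages per-element values onto nodes, weighting by element volume and
#' skipping deleted elements (mirroring how continuous stress fields are
#' produced from integration-point results for plotting).
#'
#' @param mesh an [oi_mesh()].
#' @param values per-element values.
#' @param deleted optional logical per element.
#' @return per-node averages (NA at nodes with no surviving element).
#' @export
nodal_field <- function(mesh, values, deleted = NULL) {
  vol <- mesh_volumes(mesh)$vol
  if (!is.null(deleted)) vol[deleted] <- 0
  n <- nrow(mesh$nodes)
  num <- numeric(n); den <- numeric(n)
  for (a in 1:8) {
    sel <- which(mesh$conn[, a] > 0)
    if (!length(sel)) next
    add_n <- tapply(vol[sel] * values[sel], mesh$conn[sel, a], sum)
    add_d <- tapply(vol[sel], mesh$conn[sel, a], sum)
    id <- as.integer(names(add_n))
    num[id] <- num[id] + add_n
    den[id] <- den[id] + add_d
  }
  ifelse(den > 0, num / den, NA_real_)
}

#' Extract fracture lines and a damage report
#'
#' Face-adjacency connected components over deleted elements (the fracture
#' pattern produced by element deletion) and, separately, over elements whose
#' initiation measure reached 1 (initiation maps). The crush fraction is the
#' failed volume inside the projected impactor footprint over the total
#' failed volume: values near 1 indicate pure crushing under the impactor,
#' lower values bending-driven failure away from it.
#'
#' @param mesh an [oi_mesh()].
#' @param deleted logical per element.
#' @param omega optional per-element initiation measure.
#' @param impactor optional [make_impactor()] defining the footprint.
#' @return an `oi_fracture_report` list.
#' @export
extract_fracture_lines <- function(mesh, deleted, omega = NULL,
                                   impactor = NULL) {
  comp_of <- function(flags) {
    ids <- which(flags)
    if (!length(ids))
      return(list(n = 0L, membership = integer(0), ids = integer(0)))
    ft <- mesh_face_table(mesh)
    int <- ft$e2 > 0L & flags[ft$e1] & flags[pmax(ft$e2, 1L)]
    g <- igraph::graph_from_data_frame(
      data.frame(from = match(ft$e1[int], ids),
                 to = match(ft$e2[int], ids)),
      directed = FALSE, vertices = data.frame(name = seq_along(ids)))
    cm <- igraph::components(g)
    list(n = cm$no, membership = cm$membership, ids = ids)
  }
  vol <- mesh_volumes(mesh)$vol
  centroids <- t(vapply(seq_along(mesh$nen), function(e) {
    idx <- mesh$conn[e, seq_len(mesh$nen[e])]
    colMeans(mesh$nodes[idx, , drop = FALSE])
  }, numeric(3)))

  dc <- comp_of(deleted)
  comp_tab <- if (dc$n > 0) {
    do.call(rbind, lapply(seq_len(dc$n), function(ci) {
      el <- dc$ids[dc$membership == ci]
      ex <- apply(centroids[el, , drop = FALSE], 2, range)
      data.frame(component = ci, n_elements = length(el),
                 volume_mm3 = sum(vol[el]),
                 extent_x = diff(ex[, 1]), extent_y = diff(ex[, 2]),
                 extent_z = diff(ex[, 3]))
    }))
  } else data.frame(component = integer(0), n_elements = integer(0),
                    volume_mm3 = numeric(0), extent_x = numeric(0),
                    extent_y = numeric(0), extent_z = numeric(0))

  crush <- NA_real_
  if (!is.null(impactor) && any(deleted)) {
    d <- sweep(centroids[deleted, , drop = FALSE], 2, impactor$origin)
    zp <- d %*% impactor$approach
    dp <- d - zp %*% t(impactor$approach)
    za <- dp %*% impactor$axis
    rad <- sqrt(rowSums((dp - za %*% t(impactor$axis))^2))
    inside <- abs(za) <= impactor$half_len & rad <= impactor$radius
    crush <- sum(vol[deleted][inside]) / sum(vol[deleted])
  }

  ic <- if (is.null(omega)) NULL else comp_of(omega >= 1 & !deleted)
  structure(list(
    n_failed = sum(deleted), failed_volume_mm3 = sum(vol[deleted]),
    n_components = dc$n, components = comp_tab,
    membership = stats::setNames(dc$membership, dc$ids),
    crush_fraction = crush,
    n_initiated = if (is.null(omega)) NA_integer_ else sum(omega >= 1),
    n_initiation_components = if (is.null(ic)) NA_integer_ else ic$n),
    class = "oi_fracture_report")
}

# ---------------------------------------------------------------------------
# file outputs

#' Write a mesh with fields as ASCII VTU
#'
#' Minimal VTK unstructured-grid XML writer (hexahedra and tetrahedra) for
#' inspection in ParaView.
#'
#' @param mesh an [oi_mesh()].
#' @param file output path.
#' @param point_data named list of per-node vectors or n x 3 matrices.
#' @param cell_data named list of per-element vectors.
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); E <- length(mesh$nen)
  num <- function(x) paste(format(x, digits = 10, scientific = TRUE,
                                  trim = TRUE), collapse = " ")
  da <- function(name, x, ncomp = 1)
    sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
            name, ncomp, num(if (is.matrix(x)) as.numeric(t(x)) else x))
  conn0 <- unlist(lapply(seq_len(E), function(e)
    mesh$conn[e, seq_len(mesh$nen[e])] - 1L))
  off <- cumsum(mesh$nen)
  types <- ifelse(mesh$nen == 8L, 12L, 10L)
  pd <- paste(vapply(names(point_data), function(nm) {
    x <- point_data[[nm]]
    da(nm, x, if (is.matrix(x)) ncol(x) else 1)
  }, character(1)), collapse = "\n")
  cd <- paste(vapply(names(cell_data), function(nm)
    da(nm, cell_data[[nm]]), character(1)), collapse = "\n")
  xml <- sprintf(
'<?xml version="1.0"?>
<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">
<UnstructuredGrid>
<Piece NumberOfPoints="%d" NumberOfCells="%d">
<Points>
%s
</Points>
<Cells>
<DataArray type="Int32" Name="connectivity" format="ascii">
%s
</DataArray>
<DataArray type="Int32" Name="offsets" format="ascii">
%s
</DataArray>
<DataArray type="UInt8" Name="types" format="ascii">
%s
</DataArray>
</Cells>
<PointData>
%s
</PointData>
<CellData>
%s
</CellData>
</Piece>
</UnstructuredGrid>
</VTKFile>', n, E, da("Points", mesh$nodes, 3),
    paste(conn0, collapse = " "), paste(off, collapse = " "),
    paste(types, collapse = " "), pd, cd)
  writeLines(xml, file)
  invisible(file)
}

#' Read data arrays back from a VTU written by [write_vtu()]
#'
#' @param file path to the VTU file.
#' @return named list of numeric arrays (points, point data, cell data).
#' @export
read_vtu_arrays <- function(file) {
  doc <- xml2::read_xml(file)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  out <- list()
  for (d in das) {
    nm <- xml2::xml_attr(d, "Name")
    nc <- as.integer(xml2::xml_attr(d, "NumberOfComponents"))
    v <- scan(text = xml2::xml_text(d), quiet = TRUE)
    if (!is.na(nc) && nc > 1) v <- matrix(v, ncol = nc, byrow = TRUE)
    out[[nm]] <- v
  }
  out
}

#' Write all scenario outputs
#'
#' CSV force/energy history (with the CFC180-filtered channel and the force
#' also in kgf), a VTU snapshot series with named field arrays, and a JSON
#' fracture report.
#'
#' @param result an [run_scenario()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
write_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hist <- result$history
  hist$force_kgf <- n_to_kgf(hist$force_N)
  hcsv <- file.path(dir, "history.csv")
  utils::write.csv(hist, hcsv, row.names = FALSE)
  mesh <- result$scenario$mesh
  vtus <- character(0)
  for (i in seq_along(result$snapshots)) {
    s <- result$snapshots[[i]]
    f <- file.path(dir, sprintf("snapshot_%03d.vtu", i - 1L))
    write_vtu(mesh, f,
              point_data = list(displacement = s$displacement),
              cell_data = list(von_mises_MPa = s$von_mises_MPa,
                               ductcrit = s$ductcrit, damage = s$damage,
                               deleted = as.numeric(s$deleted)))
    vtus <- c(vtus, f)
  }
  fr <- result$fracture
  rep <- list(n_failed = fr$n_failed, failed_volume_mm3 = fr$failed_volume_mm3,
              n_components = fr$n_components,
              components = fr$components, crush_fraction = fr$crush_fraction,
              n_initiated = fr$n_initiated,
              peak_force_N = max(hist$force_N),
              peak_force_cfc180_N = max(hist$force_N_cfc180),
              peak_force_kgf = n_to_kgf(max(hist$force_N)),
              added_mass_fraction = result$mass_report$added_mass_fraction,
              diverged = result$diverged)
  jf <- file.path(dir, "report.json")
  jsonlite::write_json(rep, jf, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(hcsv, vtus, jf))
}
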