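#' Lens-shaped seed geometry
#'
#' The seed is idealised as a biconvex lens: two identical spherical caps
#' joined at their circular base, rotationally symmetric about the thickness
#' axis. With base radius \eqn{a = d/2} and cap height \eqn{h = t/2} the
#' circumscribing sphere radius is \eqn{R_s = (a^2 + h^2)/(2h)}.
#'
#' @param diameter Seed diameter in metres (default 4.4 mm).
#' @param thickness Seed thickness in metres (default 2.2 mm).
#' @return An object of class `lens_geometry`.
#' @examples
#' geom <- lens_geometry()
#' characteristic_length(geom) * 1e3   # mm
#' @export
lens_geometry <- function(diameter = 4.4e-3, thickness = 2.2e-3) {
  if (!is.numeric(diameter) || !is.numeric(thickness) ||
      thickness <= 0 || diameter <= 0 || thickness > diameter)
    stop("need 0 < thickness <= diameter (metres)")
  a <- diameter / 2
  hcap <- thickness / 2
  Rs <- (a^2 + hcap^2) / (2 * hcap)
  structure(list(diameter = diameter, thickness = thickness,
                 a = a, hcap = hcap, Rs = Rs),
            class = "lens_geometry")
}

#' @export
print.lens_geometry <- function(x, ...) {
  cat(sprintf("<lens_geometry>  d = %.3g mm, t = %.3g mm, Rs = %.3g mm\n",
              x$diameter * 1e3, x$thickness * 1e3, x$Rs * 1e3))
  invisible(x)
}

#' Volume and surface area of the lens
#'
#' Closed-form spherical-cap formulas: each cap contributes
#' \eqn{V_{cap} = \pi h^2 (3 R_s - h)/3} and lateral area
#' \eqn{A_{cap} = 2 \pi R_s h}; the two caps share their base circle so no rim
#' is exposed.
#'
#' @param geom A [lens_geometry()].
#' @return A named list with `volume` (m3) and `area` (m2).
#' @export
lens_volume_area <- function(geom) {
  stopifnot(inherits(geom, "lens_geometry"))
  h <- geom$hcap
  Rs <- geom$Rs
  list(volume = 2 * pi * h^2 * (3 * Rs - h) / 3,
       area   = 2 * 2 * pi * Rs * h)
}

#' Characteristic length of the seed
#'
#' Volume divided by surface area; used to convert Biot numbers into
#' convective transfer coefficients.
#'
#' @param geom A [lens_geometry()].
#' @return Characteristic length in metres.
#' @export
characteristic_length <- function(geom) {
  va <- lens_volume_area(geom)
  va$volume / va$area
}

# Height of the upper cap profile above the midplane at radius r.
cap_profile <- function(geom, r) {
  sqrt(pmax(geom$Rs^2 - r^2, 0)) - (geom$Rs - geom$hcap)
}

#' Triangulate the half-lens cross-section
#'
#' Builds a conforming mesh of linear triangles on the axisymmetric
#' cross-section \eqn{\{(r, z): 0 \le r \le a, |z| \le z_{cap}(r)\}} by
#' mapping a structured grid onto the cap profile: radial columns of
#' equispaced nodes are scaled to the local profile height and collapse to a
#' single node at the rim. Curved (top and bottom) boundary edges are tagged
#' `convective`; the `r = 0` column is tagged as the symmetry axis.
#'
#' @param geom A [lens_geometry()].
#' @param target_h Target edge length in metres; must be positive and smaller
#'   than half the seed thickness. The default yields a mesh of roughly 500
#'   nodes and 1000 triangles on the default geometry.
#' @return An object of class `lens_mesh`: list with `nodes` (n x 2 matrix of
#'   (r, z) in metres), `triangles` (m x 3 node indices, counter-clockwise),
#'   `boundary_edges` (convective edges, pairs of node indices), `axis_edges`,
#'   the generating `geom` and `target_h`.
#' @examples
#' mesh <- generate_mesh(lens_geometry(), target_h = 3e-4)
#' nrow(mesh$triangles)
#' @export
generate_mesh <- function(geom, target_h = 1e-4) {
  stopifnot(inherits(geom, "lens_geometry"))
  if (!is.numeric(target_h) || target_h <= 0 || target_h >= geom$thickness / 2)
    stop("`target_h` must be positive and smaller than thickness/2")
  a <- geom$a
  # A floor on the radial resolution keeps the revolved-volume quadrature of
  # the curved rim accurate even on deliberately coarse meshes.
  Nr <- max(ceiling(a / target_h), 8L)
  Nz <- max(2L * ceiling(geom$thickness / (2 * target_h)), 2L)

  r_cols <- a * seq(0, Nr - 1L) / Nr
  zmax <- cap_profile(geom, r_cols)
  idx <- function(i, j) i * (Nz + 1L) + j + 1L   # i in 0..Nr-1, j in 0..Nz
  n_col_nodes <- Nr * (Nz + 1L)
  tip <- n_col_nodes + 1L

  nodes <- matrix(0, nrow = n_col_nodes + 1L, ncol = 2)
  for (i in seq_len(Nr) - 1L) {
    j <- 0:Nz
    nodes[idx(i, j), 1] <- r_cols[i + 1L]
    nodes[idx(i, j), 2] <- zmax[i + 1L] * (2 * j / Nz - 1)
  }
  nodes[tip, ] <- c(a, 0)

  tris <- vector("list", Nr)
  for (i in seq_len(Nr - 1L) - 1L) {
    j <- seq_len(Nz) - 1L
    A <- idx(i, j); B <- idx(i + 1L, j); C <- idx(i + 1L, j + 1L); D <- idx(i, j + 1L)
    tris[[i + 1L]] <- rbind(cbind(A, B, C), cbind(A, C, D))
  }
  j <- seq_len(Nz) - 1L
  tris[[Nr]] <- cbind(idx(Nr - 1L, j), tip, idx(Nr - 1L, j + 1L))
  triangles <- do.call(rbind, tris)
  dimnames(triangles) <- NULL

  i <- seq_len(Nr - 1L) - 1L
  boundary_edges <- rbind(
    cbind(idx(i, Nz), idx(i + 1L, Nz)),            # top arc
    cbind(idx(Nr - 1L, Nz), tip),
    cbind(idx(i, 0L), idx(i + 1L, 0L)),            # bottom arc
    cbind(idx(Nr - 1L, 0L), tip)
  )
  dimnames(boundary_edges) <- NULL
  j <- seq_len(Nz) - 1L
  axis_edges <- cbind(idx(0L, j), idx(0L, j + 1L))
  dimnames(axis_edges) <- NULL

  mesh <- structure(list(nodes = nodes, triangles = triangles,
                         boundary_edges = boundary_edges,
                         axis_edges = axis_edges,
                         geom = geom, target_h = target_h),
                    class = "lens_mesh")
  val <- validate_mesh(mesh)
  if (!isTRUE(val))
    stop("mesh generation failed: ", val,
         sprintf(" [d = %g m, t = %g m, h = %g m]",
                 geom$diameter, geom$thickness, target_h))
  mesh
}

#' @export
print.lens_mesh <- function(x, ...) {
  cat(sprintf("<lens_mesh>  %d nodes, %d triangles, %d convective edges (h = %.3g m)\n",
              nrow(x$nodes), nrow(x$triangles), nrow(x$boundary_edges), x$target_h))
  invisible(x)
}

# Signed triangle areas in the (r, z) plane; positive = counter-clockwise.
triangle_areas <- function(mesh) {
  p <- mesh$nodes
  t1 <- mesh$triangles[, 1]; t2 <- mesh$triangles[, 2]; t3 <- mesh$triangles[, 3]
  0.5 * ((p[t2, 1] - p[t1, 1]) * (p[t3, 2] - p[t1, 2]) -
         (p[t3, 1] - p[t1, 1]) * (p[t2, 2] - p[t1, 2]))
}

#' Validate a lens mesh
#'
#' Checks the structural invariants: non-negative radial coordinates,
#' positive (counter-clockwise) triangle areas, every tagged convective edge
#' belonging to exactly one triangle, axis edges lying on `r = 0`, and the
#' planar triangle areas summing to the analytic half-lens cross-section area
#' within discretisation tolerance.
#'
#' @param mesh A [generate_mesh()] result.
#' @return `TRUE` if valid, otherwise a string describing the first failure.
#' @export
validate_mesh <- function(mesh) {
  p <- mesh$nodes
  if (any(p[, 1] < -1e-15)) return("negative radial coordinate")
  areas <- triangle_areas(mesh)
  if (any(areas <= 0)) return("non-positive (degenerate or clockwise) triangle")
  edge_key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tri_edges <- rbind(mesh$triangles[, c(1, 2)], mesh$triangles[, c(2, 3)],
                     mesh$triangles[, c(3, 1)])
  counts <- table(edge_key(tri_edges))
  bkeys <- edge_key(mesh$boundary_edges)
  if (!all(bkeys %in% names(counts))) return("boundary edge not present in any triangle")
  if (any(counts[bkeys] != 1L)) return("boundary edge shared by more than one triangle")
  if (any(abs(p[mesh$axis_edges, 1]) > 1e-15)) return("axis edge off the symmetry axis")
  # the meshed half cross-section {r >= 0} has the area of one circular segment
  g <- mesh$geom
  theta <- asin(g$a / g$Rs)
  seg_area <- g$Rs^2 * theta - g$a * (g$Rs - g$hcap)
  rel <- abs(sum(areas) - seg_area) / seg_area
  if (rel > 0.05) return(sprintf("cross-section area off by %.1f%%", 100 * rel))
  TRUE
}

#' Axisymmetric measures of a mesh
#'
#' Revolved (about the z axis, full revolution) measure of every triangle and
#' convective boundary edge, by the Pappus rule with the centroid radius:
#' triangle volume \eqn{2\pi \bar r A}, edge area \eqn{2\pi \bar r \ell}.
#' Their sums converge to the analytic lens volume and surface area under
#' mesh refinement.
#'
#' @param mesh A [generate_mesh()] result.
#' @return A list with `tri_volumes` (m3, per triangle), `edge_areas` (m2, per
#'   convective boundary edge), and their sums `volume` and `area`.
#' @export
axisymmetric_measures <- function(mesh) {
  p <- mesh$nodes
  areas <- triangle_areas(mesh)
  rbar <- rowMeans(matrix(p[mesh$triangles, 1], ncol = 3))
  tri_volumes <- 2 * pi * rbar * areas
  e1 <- mesh$boundary_edges[, 1]; e2 <- mesh$boundary_edges[, 2]
  len <- sqrt((p[e1, 1] - p[e2, 1])^2 + (p[e1, 2] - p[e2, 2])^2)
  re <- (p[e1, 1] + p[e2, 1]) / 2
  edge_areas <- 2 * pi * re * len
  list(tri_volumes = tri_volumes, edge_areas = edge_areas,
       volume = sum(tri_volumes), area = sum(edge_areas))
}

#' Export a mesh as legacy-ASCII VTK
#'
#' Writes an unstructured-grid file for visualisation (ParaView etc.), with
#' optional per-node scalar fields.
#'
#' @param mesh A [generate_mesh()] result.
#' @param path Output file path.
#' @param point_data Optional named list of per-node numeric vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "axisymmetric lens mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(cbind(mesh$nodes, 0), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(c(sprintf("CELL_TYPES %d", m), rep("5", m)), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 10), con)
    }
  }
  invisible(path)
}
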