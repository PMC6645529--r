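# Triangulated isosurfaces and surface-to-surface distances.

new_triangulated_surface <- function(vertices, triangles, label) {
  structure(list(vertices = vertices, triangles = triangles, label = label),
            class = "triangulated_surface")
}

#' @export
print.triangulated_surface <- function(x, ...) {
  cat(sprintf("<triangulated_surface> '%s': %d vertices, %d triangles\n",
              x$label, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Extract the zero-level surface of a level-set field
#'
#' Triangulates the zero isosurface of `phi` with linear interpolation along
#' tetrahedron edges (marching tetrahedra on a consistent six-tetrahedron
#' cube split, so closed surfaces come out watertight). Vertex coordinates
#' are fractional 0-based voxel indices.
#'
#' @param phi A `level_set_field`.
#' @return A `triangulated_surface`.
#' @export
extract_zero_surface <- function(phi) {
  stopifnot(inherits(phi, "level_set_field"))
  if (min(phi$phi) >= 0 || max(phi$phi) <= 0)
    cm_stop("field does not change sign: no zero surface", "no_surface_error")
  m <- cpp_march_tetra(as.vector(phi$phi), dim(phi$phi), 0)
  new_triangulated_surface(m$vertices, m$triangles, phi$label)
}

#' Triangulated surface of a binary volume
#'
#' Extracts the 0.5-level isosurface of the 0/1 indicator volume of a mask
#' (the conventional marching-style surface of a segmentation), for
#' consistency checks against the level-set reconstruction.
#'
#' @param mask A [binary_mask] or 3D logical array.
#' @param label Label carried on the surface.
#' @return A `triangulated_surface`.
#' @export
marching_surface <- function(mask, label = "mask") {
  data <- if (inherits(mask, "binary_mask")) mask$data else mask
  if (!any(data) || all(data))
    cm_stop("mask has no surface", "no_surface_error")
  m <- cpp_march_tetra(as.numeric(data), dim(data), 0.5)
  new_triangulated_surface(m$vertices, m$triangles, label)
}

#' Symmetric Hausdorff distance between two surfaces
#'
#' `max(h(a -> b), h(b -> a))` over vertex samples, where `h(a -> b)` is the
#' largest distance from a vertex of `a` to its nearest vertex of `b`
#' (voxel units).
#'
#' @param a,b `triangulated_surface` objects.
#' @return Distance in voxels.
#' @export
hausdorff_distance <- function(a, b) {
  stopifnot(inherits(a, "triangulated_surface"),
            inherits(b, "triangulated_surface"))
  if (nrow(a$vertices) == 0 || nrow(b$vertices) == 0)
    cm_stop("empty surface", "empty_input_error")
  max(max(cpp_nn_dist(a$vertices, b$vertices, 2.0)),
      max(cpp_nn_dist(b$vertices, a$vertices, 2.0)))
}

#' Write a surface as ASCII PLY
#' @param surf A `triangulated_surface`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(surf, path) {
  stopifnot(inherits(surf, "triangulated_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment surface %s", surf$label),
               sprintf("element vertex %d", nrow(surf$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(surf$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(surf$vertices, trim = TRUE, digits = 7), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, surf$triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a surface as legacy VTK polydata
#' @param surf A `triangulated_surface`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(surf, path) {
  stopifnot(inherits(surf, "triangulated_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(surf$vertices); nt <- nrow(surf$triangles)
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("cortimap surface %s", surf$label),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nv)), con)
  utils::write.table(format(surf$vertices, trim = TRUE, digits = 7), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nt, 4L * nt), con)
  utils::write.table(cbind(3L, surf$triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
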