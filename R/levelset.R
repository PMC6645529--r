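# Signed-distance level-set fields of bone surfaces and geometry change.
#
# Sign convention: phi > 0 inside the enclosed region, phi < 0 outside,
# phi = 0 on the surface. The discrete field is built from two exact
# Euclidean distance transforms with a half-voxel offset,
#   phi = d(background) - 1/2   inside,   phi = -(d(foreground) - 1/2) outside,
# which places the zero level midway between boundary voxel centres (exactly
# where the 0.5-level surface of the binary volume lies), makes the
# complement symmetry phi -> -phi exact, and gives |phi| = 1/2 on boundary
# voxels so the signed-distance property |grad phi| ~ 1 holds through the
# interface.

#' Signed-distance level-set field of a closed surface
#'
#' Builds the signed distance function of the boundary of `region` on the
#' voxel grid (exact Euclidean distance transform), positive inside.
#'
#' @param mask A [binary_mask] providing grid/voxel size (the bone mask).
#' @param region 3D logical array: the enclosed region of one surface
#'   (for the periosteum: bone plus interior cavities; for an endosteal
#'   surface: the cavity).
#' @param label Surface label carried as metadata.
#' @param surface_voxels Optional 0-based voxel coordinate matrix of the
#'   surface voxels this field tracks (filled in by [surface_field()]).
#' @param check Verify that the region is one 6-connected component (skipped
#'   by internal callers that already know it is).
#' @return A `level_set_field` with elements `phi` (3D array, voxels),
#'   `voxel_size`, `label`, `surface_voxels`.
#' @export
signed_distance <- function(mask, region, label = "surface",
                            surface_voxels = NULL, check = TRUE) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  if (!all(dim(region) == d)) cm_stop("region/grid shape mismatch", "shape_error")
  if (!any(region)) cm_stop("region is empty", "empty_input_error")
  if (check) {
    lab <- cpp_label6(as.vector(region), d)
    if (attr(lab, "n_components") != 1L)
      cm_stop("region must be a single 6-connected component", "topology_error")
  }
  # the surface must close laterally; the z faces are the open ends of the VOI
  if (any(region[1, , ]) || any(region[d[1], , ]) ||
      any(region[, 1, ]) || any(region[, d[2], ]))
    cm_stop("region touches the lateral grid boundary: surface is open",
            "open_surface_error")
  phi <- sqrt(cpp_edt_sq(as.vector(!region), d)) - 0.5
  neg <- !region
  phi[neg] <- -(sqrt(cpp_edt_sq(as.vector(region), d))[neg] - 0.5)
  phi <- array(phi, d)
  structure(list(phi = phi, voxel_size = mask$voxel_size, label = label,
                 surface_voxels = surface_voxels),
            class = "level_set_field")
}

#' @export
print.level_set_field <- function(x, ...) {
  cat(sprintf("<level_set_field> '%s', %s voxels, phi in [%.2f, %.2f]\n",
              x$label, paste(dim(x$phi), collapse = " x "),
              min(x$phi), max(x$phi)))
  invisible(x)
}

#' Label the closed surfaces of a cortical bone mask
#'
#' Finds the closed boundary components of the bone mask by
#' connected-component analysis. Background is split into the exterior
#' (components reaching the lateral grid faces) and interior cavities; the
#' boundary component with the largest surface area (boundary voxel count)
#' is labelled `periosteum` with enclosed region bone + cavities, and each
#' cavity contributes an `endosteum_k` surface with the cavity as its
#' enclosed region. Cavities whose boundary is smaller than
#' `min_boundary_voxels` are treated as intracortical porosity: filled into
#' the periosteal region but not reported as surfaces.
#'
#' @param mask A [binary_mask].
#' @param min_boundary_voxels Minimum endosteal boundary size to keep.
#' @param keep_largest If `TRUE` (default) only the largest 6-connected bone
#'   component is analysed (segmentation speckles are dropped).
#' @return A `surface_set`: list of surfaces (each with `label`, `voxels`
#'   0-based Nx3 coordinate matrix, `region` logical array, `n_boundary`),
#'   plus `voxel_size` and the cleaned bone mask.
#' @export
label_surfaces <- function(mask, min_boundary_voxels = 50L, keep_largest = TRUE) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  bone <- mask$data
  blab <- cpp_label6(as.vector(bone), d)
  nb <- attr(blab, "n_components")
  if (nb == 0L) cm_stop("mask has empty foreground", "empty_input_error")
  if (nb > 1L) {
    if (!keep_largest)
      cm_stop("mask has multiple bone components", "topology_error")
    sizes <- tabulate(blab, nb)
    bone <- array(blab == which.max(sizes), d)
  }
  bg <- !bone
  glab <- cpp_label6(as.vector(bg), d)
  ng <- attr(glab, "n_components")
  glab_arr <- array(glab, d)
  face_labels <- unique(c(glab_arr[1, , ], glab_arr[d[1], , ],
                          glab_arr[, 1, ], glab_arr[, d[2], ]))
  face_labels <- setdiff(face_labels, 0L)
  if (length(face_labels) == 0L)
    cm_stop("no exterior background: bone fills the lateral faces",
            "topology_error")
  lut <- integer(ng + 1L)
  lut[face_labels + 1L] <- 1L
  ext <- array(lut[glab + 1L], d)
  peri_sv <- array(cpp_adjacent_to(as.vector(bone), as.vector(ext), 1L, d), d)
  if (!any(peri_sv)) cm_stop("no closed periosteal surface found", "topology_error")

  cav_ids <- setdiff(seq_len(ng), face_labels)
  cavities <- list()
  for (cid in cav_ids) {
    cav <- array(glab_arr == cid, d)
    sv <- array(cpp_adjacent_to(as.vector(bone), as.vector(glab_arr == cid), TRUE, d), d)
    cavities[[length(cavities) + 1L]] <- list(region = cav, sv = sv,
                                              n = sum(sv))
  }
  keep <- vapply(cavities, function(cv) cv$n >= min_boundary_voxels, logical(1))
  # periosteal enclosed region: bone with all cavities filled
  peri_region <- bone
  if (length(cavities))
    for (cv in cavities) peri_region <- peri_region | cv$region

  surfaces <- list(list(label = "periosteum", voxels = which_voxels(peri_sv),
                        region = peri_region, n_boundary = sum(peri_sv)))
  kept <- cavities[keep]
  if (length(kept)) {
    ord <- order(vapply(kept, function(cv) cv$n, numeric(1)), decreasing = TRUE)
    for (i in seq_along(ord)) {
      cv <- kept[[ord[i]]]
      surfaces[[length(surfaces) + 1L]] <-
        list(label = sprintf("endosteum_%d", i), voxels = which_voxels(cv$sv),
             region = cv$region, n_boundary = cv$n)
    }
  }
  # the periosteum must carry the largest surface area
  areas <- vapply(surfaces, function(s) s$n_boundary, numeric(1))
  if (which.max(areas) != 1L)
    cm_warn("an endosteal surface is larger than the periosteal one",
            "labelling_warning")
  structure(list(surfaces = surfaces, voxel_size = mask$voxel_size,
                 bone = bone), class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  cat(sprintf("<surface_set> %d surfaces @ %.3g um\n",
              length(x$surfaces), x$voxel_size))
  for (s in x$surfaces)
    cat(sprintf("  %-14s %8d surface voxels\n", s$label, s$n_boundary))
  invisible(x)
}

surface_by_label <- function(surfaces, label) {
  for (s in surfaces$surfaces) if (identical(s$label, label)) return(s)
  cm_stop(sprintf("no surface labelled '%s'", label), "label_error")
}

#' Signed-distance field for one labelled surface
#'
#' Convenience wrapper: builds the [signed_distance()] field of the enclosed
#' region of the surface `label` in a [surface_set], carrying that surface's
#' voxel list for later change-field sampling.
#'
#' @param mask A [binary_mask] (provides the grid).
#' @param surfaces A [label_surfaces()] result.
#' @param label Surface label, e.g. `"periosteum"`.
#' @return A `level_set_field`.
#' @export
surface_field <- function(mask, surfaces, label = "periosteum") {
  s <- surface_by_label(surfaces, label)
  signed_distance(mask, s$region, label = label, surface_voxels = s$voxels,
                  check = FALSE)
}

#' Geometry change between two level-set fields
#'
#' Samples the difference of the two signed-distance fields at the baseline
#' surface voxels: `change(v) = (phi_t1(v) - phi_t(v)) * voxel_size`,
#' positive where the surface evolved along its outward normal (periosteum:
#' bone formation; endosteum: resorption), in micrometres per scan interval.
#'
#' @param phi_t Baseline `level_set_field` (must carry `surface_voxels`).
#' @param phi_t1 Follow-up `level_set_field` on the same grid and label.
#' @param dt Scan interval in weeks (metadata).
#' @return A `change_field`: data frame `x, y, z, change_um` (0-based voxel
#'   coordinates) with attributes `label`, `dt`, `voxel_size`, `dims`.
#' @export
geometry_change <- function(phi_t, phi_t1, dt = 1) {
  stopifnot(inherits(phi_t, "level_set_field"),
            inherits(phi_t1, "level_set_field"))
  if (!all(dim(phi_t$phi) == dim(phi_t1$phi)))
    cm_stop("level-set grids differ in shape", "shape_error")
  if (!identical(phi_t$label, phi_t1$label))
    cm_stop("level-set fields track different surfaces", "label_error")
  sv <- phi_t$surface_voxels
  if (is.null(sv)) cm_stop("baseline field has no surface voxel list",
                           "empty_input_error")
  idx <- voxel_index(sv, dim(phi_t$phi))
  ch <- (phi_t1$phi[idx] - phi_t$phi[idx]) * phi_t$voxel_size
  structure(data.frame(x = sv[, 1], y = sv[, 2], z = sv[, 3], change_um = ch),
            label = phi_t$label, dt = dt, voxel_size = phi_t$voxel_size,
            dims = dim(phi_t$phi), class = c("change_field", "data.frame"))
}

#' Export a change field as CSV
#'
#' Writes `x, y, z, change_um` rows (0-based voxel coordinates).
#' @param field A `change_field`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_change_field <- function(field, path) {
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}
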