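# Cylindrical unwrapping of per-surface change fields into 2D maps.
#
# The map S(theta, z) is indexed by the angle theta to the posterior
# direction (+x in the registered frame) measured in the transverse plane
# about the per-slice centroid of the periosteal enclosed region (so
# periosteal and endosteal maps share angular coordinates), and by bone
# height z (slice index). Rows = z, columns = theta bins covering [0, 360).

slice_centroids <- function(region, zs) {
  nx <- dim(region)[1]
  t(vapply(zs, function(z) {
    idx <- which(region[, , z + 1L])
    if (length(idx) == 0) return(c(NA_real_, NA_real_))
    i0 <- idx - 1L
    c(mean(i0 %% nx), mean(i0 %/% nx))
  }, numeric(2)))
}

#' Unwrap a surface change field into a 2D (theta, z) map
#'
#' Each surface voxel is assigned to the angular bin
#' `round(theta / theta_bin_deg) mod nbins` of its z slice. When several
#' voxels of one slice land in the same bin (possible on concave
#' cross-sections), the voxel with the largest absolute change is kept and
#' the others are counted as mis-projected; the error rate e_r = N_mis /
#' N_tot quantifies this surjection loss. Bins hit by no voxel are in-filled
#' by circular linear interpolation along theta and flagged invalid.
#'
#' @param field A `change_field` from [geometry_change()].
#' @param surfaces The [label_surfaces()] result of the baseline mask (the
#'   periosteal enclosed region provides the per-slice angular origin).
#' @param theta_bin_deg Angular bin width in degrees (default 1).
#' @return List with `map` (a `cyl_map`: matrix `S` of micrometre changes,
#'   `valid` mask, `z_range`, `theta_bin_deg`, `label`, `voxel_size`) and
#'   `report` (a `projection_report`: `N_tot`, `N_mis`, `e_r`).
#' @export
unwrap_surface <- function(field, surfaces, theta_bin_deg = 1.0) {
  stopifnot(inherits(field, "change_field"), inherits(surfaces, "surface_set"))
  if (nrow(field) == 0) cm_stop("change field is empty", "empty_input_error")
  if (360 %% theta_bin_deg > 1e-9)
    cm_stop("theta_bin_deg must divide 360", "parameter_error")
  nbins <- as.integer(round(360 / theta_bin_deg))
  peri <- surface_by_label(surfaces, "periosteum")

  zs <- sort(unique(field$z))
  counts <- table(factor(field$z, levels = zs))
  if (any(counts < 3L))
    cm_stop("a z-slice has fewer than 3 surface voxels", "degenerate_slice_error")
  cent <- slice_centroids(peri$region, zs)
  zrow <- match(field$z, zs)
  xc <- cent[zrow, 1]; yc <- cent[zrow, 2]
  theta <- (atan2(field$y - yc, field$x - xc) * 180 / pi) %% 360
  bin <- as.integer(round(theta / theta_bin_deg)) %% nbins

  nz <- length(zs)
  S <- matrix(NA_real_, nz, nbins)
  key <- zrow + bin * nz  # column-major linear index of (zrow, bin + 1)
  # keep the largest |change| per bin: ascending order, later writes win
  ord <- order(abs(field$change_um))
  S[key[ord]] <- field$change_um[ord]
  n_mis <- sum(duplicated(key))
  valid <- !is.na(S)

  # circular in-fill along theta
  for (r in seq_len(nz)) {
    good <- which(valid[r, ])
    if (length(good) == 0L) next
    if (length(good) < nbins) {
      xg <- c(good, good[1] + nbins)
      yg <- c(S[r, good], S[r, good[1]])
      miss <- which(!valid[r, ])
      mshift <- ifelse(miss < good[1], miss + nbins, miss)
      S[r, miss] <- stats::approx(xg, yg, xout = mshift)$y
    }
  }
  map <- structure(list(S = S, valid = valid, z_range = c(zs[1], zs[nz] + 1L),
                        zs = zs, theta_bin_deg = theta_bin_deg,
                        label = attr(field, "label"),
                        voxel_size = attr(field, "voxel_size")),
                   class = "cyl_map")
  report <- structure(list(N_tot = nrow(field), N_mis = n_mis,
                           e_r = n_mis / nrow(field)),
                      class = "projection_report")
  list(map = map, report = report)
}

#' @export
print.cyl_map <- function(x, ...) {
  cat(sprintf("<cyl_map> '%s': %d z-slices x %d theta bins (%.3g deg), z in [%d, %d)\n",
              x$label, nrow(x$S), ncol(x$S), x$theta_bin_deg,
              x$z_range[1], x$z_range[2]))
  invisible(x)
}

#' @export
print.projection_report <- function(x, ...) {
  cat(sprintf("<projection_report> N_tot = %d, N_mis = %d, e_r = %.4f\n",
              x$N_tot, x$N_mis, x$e_r))
  invisible(x)
}

#' Back-project a 2D map onto the 3D surface
#'
#' Each surface voxel of the labelled surface receives the value of its
#' (theta, z) bin; the inverse of [unwrap_surface()] up to surjection losses.
#'
#' @param map A `cyl_map` (or `scale_patterns` component passed as matrix via
#'   `values`).
#' @param surfaces The [label_surfaces()] result of the same baseline mask.
#' @param values Optional matrix with the shape of `map$S` to back-project
#'   instead of `map$S` (used for synthesized patterns).
#' @return A `change_field` on the surface voxels of `map$label`.
#' @export
backproject <- function(map, surfaces, values = NULL) {
  stopifnot(inherits(map, "cyl_map"), inherits(surfaces, "surface_set"))
  s <- surface_by_label(surfaces, map$label)
  V <- if (is.null(values)) map$S else values
  if (!all(dim(V) == dim(map$S))) cm_stop("values/map shape mismatch", "shape_error")
  nbins <- ncol(V)
  peri <- surface_by_label(surfaces, "periosteum")
  sv <- s$voxels
  keep <- sv[, 3] %in% map$zs
  sv <- sv[keep, , drop = FALSE]
  zrow <- match(sv[, 3], map$zs)
  cent <- slice_centroids(peri$region, map$zs)
  xc <- cent[zrow, 1]; yc <- cent[zrow, 2]
  theta <- (atan2(sv[, 2] - yc, sv[, 1] - xc) * 180 / pi) %% 360
  bin <- as.integer(round(theta / map$theta_bin_deg)) %% nbins
  ch <- V[(bin) * nrow(V) + zrow]
  structure(data.frame(x = sv[, 1], y = sv[, 2], z = sv[, 3], change_um = ch),
            label = map$label, dt = 1, voxel_size = map$voxel_size,
            dims = NULL, class = c("change_field", "data.frame"))
}

#' Write a cylindrical map as CSV plus JSON sidecar
#'
#' The CSV holds the matrix (rows = z slices, columns = theta bins, header
#' row of bin centres in degrees); the sidecar `<path>.json` records label,
#' voxel size, bin width, z range and a run-length encoding of the valid
#' mask.
#'
#' @param map A `cyl_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cyl_map <- function(map, path) {
  stopifnot(inherits(map, "cyl_map"))
  S <- map$S
  colnames(S) <- sprintf("%g", (seq_len(ncol(S)) - 1L) * map$theta_bin_deg)
  utils::write.csv(S, path, row.names = FALSE)
  rle_valid <- rle(as.vector(map$valid))
  meta <- list(label = map$label, voxel_size_um = map$voxel_size,
               theta_bin_deg = map$theta_bin_deg,
               z_range = map$z_range, zs = map$zs,
               valid_rle = list(lengths = rle_valid$lengths,
                                values = rle_valid$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cylindrical map written by [write_cyl_map()]
#' @param path CSV path (expects `<path>.json` sidecar).
#' @return A `cyl_map`.
#' @export
read_cyl_map <- function(path) {
  S <- as.matrix(utils::read.csv(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  valid <- matrix(inverse.rle(list(lengths = meta$valid_rle$lengths,
                                   values = meta$valid_rle$values)),
                  nrow(S), ncol(S))
  structure(list(S = unname(S), valid = valid, z_range = meta$z_range,
                 zs = meta$zs, theta_bin_deg = meta$theta_bin_deg,
                 label = meta$label, voxel_size = meta$voxel_size_um),
            class = "cyl_map")
}
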