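# Synthetic tubular cortical-bone phantoms.
#
# The phantom is a hollow tube standing in for the tibial cortex: one outer
# (periosteal) and one inner (endosteal) closed lateral surface, spanning
# the full z extent of the grid like a cropped volume of interest. Optional
# linear taper along z and a three-lobed sinusoidal cross-section mimic the
# metaphyseal narrowing and the concave cross-sections that exercise the
# surjective-projection rule of the unwrapping step.

#' Generate a hollow-tube cortical phantom
#'
#' Cross-section boundary radii at angle theta and height z:
#' `r_out = outer_radius * g(z) * (1 + concavity * cos(3 theta))` and
#' `r_in = (outer_radius - wall) * g(z) * (1 + concavity * cos(3 theta))`,
#' with `g(z) = 1 - taper * z / (nz - 1)`. Bone occupies
#' `r_in < r <= r_out`.
#'
#' @param shape Grid dimensions `c(nx, ny, nz)`.
#' @param outer_radius Outer radius in voxels at the proximal end.
#' @param wall Cortical wall thickness in voxels (>= 3).
#' @param taper Linear taper ratio along z (0 = straight tube).
#' @param concavity Amplitude of the three-lobed cross-section modulation
#'   (0 = circular, convex cross-sections).
#' @param voxel_size Voxel size in micrometres.
#' @return A [binary_mask].
#' @export
make_phantom <- function(shape = c(160L, 160L, 480L), outer_radius = 50,
                         wall = 12, taper = 0, concavity = 0,
                         voxel_size = 10.4) {
  shape <- as.integer(shape)
  if (wall < 3) cm_stop("wall thinner than 3 voxels", "topology_error")
  if (outer_radius + 2 >= min(shape[1], shape[2]) / 2)
    cm_stop("outer radius too large for the grid", "parameter_error")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  xs <- (0:(nx - 1)) - cx
  ys <- (0:(ny - 1)) - cy
  r2 <- outer(xs^2, ys^2, "+")
  r <- sqrt(r2)
  th <- atan2(matrix(ys, nx, ny, byrow = TRUE), matrix(xs, nx, ny))
  shapefac <- 1 + concavity * cos(3 * th)
  mask <- array(FALSE, shape)
  for (k in seq_len(nz)) {
    g <- 1 - taper * (k - 1) / (nz - 1)
    ro <- outer_radius * g * shapefac
    ri <- (outer_radius - wall) * g * shapefac
    mask[, , k] <- r <= ro & r > ri
  }
  binary_mask(mask, voxel_size)
}

#' Render a phantom mask as a grayscale scan
#'
#' Assigns `bone` intensity to foreground and `background` to the rest
#' (contrast = bone - background), producing a clean synthetic scan that
#' [simulate_repeat_scan()] can corrupt with noise and misalignment.
#'
#' @param mask A [binary_mask].
#' @param bone,background Intensities (arbitrary units).
#' @return A [volume_image].
#' @export
phantom_scan <- function(mask, bone = 200, background = 40) {
  stopifnot(inherits(mask, "binary_mask"))
  volume_image(array(ifelse(mask$data, bone, background), dim(mask$data)),
               mask$voxel_size)
}
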