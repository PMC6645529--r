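# Synthetic accuracy-evaluation scenarios with exact ground truth.
#
# Four scenarios mirror the accuracy study: (1) null -- two repeat scans of
# the same geometry, (2) growth -- a uniform outward field F_g = c * 1 added
# to the baseline level-set field, (3) local -- a sparse random activity
# field F_r confined to a z band, each voxel independently activated with
# probability b and drawn uniformly on [-a, a], (4) combined -- both. The
# modified field Phi* + F_g + F_r is re-voxelised (quantised) so the imposed
# change suffers the same one-voxel resolution floor as the real pipeline,
# and the scans are corrupted by additive Gaussian intensity noise and a
# sub-voxel rigid misalignment emulating repeated in vivo acquisitions.

#' Specify a synthetic scenario
#'
#' @param kind One of `"null"`, `"growth"`, `"local"`, `"combined"`.
#' @param c Uniform growth in voxels (integral when `quantise = TRUE`).
#' @param a Local-activity amplitude bound in voxels.
#' @param b Activation probability in [0, 1].
#' @param band Inclusive z band `c(l1, l2)` (0-based slices) of local
#'   activity; `NULL` = central third of the grid.
#' @param seed RNG seed.
#' @param noise_sd Intensity noise SD as a fraction of the bone/background
#'   contrast.
#' @param misalign_sd Sub-voxel misalignment SD in voxels (translation).
#' @param quantise Re-voxelise the modified surface (one-voxel resolution
#'   floor of the level-set representation).
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("combined", "null", "growth", "local"),
                          c = 3, a = 3, b = 0.3, band = NULL, seed = 1L,
                          noise_sd = 0.05, misalign_sd = 0.3,
                          quantise = TRUE) {
  kind <- match.arg(kind)
  if (b < 0 || b > 1) cm_stop("b must lie in [0, 1]", "parameter_error")
  if (a < 0) cm_stop("a must be non-negative", "parameter_error")
  if (!is.null(band) && band[1] > band[2])
    cm_stop("band must satisfy l1 <= l2", "parameter_error")
  if (quantise && kind %in% c("growth", "combined") && c != round(c))
    cm_stop("growth c must be integral when quantising (sub-voxel growth is not representable)",
            "parameter_error")
  structure(list(kind = kind, c = c, a = a, b = b, band = band,
                 seed = as.integer(seed), noise_sd = noise_sd,
                 misalign_sd = misalign_sd, quantise = quantise),
            class = "scenario_spec")
}

default_band <- function(nz) c(floor(nz / 3), floor(2 * nz / 3) - 1L)

#' Impose scenario activity on a level-set field
#'
#' Builds `Phi_t1 = Phi* + F_g + F_r` where `F_g = c` everywhere (growth /
#' combined) and `F_r` is nonzero only for z in the activity band, each site
#' independently activated with probability `b` and drawn uniformly on
#' `[-a, a]` (local / combined). When `spec$quantise` the modified field is
#' re-derived from the re-voxelised zero level. Ground truth records the
#' imposed fields sampled at the baseline surface voxels.
#'
#' @param phi_star Baseline `level_set_field` (with `surface_voxels`).
#' @param spec A [scenario_spec()] (RNG state is taken as-is; seed the
#'   session or use [scenario_volumes()] for reproducible runs).
#' @param mask The [binary_mask] that produced `phi_star` (grid provider).
#' @param derive_phi Re-derive the signed-distance field of the quantised
#'   region (skip when only the region and ground truth are needed).
#' @return List: `phi_t1` (`level_set_field`), `region_t1` (logical array,
#'   the modified enclosed region), `truth` (data frame `x, y, z, low_um,
#'   high_um` on baseline surface voxels).
#' @export
impose_activity <- function(phi_star, spec, mask, derive_phi = TRUE) {
  stopifnot(inherits(phi_star, "level_set_field"),
            inherits(spec, "scenario_spec"))
  d <- dim(phi_star$phi)
  band <- if (is.null(spec$band)) default_band(d[3]) else spec$band
  if (band[1] < 0 || band[2] >= d[3])
    cm_stop("activity band outside the grid", "parameter_error")
  cgrow <- if (spec$kind %in% c("growth", "combined")) spec$c else 0
  phi1 <- phi_star$phi + cgrow

  sv <- phi_star$surface_voxels
  high_true <- numeric(nrow(sv))
  if (spec$kind %in% c("local", "combined") && spec$a > 0 && spec$b > 0) {
    zs <- band[1]:band[2]
    nsl <- length(zs)
    nxy <- d[1] * d[2]
    K <- matrix(stats::runif(nxy * nsl, -spec$a, spec$a) *
                (stats::runif(nxy * nsl) < spec$b), nxy, nsl)
    phi1[, , zs + 1L] <- phi1[, , zs + 1L] + array(K, c(d[1], d[2], nsl))
    inband <- sv[, 3] >= band[1] & sv[, 3] <= band[2]
    if (any(inband)) {
      svb <- sv[inband, , drop = FALSE]
      high_true[inband] <- K[cbind(1L + svb[, 1] + d[1] * svb[, 2],
                                   match(svb[, 3], zs))]
    }
  }

  region1 <- phi1 > 0
  phi_t1 <- NULL
  if (spec$quantise) {
    # keep the largest component (stray islands where F_r exceeded |Phi|
    # off-surface are segmentation speckle, as in a real noisy scan)
    lab <- cpp_label6(as.vector(region1), d)
    if (attr(lab, "n_components") > 1L) {
      sizes <- tabulate(lab, attr(lab, "n_components"))
      region1 <- array(lab == which.max(sizes), d)
    }
    if (derive_phi)
      phi_t1 <- signed_distance(mask, region1, label = phi_star$label,
                                surface_voxels = phi_star$surface_voxels,
                                check = FALSE)
  } else {
    phi_t1 <- structure(list(phi = phi1, voxel_size = phi_star$voxel_size,
                             label = phi_star$label,
                             surface_voxels = phi_star$surface_voxels),
                        class = "level_set_field")
  }
  vs <- phi_star$voxel_size
  truth <- data.frame(x = sv[, 1], y = sv[, 2], z = sv[, 3],
                      low_um = rep(cgrow * vs, nrow(sv)),
                      high_um = high_true * vs)
  list(phi_t1 = phi_t1, region_t1 = region1, truth = truth)
}

#' Simulate a repeated scan
#'
#' Applies a random sub-voxel rigid perturbation (translation SD
#' `spec$misalign_sd` voxels) and additive Gaussian intensity noise (SD
#' `spec$noise_sd` times the intensity range) to a grayscale volume,
#' emulating consecutive acquisitions of the same structure.
#'
#' @param img A [volume_image].
#' @param spec A [scenario_spec()].
#' @param misalign Apply the rigid perturbation (default `TRUE`).
#' @return A [volume_image]; the applied transform is attached as attribute
#'   `true_transform`.
#' @export
simulate_repeat_scan <- function(img, spec, misalign = TRUE) {
  stopifnot(inherits(img, "volume_image"), inherits(spec, "scenario_spec"))
  out <- img
  tf <- rigid_transform()
  if (misalign && spec$misalign_sd > 0) {
    tf <- rigid_transform(translation = stats::rnorm(3, 0, spec$misalign_sd))
    out <- apply_rigid(out, tf, fill = min(img$data))
  }
  if (spec$noise_sd > 0) {
    contrast <- diff(range(img$data))
    out$data <- out$data + array(stats::rnorm(length(out$data), 0,
                                              spec$noise_sd * contrast),
                                 dim(out$data))
  }
  attr(out, "true_transform") <- tf
  out
}

#' Generate a full scenario: baseline and follow-up scans plus ground truth
#'
#' Builds a phantom, derives the baseline periosteal level-set field,
#' imposes the scenario activity, renders both time points as grayscale
#' scans and corrupts them with the scenario noise model (the follow-up
#' additionally receives the sub-voxel misalignment).
#'
#' @param spec A [scenario_spec()].
#' @param phantom A [binary_mask] (default: the standard 160 x 160 x 480
#'   tube phantom).
#' @param bone,background Scan intensities.
#' @return List: `baseline`, `followup` ([volume_image]s), `truth` (data
#'   frame on baseline periosteal surface voxels), `baseline_mask`
#'   (clean phantom), `spec`.
#' @export
scenario_volumes <- function(spec, phantom = NULL, bone = 200, background = 40) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  if (is.null(phantom)) phantom <- make_phantom()
  surfaces <- label_surfaces(phantom)
  phi0 <- surface_field(phantom, surfaces, "periosteum")
  imp <- impose_activity(phi0, spec, phantom, derive_phi = FALSE)
  # follow-up bone mask: modified periosteal region minus the (static)
  # endosteal cavities
  bone1 <- imp$region_t1
  for (s in surfaces$surfaces)
    if (s$label != "periosteum") bone1 <- bone1 & !s$region
  clean0 <- phantom_scan(phantom, bone, background)
  clean1 <- phantom_scan(binary_mask(bone1, phantom$voxel_size), bone, background)
  baseline <- simulate_repeat_scan(clean0, spec, misalign = FALSE)
  followup <- simulate_repeat_scan(clean1, spec, misalign = TRUE)
  list(baseline = baseline, followup = followup, truth = imp$truth,
       baseline_mask = phantom, spec = spec)
}
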