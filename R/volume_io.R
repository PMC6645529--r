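# Volume containers, readers/writers and grayscale preprocessing.
#
# Axis convention: array dimension 1 = x (posterior direction is +x in the
# registered frame), dimension 2 = y, dimension 3 = z = the bone long axis,
# with the proximal end at low z. Coordinates are 0-based voxel indices;
# z-slice ranges are half-open [start, stop).

#' Construct a 3D grayscale volume
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param voxel_size Isotropic voxel size in micrometres.
#' @param origin Integer voxel offset of the array origin (metadata only).
#' @return A `volume_image` object.
#' @export
volume_image <- function(data, voxel_size, origin = c(0L, 0L, 0L)) {
  if (length(dim(data)) != 3L)
    cm_stop("volume data must be a 3D array", "dimensionality_error")
  if (any(dim(data) < 8L))
    cm_stop("all three dimensions must be at least 8 voxels", "dimensionality_error")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    cm_stop("voxel_size must be a single positive number (micrometres)", "parameter_error")
  if (!all(is.finite(data)))
    cm_stop("volume intensities must be finite", "parameter_error")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %d x %d x %d voxels @ %.3g um, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a binary bone mask
#'
#' @param data 3D logical array, `TRUE` = bone tissue.
#' @param voxel_size Isotropic voxel size in micrometres.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, voxel_size) {
  if (length(dim(data)) != 3L)
    cm_stop("mask data must be a 3D array", "dimensionality_error")
  if (!is.logical(data)) storage.mode(data) <- "logical"
  if (!any(data)) cm_stop("mask has empty foreground", "empty_input_error")
  structure(list(data = data, voxel_size = voxel_size), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d voxels @ %.3g um, %d foreground\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$data)))
  invisible(x)
}

# ---- file formats ----------------------------------------------------------

volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.tiff?$", lower)) "tiff"
  else if (grepl("\\.nii(\\.gz)?$", lower)) "nifti"
  else if (grepl("\\.mhd$", lower)) "mhd"
  else cm_stop(sprintf("unsupported volume format: '%s'", basename(path)),
               "format_error")
}

read_mhd <- function(path) {
  hdr <- readLines(path, warn = FALSE)
  field <- function(key) {
    ln <- grep(paste0("^\\s*", key, "\\s*="), hdr, value = TRUE)
    if (length(ln) == 0) return(NULL)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  ndims <- as.integer(field("NDims"))
  if (is.null(ndims) || ndims != 3L)
    cm_stop("MetaImage payload is not 3D", "dimensionality_error")
  dims <- as.integer(strsplit(field("DimSize"), "\\s+")[[1]])
  etype <- field("ElementType")
  datafile <- field("ElementDataFile")
  raw_path <- if (identical(datafile, "LOCAL")) path
              else file.path(dirname(path), datafile)
  spacing <- field("ElementSpacing")
  what <- switch(etype,
    "MET_DOUBLE" = list(type = "double", size = 8),
    "MET_FLOAT" = list(type = "double", size = 4),
    "MET_SHORT" = list(type = "integer", size = 2),
    "MET_USHORT" = list(type = "integer", size = 2),
    "MET_UCHAR" = list(type = "integer", size = 1),
    cm_stop(sprintf("unsupported MetaImage element type %s", etype), "format_error"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = what$type, n = prod(dims), size = what$size,
                  endian = "little", signed = !(etype %in% c("MET_UCHAR", "MET_USHORT")))
  arr <- array(as.double(vals), dim = dims)
  list(data = arr, spacing = spacing)
}

write_mhd <- function(vol, path) {
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(vol$data), collapse = " ")),
           paste("ElementSpacing =",
                 paste(rep(vol$voxel_size / 1000, 3), collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.vector(vol$data), con, size = 8, endian = "little")
}

#' Read a 3D volume from disk
#'
#' Supports stacked TIFF (one page per z-slice), NIfTI-1 and MetaImage
#' (MHD + RAW). Intensities are widened to double precision.
#'
#' @param path File path.
#' @param voxel_size Isotropic voxel size in micrometres; for NIfTI/MetaImage,
#'   if `NULL` the header spacing (assumed millimetres) is used.
#' @return A [volume_image].
#' @export
read_volume <- function(path, voxel_size = NULL) {
  fmt <- volume_format(path)
  if (!file.exists(path)) cm_stop(sprintf("file not found: %s", path), "io_error")
  if (fmt == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE))
      cm_stop("package 'tiff' is required to read TIFF volumes", "format_error")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L || length(dim(pages[[1]])) != 2L)
      cm_stop("TIFF payload is not a 3D stack", "dimensionality_error")
    # pages are y-by-x matrices; assemble as x, y, z
    arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
    if (is.null(voxel_size))
      cm_stop("voxel_size must be given for TIFF volumes", "parameter_error")
    volume_image(arr, voxel_size)
  } else if (fmt == "nifti") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      cm_stop("package 'RNifti' is required to read NIfTI volumes", "format_error")
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L)
      cm_stop("NIfTI payload is not 3D", "dimensionality_error")
    if (is.null(voxel_size))
      voxel_size <- RNifti::pixdim(img)[1] * 1000  # mm -> um
    volume_image(arr, voxel_size)
  } else {
    got <- read_mhd(path)
    if (is.null(voxel_size)) {
      sp <- as.numeric(strsplit(got$spacing, "\\s+")[[1]])[1]
      voxel_size <- sp * 1000
    }
    volume_image(got$data, voxel_size)
  }
}

#' Write a 3D volume to disk
#'
#' Format chosen by extension (`.tif`/`.tiff`, `.nii`/`.nii.gz`, `.mhd`).
#' TIFF stacks are written as 32-bit float pages with intensities rescaled
#' to the unit interval (the scale is recorded in no side file; prefer
#' NIfTI or MetaImage for lossless round trips of arbitrary intensities).
#'
#' @param vol A [volume_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  fmt <- volume_format(path)
  if (fmt == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE))
      cm_stop("package 'tiff' is required to write TIFF volumes", "format_error")
    d <- dim(vol$data)
    rng <- range(vol$data)
    sc <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(seq_len(d[3]), function(k)
      t((vol$data[, , k] - rng[1]) / sc))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (fmt == "nifti") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      cm_stop("package 'RNifti' is required to write NIfTI volumes", "format_error")
    RNifti::writeNifti(RNifti::asNifti(vol$data,
                       pixdim = rep(vol$voxel_size / 1000, 3)), path)
  } else {
    write_mhd(vol, path)
  }
  invisible(path)
}

# ---- preprocessing ---------------------------------------------------------

#' Gaussian smoothing with a truncated discrete kernel
#'
#' Separable 3D Gaussian with standard deviation `sigma` (voxels) truncated
#' to a `kernel`^3 support and renormalised to unit sum, so constants are
#' preserved exactly. Borders are handled by mirror reflection.
#'
#' @param img A [volume_image].
#' @param sigma Gaussian standard deviation in voxels.
#' @param kernel Odd kernel size (>= 3) in voxels.
#' @return Smoothed [volume_image].
#' @export
gaussian_smooth <- function(img, sigma = 0.65, kernel = 3L) {
  stopifnot(inherits(img, "volume_image"))
  if (!is.numeric(sigma) || sigma <= 0)
    cm_stop("sigma must be positive", "parameter_error")
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L || kernel < 3L)
    cm_stop("kernel size must be odd and >= 3", "parameter_error")
  h <- kernel %/% 2L
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(img$data)
  out <- img$data
  for (ax in 0:2) out <- array(cpp_conv_axis(out, d, k, ax), d)
  volume_image(out, img$voxel_size, img$origin)
}

#' Otsu global threshold segmentation
#'
#' Chooses the histogram threshold maximising the between-class variance
#' (equivalently minimising the within-class variance) and returns the mask
#' of voxels with intensity strictly above it.
#'
#' @param img A [volume_image].
#' @param nbins Number of histogram bins.
#' @return A [binary_mask]; the threshold is attached as attribute
#'   `threshold`.
#' @export
otsu_segment <- function(img, nbins = 256L) {
  stopifnot(inherits(img, "volume_image"))
  v <- as.vector(img$data)
  rng <- range(v)
  if (diff(rng) == 0)
    cm_stop("constant image: histogram is degenerate", "degenerate_histogram_error")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                          nbins), nbins)
  p <- counts / sum(counts)
  centers <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  # between-class variance for thresholds at each bin's upper edge
  denom <- w0 * (1 - w0)
  sigma_b <- ifelse(denom > 0, (mu_t * w0 - mu)^2 / denom, -Inf)
  kstar <- which.max(sigma_b[-nbins])  # last edge would leave one empty class
  thr <- edges[kstar + 1L]
  m <- binary_mask(array(img$data > thr, dim(img$data)), img$voxel_size)
  attr(m, "threshold") <- thr
  m
}

# ---- rigid registration ----------------------------------------------------

euler_matrix <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rigid transform (3 Euler angles + translation)
#'
#' @param rotation Euler angles (radians), applied as Rz Ry Rx about the
#'   volume centre.
#' @param translation Translation in voxels.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  rotation <- ((rotation + pi) %% (2 * pi)) - pi
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Invert a rigid transform
#' @param tf A [rigid_transform].
#' @return The inverse transform (as rotation matrix + translation; the
#'   Euler angles of the inverse are recovered numerically).
#' @export
invert_transform <- function(tf) {
  R <- euler_matrix(tf$rotation)
  Ri <- t(R)
  ti <- -Ri %*% tf$translation
  # recover ZYX Euler angles from Ri
  ry <- asin(-Ri[3, 1])
  rx <- atan2(Ri[3, 2], Ri[3, 3])
  rz <- atan2(Ri[2, 1], Ri[1, 1])
  rigid_transform(c(rx, ry, rz), as.vector(ti))
}

#' Resample a volume under a rigid transform
#'
#' The output voxel at position `x` (about the volume centre) samples the
#' input at `R x + t` by trilinear interpolation; positions falling outside
#' the grid receive `fill`.
#'
#' @param img A [volume_image].
#' @param tf A [rigid_transform].
#' @param fill Fill value for out-of-grid samples.
#' @return Resampled [volume_image].
#' @export
apply_rigid <- function(img, tf, fill = NULL) {
  stopifnot(inherits(img, "volume_image"), inherits(tf, "rigid_transform"))
  if (is.null(fill)) fill <- stats::quantile(img$data, 0.01, names = FALSE)
  d <- dim(img$data)
  out <- cpp_rigid_resample(img$data, d, euler_matrix(tf$rotation),
                            tf$translation, fill)
  volume_image(array(out, d), img$voxel_size, img$origin)
}

#' Intensity-based rigid registration
#'
#' Finds the 6-parameter rigid transform minimising the mean squared
#' intensity difference between `fixed` and the trilinearly resampled
#' `moving`, using a quasi-Newton (L-BFGS-B) optimiser with numerical
#' gradients over a coarse-to-fine voxel stride. Intended to refine small
#' residual misalignments (a few voxels / degrees) of approximately
#' pre-aligned scans; `apply_rigid(moving, tf)` aligns `moving` onto
#' `fixed`.
#'
#' @param moving,fixed [volume_image]s on the same grid and voxel size.
#' @param strides Voxel strides for the successive refinement stages;
#'   `NULL` picks them from the grid size.
#' @param maxit Iteration budget per stage.
#' @return A [rigid_transform] with attributes `mse` (final objective),
#'   `converged`, and `settings` (interpolation order, tolerance).
#' @export
rigid_register <- function(moving, fixed, strides = NULL, maxit = 80L) {
  stopifnot(inherits(moving, "volume_image"), inherits(fixed, "volume_image"))
  if (!isTRUE(all.equal(moving$voxel_size, fixed$voxel_size)))
    cm_stop("moving and fixed must share the voxel size", "parameter_error")
  if (!all(dim(moving$data) == dim(fixed$data)))
    cm_stop("moving and fixed must share the grid", "shape_error")
  d <- dim(fixed$data)
  if (is.null(strides)) {
    # target ~3e4 samples at the coarse stage
    s1 <- max(2L, as.integer(floor((prod(d) / 3e4)^(1 / 3))))
    strides <- c(s1, max(1L, s1 %/% 2L))
  }
  fill <- stats::quantile(moving$data, 0.01, names = FALSE)
  p <- rep(0, 6)  # rx, ry, rz, tx, ty, tz
  conv <- TRUE
  # weak Tikhonov pin: keeps directions the image content does not constrain
  # (e.g. rotation about the axis of a nearly circular shaft) at zero without
  # measurably biasing well-constrained parameters
  mse_id <- cpp_rigid_mse(moving$data, fixed$data, d, diag(3), rep(0, 3),
                          strides[1], fill)
  lam <- 1e-3 * max(mse_id, 1e-8)
  for (s in strides) {
    obj <- function(p) cpp_rigid_mse(moving$data, fixed$data, d,
                                     euler_matrix(p[1:3]), p[4:6], s, fill) +
      lam * (sum(p[4:6]^2) + 100 * sum(p[1:3]^2))
    o <- stats::optim(p, obj, method = "L-BFGS-B",
                      lower = c(rep(-0.35, 3), rep(-8, 3)),
                      upper = c(rep(0.35, 3), rep(8, 3)),
                      control = list(maxit = maxit, factr = 1e7,
                                     ndeps = c(rep(1e-4, 3), rep(1e-2, 3))))
    p <- o$par
  }
  # line-search stalls at the interpolation noise floor (code 52) are normal;
  # flag exhausted iteration budgets, non-finite objectives, results worse
  # than the identity, or a final alignment whose intensities do not
  # correlate (no overlapping content to register)
  mse0 <- cpp_rigid_mse(moving$data, fixed$data, d, diag(3), rep(0, 3),
                        strides[length(strides)], fill)
  if (o$convergence == 1L || !is.finite(o$value) || (mse0 > 0 && o$value > mse0))
    conv <- FALSE
  al <- cpp_rigid_resample(moving$data, d, euler_matrix(p[1:3]), p[4:6], fill)
  sub <- seq(1, length(al), by = max(1L, length(al) %/% 200000L))
  ncc <- suppressWarnings(stats::cor(al[sub], as.vector(fixed$data)[sub]))
  if (is.finite(ncc) && ncc < 0.2) conv <- FALSE
  tf <- rigid_transform(p[1:3], p[4:6])
  attr(tf, "mse") <- o$value
  attr(tf, "converged") <- conv
  attr(tf, "settings") <- list(interpolation = "trilinear", optimizer = "L-BFGS-B",
                               strides = strides, maxit = maxit, factr = 1e7)
  if (!conv)
    cm_warn("registration did not converge; returning best transform found",
            "convergence_warning")
  tf
}

#' Select the volume of interest along the bone axis
#'
#' Bone length is the z-extent of the minimal bounding box of the
#' foreground; the proximal `floor(fraction * length)` slices (lowest z)
#' are retained and all other slices zeroed.
#'
#' @param mask A [binary_mask].
#' @param fraction Fraction of bone length to keep, in (0, 1].
#' @return A [binary_mask] with the distal slices cleared; the retained
#'   half-open 0-based slice range is attached as attribute `z_range`.
#' @export
select_voi <- function(mask, fraction = 0.80) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    cm_stop("fraction must lie in (0, 1]", "parameter_error")
  any_z <- apply(mask$data, 3, any)
  if (!any(any_z)) cm_stop("mask has empty foreground", "empty_input_error")
  z0 <- which(any_z)[1]                       # proximal end (1-based)
  z1 <- tail(which(any_z), 1)
  len <- z1 - z0 + 1L
  keep <- max(1L, as.integer(floor(fraction * len)))
  out <- mask$data
  if (z0 + keep <= z1) out[, , (z0 + keep):z1] <- FALSE
  m <- binary_mask(out, mask$voxel_size)
  attr(m, "z_range") <- c(z0 - 1L, z0 - 1L + keep)  # 0-based half-open
  m
}
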