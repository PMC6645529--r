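# 2D dual-tree complex wavelet transform.
#
# Four real separable decimated wavelet transforms are run in parallel, one
# per (row tree, column tree) pair. Tree "b" differs from tree "a" by a
# one-sample input offset at level 1 and by time-reversed q-shift filters at
# levels >= 2, so that the cumulative delay difference between the trees is
# half a sample period at every level -- the condition that makes the paired
# subbands (approximately) analytic and their magnitudes near shift-invariant.
# Complex subbands are formed as unitary sum/difference combinations of the
# four trees; the inverse averages the four exact per-tree reconstructions.
#
# All internal filtering is circular; the map is padded once (periodic wrap
# along the circular theta axis, symmetric reflection along z) to a multiple
# of 2^levels and cropped after synthesis, which keeps the forward/inverse
# pair an exact identity.

# ---- 1D filtering primitives (circular, via FFT) --------------------------

# filter object: list(c = taps, o = index of the n = 0 tap within c)
fb_freq <- function(fil, n) {
  v <- numeric(n)
  idx <- ((seq_along(fil$c) - 1 - fil$o) %% n) + 1
  for (i in seq_along(idx)) v[idx[i]] <- v[idx[i]] + fil$c[i]
  stats::fft(v)
}

fb_reverse <- function(fil) list(c = rev(fil$c), o = length(fil$c) - 1 - fil$o)

# analysis along the row dimension (each column filtered), decimation by 2
afb1d <- function(X, f0, f1, phase) {
  n <- nrow(X)
  Xf <- stats::mvfft(X)
  y0 <- Re(stats::mvfft(Xf * fb_freq(f0, n), inverse = TRUE)) / n
  y1 <- Re(stats::mvfft(Xf * fb_freq(f1, n), inverse = TRUE)) / n
  keep <- seq(1 + phase, n, by = 2)
  list(lo = y0[keep, , drop = FALSE], hi = y1[keep, , drop = FALSE])
}

# synthesis: zero-stuff into the same phase and filter with the duals
sfb1d <- function(lo, hi, g0, g1, phase) {
  n <- 2L * nrow(lo)
  u0 <- matrix(0, n, ncol(lo))
  u1 <- matrix(0, n, ncol(lo))
  pos <- seq(1 + phase, n, by = 2)
  u0[pos, ] <- lo
  u1[pos, ] <- hi
  Re(stats::mvfft(stats::mvfft(u0) * fb_freq(g0, n) +
                  stats::mvfft(u1) * fb_freq(g1, n), inverse = TRUE)) / n
}

# ---- tree bookkeeping ------------------------------------------------------

# filters for a given tree at a given level
tree_filters <- function(bank, tree, level, synthesis = FALSE) {
  if (level == 1L) {
    f <- if (synthesis) list(f0 = bank$level1$g0, f1 = bank$level1$g1)
         else           list(f0 = bank$level1$h0, f1 = bank$level1$h1)
    f$phase <- if (tree == "a") 0L else 1L
  } else {
    qs <- if (tree == "a") bank$qshift_a else bank$qshift_b
    f <- if (synthesis) list(f0 = qs$g0, f1 = qs$g1)
         else           list(f0 = qs$h0, f1 = qs$h1)
    f$phase <- 0L
  }
  f
}

# one 2D analysis level for one (row tree, col tree) pair;
# rows of X run along z, columns along theta
dt2_analysis <- function(X, bank, rt, ct, level) {
  fr <- tree_filters(bank, rt, level)
  fc <- tree_filters(bank, ct, level)
  z <- afb1d(X, fr$f0, fr$f1, fr$phase)                    # along z
  lo <- afb1d(t(z$lo), fc$f0, fc$f1, fc$phase)             # along theta
  hi <- afb1d(t(z$hi), fc$f0, fc$f1, fc$phase)
  list(ll = t(lo$lo), lh = t(lo$hi),                       # lh: hi along theta
       hl = t(hi$lo), hh = t(hi$hi))
}

dt2_synthesis <- function(sub, bank, rt, ct, level) {
  fr <- tree_filters(bank, rt, level, synthesis = TRUE)
  fc <- tree_filters(bank, ct, level, synthesis = TRUE)
  zlo <- t(sfb1d(t(sub$ll), t(sub$lh), fc$f0, fc$f1, fc$phase))
  zhi <- t(sfb1d(t(sub$hl), t(sub$hh), fc$f0, fc$f1, fc$phase))
  sfb1d(zlo, zhi, fr$f0, fr$f1, fr$phase)
}

combo_names <- c("aa", "ab", "ba", "bb")

# four real subbands -> two complex subbands (unitary, energy preserving)
quads_to_complex <- function(w) {
  list(p = ((w$aa - w$bb) + 1i * (w$ab + w$ba)) / sqrt(2),
       m = ((w$aa + w$bb) + 1i * (w$ab - w$ba)) / sqrt(2))
}

complex_to_quads <- function(p, m) {
  list(aa = (Re(p) + Re(m)) / sqrt(2), bb = (Re(m) - Re(p)) / sqrt(2),
       ab = (Im(p) + Im(m)) / sqrt(2), ba = (Im(p) - Im(m)) / sqrt(2))
}

# orientation labels: lh pair ~ +-15 deg, hh ~ +-45 deg, hl ~ +-75 deg
orient_names <- c("d15p", "d15m", "d45p", "d45m", "d75p", "d75m")

pad_sizes <- function(nz, nt, levels) {
  mult <- 2L^levels
  c(z = ((mult - nz %% mult) %% mult), t = ((mult - nt %% mult) %% mult))
}

pad_map <- function(S, levels) {
  p <- pad_sizes(nrow(S), ncol(S), levels)
  if (p["z"] > 0) {
    n <- nrow(S)
    S <- rbind(S, S[n:(n - p["z"] + 1L), , drop = FALSE])  # symmetric on z
  }
  if (p["t"] > 0) S <- cbind(S, S[, 1:p["t"], drop = FALSE])  # periodic wrap
  S
}

#' Forward 2D dual-tree complex wavelet decomposition
#'
#' Decomposes a cylindrical change map (or plain matrix, rows = bone height z,
#' columns = circular angle theta) into `levels` dyadic scales. Each level
#' carries six complex orientation subbands (twelve real component arrays);
#' the terminal level keeps the four real scaling (lowpass) arrays, one per
#' tree pair. The theta axis is treated as circular and the z axis is
#' extended symmetrically; the input is padded to a multiple of `2^levels`
#' and the original shape is restored by [dtcwt_inverse()].
#'
#' @param map A [cyl_map] or numeric matrix.
#' @param levels Number of dyadic decomposition levels (default 4).
#' @param bank Filter bank from [dtcwt_filters()].
#' @return A `wavelet_decomposition` object.
#' @seealso [dtcwt_inverse()], [mad_threshold()], [synthesize_patterns()]
#' @export
dtcwt_forward <- function(map, levels = 4L, bank = dtcwt_filters()) {
  S <- if (inherits(map, "cyl_map")) map$S else map
  if (!is.matrix(S) || !is.numeric(S)) stop("map must be a numeric matrix or cyl_map")
  levels <- as.integer(levels)
  if (levels < 1L) cm_stop("levels must be >= 1", "parameter_error")
  if (min(dim(S)) < 2L^levels)
    cm_stop("map smaller than the decomposition depth allows", "size_error")
  X0 <- pad_map(S, levels)

  trees <- list()
  for (nm in combo_names) trees[[nm]] <- X0
  details <- vector("list", levels)
  for (lev in seq_len(levels)) {
    w <- list(lh = list(), hl = list(), hh = list())
    for (nm in combo_names) {
      rt <- substr(nm, 1, 1); ct <- substr(nm, 2, 2)
      sub <- dt2_analysis(trees[[nm]], bank, rt, ct, lev)
      trees[[nm]] <- sub$ll
      w$lh[[nm]] <- sub$lh; w$hl[[nm]] <- sub$hl; w$hh[[nm]] <- sub$hh
    }
    zlh <- quads_to_complex(w$lh)
    zhh <- quads_to_complex(w$hh)
    zhl <- quads_to_complex(w$hl)
    d <- list(zlh$p, zlh$m, zhh$p, zhh$m, zhl$p, zhl$m)
    names(d) <- orient_names
    details[[lev]] <- d
  }
  structure(list(lowpass = trees, details = details, levels = levels,
                 shape = dim(S), padded = dim(X0), bank = bank,
                 map_meta = if (inherits(map, "cyl_map"))
                   map[c("theta_bin_deg", "z_range", "label", "voxel_size")]
                 else NULL),
            class = "wavelet_decomposition")
}

#' Inverse 2D dual-tree complex wavelet transform
#'
#' Reconstructs the map from a decomposition: each of the four tree pairs is
#' inverted exactly and the four reconstructions are averaged, then the
#' padding applied by [dtcwt_forward()] is cropped off. With unmodified
#' coefficients this is an exact inverse (perfect reconstruction).
#'
#' @param dec A `wavelet_decomposition`.
#' @param drop_details Zero all detail subbands before inverting (gives the
#'   low-spatial-frequency component).
#' @param drop_lowpass Zero the terminal scaling arrays before inverting
#'   (gives the high-spatial-frequency component).
#' @return Numeric matrix with the shape of the original map.
#' @export
dtcwt_inverse <- function(dec, drop_details = FALSE, drop_lowpass = FALSE) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  bank <- dec$bank
  recon <- list()
  for (nm in combo_names) {
    ll <- dec$lowpass[[nm]]
    if (drop_lowpass) ll <- matrix(0, nrow(ll), ncol(ll))
    for (lev in seq(dec$levels, 1L)) {
      d <- dec$details[[lev]]
      qlh <- complex_to_quads(d$d15p, d$d15m)
      qhh <- complex_to_quads(d$d45p, d$d45m)
      qhl <- complex_to_quads(d$d75p, d$d75m)
      sub <- list(ll = ll, lh = qlh[[nm]], hl = qhl[[nm]], hh = qhh[[nm]])
      if (drop_details) {
        sub$lh <- 0 * sub$lh; sub$hl <- 0 * sub$hl; sub$hh <- 0 * sub$hh
      }
      rt <- substr(nm, 1, 1); ct <- substr(nm, 2, 2)
      ll <- dt2_synthesis(sub, bank, rt, ct, lev)
    }
    recon[[nm]] <- ll
  }
  out <- (recon$aa + recon$ab + recon$ba + recon$bb) / 4
  out[seq_len(dec$shape[1]), seq_len(dec$shape[2]), drop = FALSE]
}

#' Global MAD noise threshold for detail coefficients
#'
#' Estimates the noise scale from the single pooled vector of all detail
#' coefficient components across levels and orientations as
#' `tau = median(|d|) / 0.6745`, the median absolute deviation calibrated so
#' that Gaussian noise of standard deviation sigma yields `tau = sigma`.
#'
#' @param dec A `wavelet_decomposition`.
#' @return The threshold `tau` (coefficient units, i.e. the units of the map).
#' @export
mad_threshold <- function(dec) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  pool <- unlist(lapply(dec$details, function(lv)
    lapply(lv, function(d) c(Re(d), Im(d)))), use.names = FALSE)
  if (length(pool) == 0) cm_stop("decomposition has no detail coefficients", "empty_input_error")
  stats::median(abs(pool)) / 0.6745
}

#' Soft-threshold the detail coefficients of a decomposition
#'
#' Shrinks every complex detail coefficient towards zero by `tau` in
#' magnitude, preserving its phase: `d_hat = d * max(|d| - tau, 0) / |d|`.
#' Scaling (lowpass) coefficients are untouched.
#'
#' @param dec A `wavelet_decomposition`.
#' @param tau Non-negative threshold in coefficient units.
#' @return The thresholded `wavelet_decomposition`.
#' @export
soft_threshold <- function(dec, tau) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0)
    cm_stop("tau must be a single non-negative number", "parameter_error")
  if (tau == 0) return(dec)
  dec$details <- lapply(dec$details, function(lv) lapply(lv, function(d) {
    m <- Mod(d)
    scale <- ifelse(m > tau, (m - tau) / m, 0)
    d * scale
  }))
  dec
}

#' Synthesize low- and high-spatial-frequency patterns
#'
#' The low-frequency pattern reverses the decomposition keeping only the
#' terminal scaling coefficients (all details zeroed); the high-frequency
#' pattern reverses it keeping only the detail coefficients after soft
#' thresholding at `tau` (scaling zeroed). With `tau = 0` the two patterns
#' sum exactly to the input map.
#'
#' @param dec A `wavelet_decomposition`.
#' @param tau Soft threshold applied to the details of the high-frequency
#'   pattern; defaults to [mad_threshold()] of `dec`.
#' @return A `scale_patterns` object with matrices `low` and `high` (same
#'   shape and units as the source map) and the threshold `tau` used.
#' @export
synthesize_patterns <- function(dec, tau = mad_threshold(dec)) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  low <- dtcwt_inverse(dec, drop_details = TRUE)
  high <- dtcwt_inverse(soft_threshold(dec, tau), drop_lowpass = TRUE)
  structure(c(list(low = low, high = high, tau = tau), dec$map_meta),
            class = "scale_patterns")
}

#' Span of one terminal-level scaling coefficient
#'
#' After `levels` dyadic decimations one coarse-scale coefficient spans
#' `2^levels` rows and columns of the map: `2^levels * voxel_size` micrometres
#' of bone height and `2^levels * theta_bin_deg` degrees of circumference.
#'
#' @param levels Decomposition depth.
#' @param voxel_size Voxel size in micrometres.
#' @param theta_bin_deg Angular bin width in degrees.
#' @return Named vector: `z_um` (micrometres), `theta_deg` and `theta_rad`.
#' @export
coarse_scale_span <- function(levels = 4L, voxel_size = 10.4, theta_bin_deg = 1.0) {
  n <- 2^levels
  c(z_um = n * voxel_size, theta_deg = n * theta_bin_deg,
    theta_rad = n * theta_bin_deg * pi / 180)
}
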