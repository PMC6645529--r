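# Accuracy and activity metrics, spatial profiles, heatmap export.

#' Root-mean-square deviation
#'
#' `sqrt(mean((truth - estimate)^2))`, the systematic-error summary used to
#' compare imposed and recovered change fields.
#'
#' @param truth,estimate Equal-length numeric vectors.
#' @return RMSD (same units as the inputs).
#' @export
rmsd <- function(truth, estimate) {
  if (length(truth) != length(estimate))
    cm_stop("truth and estimate differ in length", "shape_error")
  if (length(truth) == 0) cm_stop("empty input", "empty_input_error")
  sqrt(mean((truth - estimate)^2))
}

#' Activation rate of a high-frequency change field
#'
#' The fraction `r = A_r / A_s` of surface voxels whose absolute
#' high-spatial-frequency change exceeds `threshold`; the framework's
#' resolution floor of one voxel is the default threshold.
#'
#' @param high A `change_field` holding the high-frequency pattern.
#' @param threshold Activation threshold in micrometres (default one
#'   voxel-equivalent).
#' @return An `activity_metrics` list: `r`, `A_r`, `A_s`, `threshold_um`.
#' @export
activation_rate <- function(high, threshold = NULL) {
  stopifnot(inherits(high, "change_field"))
  if (nrow(high) == 0) cm_stop("empty change field", "empty_input_error")
  if (is.null(threshold)) threshold <- attr(high, "voxel_size")
  if (threshold < 0) cm_stop("threshold must be non-negative", "parameter_error")
  A_s <- nrow(high)
  A_r <- sum(abs(high$change_um) > threshold)
  structure(list(r = A_r / A_s, A_r = A_r, A_s = A_s,
                 threshold_um = threshold),
            class = "activity_metrics")
}

#' @export
print.activity_metrics <- function(x, ...) {
  cat(sprintf("<activity_metrics> r = %.4f (%d of %d voxels above %.3g um)\n",
              x$r, x$A_r, x$A_s, x$threshold_um))
  invisible(x)
}

#' Spatially averaged profiles of scale patterns
#'
#' For each replicate (animal/time point): the mean over theta of the low
#' band (profile versus z), the mean over z (profile versus theta), and the
#' same aggregations of the absolute high band (high-frequency activity is
#' zero-mean, so magnitudes are integrated). Across replicates the
#' standard deviation (n - 1 denominator) is reported per profile position.
#'
#' @param patterns A `scale_patterns` object or a list of them with a
#'   common shape.
#' @return List of data frames: `z_profiles`, `theta_profiles` (columns
#'   `position`, `low_mean`, `low_sd`, `high_mean`, `high_sd`).
#' @export
spatial_profiles <- function(patterns) {
  if (inherits(patterns, "scale_patterns")) patterns <- list(patterns)
  stopifnot(all(vapply(patterns, inherits, logical(1), "scale_patterns")))
  shp <- dim(patterns[[1]]$low)
  for (p in patterns)
    if (!all(dim(p$low) == shp)) cm_stop("pattern shape mismatch", "shape_error")
  lowz <- sapply(patterns, function(p) rowMeans(p$low))
  lowt <- sapply(patterns, function(p) colMeans(p$low))
  hiz <- sapply(patterns, function(p) rowMeans(abs(p$high)))
  hit <- sapply(patterns, function(p) colMeans(abs(p$high)))
  sd_or_0 <- function(m) if (ncol(m) > 1) apply(m, 1, stats::sd) else rep(0, nrow(m))
  lowz <- as.matrix(lowz); lowt <- as.matrix(lowt)
  hiz <- as.matrix(hiz); hit <- as.matrix(hit)
  list(z_profiles = data.frame(position = seq_len(shp[1]) - 1L,
                               low_mean = rowMeans(lowz), low_sd = sd_or_0(lowz),
                               high_mean = rowMeans(hiz), high_sd = sd_or_0(hiz)),
       theta_profiles = data.frame(position = seq_len(shp[2]) - 1L,
                                   low_mean = rowMeans(lowt), low_sd = sd_or_0(lowt),
                                   high_mean = rowMeans(hit), high_sd = sd_or_0(hit)))
}

#' Accuracy report for one scenario run
#'
#' RMSD and error quantiles between imposed and recovered low/high patterns
#' over the surface voxels.
#'
#' @param truth Data frame `x, y, z, low_um, high_um` (ground truth).
#' @param low_est,high_est `change_field`s of the recovered patterns on the
#'   same voxels (matched by coordinate).
#' @param scenario Scenario id string.
#' @return An `accuracy_report` data frame: one row per band with RMSD (um)
#'   and error quantiles.
#' @export
accuracy_report <- function(truth, low_est, high_est, scenario = "") {
  key <- function(df) paste(df$x, df$y, df$z)
  i_low <- match(key(truth), key(low_est))
  i_high <- match(key(truth), key(high_est))
  ok <- !is.na(i_low) & !is.na(i_high)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  mk <- function(band, err) {
    q <- stats::quantile(err, qs, names = FALSE)
    data.frame(scenario = scenario, band = band,
               rmsd_um = sqrt(mean(err^2)), n = length(err),
               q05 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q95 = q[5])
  }
  err_low <- low_est$change_um[i_low[ok]] - truth$low_um[ok]
  err_high <- high_est$change_um[i_high[ok]] - truth$high_um[ok]
  rep <- rbind(mk("low", err_low), mk("high", err_high))
  class(rep) <- c("accuracy_report", "data.frame")
  rep
}

#' Export a map or pattern as a PNG heatmap
#'
#' Diverging colour scale (warm = outward-normal evolution, i.e. periosteal
#' formation / endosteal resorption), symmetric about zero.
#'
#' @param S Numeric matrix (rows = z, columns = theta).
#' @param path Output PNG path.
#' @param main Plot title.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(S, path, main = "") {
  lim <- max(abs(S), na.rm = TRUE)
  if (lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(255)
  grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  graphics::image(x = seq_len(ncol(S)) - 1L, y = seq_len(nrow(S)) - 1L,
                  z = t(S), zlim = c(-lim, lim), col = pal,
                  xlab = "theta (bins)", ylab = "z (slices)", main = main,
                  useRaster = TRUE)
  invisible(path)
}
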