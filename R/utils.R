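# classed error helper: every domain error carries a "cortimap_<class>"
# condition class so callers and tests can discriminate failure modes
cm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("cortimap_", class), "cortimap_error")))
}

cm_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("cortimap_", class), "cortimap_warning")))
}

# 0-based voxel coordinates of TRUE entries of a 3D logical array, as an
# integer matrix with columns x, y, z
which_voxels <- function(mask) {
  w <- which(mask)
  d <- dim(mask)
  w0 <- w - 1L
  cbind(x = w0 %% d[1],
        y = (w0 %/% d[1]) %% d[2],
        z = w0 %/% (d[1] * d[2]))
}

# linear indices (1-based) from 0-based voxel coordinate matrix
voxel_index <- function(coords, d) {
  1L + coords[, 1] + d[1] * (coords[, 2] + d[2] * coords[, 3])
}
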