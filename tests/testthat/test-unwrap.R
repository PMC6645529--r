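test_that("unwrapping convex cross-sections is injective and anchored at +x", {
  ph <- tiny_phantom()
  ss <- label_surfaces(ph)
  phi0 <- surface_field(ph, ss, "periosteum")
  phi1 <- phi0; phi1$phi <- phi0$phi + 2
  ch <- geometry_change(phi0, phi1)
  uw <- unwrap_surface(ch, ss)
  expect_equal(uw$report$e_r, 0)
  expect_equal(uw$report$N_mis, 0L)
  expect_identical(ncol(uw$map$S), 360L)

  # a surface voxel on the +x ray from the centroid maps to column theta = 0
  sv <- ss$surfaces[[1]]$voxels
  ctr <- (dim(ph$data)[1] - 1) / 2
  cand <- sv[abs(sv[, 2] - ctr) < 0.51 & sv[, 1] > ctr, , drop = FALSE]
  expect_gt(nrow(cand), 0)
  # bin of that voxel: theta measured from +x
  theta <- (atan2(cand[, 2] - ctr, cand[, 1] - ctr) * 180 / pi) %% 360
  expect_true(all(round(theta) %% 360 %in% c(0, 1, 359)))

  # round trip is the identity on convex slices
  bp <- backproject(uw$map, ss)
  m <- match(paste(bp$x, bp$y, bp$z), paste(ch$x, ch$y, ch$z))
  expect_equal(bp$change_um, ch$change_um[m])
})

test_that("the surjection rule keeps the largest absolute change", {
  # synthetic one-slice field: three voxels at the same angle, a disc region
  d <- c(32L, 32L, 9L)
  region <- array(FALSE, d)
  g <- expand.grid(x = 0:31, y = 0:31)
  rr <- sqrt((g$x - 16)^2 + (g$y - 16)^2)   # centroid exactly at (16, 16)
  disc <- matrix(rr <= 12, 32, 32)
  for (k in 1:9) region[, , k] <- disc
  surfaces <- structure(list(
    surfaces = list(list(label = "periosteum", voxels = NULL,
                         region = region, n_boundary = 0)),
    voxel_size = 1), class = "surface_set")
  # three voxels on the +x ray at different radii (all in angle bin 0) with
  # changes +1, -4, +2 -> kept value -4, two voxels mis-projected
  mkrow <- function(x, y, z, ch) data.frame(x = x, y = y, z = z, change_um = ch)
  df <- rbind(mkrow(20, 16, 4, 1), mkrow(24, 16, 4, -4), mkrow(26, 16, 4, 2),
              mkrow(10, 25, 4, 0.5), mkrow(15, 27, 4, 0.25),
              mkrow(5, 16, 4, 1))
  fld <- structure(df, label = "periosteum", dt = 1, voxel_size = 1,
                   dims = d, class = c("change_field", "data.frame"))
  uw <- unwrap_surface(fld, surfaces)
  expect_identical(uw$report$N_tot, 6L)
  expect_identical(uw$report$N_mis, 2L)
  expect_equal(uw$report$e_r, 2 / 6)
  expect_equal(uw$map$S[1, 1], -4)   # bin 0 kept the largest |change|
})

test_that("rotating the volume shifts the map circularly", {
  ph <- make_phantom(shape = c(64, 64, 48), outer_radius = 20, wall = 8,
                     concavity = 0.12)
  rot270 <- function(m) {
    # in-plane array rotation: theta -> theta - 90 degrees, i.e. the map
    # shifts circularly by +270 columns at 1-degree bins
    d <- dim(m$data)
    out <- array(FALSE, d)
    for (k in seq_len(d[3])) out[, , k] <- t(m$data[, , k])[, d[1]:1]
    binary_mask(out, m$voxel_size)
  }
  unwrap_growth <- function(m) {
    ss <- label_surfaces(m)
    phi0 <- surface_field(m, ss, "periosteum")
    set.seed(42)
    imp <- impose_activity(phi0, scenario_spec("growth", c = 2, noise_sd = 0,
                                               misalign_sd = 0), m)
    unwrap_surface(geometry_change(phi0, imp$phi_t1), ss)$map$S
  }
  S <- unwrap_growth(ph)
  S_rot <- unwrap_growth(rot270(ph))
  shift_cols <- function(S, k) S[, ((seq_len(ncol(S)) - 1 - k) %% ncol(S)) + 1]
  mismatch <- vapply(c(0, 90, 180, 270),
                     function(k) max(abs(S_rot - shift_cols(S, k))), numeric(1))
  expect_equal(which.min(mismatch), 4L)   # the 270-column shift matches
  expect_lt(mismatch[4], 1e-9)
})

test_that("constant maps survive binning and back-projection", {
  ph <- tiny_phantom()
  ss <- label_surfaces(ph)
  phi0 <- surface_field(ph, ss, "periosteum")
  phi1 <- phi0; phi1$phi <- phi0$phi + 1
  ch <- geometry_change(phi0, phi1)
  uw <- unwrap_surface(ch, ss)
  expect_true(all(uw$map$S == 10.4))
  bp <- backproject(uw$map, ss)
  expect_true(all(bp$change_um == 10.4))
})

test_that("concave phantoms keep the projection error rate under 5 percent", {
  specs <- list(list(concavity = 0.08), list(concavity = 0.12),
                list(concavity = 0.16), list(concavity = 0.12, taper = 0.2),
                list(concavity = 0.16, outer_radius = 24))
  for (sp in specs) {
    ph <- do.call(make_phantom,
                  c(list(shape = c(72, 72, 40), wall = 9),
                    c(sp, if (is.null(sp$outer_radius)) list(outer_radius = 22))))
    ss <- label_surfaces(ph)
    phi0 <- surface_field(ph, ss, "periosteum")
    phi1 <- phi0; phi1$phi <- phi0$phi + 2
    uw <- unwrap_surface(geometry_change(phi0, phi1), ss)
    expect_lt(uw$report$e_r, 0.05)
  }
})

test_that("cylindrical maps round-trip through CSV + sidecar", {
  ph <- tiny_phantom()
  ss <- label_surfaces(ph)
  phi0 <- surface_field(ph, ss, "periosteum")
  phi1 <- phi0; phi1$phi <- phi0$phi + 1
  uw <- unwrap_surface(geometry_change(phi0, phi1), ss)
  td <- withr::local_tempdir()
  p <- write_cyl_map(uw$map, file.path(td, "map.csv"))
  back <- read_cyl_map(p)
  expect_equal(back$S, uw$map$S, tolerance = 1e-9)
  expect_identical(back$valid, uw$map$valid)
  expect_identical(back$label, "periosteum")
})
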