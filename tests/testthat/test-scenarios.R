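test_that("phantom construction satisfies its topological contract", {
  ph <- tiny_phantom()
  labs <- vapply(label_surfaces(ph)$surfaces, function(s) s$label, character(1))
  expect_identical(labs, c("periosteum", "endosteum_1"))
  expect_error(make_phantom(wall = 2), class = "cortimap_topology_error")
  expect_error(make_phantom(shape = c(64, 64, 64), outer_radius = 40),
               class = "cortimap_parameter_error")

  # analytic signed-distance oracle for the straight tube: distance of an
  # interior bone voxel to the nearer of the two cylinders
  ss <- label_surfaces(ph)
  phi <- surface_field(ph, ss, "periosteum")
  d <- dim(ph$data)
  ctr <- (d[1] - 1) / 2
  idx <- which(ph$data)
  w0 <- idx - 1L
  x <- w0 %% d[1]; y <- (w0 %/% d[1]) %% d[2]
  r <- sqrt((x - ctr)^2 + (y - ctr)^2)
  # periosteal field: inside the filled tube, analytic distance = R_out - r
  analytic <- 20 - r
  expect_lt(max(abs(phi$phi[idx] - analytic)), 0.6)
})

test_that("imposed activity matches the scenario definitions", {
  ph <- tiny_phantom()
  ss <- label_surfaces(ph)
  phi0 <- surface_field(ph, ss, "periosteum")

  # null scenario: phi unchanged, all-zero ground truth
  set.seed(1)
  imp0 <- impose_activity(phi0, scenario_spec("null", quantise = FALSE), ph)
  expect_identical(imp0$phi_t1$phi, phi0$phi)
  expect_true(all(imp0$truth$low_um == 0) && all(imp0$truth$high_um == 0))

  # growth c = 3 before quantisation: change is exactly +3 voxels (31.2 um)
  set.seed(2)
  impg <- impose_activity(phi0, scenario_spec("growth", c = 3, quantise = FALSE), ph)
  chg <- geometry_change(phi0, impg$phi_t1)
  expect_equal(unique(chg$change_um), 3 * 10.4)
  expect_true(all(impg$truth$low_um == 3 * 10.4))

  # local activity: activated fraction b within the band, zero outside
  # (larger phantom so the band holds >= 1e4 surface sites)
  ph <- small_phantom()
  ss <- label_surfaces(ph)
  phi0 <- surface_field(ph, ss, "periosteum")
  set.seed(3)
  spec <- scenario_spec("local", a = 3, b = 0.3, band = c(30, 130),
                        quantise = FALSE)
  impl <- impose_activity(phi0, spec, ph)
  tr <- impl$truth
  inband <- tr$z >= 30 & tr$z <= 130
  expect_gt(sum(inband), 1e4)
  frac <- mean(tr$high_um[inband] != 0)
  expect_lt(abs(frac - 0.3), 0.02)
  expect_true(all(tr$high_um[!inband] == 0))
  expect_true(all(abs(tr$high_um) <= 3 * 10.4))

  # non-integral growth with quantisation refused
  expect_error(scenario_spec("growth", c = 2.5, quantise = TRUE),
               class = "cortimap_parameter_error")
})

test_that("repeat-scan simulation is identity at zero noise and reproducible", {
  ph <- tiny_phantom()
  scan <- phantom_scan(ph)
  spec0 <- scenario_spec("null", noise_sd = 0, misalign_sd = 0)
  expect_identical(simulate_repeat_scan(scan, spec0)$data, scan$data)

  # segmentation robustness: Dice of noisy-scan mask vs clean mask > 0.98
  set.seed(6)
  noisy <- simulate_repeat_scan(scan, scenario_spec("null", noise_sd = 0.05,
                                                    misalign_sd = 0))
  m <- otsu_segment(gaussian_smooth(noisy))
  expect_gt(dice(m$data, ph$data), 0.98)

  # identical seeds give bit-identical scenario volumes and truth
  s1 <- scenario_volumes(scenario_spec("combined", seed = 11), phantom = ph)
  s2 <- scenario_volumes(scenario_spec("combined", seed = 11), phantom = ph)
  expect_identical(s1$baseline$data, s2$baseline$data)
  expect_identical(s1$followup$data, s2$followup$data)
  expect_identical(s1$truth, s2$truth)
})

test_that("simulated misalignment is recovered by registration", {
  img <- render_blobs()
  spec <- scenario_spec("null", noise_sd = 0.01, misalign_sd = 0.3)
  set.seed(12)
  base <- simulate_repeat_scan(img, spec, misalign = FALSE)
  rep1 <- simulate_repeat_scan(img, spec, misalign = TRUE)
  true_tf <- attr(rep1, "true_transform")
  tf <- rigid_register(rep1, base)
  # the registration recovers the inverse of the applied perturbation
  expect_lt(max(abs(tf$translation + true_tf$translation)), 0.2)
})

test_that("pure growth without quantisation is recovered almost exactly", {
  ph <- tiny_phantom()
  ss <- label_surfaces(ph)
  phi0 <- surface_field(ph, ss, "periosteum")
  set.seed(7)
  spec <- scenario_spec("growth", c = 3, quantise = FALSE,
                        noise_sd = 0, misalign_sd = 0)
  imp <- impose_activity(phi0, spec, ph)
  uw <- unwrap_surface(geometry_change(phi0, imp$phi_t1), ss)
  pat <- synthesize_patterns(dtcwt_forward(uw$map), 0)
  low <- backproject(uw$map, ss, values = pat$low)
  high <- backproject(uw$map, ss, values = pat$high)
  expect_lt(rmsd(imp$truth$low_um, low$change_um) / 10.4, 0.2)
  expect_lt(rmsd(imp$truth$high_um, high$change_um) / 10.4, 0.2)
})
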