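test_that("static sphere rasterization reproduces the analytic volume", {
  spec <- fit_grid(phantom_spec(spacing = c(0.1, 0.1, 0.1)),
                   motion_trajectory(0), headroom_cm = 0.5)
  gtv <- segment_gtv(rasterize_phantom(spec))
  expect_lt(abs(volume_cc(gtv) / capsule_volume(1.5, 0) - 1), 0.02)

  # voxel-count volume converges to (4/3) pi r^3 as spacing shrinks
  fine <- fit_grid(phantom_spec(spacing = c(0.05, 0.05, 0.05)),
                   motion_trajectory(0), headroom_cm = 0.3)
  gtv_fine <- segment_gtv(rasterize_phantom(fine))
  expect_lt(abs(volume_cc(gtv_fine) / capsule_volume(1.5, 0) - 1), 0.01)
})

test_that("rasterization is translation-equivariant", {
  spec <- fit_grid(phantom_spec(spacing = c(0.1, 0.1, 0.1)),
                   motion_trajectory(2), headroom_cm = 0.5)
  v0 <- rasterize_phantom(spec, c(0, 0, 0))
  v2 <- rasterize_phantom(spec, c(0, 0, 2))  # 20-voxel shift along z
  nz <- dim(v0$values)[3]
  expect_identical(v0$values[, , 1:(nz - 20)], v2$values[, , 21:nz])
})

test_that("degenerate phantom inputs are rejected", {
  expect_error(phantom_spec(target_radius = 0), "positive")
  expect_error(phantom_spec(target_intensity = -700, lung_intensity = 0),
               "exceed")
  spec <- coarse_spec()
  expect_error(rasterize_phantom(spec, c(0, 0, 10)), "displacement")
  expect_error(rasterize_phantom(phantom_spec()), "fit_grid")
})

test_that("zero amplitude is a fixed point of every acquisition mode", {
  spec <- coarse_spec()
  traj <- motion_trajectory(0)
  static <- rasterize_phantom(spec)
  stack <- simulate_phase_stack(spec, traj)
  for (p in stack$phases) expect_equal(p$values, static$values)
  fb <- simulate_free_breathing(spec, traj)
  expect_equal(fb$values, static$values)
  fb_snap <- simulate_free_breathing(spec, traj,
                                     scan_model(integration = "snapshot"))
  expect_equal(fb_snap$values, static$values)
})

test_that("phase 0%/50% targets sit at the motion extremes", {
  A <- 1
  traj <- motion_trajectory(A)
  spec <- fit_grid(phantom_spec(), traj)
  stack <- simulate_phase_stack(spec, traj)
  g0 <- segment_gtv(get_phase(stack, 0))
  g50 <- segment_gtv(get_phase(stack, 0.5))
  half_voxel <- spec$spacing[3] / 2
  expect_lt(abs(centroid_z(g0) - A), half_voxel)
  expect_lt(abs(centroid_z(g50) + A), half_voxel)

  # residual intra-bin motion enlarges the SI extent, but by less than the
  # within-bin excursion bound A * (1 - cos(pi/10))
  extent <- si_extent(g0) + spec$spacing[3]
  bound <- A * (1 - cos(pi / 10))
  expect_gt(extent, 3.0 - spec$spacing[3])
  expect_lt(extent, 3.0 + bound + 2 * spec$spacing[3])
})

test_that("free-breathing interplay truncates a fast-moving target", {
  traj <- motion_trajectory(2)
  spec <- fit_grid(phantom_spec(spacing = c(0.15, 0.15, 0.125)), traj)
  fb <- simulate_free_breathing(spec, traj, scan_model(start_phase = 0.125))
  gtv <- segment_gtv(fb)
  expect_lt(volume_cc(gtv), capsule_volume(1.5, 0))
})

test_that("couch and bin-count guards fire", {
  expect_error(scan_model(slab_time_s = 0), "couch speed")
  expect_error(scan_model(slab_thickness_cm = -1), "couch speed")
  expect_warning(
    simulate_phase_stack(coarse_spec(), motion_trajectory(0),
                         acquisition_config(n_bins = 5)),
    "10")
})

test_that("virtual patients are reproducible and consistent with 1-D motion", {
  traj3 <- motion_trajectory(1.2, lateral_amplitude = 0.3, ap_amplitude = 0.4,
                             period_jitter_sd = 0.2,
                             amplitude_jitter_sd = 0.1, seed = 42L)
  spec <- fit_grid(phantom_spec(spacing = c(0.25, 0.25, 0.25)), traj3)
  vp1 <- generate_virtual_patient(traj3, spec = spec)
  vp2 <- generate_virtual_patient(traj3, spec = spec)
  expect_identical(vp1$stack$phases[[3]]$values, vp2$stack$phases[[3]]$values)
  expect_identical(vp1$fb$values, vp2$fb$values)

  expect_equal(vp1$ground_truth$m_amplitude, 1.3)

  # regular pure-SI motion reduces to the phantom pipeline
  si <- motion_trajectory(1.2)
  spec_si <- fit_grid(phantom_spec(spacing = c(0.25, 0.25, 0.25)), si)
  vp <- generate_virtual_patient(si, spec = spec_si)
  ref <- simulate_phase_stack(spec_si, si)
  expect_equal(vp$stack$phases[[1]]$values, ref$phases[[1]]$values)
  expect_equal(vp$ground_truth$m_peak_to_peak, 2.4, tolerance = 1e-3)

  expect_error(generate_virtual_patient(motion_trajectory(0)), "nonzero")
})
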