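test_that("threshold segmentation recovers the sphere and handles degeneracies", {
  spec <- fit_grid(phantom_spec(spacing = c(0.1, 0.1, 0.1)),
                   motion_trajectory(0), headroom_cm = 0.5)
  gtv <- segment_gtv(rasterize_phantom(spec))
  expect_lt(abs(volume_cc(gtv) / 14.137 - 1), 0.02)

  flat <- image_volume(array(-700, c(4, 4, 4)), c(0.2, 0.2, 0.2))
  expect_warning(empty <- segment_gtv(flat), "empty")
  expect_equal(volume_cc(empty), 0)

  # two disjoint supra-threshold blobs: only the larger survives
  v <- array(-700, c(12, 12, 12))
  v[2:4, 2:4, 2:4] <- 0        # 27 voxels
  v[9:10, 9:10, 9:10] <- 0     # 8 voxels
  img <- image_volume(v, c(0.1, 0.1, 0.1))
  g <- segment_gtv(img)
  expect_equal(sum(g$mask), 27L)
  expect_true(all(g$mask[2:4, 2:4, 2:4]))
})

test_that("boolean ITV constructions obey union algebra", {
  spec <- coarse_spec()
  g <- segment_gtv(rasterize_phantom(spec))
  same10 <- rep(list(g), 10)
  expect_equal(build_itv_gold(same10)$mask, g$mask)
  expect_error(build_itv_gold(same10[1:9]), "10")

  traj <- motion_trajectory(1)
  spec_m <- fit_grid(phantom_spec(spacing = c(0.2, 0.2, 0.2)), traj)
  stack <- simulate_phase_stack(spec_m, traj)
  gtvs <- lapply(stack$phases, segment_gtv)
  itv <- build_itv_gold(gtvs)
  expect_gte(volume_cc(itv), max(vapply(gtvs, volume_cc, numeric(1))))

  # FB-Aug: union of the three inputs, each contained in the result
  empty <- structure_mask(array(FALSE, dim(gtvs[[1]]$mask)),
                          gtvs[[1]]$spacing, gtvs[[1]]$origin)
  aug <- build_itv_fb_aug(empty, gtvs[[1]], gtvs[[6]])
  expect_equal(aug$mask, gtvs[[1]]$mask | gtvs[[6]]$mask)
  aug2 <- build_itv_fb_aug(g, g, g)
  expect_equal(aug2$mask, g$mask)

  shifted <- structure_mask(g$mask, g$spacing, g$origin + 1)
  expect_error(mask_union(list(g, shifted)), "same grid")
})

test_that("margin expansion matches its analytic sphere-growth oracle", {
  spec <- fit_grid(phantom_spec(spacing = c(0.1, 0.1, 0.1)),
                   motion_trajectory(0), headroom_cm = 1)
  g <- segment_gtv(rasterize_phantom(spec))
  target <- capsule_volume(2, 0)  # 33.51 cc

  # centre-to-centre convention: within 3% (slightly under, lattice loss)
  plain <- expand_margin(g, margin_spec(5, 5), surface_correction = FALSE)
  expect_lt(abs(volume_cc(plain) / target - 1), 0.03)

  # surface-corrected default: a controlled sub-voxel overshoot (within 6%),
  # never smaller than the plain convention
  corr <- expand_margin(g, margin_spec(5, 5))
  expect_lt(abs(volume_cc(corr) / target - 1), 0.06)
  expect_true(all(corr$mask[plain$mask]))

  # zero margin is the identity
  expect_equal(expand_margin(g, margin_spec(0, 0))$mask, g$mask)
  expect_error(margin_spec(-1, 5), "non-negative")
})

test_that("anisotropic expansion of a point has the structuring-element extents", {
  m <- array(FALSE, c(31, 31, 41))
  m[16, 16, 21] <- TRUE
  pt <- structure_mask(m, c(0.1, 0.1, 0.1))
  ptv <- expand_margin(pt, margin_spec(5, 10))
  expect_lt(abs(si_extent(ptv) - 2.0), 2 * 0.1 + 1e-9)
  expect_lt(abs(axial_extent(ptv) - 1.0), 2 * 0.1 + 1e-9)
})

test_that("dilation is monotone and distributes over union", {
  set.seed(11)
  for (i in 1:5) {
    a <- random_mask()
    b <- random_mask()
    small <- expand_margin(a, margin_spec(2, 2))
    big <- expand_margin(a, margin_spec(4, 4))
    expect_true(all(big$mask[small$mask]))
    expect_true(all(small$mask[a$mask]))
    u <- mask_union(list(a, b))
    lhs <- expand_margin(u, margin_spec(3, 3))
    rhs <- mask_union(list(expand_margin(a, margin_spec(3, 3)),
                           expand_margin(b, margin_spec(3, 3))))
    expect_equal(lhs$mask, rhs$mask)
  }
})

test_that("run_strategy builds each PTV and names missing inputs", {
  traj <- motion_trajectory(0.5)
  spec <- fit_grid(phantom_spec(spacing = c(0.2, 0.2, 0.2)), traj)
  stack <- simulate_phase_stack(spec, traj)
  fb <- simulate_free_breathing(spec, traj)
  expect_error(run_strategy("GS"), "stack")
  expect_error(run_strategy("FB"), "fb_image")
  expect_error(run_strategy("FB_AUG", stack = stack), "fb_image")

  gs <- run_strategy("GS", stack = stack)
  expect_identical(gs$strategy, "GS")
  expect_identical(gs$label, "PTV")
  expect_gt(volume_cc(gs), volume_cc(attr(gs, "itv")))

  # the FB PTV adds the 10 mm SI margin on top of the GTV extent
  static <- coarse_spec(spacing = c(0.1, 0.1, 0.1), headroom = 1.3)
  fb_static <- rasterize_phantom(static)
  fb_ptv <- run_strategy("FB", fb_image = fb_static)
  fb_gtv <- attr(fb_ptv, "itv")
  expect_lt(abs(si_extent(fb_ptv) - (si_extent(fb_gtv) + 2.0)), 2 * 0.1 + 1e-9)
})
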