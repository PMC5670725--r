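test_that("dice matches an exhaustive voxel-count oracle on random masks", {
  set.seed(101)
  sp <- c(0.1, 0.1, 0.1)
  for (i in 1:100) {
    a <- array(stats::runif(512) < 0.3, c(8, 8, 8))
    b <- array(stats::runif(512) < 0.3, c(8, 8, 8))
    ma <- structure_mask(a, sp)
    mb <- structure_mask(b, sp)
    inter <- sum(a & b)
    expected <- if (sum(a) + sum(b) == 0) 1 else 2 * inter / (sum(a) + sum(b))
    expect_identical(dice(ma, mb), expected)
    expect_identical(dice(ma, mb), dice(mb, ma))
  }
})

test_that("dice honours its boundary conventions", {
  sp <- c(0.1, 0.1, 0.1)
  full <- structure_mask(array(TRUE, c(4, 4, 4)), sp)
  none <- structure_mask(array(FALSE, c(4, 4, 4)), sp)
  expect_equal(dice(full, full), 1)
  expect_equal(dice(none, none), 1)   # both empty: identical sets
  expect_equal(dice(full, none), 0)   # one empty: no overlap

  # two unit cubes overlapping half their volume
  a <- array(FALSE, c(20, 20, 20)); a[1:10, 1:10, 1:10] <- TRUE
  b <- array(FALSE, c(20, 20, 20)); b[6:15, 1:10, 1:10] <- TRUE
  expect_equal(dice(structure_mask(a, sp), structure_mask(b, sp)), 0.5)

  other <- structure_mask(array(TRUE, c(4, 4, 4)), c(0.2, 0.2, 0.2))
  expect_error(dice(full, other), "same grid")
})

test_that("volume and ratio arithmetic are exact", {
  sp <- c(0.1, 0.1, 0.1)
  m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(volume_cc(structure_mask(m, sp)), 1.0)  # 1000 voxels
  expect_equal(volume_cc(structure_mask(array(FALSE, c(4, 4, 4)), sp)), 0)

  expect_equal(ptv_ratio(48.4, 48.4), 1)
  expect_equal(ptv_ratio(42.6, 48.4), 0.88, tolerance = 0.005)
  expect_error(ptv_ratio(10, 0), "positive")

  # R and DSC are decoupled: equal volumes, zero overlap
  a <- array(FALSE, c(10, 10, 10)); a[1:3, , ] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[8:10, , ] <- TRUE
  ma <- structure_mask(a, sp); mb <- structure_mask(b, sp)
  expect_equal(ptv_ratio(volume_cc(ma), volume_cc(mb)), 1)
  expect_equal(dice(ma, mb), 0)
})

test_that("motion vector is the Euclidean norm of the displacements", {
  expect_equal(motion_vector(0, 0, 1.5), 1.5)
  expect_equal(motion_vector(0.3, 0.4, 1.2), 1.3)
  expect_equal(motion_vector(0, 0, 0), 0)
})

test_that("capsule volume has the closed form and is linear in sweep length", {
  expect_equal(capsule_volume(1.5, 0), (4 / 3) * pi * 1.5^3)
  expect_equal(capsule_volume(2, 2), (4 / 3) * pi * 8 + pi * 4 * 2)
  expect_error(capsule_volume(-1, 0), "positive")
  expect_error(capsule_volume(2, -1), "non-negative")

  # finite-difference slope equals pi r^2
  for (r in c(0.7, 1.5, 2)) {
    slope <- (capsule_volume(r, 3.5) - capsule_volume(r, 1.5)) / 2
    expect_equal(slope, pi * r^2)
  }
})

test_that("agreement classification uses the strict 0.700 cutoff", {
  expect_identical(classify_agreement(0.701), "good")
  expect_identical(classify_agreement(0.700), "poor")
  expect_identical(classify_agreement(0.408), "poor")
  expect_error(classify_agreement(1.2), "0, 1")
  expect_error(classify_agreement(-0.1), "0, 1")
})

test_that("overlap_result bundles volumes, ratio and DSC consistently", {
  sp <- c(0.1, 0.1, 0.1)
  a <- array(FALSE, c(10, 10, 10)); a[1:6, , ] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[4:10, , ] <- TRUE
  res <- overlap_result(structure_mask(a, sp, strategy = "MIP"),
                        structure_mask(b, sp))
  expect_equal(res$v_x, 0.6)
  expect_equal(res$v_gs, 0.7)
  expect_equal(res$intersection, 0.3)
  expect_equal(res$dsc, 2 * 0.3 / 1.3)
  expect_equal(res$r_ratio, 6 / 7)
  expect_identical(res$strategy, "MIP")
})
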