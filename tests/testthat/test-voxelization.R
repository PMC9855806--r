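# Heme frame construction, occupancy grids, and discarding masks.

test_that("heme frame has the documented fixed point and equivariance", {
  # canonical porphyrin: identity rotation, zero origin
  fr <- compute_heme_frame(make_porphyrin())
  expect_equal(fr$axes, diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(det(fr$axes), 1, tolerance = 1e-12)

  # pure translation moves the origin and leaves the axes alone
  fr2 <- compute_heme_frame(make_porphyrin(translation = c(5, -3, 2)))
  expect_equal(fr2$axes, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fr2$origin, c(5, -3, 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # round trip over 100 random proper rotations: axes . R = identity
  for (s in 1:100) {
    R <- random_rotation(seed = s)
    tr <- with_seed_test(1000 + s, stats::runif(3, -30, 30))
    fr <- compute_heme_frame(make_porphyrin(R, tr))
    expect_lt(max(abs(fr$axes %*% R - diag(3))), 1e-9)
    expect_lt(max(abs(fr$origin - tr)), 1e-9)
    expect_equal(det(fr$axes), 1, tolerance = 1e-9)
  }

  # degenerate (collinear) methines are refused
  bad <- make_porphyrin()
  mets <- match(c("CHA", "CHB", "CHC", "CHD"), bad$atom_name)
  bad[mets, c("x", "y", "z")] <- cbind(1:4, 1:4, 0)
  expect_error(compute_heme_frame(bad), "collinear")
})

test_that("voxelization matches the brute-force oracle", {
  # empty input -> all-zero grid
  g0 <- voxelize_site(toy_site(), edge = 8, voxel = 1)
  expect_equal(sum(g0), 0)
  expect_equal(dim(g0), c(8L, 8L, 8L, 4L))

  # single carbon at the frame origin -> exactly one voxel, C channel
  g1 <- voxelize_site(toy_site(make_atoms(c(0, 0, 0))), edge = 8,
                      voxel = 1)
  expect_equal(sum(g1), 1)
  expect_equal(sum(g1[, , , "C"]), 1)
  expect_equal(which(g1[, , , "C"] == 1L), 5L + 8L * 4L + 64L * 4L)

  # oracle equivalence on 20 random toy sites, including posed hemes
  for (s in 1:20) {
    site <- random_toy_site(s)
    fr <- compute_heme_frame(site$heme)
    expect_identical(
      unclass(voxelize_site(site, fr, edge = 8, voxel = 1))[],
      unclass(voxelize_oracle(site, fr, edge = 8, voxel = 1))[])
  }

  # frame invariance: rigidly moving the whole site leaves the grid alone
  base <- random_toy_site(99)
  g_base <- voxelize_site(base, edge = 12, voxel = 1)
  R <- random_rotation(seed = 123); tr <- c(7, -2, 4)
  moved <- base
  for (part in c("heme", "protein")) {
    m <- as.matrix(moved[[part]][, c("x", "y", "z")])
    moved[[part]][, c("x", "y", "z")] <- m %*% t(R) +
      rep(tr, each = nrow(m))
  }
  moved$iron <- drop(R %*% base$iron + tr)
  g_moved <- voxelize_site(moved, edge = 12, voxel = 1)
  expect_equal(unclass(g_moved)[], unclass(g_base)[])

  # channel conservation: occupied voxels per channel <= atoms of element
  site <- random_toy_site(7, n_atoms = 60)
  g <- voxelize_site(site, edge = 24, voxel = 1)
  for (e in c("C", "N", "O", "S"))
    expect_lte(sum(g[, , , e]), sum(site$protein$element == e))

  # the vdw rule marks at least the voxels of the center rule
  gv <- voxelize_site(site, edge = 24, voxel = 1, rule = "vdw")
  expect_true(all(gv[unclass(g) == 1L] == 1L))
})

test_that("discarding masks zero exactly the advertised voxels", {
  site <- random_toy_site(13, n_atoms = 120, spread = 11)
  g <- voxelize_site(site, edge = 24, voxel = 1)

  # r = 0 leaves the grid untouched in both modes
  expect_identical(discard_region(g, "outside", 0), g)
  expect_identical(discard_region(g, "inside", 0), g)

  # outside discarding at r = 3 keeps exactly the 18 A inner cube
  g3 <- discard_region(g, "outside", 3)
  centers <- abs(hemepocket:::voxel_centers(24, 1))
  inner <- centers <= 9
  expect_true(all(g3[!inner, , , ] == 0L, g3[, !inner, , ] == 0L,
                  g3[, , !inner, ] == 0L))
  expect_identical(g3[inner, inner, inner, ], g[inner, inner, inner, ])

  # inside discarding on an all-ones grid: survivor count equals total
  # voxels minus the brute-force count of centers in the +/-6 cube
  ones <- structure(array(1L, dim = c(24, 24, 24, 4)), edge = 24,
                    voxel = 1)
  g6 <- discard_region(ones, "inside", 6)
  cnt <- sum(outer(outer(centers < 6, centers < 6, `&`), centers < 6,
                   `&`))
  expect_equal(sum(g6), 4 * (24^3 - cnt))
  expect_equal(sum(g6), 4 * (24^3 - 12^3))

  # composition collapses to the larger radius (outside mode)
  g_a <- discard_region(discard_region(g, "outside", 2), "outside", 5)
  g_b <- discard_region(discard_region(g, "outside", 5), "outside", 2)
  expect_identical(g_a, discard_region(g, "outside", 5))
  expect_identical(g_b, discard_region(g, "outside", 5))

  # monotone occupancy in r for both modes
  for (mode in c("outside", "inside")) {
    occ <- vapply(0:11, function(r)
      sum(discard_region(g, mode, r)), numeric(1))
    expect_true(all(diff(occ) <= 0))
  }

  # out-of-range r is refused
  expect_error(discard_region(g, "outside", 12), "must be in")
  expect_error(discard_region(g, "inside", -1), "must be in")
})

test_that("grid geometry honours edge and voxel parameters", {
  site <- random_toy_site(5)
  g17 <- voxelize_site(site, edge = 17, voxel = 1)
  expect_equal(dim(g17)[1:3], rep(17L, 3))
  g8 <- voxelize_site(site, edge = 24, voxel = 3)
  expect_equal(dim(g8)[1:3], rep(8L, 3))
  expect_error(voxelize_site(site, edge = 24, voxel = 0.7),
               "whole multiple")
})
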