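test_that("rmsd_pair matches hand-evaluated deviations", {
  a <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)

  # single atom, unit displacement
  expect_identical(rmsd_pair(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3),
                             align = FALSE), 1)

  # hand evaluation: B differs from A only in one z coordinate by 1
  b <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 1), 3, 3, byrow = TRUE)
  expect_equal(rmsd_pair(a, b, align = FALSE), sqrt(1 / 3),
               tolerance = 1e-15)

  # rigid motion is removed by superposition
  moved <- rigid_move(a, pi / 2, shift = c(1, 2, 3))
  expect_lt(rmsd_pair(a, moved, align = TRUE), 1e-9)

  expect_error(rmsd_pair(a, b[1:2, ]), "atom counts differ")
  expect_error(rmsd_pair(a, b, weights = c(1, 0, 1)), "positive")
})

test_that("self-RMSD is exactly zero and symmetry/align inequalities hold", {
  set.seed(11)
  for (rep in 1:20) {
    na <- sample(2:10, 1)
    a <- rand_frame(na)
    b <- rand_frame(na)
    expect_identical(rmsd_pair(a, a, align = TRUE), 0)
    expect_identical(rmsd_pair(a, a, align = FALSE), 0)
    expect_equal(rmsd_pair(a, b, align = FALSE),
                 rmsd_pair(b, a, align = FALSE), tolerance = 1e-14)
    expect_equal(rmsd_pair(a, b, align = TRUE),
                 rmsd_pair(b, a, align = TRUE), tolerance = 1e-9)
    expect_lte(rmsd_pair(a, b, align = TRUE),
               rmsd_pair(a, b, align = FALSE) + 1e-12)
    # invariance under rigid motion of one frame
    bm <- rigid_move(b, runif(1, 0, 2 * pi), shift = rnorm(3))
    expect_equal(rmsd_pair(a, bm, align = TRUE),
                 rmsd_pair(a, b, align = TRUE), tolerance = 1e-9)
  }
})

test_that("kabsch recovers exact transforms and excludes reflections", {
  set.seed(12)
  ref <- rand_frame(6)
  s <- kabsch(ref, ref)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)
  expect_equal(s$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(s$rmsd_after, 0, tolerance = 1e-12)

  shifted <- sweep(ref, 2, -c(5, 5, 5))
  s2 <- kabsch(ref, shifted)
  expect_equal(s2$rotation, diag(3), tolerance = 1e-9)
  expect_equal(s2$translation, c(-5, -5, -5), tolerance = 1e-9)
  expect_equal(s2$rmsd_after, 0, tolerance = 1e-12)

  for (rep in 1:10) {
    a <- rand_frame(6)
    b <- rand_frame(6)
    s3 <- kabsch(a, b)
    expect_equal(det(s3$rotation), 1, tolerance = 1e-9)
    expect_equal(crossprod(s3$rotation), diag(3), tolerance = 1e-9)
    # returned transform reproduces rmsd_after
    moved <- sweep(b %*% t(s3$rotation), 2, -s3$translation)
    expect_equal(sqrt(mean(rowSums((a - moved)^2))), s3$rmsd_after,
                 tolerance = 1e-12)
  }
})

test_that("aligned RMSD agrees with the brute-force rotation-grid oracle", {
  G <- rotation_grid(4)    # 4-degree module-level grid; 2-degree grid in
                           # the acceptance suite
  set.seed(13)
  for (rep in 1:8) {
    na <- sample(3:8, 1)
    a <- rand_frame(na)
    b <- rand_frame(na)
    expect_equal(rmsd_pair(a, b, align = TRUE), grid_min_rmsd(a, b, G),
                 tolerance = 4e-3)
  }
})

test_that("rmsd_matrix is exact, symmetric and entry-wise consistent", {
  xs <- traj_1d(c(0, 1))
  m <- rmsd_matrix(xs, align = FALSE)
  expect_identical(m$values, matrix(c(0, 1, 1, 0), 2, 2))

  traj <- generate_ou_trajectory(5, 40, sigma = 1, tau_c = 10, dt_ps = 1,
                                 seed = 21)
  m2 <- rmsd_matrix(traj, align = FALSE)
  expect_identical(m2$values, t(m2$values))
  for (idx in list(c(1, 2), c(3, 17), c(10, 40))) {
    fa <- matrix(traj$coords[idx[1], , ], 5, 3)
    fb <- matrix(traj$coords[idx[2], , ], 5, 3)
    expect_identical(m2$values[idx[1], idx[2]],
                     rmsd_pair(fa, fb, align = FALSE))
  }
  m3 <- rmsd_matrix(traj, align = TRUE)
  expect_identical(m3$values, t(m3$values))
  expect_true(all(m3$values <= m2$values + 1e-12))
  expect_identical(diag(m3$values), rep(0, 40))
})

test_that("reference curves identify outlier and central frames", {
  m <- new_rmsd_matrix(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3),
                       times = 0:2)
  rc <- reference_curves(m)
  expect_equal(rc$per_frame_mean, c(1.5, 1, 1.5))
  expect_identical(rc$idx_min, 2L)
  expect_identical(rc$idx_max, 1L)   # tie between frames 1 and 3 -> first
  expect_identical(rc$curve_min[rc$idx_min], 0)
  expect_identical(rc$curve_max[rc$idx_max], 0)
  expect_identical(rc$curve_first, m$values[1, ])

  m2 <- new_rmsd_matrix(matrix(c(0, 3, 3, 0), 2, 2), times = 0:1)
  rc2 <- reference_curves(m2)
  expect_equal(rc2$per_frame_mean, c(3, 3))
  expect_identical(rc2$idx_max, 1L)
  expect_identical(rc2$idx_min, 1L)
})

test_that("mass weighting shifts the superposition towards heavy atoms", {
  set.seed(14)
  a <- rand_frame(5)
  b <- rand_frame(5)
  w <- c(10, 1, 1, 1, 1)
  rw <- rmsd_pair(a, b, align = TRUE, weights = w)
  ru <- rmsd_pair(a, b, align = TRUE)
  expect_false(isTRUE(all.equal(rw, ru)))
  # weighted aligned never beats weighted unaligned
  expect_lte(rw, rmsd_pair(a, b, align = FALSE, weights = w) + 1e-12)
})
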