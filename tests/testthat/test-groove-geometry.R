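# Helix principal axis, groove vector, deviation angles.

test_that("ideal helix along +z has axis (0,0,1); N->C fixes the sign", {
  h <- make_ideal_helix()
  a <- helix_principal_axis(h, helix_def(1, 23))
  expect_equal(a, c(0, 0, 1), tolerance = 1e-6)
  hdown <- make_ideal_helix(n_to_c = -1)
  expect_equal(helix_principal_axis(hdown, helix_def(1, 23)), c(0, 0, -1),
               tolerance = 1e-6)
})

test_that("principal axis matches SVD and brute-force inertia oracles on 100 random instances", {
  withr::local_seed(101)
  for (k in 1:100) {
    n <- sample(5:40, 1)
    # anisotropic random cloud: guaranteed distinct long axis
    X <- cbind(rnorm(n, sd = 8), rnorm(n, sd = 2), rnorm(n, sd = 0.8))
    R <- random_rotation()
    X <- X %*% t(R)
    m <- mol_model(data.frame(name = "CA", element = "C", resname = "ALA",
                              resno = seq_len(n), chain = "A",
                              x = X[, 1], y = X[, 2], z = X[, 3]))
    a <- helix_principal_axis(m, helix_def(1, n))
    expect_equal(a, axis_oracle(X), tolerance = 1e-9)
    expect_equal(a, inertia_axis_bruteforce(X), tolerance = 1e-9)
  }
})

test_that("a known rotation moves the axis to its rotated image", {
  withr::local_seed(7)
  for (k in 1:10) {
    R <- random_rotation()
    h <- make_ideal_helix(orientation = R)
    expect_equal(helix_principal_axis(h, helix_def(1, 23)), as.numeric(R %*% c(0, 0, 1)),
                 tolerance = 1e-6)
  }
})

test_that("degenerate (isotropic) point sets are refused", {
  # octahedron vertices: all three inertia eigenvalues equal
  X <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)) * 5
  m <- mol_model(data.frame(name = "CA", element = "C", resname = "ALA",
                            resno = 1:6, chain = "A",
                            x = X[, 1], y = X[, 2], z = X[, 3]))
  expect_error(helix_principal_axis(m, helix_def(1, 6)), "degenerate")
  expect_error(helix_principal_axis(make_ideal_helix(4), helix_def(1, 2)), "at least 3")
})

make_groove_toy <- function() {
  # alpha5 exactly along +z, alpha6 center window displaced along +x:
  # a = +z, c = +x, so g = z x x = +y
  a5 <- make_ideal_helix(11, first_resno = 143)$atoms
  a6 <- make_ideal_helix(13, first_resno = 166, origin = c(12, 0, 0))$atoms
  mol_model(rbind(a5, a6))
}

test_that("groove vector is the cross product of axis and connector", {
  m <- make_groove_toy()
  g <- groove_vector(m)
  # connector has a small off-axis component from the helix twist; y dominates
  expect_equal(g[2], 1, tolerance = 0.02)
  expect_lt(deviation_angle(g, c(0, 1, 0)), 2)
})

test_that("groove vector is rotation-equivariant and flips under cross-order reversal", {
  withr::local_seed(11)
  m <- make_groove_toy()
  g <- groove_vector(m)
  for (k in 1:20) {
    R <- random_rotation()
    m2 <- set_coords(m, coords(m) %*% t(R))
    expect_equal(groove_vector(m2), as.numeric(R %*% g), tolerance = 1e-9)
  }
  expect_equal(groove_vector(m, groove_def(flip = TRUE)), -g, tolerance = 1e-12)
})

test_that("collinear axis and connector are refused", {
  a5 <- make_ideal_helix(11, first_resno = 143)$atoms
  a6 <- make_ideal_helix(13, first_resno = 166, origin = c(0, 0, 30))$atoms
  m <- mol_model(rbind(a5, a6))
  # connector nearly parallel to the a5 axis (+z): residual twist offsets
  # keep it within a fraction of a degree, below the collinearity gate only
  # if exactly parallel - build the exact case by hand
  ctr143 <- colMeans(coords(m)[resolve_selection(m, selection(143, 146)), ])
  X <- coords(m)
  i6 <- resolve_selection(m, selection(170, 173))
  shift <- matrix(ctr143 + c(0, 0, 25), length(i6), 3, byrow = TRUE) -
    matrix(colMeans(X[i6, ]), length(i6), 3, byrow = TRUE)
  X[i6, ] <- X[i6, ] + shift
  m <- set_coords(m, X)
  expect_error(groove_vector(m), "collinear")
})

test_that("deviation angle hits the closed-form values and rejects zero vectors", {
  expect_equal(deviation_angle(c(0, 0, 1)), 0)
  expect_equal(deviation_angle(c(1, 0, 0)), 90)
  expect_equal(deviation_angle(c(0, 0, -1)), 180)
  expect_equal(deviation_angle(c(0, 1, 1)), 45, tolerance = 1e-12)
  expect_error(deviation_angle(c(0, 0, 0)), "zero")
})

test_that("accessibility classification: <90 accessible, >=90 occluded (boundary occluded)", {
  expect_equal(classify_accessibility(100), "occluded")
  expect_equal(classify_accessibility(40), "accessible")
  expect_equal(classify_accessibility(90), "occluded")
  expect_equal(classify_accessibility(c(89.999, 90.001)),
               c("accessible", "occluded"))
  expect_error(classify_accessibility(181), "0, 180")
  expect_error(classify_accessibility(-1), "0, 180")
})

test_that("groove series: static trajectory is constant; z-rotations leave phi and psi invariant", {
  toy <- make_test_toy()
  slab <- make_test_slab()
  gen <- make_rigid_body_trajectory(toy, slab, schedule_constant(105),
                                    n_frames = 12)
  tr <- gen$trajectory
  phi <- groove_angle_series(tr)
  expect_equal(phi$values, rep(105, 12), tolerance = 1e-9)
  # rotate every frame about z by a different angle
  arr <- tr$coords
  withr::local_seed(5)
  for (k in seq_len(n_frames(tr))) {
    Rz <- rotation_about_axis(c(0, 0, 1), runif(1, 0, 360))
    arr[, , k] <- arr[, , k] %*% t(Rz)
  }
  tr2 <- trajectory(get_frame(tr, 1), arr, tr$times)
  expect_equal(groove_angle_series(tr2)$values, phi$values, tolerance = 1e-9)
  expect_equal(tm_tilt_series(tr2)$values, tm_tilt_series(tr)$values,
               tolerance = 1e-9)
})
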