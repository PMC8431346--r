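# Loop radius of gyration and residue z-distributions.

point_model <- function(X) {
  mol_model(data.frame(name = "CA", element = "C", resname = "ALA",
                       resno = seq_len(nrow(X)), chain = "A",
                       x = X[, 1], y = X[, 2], z = X[, 3]))
}

test_that("Rg closed forms: single atom, two points, collinear beads", {
  expect_equal(radius_of_gyration(point_model(matrix(c(1, 2, 3), 1)),
                                  selection(1, 1)), 0)
  d <- 7.3
  expect_equal(radius_of_gyration(point_model(rbind(c(0, 0, 0), c(d, 0, 0))),
                                  selection(1, 2)), d / 2)
  for (N in c(3, 10, 61)) {
    a <- 1.9
    X <- cbind(a * (seq_len(N) - 1), 0, 0)
    expect_equal(radius_of_gyration(point_model(X), selection(1, N))^2,
                 a^2 * (N^2 - 1) / 12, tolerance = 1e-12)
  }
})

test_that("Rg equals the brute-force pairwise double sum on 100 random point sets", {
  withr::local_seed(77)
  for (k in 1:100) {
    n <- sample(2:30, 1)
    X <- matrix(rnorm(3 * n, sd = 5), n)
    m <- point_model(X)
    expect_equal(radius_of_gyration(m, selection(1, n)), rg_pairwise(X),
                 tolerance = 1e-9)
  }
})

test_that("Rg is invariant under rigid rotation and translation", {
  withr::local_seed(78)
  X <- matrix(rnorm(60, sd = 6), 20)
  m <- point_model(X)
  r0 <- radius_of_gyration(m, selection(1, 20))
  for (k in 1:10) {
    R <- random_rotation()
    m2 <- set_coords(m, transform_coords(X, R, shift = rnorm(3, sd = 30)))
    expect_equal(radius_of_gyration(m2, selection(1, 20)), r0, tolerance = 1e-9)
  }
  expect_error(radius_of_gyration(m, selection(50, 60)), "empty")
})

test_that("scheduled loop breathing is recovered exactly; rigid trajectories give constant Rg", {
  toy <- make_test_toy()
  slab <- make_test_slab()
  n <- 60
  rg_target <- 10 + 2 * sin(seq(0, 2 * pi, length.out = n))
  gen <- make_rigid_body_trajectory(toy, slab, schedule_constant(100),
                                    n_frames = n, loop_rg = rg_target)
  rg <- rg_series(gen$trajectory)
  expect_equal(rg$rg_A, rg_target, tolerance = 1e-6)
  expect_equal(range(rg$rg_A), range(rg_target), tolerance = 1e-6)
  gen2 <- make_rigid_body_trajectory(toy, slab, schedule_constant(100),
                                     n_frames = 10)
  expect_equal(diff(range(rg_series(gen2$trajectory)$rg_A)), 0, tolerance = 1e-9)
})

test_that("a broader prescribed Rg schedule yields a broader recovered distribution", {
  toy <- make_test_toy()
  slab <- make_test_slab()
  n <- 120
  narrow <- withr::with_seed(1, rnorm(n, 10, 0.3))
  broad <- withr::with_seed(2, rnorm(n, 10, 1.2))
  g1 <- make_rigid_body_trajectory(toy, slab, schedule_constant(100),
                                   n_frames = n, loop_rg = narrow)
  g2 <- make_rigid_body_trajectory(toy, slab, schedule_constant(100),
                                   n_frames = n, loop_rg = broad)
  s1 <- sd(rg_series(g1$trajectory)$rg_A)
  s2 <- sd(rg_series(g2$trajectory)$rg_A)
  expect_gt(s2, s1 * 2)
})

test_that("scripted residue placements give separated z-distributions at the prescribed centers", {
  toy <- make_test_toy()
  slab <- make_test_slab()
  n <- 50
  gen <- make_rigid_body_trajectory(
    toy, slab, schedule_constant(100), n_frames = n,
    z_targets = list(`21` = rep(0, n), `70` = rep(15, n)))
  z21 <- residue_z_series(gen$trajectory, 21)$z_A
  z70 <- residue_z_series(gen$trajectory, 70)$z_A
  expect_equal(mean(z21), 0, tolerance = 1e-9)
  expect_equal(mean(z70), 15, tolerance = 1e-9)
  h21 <- histogram_density(z21, bin_width = 1)
  h70 <- histogram_density(z70, bin_width = 1)
  occupied <- function(h) {
    mid <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
    mid[h$density > 0]
  }
  expect_true(max(occupied(h21)) < min(occupied(h70)))
})
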