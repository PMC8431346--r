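# Synthetic generator: fixtures, schedules, ground-truth recovery.

test_that("ideal helix defaults and parameter validation", {
  h <- make_ideal_helix()
  expect_equal(nrow(h$atoms), 23)
  expect_equal(helix_principal_axis(h, helix_def(1, 23)), c(0, 0, 1),
               tolerance = 1e-9)
  expect_error(make_ideal_helix(2), "at least 3")
  expect_error(make_ideal_helix(rise = -1), "positive")
})

test_that("the toy protein carries the production residue architecture", {
  toy <- make_test_toy()
  m <- toy$model
  expect_length(resolve_selection(m, selection(143, 146, "CA")), 4)
  expect_length(resolve_selection(m, selection(170, 173, "CA")), 4)
  expect_length(resolve_selection(m, selection(21, 81, "CA")), 61)
  expect_equal(m$atoms$resname[m$atoms$resno == 213], "TRP")
  expect_equal(m$atoms$resname[m$atoms$resno == 21], "GLY")
  expect_equal(m$atoms$resname[m$atoms$resno == 70], "GLY")
  expect_equal(m$atoms$resname[m$atoms$resno == 207], "GLN")
  # stored reference groove angle matches a direct evaluation
  expect_equal(toy$groove_angle0,
               deviation_angle(groove_vector(m), c(0, 0, 1)))
})

test_that("membrane slabs are exact without noise and reproducible with a seed", {
  s0 <- make_membrane_slab(n_per_leaflet = 30, plane_z = 18)
  expect_true(all(abs(abs(coords(s0)[, 3]) - 18) < 1e-12))
  s1 <- make_membrane_slab(n_per_leaflet = 30, plane_z = 18, noise_sd = 1, seed = 4)
  s2 <- make_membrane_slab(n_per_leaflet = 30, plane_z = 18, noise_sd = 1, seed = 4)
  expect_identical(coords(s1), coords(s2))
  expect_error(make_membrane_slab(noise_sd = 1), "seed")
})

test_that("schedules validate their angles and realize deterministically", {
  expect_error(schedule_constant(0), "strictly inside")
  expect_error(schedule_constant(180), "strictly inside")
  expect_error(schedule_piecewise(c(100, 190), 1), "strictly inside")
  expect_error(schedule_piecewise(c(100, 40, 95), 1), "switch times")
  t <- seq(0, 4.99, by = 0.01)
  pw <- realize_schedule(schedule_piecewise(c(100, 40), 3), t)
  expect_equal(pw, ifelse(t < 3, 100, 40))
  ou <- schedule_ou(100, 5, 0.2)
  expect_identical(realize_schedule(ou, t, seed = 8),
                   realize_schedule(ou, t, seed = 8))
  expect_error(realize_schedule(ou, t), "seed")
})

test_that("the exact OU discretization has the analytic stationary moments", {
  t <- seq(0, 99.99, by = 0.01)   # 1e4 frames
  x <- realize_schedule(schedule_ou(100, 5, 0.25), t, seed = 13)
  # effective sample size ~ n * dt / (2 tau)
  n_eff <- length(t) * 0.01 / (2 * 0.25)
  expect_lt(abs(mean(x) - 100), 3 * 5 / sqrt(n_eff))
  expect_lt(abs(sd(x) - 5), 1)
  # lag-1 autocorrelation of the exact scheme is exp(-dt/tau)
  r1 <- cor(x[-1], x[-length(x)])
  expect_equal(r1, exp(-0.01 / 0.25), tolerance = 0.05)
})

test_that("piecewise schedules are recovered with the transition at the exact frame", {
  toy <- make_test_toy()
  gen <- make_rigid_body_trajectory(toy, make_test_slab(),
                                    schedule_piecewise(c(100, 40), 3),
                                    n_frames = 500, dt_us = 0.01)
  phi <- groove_angle_series(gen$trajectory)
  sched <- ifelse(gen$trajectory$times < 3, 100, 40)
  expect_lt(max(abs(phi$values - sched)), 1e-6)
  expect_equal(min(which(phi$values < 90)), 301)  # first frame with t >= 3 us
})

test_that("all stored ground-truth descriptors are recovered from the noise-free trajectory", {
  toy <- make_test_toy()
  n <- 80
  gen <- make_rigid_body_trajectory(
    toy, make_test_slab(), schedule_piecewise(c(120, 60), 0.4),
    n_frames = n, dt_us = 0.01, tm_tilt = 12,
    loop_rg = seq(9, 12, length.out = n))
  tr <- gen$trajectory; truth <- gen$truth
  expect_lt(max(abs(groove_angle_series(tr)$values - truth$phi_deg)), 1e-6)
  expect_lt(max(abs(tm_tilt_series(tr)$values - truth$psi_deg)), 1e-6)
  expect_lt(max(abs(rg_series(tr)$rg_A - truth$rg_A)), 1e-6)
  expect_lt(max(abs(residue_z_series(tr, 21)$z_A - truth$z21_A)), 1e-6)
  expect_lt(max(abs(residue_z_series(tr, 70)$z_A - truth$z70_A)), 1e-6)
  # N-to-C-down anchor: axis deviation is the supplement of the 12-deg tilt
  expect_equal(truth$psi_deg, rep(168, n), tolerance = 1e-9)
})

test_that("identical seeds give identical trajectories; constant 90 is all-occluded", {
  toy <- make_test_toy(); slab <- make_test_slab()
  g1 <- make_rigid_body_trajectory(toy, slab, schedule_ou(100, 5, 0.2),
                                   n_frames = 50, seed = 99)
  g2 <- make_rigid_body_trajectory(toy, slab, schedule_ou(100, 5, 0.2),
                                   n_frames = 50, seed = 99)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  expect_identical(g1$truth, g2$truth)
  g3 <- make_rigid_body_trajectory(toy, slab, schedule_constant(90), n_frames = 10)
  phi <- groove_angle_series(g3$trajectory)
  expect_true(all(classify_accessibility(round(phi$values, 9)) == "occluded"))
  expect_error(make_rigid_body_trajectory(toy, slab, schedule_constant(90),
                                          n_frames = 10, noise_sd = 1),
               "seed")
})
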