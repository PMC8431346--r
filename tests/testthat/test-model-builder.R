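# Full-length model assembly: z-alignment, joining, membrane embedding.

test_that("align_helix_to_z recovers a randomly placed ideal helix, rigidly", {
  withr::local_seed(21)
  ref <- make_ideal_helix(23, first_resno = 209)
  for (k in 1:5) {
    R <- random_rotation()
    placed <- set_coords(ref, transform_coords(coords(ref), R,
                                               shift = rnorm(3, sd = 20)))
    out <- align_helix_to_z(placed, helix_def(209, 231))
    a <- helix_principal_axis(out, helix_def(209, 231))
    expect_equal(deviation_angle(a, c(0, 0, 1)), 0, tolerance = 1e-6)
    # rigid: pairwise distances preserved
    expect_equal(pairdist(out), pairdist(ref), tolerance = 1e-6)
    # same shape as a directly built z-aligned helix
    expect_lt(kabsch_rmsd(coords(out), coords(ref)), 1e-6)
  }
})

test_that("aligning an already-aligned helix is the identity up to numerical noise", {
  h <- make_ideal_helix(23, first_resno = 209, origin = c(3, -2, 7))
  out <- align_helix_to_z(h, helix_def(209, 231))
  expect_equal(coords(out), coords(h), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("joining two halves of one structure at the junction reproduces it with zero fit RMSD", {
  toy <- make_test_toy()$model
  head <- mol_model(toy$atoms[toy$atoms$resno <= 222, ])
  tail <- mol_model(toy$atoms[toy$atoms$resno >= 209, ])
  j <- join_structures(head, tail, junction = 207, superpose_span = c(209, 214))
  expect_equal(j$fit_rmsd, 0, tolerance = 1e-9)
  expect_equal(coords(j$model), coords(toy), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sort(unique(j$model$atoms$resno)), 1:231)
  expect_equal(unique(j$model$atoms$chain), "A")
})

test_that("a rigidly perturbed head is recovered by the join within 1e-6 A", {
  withr::local_seed(31)
  toy <- make_test_toy()$model
  head <- mol_model(toy$atoms[toy$atoms$resno <= 222, ])
  tail <- mol_model(toy$atoms[toy$atoms$resno >= 209, ])
  R <- random_rotation()
  head_p <- set_coords(head, transform_coords(coords(head), R, shift = c(10, -4, 25)))
  j <- join_structures(head_p, tail, junction = 207, superpose_span = c(209, 214))
  expect_lt(j$fit_rmsd, 1e-9)
  expect_equal(coords(j$model), coords(toy), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("junction outside the head range is a precondition error; disjoint sources are refused", {
  toy <- make_test_toy()$model
  head <- mol_model(toy$atoms[toy$atoms$resno <= 222, ])
  tail <- mol_model(toy$atoms[toy$atoms$resno >= 209, ])
  expect_error(join_structures(head, tail, junction = 300), "outside")
  lone <- mol_model(toy$atoms[toy$atoms$resno <= 100, ])
  expect_error(join_structures(lone, tail, junction = 50), "no residues")
})

test_that("embedding satisfies the anchor, head-gap and span constraints", {
  toy <- make_test_toy()
  # lift the whole protein far above the membrane first
  lifted <- set_coords(toy$model,
                       sweep(coords(toy$model), 2, c(0, 0, 40), "+"))
  slab <- make_membrane_slab(plane_z = 15)
  mf <- membrane_frame(slab)
  out <- embed_in_membrane(lifted, mf, head_range = c(1, 208))
  X <- coords(out)
  z213 <- X[resolve_selection(out, selection(213, atom = "CA")), 3]
  expect_lt(z213, mf$upper_plane_z)
  expect_gte(z213, mf$upper_plane_z - 3)
  hidx <- resolve_selection(out, selection(1, 208, atom = NULL))
  expect_lte(min(X[hidx, 3]) - mf$upper_plane_z, 4)
  tmz <- range(X[resolve_selection(out, selection(209, 231, atom = NULL)), 3])
  expect_lte(tmz[1], mf$lower_plane_z)
  expect_gte(tmz[2], mf$upper_plane_z)
  # rigid z-translation only
  expect_equal(pairdist(out), pairdist(lifted), tolerance = 1e-9)
  expect_equal(X[, 1:2], coords(lifted)[, 1:2], ignore_attr = TRUE)
})

test_that("unsatisfiable embedding constraints name the violated constraint", {
  # TM helix far too short to span a very thick slab
  short_tm <- make_ideal_helix(5, first_resno = 209)$atoms
  anchor <- data.frame(name = "CA", element = "C", resname = "TRP",
                       resno = 213, chain = "A", x = 0, y = 4, z = 2)
  short_tm <- short_tm[short_tm$resno != 213, ]
  head <- data.frame(name = "CA", element = "C", resname = "ALA",
                     resno = 1:5, chain = "A", x = 1:5, y = 0, z = 12)
  m <- mol_model(rbind(head, anchor, short_tm))
  slab <- make_membrane_slab(plane_z = 30)
  expect_error(embed_in_membrane(m, membrane_frame(slab), head_range = c(1, 5),
                                 tm_span = c(209, 214)),
               "unsatisfiable")
})
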