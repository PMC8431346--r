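#!/usr/bin/env Rscript
# Assemble a full-length membrane-anchored model from two partial sources.
#
# The two sources are cut from the synthetic reference protein: a "head"
# covering residues 1-222 and an anchor-helix "tail" covering 209-231, the
# tail placed in its membrane-aligned pose and the head given an arbitrary
# rigid displacement (as two independently determined structures would be).
# The build: align the tail helix with z, superimpose the head over the
# 209-214 overlap window, join at Gln-207, and embed at the phosphate
# planes under the anchor/head-gap constraints. The report records the fit
# RMSD and every constraint value.

suppressMessages(library(memgroove))
dir.create("results", showWarnings = FALSE)

toy <- make_anchored_toy()
ref <- toy$model
head <- mol_model(ref$atoms[ref$atoms$resno <= 222, ])
tail <- mol_model(ref$atoms[ref$atoms$resno >= 209, ])

# displace the head rigidly, as an independently solved structure
set.seed(1)
R <- rotation_about_axis(c(1, 1, 0), 35)
head <- set_coords(head, sweep(coords(head) %*% t(R), 2, c(25, -10, 30), "+"))

tail <- align_helix_to_z(tail, helix_def(209, 231), direction = -1)
j <- join_structures(head, tail, junction = 207, superpose_span = c(209, 214))
cat(sprintf("join fit RMSD over the overlap C-alphas: %.2e A\n", j$fit_rmsd))

slab <- make_membrane_slab()
mf <- membrane_frame(slab)
model <- embed_in_membrane(j$model, mf, head_range = c(1, 208))

X <- coords(model)
z213 <- X[resolve_selection(model, selection(213, atom = "CA")), 3]
head_gap <- min(X[resolve_selection(model, selection(1, 208, atom = NULL)), 3]) -
  mf$upper_plane_z
tm_z <- range(X[resolve_selection(model, selection(209, 231, atom = NULL)), 3])

report <- data.frame(
  quantity = c("fit_rmsd_A", "upper_plane_z_A", "lower_plane_z_A",
               "trp213_ca_z_A", "trp213_depth_below_plane_A",
               "head_gap_above_plane_A", "tm_zmin_A", "tm_zmax_A"),
  value = c(j$fit_rmsd, mf$upper_plane_z, mf$lower_plane_z, z213,
            mf$upper_plane_z - z213, head_gap, tm_z[1], tm_z[2]))
write.table(report, "results/build_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_structure(model, "results/full_length_model.pdb")
cat(sprintf("Trp-213 sits %.2f A below the upper phosphate plane;\n",
            mf$upper_plane_z - z213))
cat(sprintf("the head approaches the plane to %.2f A (constraint: <= 4 A);\n",
            head_gap))
cat(sprintf("the TM helix spans z = %.1f .. %.1f A across planes at %.0f/%.0f A.\n",
            tm_z[1], tm_z[2], mf$lower_plane_z, mf$upper_plane_z))
cat("wrote results/build_report.tsv and results/full_length_model.pdb\n")
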