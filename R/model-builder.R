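# Full-length model assembly.
#
# The membrane-anchored full-length model is built from two source
# structures: a soluble head lacking the C-terminal helix and an isolated
# C-terminal (TM) helix. The TM helix is aligned with the Cartesian z-axis,
# the two structures are superimposed over a short residue window bracketing
# the junction and joined there, and the chimera is placed at the bilayer so
# the anchor tryptophan sits just below the upper phosphate plane while the
# head stays within a stated gap of the membrane surface. Every operation is
# rigid: pairwise distances are preserved and the build is deterministic.

#' Align a helix with the +z axis
#'
#' Applies the rigid rotation (about the helix C-alpha centroid) that takes
#' the helix principal axis onto +z.
#'
#' @param model a `mol_model`.
#' @param helix a `helix_def` or selection resolving to the helix C-alphas.
#' @param direction +1 (default) aligns the N-to-C axis with +z; -1 with -z
#'   (a C-terminal membrane anchor entering the bilayer from the head side
#'   runs N-to-C downward).
#' @return the rotated `mol_model`; the helix axis deviates from the target
#'   direction by less than 1e-6 degrees afterwards.
#' @export
align_helix_to_z <- function(model, helix, direction = 1) {
  stopifnot(direction %in% c(-1, 1))
  axis <- helix_principal_axis(model, helix)
  sel <- if (inherits(helix, "helix_def"))
    selection(helix$first, helix$last, "CA", helix$chain) else helix
  idx <- resolve_strict(model, sel, "helix selection")
  ctr <- colMeans(coords(model)[idx, , drop = FALSE])
  R <- rotation_between(axis, c(0, 0, direction))
  out <- set_coords(model, transform_coords(coords(model), R, center = ctr))
  dev <- deviation_angle(helix_principal_axis(out, helix), c(0, 0, direction))
  if (dev > 1e-6)
    stop(sprintf("alignment failed: residual axis deviation %.3g deg", dev))
  out
}

#' Join a head structure and a tail structure at a junction residue
#'
#' The head is rigidly superimposed onto the tail frame by a least-squares
#' fit of the C-alphas in `superpose_span` (present in both sources), then
#' residues up to and including `junction` are taken from the transformed
#' head and residues beyond it from the tail, yielding a single chain.
#'
#' @param head `mol_model` providing residues `<= junction`.
#' @param tail `mol_model` providing residues `> junction` (kept fixed; it
#'   carries the membrane alignment).
#' @param junction junction residue number (default 207).
#' @param superpose_span length-2 inclusive span of overlap C-alphas fitted
#'   (default 207-214).
#' @param rmsd_warn warn (not fail) if the post-fit overlap C-alpha RMSD
#'   exceeds this many Angstrom (default 2); the two source structures are
#'   independent experimental models and need not agree perfectly.
#' @return list with `model` (the joined `mol_model`, chain "A") and
#'   `fit_rmsd` (Angstrom, over the fitted C-alphas).
#' @export
join_structures <- function(head, tail, junction = 207,
                            superpose_span = c(207, 214), rmsd_warn = 2) {
  head_rng <- range(head$atoms$resno)
  tail_rng <- range(tail$atoms$resno)
  if (junction < head_rng[1] || junction > head_rng[2])
    stop("junction residue ", junction, " lies outside the head range ",
         head_rng[1], "-", head_rng[2])
  overlap <- intersect(unique(head$atoms$resno), unique(tail$atoms$resno))
  if (length(overlap) == 0) stop("head and tail share no residues; cannot superimpose")
  hidx <- resolve_strict(head, selection(superpose_span[1], superpose_span[2], "CA"),
                         "head overlap C-alphas")
  tidx <- resolve_strict(tail, selection(superpose_span[1], superpose_span[2], "CA"),
                         "tail overlap C-alphas")
  if (length(hidx) != length(tidx))
    stop("overlap windows resolve to different C-alpha counts in head and tail")
  # least-squares rigid fit of the head overlap onto the tail overlap,
  # applied to all head atoms
  fitted <- bio3d::fit.xyz(fixed = as.numeric(t(coords(tail))),
                           mobile = as.numeric(t(coords(head))),
                           fixed.inds = bio3d::atom2xyz(tidx),
                           mobile.inds = bio3d::atom2xyz(hidx))
  head_xyz <- matrix(as.numeric(fitted), ncol = 3, byrow = TRUE)
  fit_rmsd <- sqrt(mean(rowSums((head_xyz[hidx, , drop = FALSE] -
                                 coords(tail)[tidx, , drop = FALSE])^2)))
  if (fit_rmsd > rmsd_warn)
    warning(sprintf("overlap C-alpha RMSD %.2f A exceeds %.2f A", fit_rmsd, rmsd_warn))
  head2 <- set_coords(head, head_xyz)
  keep_t <- tail$atoms$resno > junction
  # the tail may start a few residues past the junction (the anchor-helix
  # source begins at 209 while the junction is 207); the head fills that gap
  tail_first <- min(tail$atoms$resno[keep_t])
  keep_h <- head2$atoms$resno <= junction |
    (head2$atoms$resno > junction & head2$atoms$resno < tail_first)
  joined <- rbind(head2$atoms[keep_h, ], tail$atoms[keep_t, ])
  joined <- joined[order(joined$resno), ]
  joined$chain <- "A"
  list(model = mol_model(joined), fit_rmsd = fit_rmsd)
}

#' Embed a z-aligned model at the bilayer
#'
#' Finds the rigid z-translation satisfying the embedding constraints:
#' the anchor residue's C-alpha lies just below the upper phosphate plane
#' (within `anchor_window` Angstrom below it), every head atom is no more
#' than `max_head_gap` above the upper plane at its closest approach, and
#' the TM helix spans both phosphate planes. The midpoint of the feasible
#' translation interval is used, making the build deterministic.
#'
#' @param model a `mol_model` whose TM helix axis is parallel to z.
#' @param membrane a `membrane_frame`.
#' @param anchor_residue anchor tryptophan residue number (default 213).
#' @param max_head_gap maximum allowed gap (Angstrom) between the head
#'   domain and the upper phosphate plane (default 4).
#' @param head_range inclusive residue span of the head domain
#'   (default 1-207).
#' @param tm_span inclusive residue span of the TM helix (default 209-231).
#' @param anchor_window depth window below the upper plane for the anchor
#'   C-alpha, as c(lowest, highest) offsets (default c(-3, 0)).
#' @return the translated `mol_model`.
#' @export
embed_in_membrane <- function(model, membrane, anchor_residue = 213,
                              max_head_gap = 4, head_range = c(1, 207),
                              tm_span = c(209, 231),
                              anchor_window = c(-3, 0)) {
  stopifnot(inherits(membrane, "membrane_frame"), max_head_gap > 0)
  X <- coords(model)
  up <- membrane$upper_plane_z; lo <- membrane$lower_plane_z
  aidx <- resolve_strict(model, selection(anchor_residue, anchor_residue, "CA"),
                         "anchor residue C-alpha")
  z_anchor <- X[aidx[1], 3]
  hidx <- resolve_strict(model, selection(head_range[1], head_range[2], atom = NULL),
                         "head domain")
  tmidx <- resolve_strict(model, selection(tm_span[1], tm_span[2], atom = NULL),
                          "TM helix")
  z_head_min <- min(X[hidx, 3])
  z_tm <- range(X[tmidx, 3])
  # each constraint is an interval in the z-shift t
  iv <- rbind(
    anchor   = c(up + anchor_window[1] - z_anchor, up + anchor_window[2] - z_anchor),
    head_gap = c(-Inf, up + max_head_gap - z_head_min),
    tm_lower = c(-Inf, lo - z_tm[1]),
    tm_upper = c(up - z_tm[2], Inf))
  t_lo <- max(iv[, 1]); t_hi <- min(iv[, 2])
  if (t_lo > t_hi) {
    bad <- rownames(iv)[iv[, 1] > t_hi | iv[, 2] < t_lo]
    stop("embedding constraints unsatisfiable; violated: ",
         paste(bad, collapse = ", "))
  }
  t_star <- if (is.finite(t_lo) && is.finite(t_hi)) (t_lo + t_hi) / 2
            else if (is.finite(t_lo)) t_lo else t_hi
  X[, 3] <- X[, 3] + t_star
  set_coords(model, X)
}
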