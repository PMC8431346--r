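# alpha1-alpha2 loop descriptors: radius of gyration and transmembrane
# residue positions.

#' Loop definition
#'
#' Defaults to the 61-residue alpha1-alpha2 loop, residues 21-81 (Gly-21 is
#' the first loop residue), C-alpha atoms only.
#'
#' @param span length-2 inclusive residue span (default c(21, 81)).
#' @param atom atom-name filter (default "CA"; NULL for all atoms).
#' @return object of class `loop_def`.
#' @export
loop_def <- function(span = c(21, 81), atom = "CA") {
  if (length(span) != 2 || span[1] > span[2]) stop("span must be c(first, last)")
  structure(list(span = as.integer(span), atom = atom), class = "loop_def")
}

#' Radius of gyration of a selection
#'
#' Unit-mass Rg: the root-mean-square distance of the selected atoms from
#' their centroid.
#'
#' @param model a `mol_model`.
#' @param spec a `selection_spec`, selection string, or `loop_def`.
#' @return Rg in Angstrom (0 for a single atom).
#' @export
radius_of_gyration <- function(model, spec) {
  if (inherits(spec, "loop_def"))
    spec <- selection(spec$span[1], spec$span[2], atom = spec$atom)
  idx <- resolve_strict(model, spec, "Rg selection")
  X <- coords(model)[idx, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  sqrt(mean(rowSums(Xc^2)))
}

#' Per-frame loop radius of gyration
#'
#' @param traj a `trajectory`.
#' @param loop a `loop_def`.
#' @return data.frame with columns frame, time_us, rg_A.
#' @export
rg_series <- function(traj, loop = loop_def()) {
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    tryCatch(radius_of_gyration(get_frame(traj, k), loop),
             error = function(e) stop("frame ", k, ": ", conditionMessage(e),
                                      call. = FALSE))
  }, numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), time_us = traj$times, rg_A = vals)
}

#' Per-frame transmembrane position of a residue
#'
#' Signed z-position of the residue C-alpha relative to the chosen membrane
#' reference plane, on every frame.
#'
#' @param traj a `trajectory`.
#' @param residue residue number (C-alpha used).
#' @param phosphorus phosphorus atom name(s) for the membrane frame.
#' @param reference `"upper_plane"` (default) or `"midplane"`.
#' @return data.frame with columns frame, time_us, z_A.
#' @export
residue_z_series <- function(traj, residue, phosphorus = "P",
                             reference = "upper_plane") {
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    m <- get_frame(traj, k)
    tryCatch(z_position(m, residue, membrane_frame(m, phosphorus), reference),
             error = function(e) stop("frame ", k, ": ", conditionMessage(e),
                                      call. = FALSE))
  }, numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), time_us = traj$times, z_A = vals)
}
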