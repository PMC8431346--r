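# Membrane frame: per-configuration phosphate-plane reference.
#
# The bilayer is planar and the membrane normal is taken as the box +z axis.
# Each leaflet is summarized by the arithmetic mean z of its lipid
# phosphorus atoms; atoms are assigned to leaflets by the sign of their z
# relative to the median phosphorus z.

#' Membrane frame of a configuration
#'
#' @param model a `mol_model` containing lipid phosphorus atoms.
#' @param phosphorus character vector of atom names identifying lipid
#'   phosphorus (default `"P"`).
#' @return object of class `membrane_frame` with fields `normal` (unit
#'   vector, +z), `upper_plane_z`, `lower_plane_z`, `midplane_z` (Angstrom).
#' @export
membrane_frame <- function(model, phosphorus = "P") {
  at <- model$atoms
  pz <- at$z[at$name %in% phosphorus]
  if (length(pz) == 0) stop("no phosphorus atoms (names ",
                            paste(phosphorus, collapse = ","), ") found")
  med <- stats::median(pz)
  upper <- pz[pz > med]
  lower <- pz[pz <= med]
  if (length(upper) == 0 || length(lower) == 0)
    stop("all phosphorus atoms fall in one leaflet; cannot define two planes")
  uz <- mean(upper); lz <- mean(lower)
  if (!(uz > lz)) stop("degenerate bilayer: leaflet planes coincide")
  structure(list(normal = c(0, 0, 1), upper_plane_z = uz, lower_plane_z = lz,
                 midplane_z = (uz + lz) / 2), class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("<membrane_frame> planes z = %.2f / %.2f A (midplane %.2f A)\n",
              x$upper_plane_z, x$lower_plane_z, x$midplane_z))
  invisible(x)
}

#' Position of atoms along the transmembrane direction
#'
#' Signed distance, along the membrane normal, of the centroid of the
#' selected atoms from the chosen reference plane. Positive values point
#' away from the membrane toward the solvent on the soluble-head side.
#'
#' @param model a `mol_model`.
#' @param spec a `selection_spec`, selection string, or a single residue
#'   number (its C-alpha is used).
#' @param frame_ref a `membrane_frame` for this configuration.
#' @param reference `"upper_plane"` (default) or `"midplane"`.
#' @return signed distance in Angstrom.
#' @export
z_position <- function(model, spec, frame_ref,
                       reference = c("upper_plane", "midplane")) {
  reference <- match.arg(reference)
  stopifnot(inherits(frame_ref, "membrane_frame"))
  if (is.numeric(spec) && length(spec) == 1) spec <- selection(spec, spec, "CA")
  idx <- resolve_strict(model, spec, "z-position selection")
  zc <- mean(coords(model)[idx, 3])
  ref_z <- switch(reference, upper_plane = frame_ref$upper_plane_z,
                  midplane = frame_ref$midplane_z)
  (zc - ref_z) * frame_ref$normal[3]
}
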