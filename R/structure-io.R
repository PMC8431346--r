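# Structures, trajectories and atom selections.
#
# A `mol_model` is a single configuration: an atom table with names, residue
# identity, chain and Cartesian coordinates in Angstrom. A `trajectory` is an
# ordered stack of configurations sharing one atom table, with time stamps in
# microseconds. Multi-model PDB is the baseline on-disk dialect for both.

#' Construct a molecular model
#'
#' @param atoms data.frame with columns `name` (atom name, e.g. "CA"),
#'   `element`, `resname`, `resno` (positive integer residue number),
#'   `chain`, and coordinates `x`, `y`, `z` in Angstrom.
#' @return an object of class `mol_model`.
#' @details Invariants enforced: residue numbers strictly positive, all
#'   coordinates finite, atom names unique within each residue. Missing
#'   chain identifiers are assigned chain "A".
#' @export
mol_model <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  required <- c("name", "element", "resname", "resno", "chain", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[required]
  atoms$resno <- as.integer(atoms$resno)
  atoms$chain[is.na(atoms$chain) | atoms$chain == ""] <- "A"
  if (any(is.na(atoms$resno)) || any(atoms$resno <= 0L))
    stop("residue numbers must be strictly positive integers")
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate atom name within a residue: ", key[duplicated(key)][1])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "mol_model")
}

#' @export
print.mol_model <- function(x, ...) {
  cat(sprintf("<mol_model> %d atoms, %d residues, chain(s) %s\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a model or trajectory frame
#' @param x a `mol_model` or `trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) nrow(x$atoms) else nrow(x$atoms)
}

#' Coordinates of a model as a matrix
#' @param model a `mol_model`.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(model) {
  as.matrix(model$atoms[c("x", "y", "z")])
}

#' Replace the coordinates of a model
#' @param model a `mol_model`.
#' @param value numeric n x 3 matrix.
#' @return the modified `mol_model`.
#' @export
set_coords <- function(model, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(model$atoms), ncol(value) == 3)
  if (!all(is.finite(value))) stop("non-finite coordinates")
  model$atoms[c("x", "y", "z")] <- value
  model
}

#' Construct a trajectory
#'
#' @param model template `mol_model` giving the atom table shared by all
#'   frames.
#' @param coords_array numeric array of dimension (n_atoms, 3, n_frames).
#' @param times numeric vector of frame times in microseconds, strictly
#'   increasing, one per frame.
#' @param box optional n_frames x 3 matrix of cell lengths (Angstrom).
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(model, coords_array, times, box = NULL) {
  stopifnot(inherits(model, "mol_model"))
  if (length(dim(coords_array)) != 3 ||
      dim(coords_array)[1] != nrow(model$atoms) || dim(coords_array)[2] != 3)
    stop("coords_array must have dimension (n_atoms, 3, n_frames)")
  nf <- dim(coords_array)[3]
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1 && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (!all(is.finite(coords_array))) stop("non-finite trajectory coordinates")
  if (is.null(box)) box <- matrix(NA_real_, nf, 3)
  structure(list(atoms = model$atoms, coords = coords_array,
                 times = as.numeric(times), box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %.4g..%.4g us\n",
              n_frames(x), nrow(x$atoms), x$times[1], x$times[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory as a model
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return a `mol_model`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  m <- structure(list(atoms = traj$atoms), class = "mol_model")
  set_coords(m, traj$coords[, , i, drop = TRUE])
}

# ---- selections --------------------------------------------------------

#' Atom selection specification
#'
#' Residue-range selections with an optional atom-name filter and chain,
#' using inclusive 1-based residue bounds. The string form is
#' `"chain:first-last:atomname"`, e.g. `"A:143-146:CA"`; chain `"*"` (or a
#' NULL chain here) matches any chain, atom name `"*"` matches any atom.
#'
#' @param first,last inclusive residue-number bounds (first <= last).
#' @param atom atom-name filter (default `"CA"`, alpha-carbons); `NULL` or
#'   `"*"` selects all atoms.
#' @param chain chain identifier or `NULL` for any chain.
#' @return an object of class `selection_spec`.
#' @export
selection <- function(first, last = first, atom = "CA", chain = NULL) {
  first <- as.integer(first); last <- as.integer(last)
  if (is.na(first) || is.na(last) || first > last)
    stop("selection requires integer bounds with first <= last")
  if (!is.null(atom) && identical(atom, "*")) atom <- NULL
  if (!is.null(chain) && identical(chain, "*")) chain <- NULL
  structure(list(first = first, last = last, atom = atom, chain = chain),
            class = "selection_spec")
}

#' Parse a selection string
#' @param s string `"chain:first-last:atomname"`.
#' @return a `selection_spec`.
#' @rdname selection
#' @export
parse_selection <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("selection string must be 'chain:first-last:atom'")
  rng <- strsplit(parts[2], "-", fixed = TRUE)[[1]]
  if (length(rng) == 1) rng <- c(rng, rng)
  selection(as.integer(rng[1]), as.integer(rng[2]), atom = parts[3],
            chain = parts[1])
}

#' Resolve a selection to atom indices
#'
#' @param model a `mol_model` (or `trajectory`; the shared atom table is
#'   used).
#' @param spec a `selection_spec` or a selection string.
#' @return integer vector of atom indices in model order; `integer(0)` if
#'   the selection matches nothing (callers decide whether that is fatal).
#' @export
resolve_selection <- function(model, spec) {
  if (is.character(spec)) spec <- parse_selection(spec)
  stopifnot(inherits(spec, "selection_spec"))
  at <- model$atoms
  keep <- at$resno >= spec$first & at$resno <= spec$last
  if (!is.null(spec$atom)) keep <- keep & at$name == spec$atom
  if (!is.null(spec$chain)) keep <- keep & at$chain == spec$chain
  which(keep)
}

# Resolve and fail on an empty result, naming the selection.
resolve_strict <- function(model, spec, what = "selection") {
  idx <- resolve_selection(model, spec)
  if (length(idx) == 0)
    stop("empty ", what, " (residues ",
         if (is.character(spec)) spec else paste0(spec$first, "-", spec$last),
         ")")
  idx
}

# ---- PDB reading/writing ----------------------------------------------

bio3d_to_atoms <- function(pdb) {
  at <- pdb$atom
  data.frame(name = at$elety,
             element = ifelse(is.na(at$elesy) | at$elesy == "",
                              substr(trimws(at$elety), 1, 1), at$elesy),
             resname = at$resid,
             resno = at$resno,
             chain = ifelse(is.na(at$chain), "A", at$chain),
             x = at$x, y = at$y, z = at$z,
             stringsAsFactors = FALSE)
}

#' Read a structure from a PDB file
#'
#' @param path path to a PDB file (first MODEL used if several).
#' @return a `mol_model` with atoms in file order and residue numbers as
#'   deposited.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
  atoms <- bio3d_to_atoms(pdb)
  if (any(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z)))
    stop("missing coordinates in ", path)
  if (any(is.na(atoms$resno)))
    stop("malformed ATOM records (unreadable residue numbers) in ", path)
  mol_model(atoms)
}

#' Write a model to a PDB file
#' @param model a `mol_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords(model))),
                   elety = at$name, resid = at$resname, resno = at$resno,
                   chain = at$chain, elesy = at$element)
  invisible(path)
}

#' Read a trajectory from a multi-model PDB file
#'
#' Frame times are not stored in the PDB dialect; they are assigned as
#' `(0:(n-1)) * dt_us` unless an explicit `times` vector is supplied.
#'
#' @param path path to a multi-model PDB (MODEL/ENDMDL blocks with a
#'   constant atom order).
#' @param dt_us frame interval in microseconds (default 0.01).
#' @param times optional explicit time stamps (overrides `dt_us`).
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path, dt_us = 0.01, times = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
  atoms <- bio3d_to_atoms(pdb)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  n <- nrow(atoms)
  if (ncol(xyz) != 3 * n)
    stop("inconsistent atom counts across MODEL blocks in ", path)
  arr <- array(NA_real_, c(n, 3, nf))
  for (k in seq_len(nf)) arr[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt_us
  atoms[c("x", "y", "z")] <- arr[, , 1, drop = TRUE]
  trajectory(mol_model(atoms), arr, times)
}

#' Write a trajectory to a multi-model PDB file
#' @param traj a `trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- traj$atoms
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    X <- traj$coords[, , k, drop = TRUE]
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)),
      ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name),
      at$resname, substr(at$chain, 1, 1), at$resno,
      X[, 1], X[, 2], X[, 3], at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
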