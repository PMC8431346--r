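# Simulation-system composition bookkeeping.
#
# Given a protein sequence, a protonation convention for the titratable
# residues, lipid counts (zwitterionic PC plus anionic cardiolipin) and a
# water count with an excess-salt concentration, compute the neutralizing
# and excess Na+/Cl- ion numbers. Two protonation conventions are
# supported: "unprotonated" (Asp/Glu -1, His neutral) and "protonated"
# (Asp/Glu neutral, His +1); Lys/Arg are +1 and the termini are charged
# (+1/-1, net 0) in both.

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Protonation state charge rules
#'
#' @param name `"unprotonated"` or `"protonated"`.
#' @return object of class `protonation_state`: per-residue-type integer
#'   charges for D, E, H, K, R plus `nter` and `cter`.
#' @export
protonation_state <- function(name = c("unprotonated", "protonated")) {
  name <- match.arg(name)
  charges <- if (name == "unprotonated")
    c(D = -1L, E = -1L, H = 0L, K = 1L, R = 1L)
  else
    c(D = 0L, E = 0L, H = 1L, K = 1L, R = 1L)
  structure(list(name = name, charges = charges, nter = 1L, cter = -1L),
            class = "protonation_state")
}

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), AA1)
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ","))
  aa
}

#' Count residues of one type in a sequence
#'
#' @param sequence protein sequence, one-letter code.
#' @param residue_type single one-letter residue code (e.g. "D").
#' @return integer count.
#' @export
count_residues <- function(sequence, residue_type) {
  aa <- check_sequence(sequence)
  if (!residue_type %in% AA1) stop("unknown residue type: ", residue_type)
  sum(aa == residue_type)
}

#' Protein net charge under a protonation state
#'
#' @param sequence protein sequence, one-letter code.
#' @param state a `protonation_state` (or its name).
#' @return integer net charge including the (+1/-1) termini.
#' @export
protein_net_charge <- function(sequence, state = protonation_state()) {
  if (is.character(state)) state <- protonation_state(state)
  aa <- check_sequence(sequence)
  if (length(aa) == 0) return(0L)
  q <- sum(state$charges[aa], na.rm = TRUE)
  as.integer(q + state$nter + state$cter)
}

#' Excess NaCl ion pairs from water count and concentration
#'
#' Converts a molar salt concentration into a whole number of Na+/Cl-
#' pairs using the pure-water molarity 55.345 mol/L:
#' `floor(n_water * conc_mM / 1000 / 55.345)`.
#'
#' @param n_water number of water molecules (>= 0).
#' @param conc_mM excess salt concentration in mM (>= 0).
#' @return integer pair count.
#' @export
excess_salt_pairs <- function(n_water, conc_mM) {
  if (n_water < 0 || conc_mM < 0) stop("n_water and conc_mM must be non-negative")
  as.integer(floor(n_water * conc_mM / 1000 / 55.345))
}

#' Simulation-system composition specification
#'
#' @param sequence protein sequence (one-letter).
#' @param n_popc,n_tocl lipid counts (PC is net-neutral; TOCL anionic).
#' @param n_water water molecule count.
#' @param salt_mM excess NaCl concentration in mM.
#' @param tocl_charge_per_lipid integer charge per cardiolipin
#'   (default -1, singly ionized).
#' @return object of class `composition_spec`.
#' @export
composition_spec <- function(sequence, n_popc, n_tocl = 0, n_water, salt_mM = 0,
                             tocl_charge_per_lipid = -1L) {
  if (any(c(n_popc, n_tocl, n_water, salt_mM) < 0)) stop("counts must be >= 0")
  check_sequence(sequence)
  structure(list(sequence = sequence, n_popc = n_popc, n_tocl = n_tocl,
                 n_water = n_water, salt_mM = salt_mM,
                 tocl_charge_per_lipid = as.integer(tocl_charge_per_lipid)),
            class = "composition_spec")
}

#' Na+/Cl- counts neutralizing a simulation system
#'
#' Total charge to neutralize is the protein net charge plus the total
#' lipid charge; the deficit is covered by counterions on top of the
#' excess-salt pairs, so the assembled system is exactly neutral.
#'
#' @param spec a `composition_spec`.
#' @param state a `protonation_state` (or its name).
#' @return list with `n_na`, `n_cl`, `protein_charge`, `lipid_charge`,
#'   `salt_pairs`, `total_charge` (always 0).
#' @export
ion_counts <- function(spec, state = protonation_state()) {
  stopifnot(inherits(spec, "composition_spec"))
  if (is.character(state)) state <- protonation_state(state)
  q_p <- protein_net_charge(spec$sequence, state)
  q_l <- as.integer(spec$n_tocl * spec$tocl_charge_per_lipid)
  pairs <- excess_salt_pairs(spec$n_water, spec$salt_mM)
  q <- q_p + q_l
  n_na <- pairs + max(0L, -q)
  n_cl <- pairs + max(0L, q)
  list(n_na = as.integer(n_na), n_cl = as.integer(n_cl),
       protein_charge = q_p, lipid_charge = q_l, salt_pairs = pairs,
       total_charge = as.integer(q_p + q_l + n_na - n_cl))
}

#' The Bcl-xL sequence shipped with the package
#'
#' Canonical human Bcl-xL (UniProt Q07817, 233 residues), the full-length
#' protein whose titratable-residue complement (10 Asp, 21 Glu, 4 His,
#' 20 Lys+Arg) drives the charge bookkeeping for the four membrane-anchored
#' simulation systems.
#'
#' @return one-letter sequence string.
#' @export
bclxl_sequence <- function() {
  path <- system.file("extdata", "bclxl_q07817.fasta", package = "memgroove")
  lines <- readLines(path)
  paste(lines[!startsWith(lines, ">")], collapse = "")
}
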