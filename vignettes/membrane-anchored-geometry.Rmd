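---
title: "Conformational geometry of membrane-anchored Bcl-xL: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational geometry of membrane-anchored Bcl-xL: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memgroove)
```

## The scientific problem

Bcl-xL in its membrane-anchored conformation keeps its soluble head
(helices α1–α7) folded above the bilayer while only the C-terminal helix
α8 crosses the membrane. Whether the head's BH3-binding groove — the cleft
around helices α3–α5 that engages the BH3 domains of pro-apoptotic
partners — faces the solvent or the membrane is a geometric question, and
this package provides the descriptors that answer it on molecular-dynamics
trajectories:

* **Groove orientation ϕ** — the deviation angle between a "groove vector"
  and the membrane normal. The groove vector is the unit normal of the
  plane spanned by (i) the principal axis of helix α5 (residues 143–153)
  and (ii) the vector from the geometric center of the α-carbons of
  residues 143–146 (on α5) to that of residues 170–173 (on α6). Angles
  above 90° indicate a partially occluded groove, angles below 90° a more
  accessible one.
* **Loop geometry** — the radius of gyration of the 61-residue α1–α2 loop
  (residues 21–81) and the positions of Gly-21 and Gly-70 along the
  transmembrane direction, measured from the upper phosphate plane.
* **TM tilt ψ** — the deviation angle of the α8 (residues 209–231)
  principal axis from the membrane normal.

Around these descriptors the package carries the supporting machinery: a
full-length model builder that joins a head structure and an anchor-helix
structure at Gln-207 and embeds the chimera at the bilayer, stationary-
interval histograms, charge/ion bookkeeping for simulation-system
composition, and a synthetic-trajectory generator with exact ground truth.

## Helix axes and the groove vector

A helix principal axis is computed from the moment-of-inertia tensor of
its α-carbons, `I = Σᵢ (|rᵢ|²·Id − rᵢrᵢᵀ)` over centroid-centered
positions with **unit masses** (masses are a convention here, not physics;
unit masses make the computation reproducible without an element table).
The long axis is the eigenvector of the smallest eigenvalue, sign-fixed so
it points N→C. If the two smallest eigenvalues agree to a relative gap
below 1e-9 the geometry is degenerate (no unique long axis) and the
package raises an error rather than picking arbitrarily.

Helix *membership* (which residues belong to α5, α8, …) is fixed once from
the initial configuration; the axis itself is recomputed on every frame —
a frozen axis could not produce a time series of orientations.

The groove vector is `g = unit(a × c)` with `a` the α5 axis and `c` the
α5→α6 center connector. The cross-product order is a convention: flipping
it maps every angle ϕ to 180° − ϕ (an involution exposed via the `flip`
flag of `groove_def()` and covered by tests). The chosen order preserves
the >90° = occluded / <90° = accessible semantics on the toy reference
architecture. Exactly 90° is classified as occluded — the conservative
choice for a descriptor whose accessible reading would invite biological
interpretation.

The membrane normal is the simulation-box +z axis, oriented toward the
leaflet adjacent to the soluble head. Bilayers here are planar;
instantaneous fitted normals for curved membranes are out of scope. Each
leaflet's phosphate plane is the arithmetic mean z of its lipid
phosphorus atoms, with leaflet assignment by sign relative to the median
phosphorus z — robust for planar bilayers without clustering.

One consequence of the N→C sign convention deserves a note: a C-terminal
anchor helix enters the membrane from the head side, so its N→C axis
points *down* the normal and its raw deviation angle ψ sits near
180° minus its geometric tilt. The supplement is the acute tilt usually
quoted for TM helices.

## Model building

`join_structures()` joins a head source (residues 1–222 in the reference
use case) to an anchor source (residues 209–231) at junction residue 207.
The head is rigidly superimposed onto the tail frame by a least-squares
fit of the α-carbons of residues 209–214 — the smallest window inside the
overlap of both sources that gives a well-conditioned fit (the junction
residue itself exists only in the head, so the fitted window starts at the
tail's first residue). Residues up to the junction come from the head;
residues beyond it from the tail; residues between the junction and the
tail's first residue (here, 208) are taken from the head so the chain is
gapless. The overlap RMSD is returned, and a large value warns rather
than fails: two independently determined experimental structures need not
agree.

`embed_in_membrane()` applies a rigid z-translation chosen
deterministically (midpoint of the feasible interval) so that three
constraints hold simultaneously: the anchor tryptophan's (Trp-213) Cα
lies within a configurable window just below the upper phosphate plane
(default 0–3 Å below — "just below" needs a number, and 3 Å is roughly
one helical turn); no head atom is more than 4 Å above the plane at its
closest approach; and the TM helix spans both planes. Unsatisfiable
constraint sets produce an error naming the violated constraints. All
builder operations are rigid — pairwise distances are preserved to
numerical precision — and nothing is minimized or remodeled after the
join; the builder's contract ends at rigid placement.

## Interval statistics

Time windows are half-open, `[t0, t1)`, so adjacent windows partition a
trajectory without double counting. Stationarity is declared by the user
(typically the first microsecond of a run is discarded as equilibration);
the package deliberately performs no changepoint detection. Histograms
are density-normalized (they integrate to 1) with bin edges anchored at
integer multiples of the bin width so that binning is deterministic and
comparable across runs. Default bin widths — 2.5° for angles, 0.5 Å for
Rg, 1 Å for z — resolve the structure of microsecond-scale distributions
without over-fragmenting a few hundred frames; all are configurable.
Summaries (mean, sd, modal bin) are plain linear statistics: deviation
angles live on the bounded interval [0°, 180°], not on a circle, so
circular statistics would be wrong here.

## Composition bookkeeping

`ion_counts()` assembles the Na⁺/Cl⁻ complement of a protein/membrane/
water system from four ingredients: the protein net charge under a
protonation convention, the lipid charge, the excess-salt pair count, and
exact neutralization. Conventions, each forced by the requirement that a
single configuration reproduce the reference ion listings of all four
membrane-anchored Bcl-xL systems the package is validated against
(43 Na⁺/32 Cl⁻ and 32 Na⁺/56 Cl⁻ for the two PC systems; 131 and 96
neutralizing Na⁺ for the two PC/cardiolipin systems):

* *Unprotonated*: Asp/Glu −1, His neutral. *Protonated*: Asp/Glu neutral,
  His +1. Lys/Arg +1 and termini +1/−1 in both. His⁰ in the unprotonated
  state is the unique reading consistent with all four listings
  (the protonated-minus-unprotonated charge difference must equal
  D + E + H = 35).
* Cardiolipin at −1 per lipid (singly ionized): the unique value
  reconciling 131 = 120 + 11 and 96 = 120 − 24.
* Excess pairs = `floor(n_water × mM/1000 / 55.345)` with the 55.345 M
  pure-water molarity; `floor` (not `round`) is required for both 36,055
  and 36,094 waters at 50 mM to give 32 pairs.
* The shipped sequence is canonical human Bcl-xL (UniProt Q07817, 233
  residues: 10 Asp, 21 Glu, 4 His, 20 Lys+Arg, net −11/+24). A
  construct truncated after residue 231 would lose Arg-232/Lys-233 and
  give net −13/+22, inconsistent with every one of the four listings;
  the full-length charge complement is the only one that reproduces them,
  so it is the one shipped.

Every assembled system is exactly neutral by construction, a property
tested over randomized sequences and compositions.

## The synthetic generator: what it emulates, and what it does not

Microsecond all-atom trajectories of a membrane protein cannot be
regenerated at desk scale, so validation rests on synthetic fixtures with
known ground truth. The generator builds a Cα-only toy protein using the
production residue numbering (α5 at 143–153, α6 windows at 170–173, loop
21–81 with Gly-21/Gly-70, Gln-207, Trp-213, α8 at 209–231), a phosphate-
bead bilayer at ±14 Å (a 23-residue, 33 Å ideal helix spans these planes
with slack), and rigid-body trajectories in which:

* the head is rotated each frame so the groove angle follows a prescribed
  schedule *exactly* — constant, piecewise (sharp transitions), or a
  stationary Ornstein–Uhlenbeck process discretized with exact
  conditional updates (`x' = μ + (x−μ)e^{−Δt/τ} + σ√(1−e^{−2Δt/τ}) ε`),
  so its stationary mean and sd are analytic, not Euler approximations;
* the TM helix is held at a prescribed geometric tilt;
* loop Cαs are isotropically rescaled about their centroid to hit
  prescribed radii of gyration, and selected residues can be pinned at
  prescribed heights above the upper phosphate plane;
* optional isotropic Gaussian noise (σ per atom) degrades the coordinates
  after the fact, with the stored truth remaining noise-free.

Ideal helices receive a small shear correction (below 0.05 Å per
coordinate) that removes the residual covariance between transverse and
axial coordinates left by an incomplete final turn; without it the
inertia axis of a finite helix deviates from the nominal axis by ~0.1°.

Default fixtures are 500 frames at 0.01 μs/frame — a 5 μs emulation small
enough to analyze in seconds. All randomness is seeded and identical
seeds give byte-identical output.

What passing these tests shows: the descriptor pipeline recovers known
orientations, transitions, loop dimensions and insertion depths exactly
(noise-free) and to better than 2° mean error under 0.5 Å atomic noise.
What it does not show: anything about force fields, sampling, lipid
specificity, or real conformational thermodynamics — the fixtures are
rigid-body kinematics with no physics, no lipid tails and no water, and
real trajectories additionally contain internal deformations of the head
that the rigid toy cannot produce.

## Degenerate inputs and numerical choices

* Selections resolving to nothing return an explicit empty result; every
  analysis operation converts that into an error naming the selection.
* Collinear α5 axis and α5→α6 connector (cross product below 1e-6) —
  error: the groove plane is undefined.
* Fewer than 3 Cαs in a helix, isotropic point sets, all phosphorus beads
  in one leaflet, non-finite coordinates or times — errors, never silent
  repair.
* Per-frame errors in series computations are rethrown with the frame
  index.
* Angle clamping: `acos` arguments are clamped to [−1, 1] to absorb
  floating-point drift at 0° and 180°.

## Known limitations

* The trajectory dialect is multi-model PDB (plus in-memory arrays);
  binary formats would need an adapter behind `read_trajectory()`'s
  contract.
* Whole-molecule recentring across periodic boundaries is assumed done
  upstream; the analysis expects unbroken molecules.
* pKa prediction is out of scope: protonation enters only as the two
  bookkeeping conventions.
* The membrane frame assumes a planar bilayer normal to z.
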