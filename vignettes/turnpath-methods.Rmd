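---
title: "Turn-driven hairpin folding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turn-driven hairpin folding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnpath)
```

`turnpath` analyses trajectories of short peptides that interconvert between
an α-helical and a β-hairpin state, with the 12-residue N-terminal fragment of
α-synuclein (MDVFMKGLSKAK) as its reference system. This vignette explains the
statistical and geometric models behind each stage, the tunable parameters and
their defaults, what the synthetic-trajectory generator does and does not
emulate, and the design choices that were genuinely open.

## The analysis model

The pipeline asks three questions of an ensemble of backbone conformations.

**What is the dominant structure?** Conformations are clustered on their
mutual Cα RMSD after optimal superposition, with the GROMOS/Daura
neighbour-count algorithm: the frame with the most neighbours within the
cutoff becomes a cluster centre, the cluster is removed, and the procedure
repeats. The centre of the largest cluster — the *most-clustered structure* —
is the ensemble's representative conformation and the reference for every
RMSD coordinate downstream. The cutoff defaults to 0.1 nm, strict
inequality; ties on neighbour count break to the lowest frame index, the
convention of the original algorithm.

**Which interactions define it?** Backbone hydrogen bonds are detected
geometrically: a bond `HB_d-a` (amide H of residue *d* to carbonyl O of
residue *a*) is present when d(H···O) < 0.25 nm **and** ∠(N–H···O) > 135°,
both strict — the criteria of the GROMOS++ analysis suite. β-turns are
four-residue windows `Turn_(i+3)-i` (written later residue first, so
`Turn_9-6` spans residues 6–9); the native criterion is
d(Cα\_i, Cα\_{i+3}) < 0.7 nm with the two interior residues outside the
helical φ/ψ region. Residue 1 carries no amide hydrogen and can never be a
donor; amide hydrogens missing from input files are rebuilt 0.1 nm from N in
the peptide plane, anti to the preceding carbonyl.

The secondary-structure assigner is deliberately transparent geometry —
helix from φ/ψ windows (−57 ± 30°, −47 ± 30° over a three-residue window),
strand from the β region of the Ramachandran map plus a nearby inter-strand
hydrogen bond, turn from the window criterion, precedence H > E > T > C. It
is *not* a STRIDE re-implementation (STRIDE's knowledge-based energy function
is out of scope); externally computed STRIDE or DSSP assignments are
first-class inputs via `read_ss_assignment()`, with DSSP bend codes mapped to
coil and counted separately. Because strand precedence claims the
hydrogen-bonded flanking pair of an ideal hairpin, a turn label requiring all
four window residues to be coded T is unattainable on perfect geometry;
`turn_track()` therefore defaults to the native window criterion and offers
the all-four-T mode for imported assignments.

**How does it fold?** Two complementary statistics. First, the conditional
probability P(H-bond | turn absent): if the designated bonds are never
observed in frames lacking the designated turn, the turn must form first —
the zipper mechanism. Frames with the turn always present give an *undefined*
conditional (flagged, never reported as 0). Second, transition paths across a
two-dimensional free-energy surface, F = −kT ln P with
kT = 0.0083145 kJ mol⁻¹ K⁻¹ × T and T = 300 K by default, over the
coordinates (RMSD to the most-clustered structure, discrete code). The code
is −1 when the turn is absent and k ∈ 0…n when the turn is present with k of
the n designated bonds formed; only the designated set is counted. RMSD is
binned at 0.01 nm (matching the two-decimal precision at which basin
positions are conventionally reported); the code axis is categorical. The
global sampled minimum is shifted to zero; unsampled bins are `NA`, never
+∞. A sampled bin is a local minimum when strictly lower than all sampled
8-neighbours, so plateaus report no minima — a documented tie rule.

Per-frame basin labels come from rectangles of ± 0.05 nm around the basin
positions at their exact code level (the defaults encode the two standard
conditions: U1 (0.23, 0), U2 (0.38, 2), F (0.08, 3) at physiological pH;
U1 (0.27, 0), F (0.08, 4) at acidic pH — overridable, since basin boundaries
are an analysis choice, not data). The label series is compressed to its
sequence of visited basins (unassigned frames and repeats dropped); each
maximal segment from an unfolded basin to the folded label is one folding
event, a trailing multi-basin segment without folding is an interconversion
event, and events are tallied against a configurable catalog
(U1>F, U2>F, U1>U2>F, U2>U1>F, U1>U2, U2>U1 by default). This segmentation is
the package's own definition — the field reports path probabilities without
stating a counting rule — so it is prominent here, and a first-passage-only
mode is available as the natural alternative.

## The two pH conditions

The protonation label on a topology selects the designated registries that
the field associates with each condition: at physiological pH the hairpin has
`Turn_9-6` with four bonds (HB_9-6, HB_6-9, HB_11-4, HB_4-11); at acidic pH
`Turn_8-5` with five (HB_8-5, HB_5-8, HB_10-3, HB_3-10, HB_12-1 — residue 1
appears only as an acceptor, having no amide H). Both follow the antiparallel
register implied by their turn: the turn-flanking pair bonds in both
directions, then every second pair outward.

## The synthetic-trajectory generator

The generator stands in for microsecond MD data. Its templates are
ideal-geometry backbones built residue by residue (NeRF construction from
ideal bond lengths and angles; ω = 180°) whose φ/ψ dihedrals are refined by a
deterministic penalized least-squares fit until the template realizes a
programmed structural state: which designated bonds are formed (target
d(H···O) ∈ 0.17–0.19 nm, angle ≥ 168°), which are absent (pushed past 0.32 nm
or below 104°), whether the turn window is closed or open, and the Cα RMSD
from the folded reference. Construction is verified against the package's own
annotators and aborts if a programmed state is not realized — an
inconsistent registry fails loudly rather than silently degrading.

Each mechanism mode is a schedule over these templates:

- `turn_first` — helix, then the turn-formed basin U1, then bond-gaining
  states through to the folded hairpin. The default turn onset at 19 % of the
  trajectory gives a turn occupancy of 0.81, and the dwell fractions of
  U1/U2/F follow the Boltzmann weights exp(−F/kT) of basin depths of
  0.3 / 1.7 / 0 kJ mol⁻¹ (physiological) and 1.8 / 0 kJ mol⁻¹ (acidic) —
  i.e. the generator's defaults *are* the study conditions its output is
  meant to emulate. No designated bond geometry exists before the turn onset.
- `hbond_first` — the outer bond pair forms while the turn window is still
  open (a "collapse" template holds d(Cα₆, Cα₉) ≈ 0.78 nm with HB_11-4 and
  HB_4-11 intact), then the turn closes. The turn-closing pair cannot
  physically precede the turn — an H-bond between residues 6 and 9 forces
  their Cα distance under the turn cutoff — so the collapse signature lives
  in the outer bonds, and their conditional P(HB | no turn) sits near 0.5.
- `two_path` — repeated folding events, each starting folded, unfolding into
  U1 or U2 (drawn from the mixture, default 0.7/0.3) and refolding through
  the F basin. Starting events folded keeps the folded structure dominant,
  as in the ensembles this emulates.

The F basin is deliberately a **two-conformer mixture**: both members sit at
the basin's RMSD (0.08 nm) from the folded structure but ≥ 0.11 nm from each
other. A single F conformer would make every F and folded frame mutual
neighbours at the 0.1 nm cutoff with exactly equal neighbour counts, so the
most-clustered structure would be decided by the index tie-break — a
degeneracy real, conformationally heterogeneous basins do not have.

State switches are instantaneous by default, which makes programmed onsets
exact (an annotated zero-noise trajectory flips its turn track at precisely
the scripted frame); `switch_frames > 0` instead interpolates linearly in
dihedral space, keeping every intermediate chemically sane — Cartesian
interpolation would break bond lengths. Isotropic Gaussian noise (default
σ = 0.005 nm, truncated at 3σ) is added to every atom after the rebuild. At
σ = 0.005 nm the 3σ truncation makes flipping a helix-frame bond detection
geometrically impossible, so turn-first conditionals are exactly zero, not
merely small; at σ = 0.01 nm the stated template margins keep detected tracks
equal to ground truth on ≥ 99 % of frames. What the generator does **not**
emulate: force-field energetics, solvent, realistic kinetics (dwell times are
scheduled, not sampled from any rate model), side chains, and the relation
between basin depths and transition frequencies. Passing tests therefore
demonstrate that the *analysis* recovers programmed structure and mechanism
signals from noisy coordinates — not that real trajectories behave this way.

## Numerical choices

- Superposition solves the Kabsch problem via SVD with a determinant-sign
  correction (reflections disallowed); a Horn quaternion solver is kept as an
  independent second algorithm and the two agree to 10⁻¹⁰ nm in the test
  suite. The reported RMSD is the explicit post-rotation residual — the
  E₀ − 2Σσ shortcut loses ~8 digits to cancellation for near-identical
  frames.
- All coordinates are nm in memory; the PDB reader/writer (the only Å↔nm
  boundary) round-trips to PDB precision (10⁻³ nm), and the plain-text
  frame-array dialect round-trips bit-exactly (full `%.17g` doubles).
- Times default to 50 ps spacing when a file carries none (50 000
  conformations per 2 500 ns pair of trajectories).
- Strict inequalities everywhere a threshold is stated ("less than" /
  "more than"), including the cluster cutoff and both H-bond criteria.
- `run_pipeline()` thins pooled frames to `max_cluster_frames` (default
  2 000) by a deterministic uniform stride before the quadratic RMSD matrix;
  the analyses in this package's tests and acceptance script use 300–2 000
  frames for clustering and 2 000–5 000-frame trajectories elsewhere, sizes
  chosen so the whole validation suite runs in minutes on a single core.
- The acceptance script reports basin depths as region-integrated free
  energies, −kT ln(P_region/P_F), rather than single-bin minimum depths:
  basin templates sit at RMSD values that are multiples of the bin width, so
  a single bin's count can split across an edge; the integrated quantity is
  the one the generator's Boltzmann dwell design actually controls.

## Known limitations

Periodic-boundary imaging is not handled (inputs are assumed whole-molecule);
the PDB reader covers the common ATOM/MODEL subset, not altlocs or insertion
codes; the secondary-structure assigner is a geometric approximation that
agrees with STRIDE on ideal fixtures but not necessarily on marginal
conformations (import real STRIDE/DSSP output where that matters); clustering
is quadratic in frames, so very long trajectories should be thinned; and the
transition-path probabilities inherit the event-segmentation definition
above — comparisons against other software should check which counting rule
it uses.
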