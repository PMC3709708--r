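# turnpath

Trajectory analysis of the α-helix → β-hairpin transition of short peptides,
built around α-syn12 (MDVFMKGLSKAK, residues 1–12 of human α-synuclein, an
amyloidogenic fragment implicated in Parkinson's disease). The package is for
people who have molecular-dynamics trajectories of a small peptide (or want
synthetic stand-ins) and need the standard mechanism questions answered: what
is the dominant conformation, which β-turn and which backbone hydrogen bonds
define it, does the turn form before the hydrogen bonds (zipper mechanism) or
after them (hydrophobic collapse), and which routes across the free-energy
surface connect the unfolded and folded basins.

## What it computes

- **Superposition & RMSD** — Kabsch least-squares fitting (SVD, with a
  quaternion cross-check) and Cα RMSD time series / pairwise matrices.
- **Conformational clustering** — the GROMOS/Daura neighbour-count algorithm:
  conformations within RMSD<sub>Cα</sub> < 0.1 nm cluster together; the centre
  of the largest cluster is the *most-clustered structure*.
- **Annotation** — backbone hydrogen bonds by the geometric criterion
  d(H···O) < 2.5 Å and ∠(N–H···O) > 135°; β-turn windows
  (d(Cα<sub>i</sub>, Cα<sub>i+3</sub>) < 0.7 nm with non-helical interior);
  a transparent H/E/T/C secondary-structure assigner plus STRIDE/DSSP file
  import; per-residue turn/strand propensities.
- **Free-energy surfaces** — F = −kT ln P over two reaction coordinates:
  RMSD<sub>Cα</sub> from the most-clustered structure (x) and a discrete code
  (y): −1 when the designated turn is absent, k = 0…n when the turn is present
  with k of the n designated bonds formed. Local minima, basin labelling.
- **Mechanism statistics** — occurrence probabilities per trajectory and
  pooled; the conditional P(H-bond | turn absent), whose vanishing is the
  signature of turn-first folding; transition-path counts between basins
  (U1→F, U2→F, U1→U2→F, …).
- **Synthetic trajectories** — a backbone generator with programmed
  mechanisms (`turn_first`, `hbond_first`, `two_path`) and ground-truth
  tracks, so every stage is testable without MD data.

## Worked example

Two synthetic 2000-frame trajectories with a programmed turn-first mechanism
at physiological pH, run through the full pipeline:

```r
library(turnpath)
g1 <- generate_trajectory(mechanism_script("turn_first", n_frames = 2000, seed = 1))
g2 <- generate_trajectory(mechanism_script("turn_first", n_frames = 2000, seed = 2))
cfg <- pipeline_config(list(g1$trajectory, g2$trajectory),
                       condition = "physiological", max_cluster_frames = 800)
report <- run_pipeline(cfg)
report
#> <mechanism_report> (physiological pH)
#>   top cluster population: 0.420
#>   verdict: turn precedes H-bonds
#>   paths: U1>U2>F 1.00
```

The occurrence table summarises formation probabilities per trajectory and
pooled (the generator programs a turn occupancy of 0.81):

```r
tidy(report, "occurrence")
#>    trajectory label    probability n_frames
#>  1 1          Turn_9-6       0.81      2000
#>  2 1          HB_9-6         0.282     2000
#>  3 1          HB_6-9         0.562     2000
#>  ...
#> 11 pooled     Turn_9-6       0.81      4000
```

The conditional probabilities show the zipper signature — the designated
bonds are never seen without Turn_9-6:

```r
tidy(report, "conditionals")
#>   turn     hbond   probability n_conditioning_frames defined
#> 1 Turn_9-6 HB_9-6            0                   760 TRUE
#> 2 Turn_9-6 HB_6-9            0                   760 TRUE
#> 3 Turn_9-6 HB_11-4           0                   760 TRUE
#> 4 Turn_9-6 HB_4-11           0                   760 TRUE
```

and the free-energy surface recovers the programmed basins on the
(RMSD, turn/H-bond code) plane — the unfolded-with-turn basin near
(0.23 nm, 0), the two-bond basin near (0.38 nm, 2), the three-bond basin near
(0.085 nm, 3), the folded hairpin at (0.005 nm, 4) and the helix at
(0.6 nm, −1):

```r
tidy(report, "minima")
#>   x_center y_level depth
#> 1    0.235       0 0
#> 2    0.615      -1 0.179
#> 3    0.085       3 0.226
#> 4    0.385       2 2.41
#> 5    0.005       4 2.55
```

(Depths of individual histogram bins fluctuate at this desk scale when a
basin straddles a bin edge; `scripts/acceptance.R` reports the stabler
region-integrated depths.) `autoplot(attr(report, "fes"))` draws the surface
with 1 kJ/mol contours; `plot_rmsd_series(attr(report, "rmsd"))` the RMSD
traces.

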