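---
title: "Symmetry and gating analysis of homodimeric transporter transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry and gating analysis of homodimeric transporter transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimergate)
```

## The problem

Homodimeric ABC importers such as BtuCD translocate their substrate by
switching the transmembrane pathway between an outward-facing state (open
to the periplasm, occluded on the cytoplasmic side) and an inward-facing
state (the reverse), with the motion powered by the cytoplasmic
nucleotide-binding domains. Characterizing a simulated transition of such a
machine calls for metrics that respect its architecture: a *dimer of
dimers* with an approximate two-fold axis normal to the membrane. This
package implements those metrics — the TMD/NBD spin angle, symmetry-breaking
statistics, pore and gate geometry — together with a synthetic trajectory
generator that provides ground truth to validate them against.

## The metrics and their assumptions

### Spin angle

For a frame of a trajectory, the reference structure's TMD dimer is
least-squares superposed onto the frame's TMD C&alpha; atoms, and the
reference NBD dimer onto the frame's NBD C&alpha; atoms (Kabsch algorithm,
proper rotations only). The transformed reference subunit mass centers
define one line through the TMD dimer and one through the NBD dimer; the
spin angle is the angle between them.

Two conventions here were genuinely open and are settled as follows:

- **Projection.** The motion being measured is a *spin* about the
  transporter's quasi-C2 axis, so by default both lines are projected onto
  the plane perpendicular to the membrane normal before taking the angle;
  this makes the angle respond one-to-one to rotations about the normal
  (recovered to well under 0.1° in the tests). The unprojected 3D angle is
  available with `projection = "none"`; it is the variant invariant under
  arbitrary rigid motions of the frame, while the projected angle is
  invariant under motions that preserve the membrane orientation.
- **Membrane normal.** Taken to be the z axis of the input, which is
  assumed pre-oriented (crystal structures of membrane proteins in this
  workflow are membrane-aligned); an explicit normal can be supplied.
- **Sign and range.** The angle is reported in [0°, 180°); a signed
  variant, oriented by the normal, is reported alongside so that series
  remain continuous across frames.

Mass centers are computed over C&alpha; atoms with equal weights — at
C&alpha; resolution per-residue masses would add noise, not information.

### Symmetry-breaking statistics

Residue pairs are selected once, from the reference structure: every
unordered C&alpha; pair closer than `d0` (default 8 Å, strict inequality)
whose residues both have symmetry partners. Each pair (i, j) has a partner
pair (i′, j′) in the opposite half, and the per-frame ingredient of every
statistic is |d_ij − d_i′j′|, a pure internal-distance quantity.

- `casymm()` aggregates over pairs within one frame. The mean-absolute
  form is the default; the root-mean-square form is provided because either
  is a defensible aggregation of the same ingredients, and the choice
  matters (RMS weights outliers more, and is never smaller — a Jensen
  inequality the test suite checks). Reported values state their form.
- `aij()` is the quadratic mean of |d_ij − d_i′j′| over frames, reducing
  to the static value for a single frame; static structures and
  trajectories deliberately share this one code path.
- `classify_arps()` flags pairs with A_ij strictly above the threshold
  (default 0.8 Å) and attributes counts to region classes; the 0.5/1.0/2.0 Å
  tier histogram is a display aid, not the selection rule.

Pair bookkeeping keeps a pair and its symmetry partner as *distinct*
entries when both satisfy the cutoff (`dedup = "none"`), because the
partner pair probes the geometry of the other half; `dedup = "symmetric"`
counts each symmetry-equivalent duo once for analyses where that double
counting would bias totals. Symmetry partners are same-numbered residues in
the paired chain — the natural convention for a sequence-identical
homodimer.

### Pore and gate geometry

The pore profile follows the maximal-inscribed-sphere construction: per z
slice, the radius is the largest clearance min(|c − x_a| − r_a) over atoms
a, maximized over in-plane centers c. The maximizer is a multi-start
pattern search (previous slice's center plus four jittered starts,
step-halving to 0.01 Å); an exhaustive 0.05 Å grid oracle in the tests
guards its correctness at test scale. Numerical choices:

- radii are clamped to [0, `max_radius`] (default cap 10 Å — beyond that
  the probe has escaped the protein and the value is meaningless; capped
  slices are flagged, not errors);
- the greedy uphill search cannot leak through gaps between discrete
  atoms, because escaping a basin would require moving downhill first;
- van der Waals radii come from a small per-element table (C 1.70, N 1.55,
  O 1.52, S 1.80, H 1.20, P 1.80 Å, default 1.70), overridable per call.

A *layer* is a z slab named after a lining residue; a residue-anchored
layer is centered at the mean z of the residue's two partner C&alpha;
atoms in a reference frame, with half-width 2 Å (both overridable — the
literature labels layers by residue but never defines extents). `d_pair`,
`delta_dpair` and the minimal heavy-atom contact distances are raw
internal distances, never superposed.

## The synthetic generator

`build_toy_homodimer()` produces a four-chain bead model: two TMD-role
chains forming a stacked-ring channel and two NBD-role chains as bead
balls beneath it, with halves exactly related by a 180° rotation about z
in both end states (C_asymm is zero to machine precision by construction).
Study conditions, fixed once:

- 30 beads per chain (120 total), six rings at z = 0..25 Å, bead vdW
  radius 1.7 Å;
- state O: periplasmic gate ring radius 6 Å, cytoplasmic 3 Å, core rings
  7 Å; state I mirrors the gates and twists the two gate rings by 120°
  azimuthally. The twist is what makes the straight-line path between the
  states *double-occluded*: linearly interpolated gate beads pass closer
  to the axis than in either end state, emulating the occluded
  intermediate expected between outward- and inward-facing states and
  giving the gate-detection machinery a real signal to find;
- the NBD dimer spins by 8° about z and separates by 1.5 Å between states.

`run_steered()` evolves the beads by overdamped (position) Langevin
dynamics on an elastic network plus the targeted-MD potential
E = k/(2N)(rmsd − rmsd*)², with the rmsd* schedule decreasing linearly
from the inter-state best-fit RMSD to zero. Forces are the negative
gradient computed after rotating the target into the frame; the gradient
through the optimal rotation vanishes at the optimum (envelope argument),
which the finite-difference tests confirm to 1e-5 relative. The steering
force has zero net sum, so no translation is injected.

Numerical defaults, chosen from the overdamped relaxation analysis (the
schedule-tracking lag is approximately v·γN²/k for schedule speed v) and
held fixed: dt = 0.2 and friction 1 in reduced units, spring constant
0.0025 energy/Å², temperature factor 5e-4, k = 5550 in the familiar
kcal/mol/Å² convention with N the bead count. Only the ratio of steering
to network stiffness matters at toy scale; the network is deliberately
soft so that steering dominates, as in targeted MD proper, giving
schedule tracking within ~0.1 Å RMS and final deviation well under
0.25 Å. A run is declared unstable (classed error) if rmsd exceeds twice
its initial value. Default runs use 1500 steps with every 15th frame
saved — problem sizes at which a full two-direction analysis completes in
seconds.

`inject_asymmetry()` displaces chosen residues of one half along
seed-reproducible directions, statically or growing linearly across
frames, providing labelled ground truth for ARP recovery: with a 2 Å
injection every flagged ARP involves the injected neighborhood (the
injected residues, anything within d0 of them, or their partners — partner
pairs mirror the signal by construction of A_ij), and zero amplitude
yields zero ARPs.

### What the toy does and does not emulate

It reproduces the *structural logic* the statistics rely on: exact
two-fold symmetry at rest, two end conformations with opposite gate
apertures, an NBD spin, thermal noise, schedule-driven steering, and
optional asymmetric perturbations of known location. It does not attempt
realistic energetics, all-atom geometry, membrane or solvent, nor the
kinetics of a real 500-ps targeted-MD run. Passing tests therefore
demonstrate that the *analysis machinery* measures what it claims on
trajectories with known truth — not that any particular protein behaves
this way.

## Degenerate inputs and tie-breaks

- Superposition requires ≥ 3 non-collinear points; collinear sets raise a
  conditioning error rather than returning an arbitrary rotation.
- Residues without a C&alpha; are skipped (and reported) by selections;
  residues without a same-numbered counterpart are excluded (and reported)
  from the homodimer map.
- Alternate locations other than blank/'A' are dropped at read time;
  insertion-coded residues stay distinct; residue numbering is never
  silently changed.
- An empty trajectory yields an empty series from series functions, but an
  error from `aij()`, where an average over zero frames has no value.
- Pore slices with no nearby atoms report the capped radius with a flag.

## Known limitations

- The pore optimizer finds the inscribed sphere in the basin seeded from
  the previous slice; profiles through branched or strongly off-axis
  channels should be seeded explicitly.
- The spin angle presumes a membrane-oriented input frame unless a normal
  is given.
- Trajectories are exchanged as multi-model PDB; binary trajectory
  formats (DCD/XTC) are out of scope — convert externally before analysis.
- C_asymm's two aggregation forms can differ materially on heavy-tailed
  pair distributions; comparisons across studies must state the form.

## Reproducibility

Every stochastic routine takes an integer seed and restores the caller's
RNG state; identical seeds give bitwise-identical toys, trajectories and
pipeline outputs. `run_pipeline()` stamps each output with the package
version, a hash of the configuration and the seed.
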