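---
title: "Calling disorder-to-order capping events across structural ensembles"
author: "capscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling disorder-to-order capping events across structural ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capscan)
```

## The problem

Mobile structural elements that fold over an enzyme's catalytic cavity —
"active-site caps" — are invisible to any single-structure analysis: each
deposited or reconstructed model shows only one of the co-existing
conformations. When several models of the same protein exist (cryo-EM
sub-state reconstructions, independent crystal forms, predicted ensembles),
a segment that is α-helical in some members and absent or displaced in
others is the signature of a disorder-to-order transition coupled to
function. `capscan` turns that signature into an explicit, parameterized
detection rule, assigns every ensemble member to a conformational state with
quantitative fractions, tests the association with AlphaFold's per-residue
confidence (pLDDT), and measures the geometric consequences of capping.

The package's motivating scenario is an inositol-pathway synthase whose
active-site entrance is guarded by a ~16-residue helix (around residues
385–400 of a ~550-residue chain, with a flexible ~39-residue N terminus that
is never resolved). Ensembles of that enzyme partition into a folded-helix
state, a majority state with the helix unfolded, and a minor state with the
helix rigidly shifted by roughly 8 Å — the three-state mixture
(23% / 69% / 8%) used as the default study conditions of the synthetic
generator and the acceptance analysis.

## Pipeline and model

1. **Mapping.** Every chain is aligned globally (Needleman–Wunsch via
   `Biostrings`, match +1 / mismatch 0 / gap open 5 / gap extend 0.5)
   against one reference sequence. Residues keep their author numbers — the
   field names residues that way — while all cross-member comparison happens
   in 1-based reference coordinates. An identity floor (default 0.3)
   rejects mapping the wrong protein; the exact alignment scores are
   immaterial above that floor for the near-identical sequences the tool is
   meant for.

2. **Secondary structure from Cα geometry.** Deposited models and
   backbone-only fixtures must be treated identically, and hydrogen-bond
   based assignment (DSSP) needs full backbones, so assignment is P-SEA
   style on Cα geometry only: a window seeds helix when
   d(i,i+2) ∈ [5.1, 6.4] Å and d(i,i+3) ∈ [4.2, 5.5] Å, or when the Cα
   pseudo-dihedral ∈ [30°, 80°] and pseudo-angle ∈ [85°, 100°]; strand uses
   the extended-geometry analogues (d(i,i+2) ∈ [6.7, 7.1] Å,
   d(i,i+3) ∈ [9.9, 10.7] Å). Each satisfied window marks residues
   i..i+3; helix runs shorter than 5 and strand runs shorter than 3 are
   demoted to coil, which suppresses isolated geometric coincidences in
   coils (measured false-helix rate on self-avoiding random coils: ~3% of
   residues, versus 100% helix on ideal helices of length ≥ 8). 3₁₀ and π
   helices are folded into `H`. Consecutive mapped residues more than
   4.5 Å apart split assignment windows, so chain breaks and unmodeled
   gaps never leak geometry across.

3. **Order matrix and event calling.** Position × member states
   `H`/`O`/`D` (`D` exactly where a position is unmapped or has no
   coordinates). A position is event-positive when the helical fraction
   reaches `θ_H` (scaled by the best member support on the chain, so
   never-modeled termini cannot dilute the criterion) *and* the disordered
   fraction reaches `θ_D`. Defaults `θ_H = θ_D = 0.15`, minimum event
   length 5, merge gap 2: a 16-residue helix present in ~31% of members and
   absent in ~69% is detected with a wide margin, while a region that is
   always ordered (f_D ≈ 0) or never ordered (f_H ≈ 0) can never fire. The
   defaults are deliberately permissive — the screen is a hypothesis
   generator; raising `θ_D` is monotone (never adds events). Ensembles
   smaller than 4 members are refused by default (overridable with a
   warning): with fewer than four structures the occupancy fractions are
   too coarse to mean anything.

4. **State assignment.** Helicity first, displacement second: members whose
   event-segment helicity is undefined (all `D`) or below 0.3 are
   *unfolded*; remaining members are superposed on the rigid core (all
   shared positions outside the segment ± 5 residues) onto the medoid
   helical member — the member whose superposed segment centroid is closest
   to all others, a deterministic stand-in for the consensus folded
   position that is robust as long as the folded class outnumbers the
   alternative class. Members within 4 Å mean segment displacement of the
   medoid are *folded*, the rest *alternative*. The 4 Å default sits
   halfway to the ~8 Å shift the motivating case exhibits; both thresholds
   are exposed.

5. **pLDDT dip test.** The statistic is the event-mean minus the mean of
   two 15-residue flanks (truncated at chain ends). A flank baseline, not
   the whole-chain mean, makes the test robust to domain-level pLDDT
   gradients. The null slides the window to `n_perm` uniformly drawn valid
   positions that do not overlap the true segment and recomputes the
   identical statistic, preserving the statistic's segment-length
   dependence; the one-sided p-value uses the add-one rule, so p ∈
   (0, 1] and can never be exactly zero. Empirical size at α = 0.05 is
   0.03–0.07 and power for a 10-unit dip at noise σ = 2 on a 16-residue
   segment exceeds 0.8 (both recomputed by the acceptance script).

6. **Geometry.** Kabsch superposition (base-R SVD with reflection
   correction; cross-checked in the tests against `bio3d::fit.xyz`),
   named-atom distances and ion coordination shells (default candidate
   elements O/N, cutoff 3.5 Å), Shrake–Rupley SASA (spherical Fibonacci
   quadrature, default 960 points ⇒ <1% error on an isolated atom), buried
   surface area as SASA(A) + SASA(B) − SASA(A∪B), and a two-probe grid
   pocket volume: voxels farther than (vdW + 1.4 Å) from every atom are
   empty; the large probe (3.4 Å) defines bulk solvent by flood fill from
   the box faces followed by a rolling-sphere sweep; remaining empty
   components are cavities, selected by seed point or largest volume.
   Element radii: C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å (plus H,
   halogens and common ions), all overridable.

## The synthetic generator

`make_ensemble()` plants ground truth: one shared self-avoiding random-coil
scaffold; an ideal α-helix (radius 2.3 Å, rise 1.5 Å, twist 100°/residue)
across the event segment for folded members; the same helix rigidly
translated by the planted displacement for alternative members; and the
segment's residues *deleted* for unfolded members — matching how an
unfolded element manifests in real ensembles (unmodeled density), with a
coil-coordinates variant behind a flag. State counts follow
largest-remainder rounding, noise is isotropic Gaussian on Cα positions,
and every generator is bit-reproducible from its seed. Companion fixtures
plant analytic geometry: a hollow atom shell whose cavity volume is known in
closed form, and an active-site fixture with configurable C1–C6 separation
(default 3.4 Å) and ion-coordination distances (defaults 2.4 / 2.8 / 3.2 Å).

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: side chains and realistic backbone geometry
outside the event segment (the scaffold is a random coil, not a folded
domain); partial-occupancy or fractional-helicity members between the three
pure states; correlated noise from model refinement; per-chain numbering
heterogeneity beyond a missing prefix; and any coupling between the planted
pLDDT dip and the coordinates. Recovery of the planted mixture at noise
σ ≤ 0.3 Å is a consistency check of the pipeline's logic, not evidence
about discrimination on borderline experimental ensembles.

## Numerical choices and degenerate inputs

* Altlocs: highest occupancy wins, ties by altloc letter.
* Superposition refuses < 3 points or rank-deficient (collinear) sets;
  a recovered transform followed by its inverse restores coordinates to
  1e-9 Å.
* Segment displacement against a member lacking the whole segment is
  undefined (`NA` with a warning), not zero.
* Pocket volume: grid spacing default 0.5 Å (halving it changes the
  sphere-fixture volume by <3%); the large-probe sweep digitizes the
  Euclidean ball on the voxel grid, iterating smaller balls when the kernel
  would exceed ~500 offsets — a sub-voxel approximation that cannot affect
  fully enclosed cavities and is well inside the method's tolerance for
  open pockets. A seed point inside an atom is an error; no cavity yields
  0 with a warning.
* The permutation test requires `n_perm ≥ 99` and a seed; a segment longer
  than chain − 2 is an error.
* Waters are excluded from SASA/BSA and pocket grids by default, since
  deposited models differ arbitrarily in retained waters.

## Problem sizes

The test suite and acceptance script run the full scenario at 100 members ×
552 residues (the study conditions), calibrate the dip test on 500 null and
100 alternative profiles at `n_perm = 999`, and use compact fixtures
elsewhere (20-member ensembles of 120 residues; shells of a few hundred
atoms) — sizes chosen so each property is measured at the scale where it is
informative.

## Limitations

* Secondary structure from Cα geometry only: no hydrogen-bond evidence, no
  β-pairing/topology; strands are detected but not used by the screen.
* Event calling is occupancy-based; it does not model continuous
  order-disorder gradients within a member.
* The pocket volume targets the stated two-probe semantics, not
  bit-compatibility with any particular surface implementation; comparisons
  of volumes are meaningful within `capscan`, and cross-tool agreement is
  expected only to within the surface-definition differences.
* The dip test treats pLDDT positions as exchangeable under the null;
  strong autocorrelation in a profile makes it conservative rather than
  anticonservative (the sliding null inherits the profile's local
  structure).
* No structure fetching, map handling, or model refinement; inputs are
  coordinate files and profiles already on disk.
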