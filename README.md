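# capscan

Detection and quantification of disorder-to-order **active-site capping**
across structural ensembles of a protein.

Many enzymes gate their catalytic site with a short mobile element — often a
~16-residue α-helix — that is folded over the active site in part of the
population, disordered (invisible in maps/models) in another part, and
sometimes parked in an alternative, "backfolded" position. Resolving these
sub-states and their populations links conformational selection to catalysis:
the capped state assembles catalytic residues, the uncapped state releases
product, and the displaced state may be an intermediate or an autoinhibited
form. `capscan` is aimed at structural bioinformaticians who have several
coordinate models of the same protein (cryo-EM sub-state models, crystal
forms, predicted ensembles) and want to call such *folding events*
quantitatively and reproducibly.

## What it computes

Given an ensemble of models mapped onto one reference sequence, `capscan`
builds the **order matrix** `M[i, m] ∈ {H, O, D}` — reference position `i` in
member `m` is helical (`H`, from Cα-only P-SEA-style assignment), ordered but
non-helical (`O`), or disordered/missing (`D`). With per-position fractions
`f_H(i)` and `f_D(i)`, a position is event-positive when

```
f_H(i) ≥ θ_H · max_support   and   f_D(i) ≥ θ_D        (defaults θ_H = θ_D = 0.15)
```

Maximal event-positive runs of ≥ 5 residues (runs separated by ≤ 2 positions
are merged) become **folding events**. For each event, members are assigned
to three conformational states — *unfolded* (segment helicity < 0.3 or
undefined), *folded* (segment mean Cα displacement from the consensus folded
position < 4 Å after rigid-core superposition), or *alternative* (displaced
helical) — yielding state fractions. A one-sided permutation test asks
whether the event coincides with a local dip in AlphaFold pLDDT:

```
δ = mean pLDDT(event) − mean pLDDT(flanks),   p = (1 + #{δ_null ≤ δ}) / (n_perm + 1)
```

with the null built by sliding the event window to random non-overlapping
positions. Geometry companions quantify the consequences: Kabsch
superposition and segment displacement, catalytic atom distances, ion
coordination shells, Shrake–Rupley SASA and buried interface areas, and a
two-probe grid pocket volume (small probe defines the surface, large probe
peels off bulk solvent — the PyVOL-style min/max-radius semantics).

A fully seeded synthetic-ensemble generator plants all of the above with
known ground truth, so the entire pipeline is testable end to end without
any downloads.

## Worked example

The bundled three-state scenario: 100 members of a 552-residue chain
(residues 1–39 unresolved), with residues 385–400 helical-in-place in 23% of
members, missing in 69%, and helical-but-displaced by 8 Å in 8%, plus a pLDDT
profile with a 5-unit dip over the event:

```r
library(capscan)
cfg <- list(
  synthetic = list(n_members = 100L, chain_length = 552L,
                   event_segment = c(385L, 400L),
                   state_fractions = c(0.23, 0.69, 0.08),
                   displacement = 8, missing_prefix = 39L, noise_sigma = 0,
                   plddt = list(baseline = 90, dip_depth = 5, noise_sigma = 2)),
  seed = 42L)
run_pipeline(cfg)
```

prints (seed 42):

```
<cap_report> 1 event(s)
  start end length helical_members disordered_members mean_dip p_value
1   385 400     16            0.31               0.69 -4.90023   0.001
<cap_states> 100 members: folded 0.230 / unfolded 0.690 / alternative 0.080 (threshold 4.0 A)
<cap_dip> delta -4.900 pLDDT units, one-sided p = 0.001 (999 permutations)
```

One event is called at exactly the planted bounds; 31% of members carry the
helix there (23% in place + 8% displaced) while 69% lack it; the state
fractions recover the planted mixture exactly; and the pLDDT dip (−4.9 units
against the flanks) is significant at p = 0.001. `rep$geometry` additionally
reports the folded-versus-alternative segment displacement (8 Å here).

The same analysis runs from disk (PDB/mmCIF members + reference FASTA +
pLDDT table) via a `files` config block, or from a shell through the thin
CLI in `inst/scripts/capscan.R` (`screen` and `simulate` subcommands).

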