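---
title: "Interface curation and design filtering: methods and design choices"
author: "binderprep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface curation and design filtering: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binderprep)
```

## The problem

Generative models for binder design are conditioned on per-residue
interface cues (which target residues to engage, which to avoid, how
exposed each is) and are trained on curated complexes whose binder is
compact, well packed and genuinely in contact with its target. This
package implements that curation and conditioning arithmetic, plus the
geometric accept/reject gates used to triage designed phosphotyrosine
(pTyr) peptide binders. Everything operates on heavy atoms only:
structures without hydrogens are first-class, and no protonation or
bond-order perception is attempted.

A complex is a flat atom table with chains tagged `binder` or `target`.
Residues are addressed by `chain:resno` with the author numbering
preserved for reporting, while per-residue results are returned in
positional order, so numbering gaps in deposited files never affect
geometry.

## Interface annotation

A target residue is a **hotspot** iff its Cβ lies within 7 Å (inclusive)
of any binder Cβ *and* its solvent-accessible surface area is at least
30 Å² at probe radius 2.8 Å. Glycines and Cβ-less models use a virtual Cβ
built from N/Cα/C at 1.522 Å with the standard L-amino-acid improper
(C–N–Cα–Cβ = −122.6°). An **anti-hotspot** is a target residue whose
minimum heavy-atom distance to the binder exceeds 10 Å (exclusive); the
"any binder residue" wording is read as any-atom, whereas the hotspot rule
is explicitly Cβ–Cβ. Because 7 ≤ 10 the two masks are disjoint by
construction, and the tensor builder enforces that invariant anyway.

**Super-hotspot values** grade hotspots by local contact density: count
binder Cα within 10 Å of the hotspot's Cα, optionally add an integer
jitter drawn uniformly from {−1, 0, +1}, cap at 12 and divide by 12. The
uniform distribution is our choice — "±1" does not pin one down — and the
draw comes from a generator seeded per run and isolated from the session's
RNG state, so annotation never perturbs or depends on user randomness.

Hotspot masks are downsampled to at most 20% of target residues
(`ceiling(0.20 · n_target)`). The *speckle* strategy samples uniformly
without replacement; the *region* strategy seeds one hotspot and grows by
3D nearest-neighbor order among hotspot Cβs until the budget fills. Which
contiguous patch the paper-style region masking selects is unspecified;
nearest-neighbor growth from a seeded pick is our deterministic,
reproducible reading. The **ORI** pseudoatom is the arithmetic mean of
hotspot Cβ positions (or a user-supplied point) and is emitted as a
`REMARK`/`HETATM` pair in written PDBs.

The training-time schedule (hotspot masks in 75% of examples,
anti-hotspots in 10%) is carried as configuration
(`mask_sampling_config()`); this package does not re-validate those rates
statistically, only their seeded determinism.

## Solvent accessibility

SASA is Shrake–Rupley point sampling with a **deterministic golden-spiral
sphere** (default 960 points/atom), chosen so results are bit-for-bit
reproducible at fixed `n_points` — a property we value above the marginal
accuracy of randomized sphere sets. Van der Waals radii: C 1.70, N 1.55,
O 1.52, S 1.80, P 1.80 Å. Two probes are in play, deliberately: the
hotspot gate uses 2.8 Å in complex context (the gate is paired with
interface detection, which only exists in the complex), while the RASA
conditioning channel uses the conventional 1.4 Å water probe normalized by
Tien-style theoretical maximum ASA, clipped to [0, 1]. PTR normalizes by
the tyrosine maximum; residue types outside the table report `NA`
(missing), never 0, so a parser hiccup cannot silently fabricate a buried
residue. Whether training-time SASA was measured on the complex or the
isolated target is unknowable from the text; complex context is the
default and `context = "chain_alone"` is available.

The sampling sphere is fixed in the lab frame, so SASA (hence RASA) has a
small orientation dependence — the test suite asserts rigid-motion
invariance of RASA at 0.02 and of all discrete channels exactly.

## Packing quality and example curation

The side-chain-neighbor count for residue *i* with Cα position *a* and
unit Cβ direction *u*:

$$\mathrm{SCN}_i = \sum_{j \ne i} \frac{1}{1+e^{d_{ij}-9}} \cdot
\begin{cases}\left(\frac{\cos\theta_{ij}+0.5}{1.5}\right)^2 & \cos\theta_{ij} > -0.5\\ 0 & \text{otherwise}\end{cases}$$

with $d_{ij}$ the Cα–Cα distance and $\theta_{ij}$ the angle between *u*
and the vector to Cα$_j$. This is the published Rosetta-style cone form;
the thresholds that consume it (SCN > 4.0 for "packed", > 1.0 for
"folded") are used unchanged. Curation rejects a complex when
`binder_FBSCN < 0.12`, `interface_FBSCN < 0.13` (defined as 0 when there
are no interface residues — degenerate inputs reject, they do not throw),
no hotspots were found, or the binder exceeds 170 residues. The target is
never packing-scored or trimmed, so peptide targets survive intact.

**Trimming** walks in from each binder terminus: take the terminal window
of `min(9, remaining)` residues; if it holds at most 0/1/2 folded residues
(window length ≤4/≤8/>8), remove one terminal residue and repeat; stop at
the first window over tolerance. Removing one residue per iteration (vs
the whole window) keeps the stopping point well defined; that ambiguity
was genuinely open and is resolved this way throughout. When hotspot
bounds are supplied, trimming may continue past a bound only through
unfolded residues and at most 9 deep. If a chain would be trimmed away
entirely, the last residue is kept with a warning. Trimming is idempotent
and always yields a contiguous subsequence.

**Radial cropping** keeps every binder residue and every target residue
with any heavy atom within 25 Å of the crop center's Cβ, the center being
a seeded-uniform choice among hotspots. We read the source text's
"within >25 Å" as a typo for "within 25 Å": a crop that *discards* the
neighborhood of the chosen hotspot would defeat its stated purpose of
limiting context while preserving local geometry. The radius, like every
other threshold, is configurable and echoed into the run manifest.
Measuring center-Cβ to candidate-any-atom (rather than Cβ–Cβ or Cα–Cα) was
an open choice; it is the most retentive of the three, which suits a
context-limiting step.

## Conditioning tensor

29 fixed channels: `aa_*` one-hot (20 standard + unknown), `ss_{H,E,C}`,
`motif_flag`, `hotspot_mask`, `antihotspot_mask`, `hotspot_value`, `rasa`.
PTR (and any nonstandard residue) maps to the unknown slot — the upstream
one-hot has no PTM slot — with the identity recorded in tensor metadata so
nothing is lost. Secondary structure comes from a self-contained
dihedral-window rule (helix: (φ,ψ) ∈ [−100,−30]×[−80,−5] for the residue
and both neighbors; strand: φ ∈ [−180,−80] with ψ ∈ [80,180] ∪
[−180,−170] for the residue and one neighbor; otherwise coil, termini
coil). An external assigner would add a tool dependency for a three-token
signal; the windows are chosen to classify ideal helix (−57,−47) and
strand (−120,+120) geometry correctly, which the tests pin down. Channels
can be masked off per run; masked channels are zero-filled and the mask is
recorded in the JSON sidecar, so "off" is distinguishable from
"zero-valued". Broadcasting copies each residue row to all of its atom
slots. The TSV interface writes 6 significant digits and round-trips
exactly at that precision.

## Design filters

Hydrogen bonds use a heavy-atom geometric criterion: donor–acceptor
distance ≤ 3.5 Å and acceptor-antecedent angle ≥ 90°, plus D–H⋯A ≥ 120°
when explicit hydrogens exist. These numbers are common structural-biology
practice (the source describes the gates, not the geometry) and are
configurable. Donor/acceptor typing is table-driven per residue; unknown
chemistry is skipped with a warning rather than guessed.

The gates: ≥ 2 hydrogen bonds from binder donors to *terminal* phosphate
oxygens of a target-chain PTR; ≤ 12 total binder↔peptide hydrogen bonds
(both directions, backbone included, phosphate bonds included — subset
semantics); pTyr RMSD < 5 Å computed over the PTR's shared heavy atoms
after Kabsch superposition on binder Cα pairs matched by chain and
sequential position (mismatched lengths use the common prefix with a
warning; `phosphate_only = TRUE` restricts the RMSD to the phosphate
group); binder length < 160. Confidence gates (pLDDT, iPAE, iPTM, PTM)
have **no defaults**: a gate is applied only when its threshold is
explicitly supplied, and a supplied gate whose metric is missing is
skipped with a warning. Degenerate inputs produce a `fail` verdict with
reasons, never an exception, and relaxing any threshold can never turn a
pass into a fail (tested as a property).

## What the synthetic fixtures emulate — and what they don't

The generator builds idealized complexes by internal-coordinate chaining
with ideal bond lengths and angles: a three-helix bundle (10 Å axis
spacing, antiparallel, the peptide docked in the groove between two
helices), a single helix, or a three-strand sheet; peptides in helical,
strand or extended conformation with a full-geometry PTR (ring +
phosphate); pseudo-donor nitrogens planted at exact distances from a
terminal phosphate oxygen; disordered extended tails hinged rigidly away
from the core. Peptide placement is calibrated by bisection so the
slackest contact residue sits at the requested Cβ gap (default 5.5 Å, a
typical interface contact distance), and the non-contact tail is hinged
until the realized contact set equals the request — the generator verifies
its own honesty and errors on infeasible requests rather than silently
approximating.

These fixtures exercise every code path deterministically, which is their
job. They are **not** physical models: no rotamers beyond Cβ (except
PTR), no clash minimization, hinge junctions with idealized (broken-bond)
geometry, poly-alanine sequences. Passing tests therefore demonstrate
that the *rules* are implemented exactly as stated and behave correctly on
geometry with known ground truth; they do not demonstrate robustness to
the messiness of deposited structures (altloc thickets, insertion codes,
chain breaks, modified residues beyond PTR), of which only the common
cases (highest-occupancy altloc selection, numbering gaps, missing atoms)
are handled and tested.

## Numerical choices and problem sizes

Default fixture sizes (48-residue binder, 7-residue peptide) keep the full
test suite under a minute and the acceptance script under a few seconds on
one CPU while still producing non-trivial packing statistics; sizes are
arguments everywhere. SASA uses 960 sphere points by default (the
closed-form isolated-atom check holds to well under 1%); the independent
Monte-Carlo oracle comparison in the tests runs at 10 000 points on ≤5-atom
systems. Kabsch superposition enforces a proper rotation via the SVD
determinant correction and refuses rank-deficient point sets (< 3 points or
collinear). Ties at decision boundaries are exact: "within 7 Å" is ≤ 7.0,
"more than 10 Å" is > 10.0, "SCN > 4.0", "RMSD < 5 Å" — all inclusive or
exclusive per their plain reading, and the boundary cases are pinned by
tests at exactly those values.

## Known limitations

- mmCIF reading relies on `bio3d::read.cif`, which handles atom records
  but not every exotic category; PDB is the primary format.
- Chain partitioning into binder/target must be user-specified; there is
  no automatic inference for multichain complexes.
- The H-bond model has no explicit-hydrogen placement and no
  donor-capacity bookkeeping (a donor may appear in several bonds).
- RASA inherits a small orientation dependence from the fixed sampling
  sphere (≤ ~1% in practice).
- Only PTR is treated as a first-class modified residue; other PTMs pass
  through as unknown-type residues.
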