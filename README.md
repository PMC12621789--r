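# binderprep

Interface curation and design filtering for phosphopeptide binder design.

Generative binder-design models condition structure generation on
per-residue interface cues and are trained only on complexes whose binder
is compact, well packed and genuinely in contact with its target. The
computations that produce those cues and enforce those standards are simple
but easy to get subtly wrong, and they recur at both ends of a design
campaign: once when curating training examples, and again when triaging
thousands of generated designs. `binderprep` implements them as a tested,
deterministic R library with a small command-line wrapper, aimed at
structural bioinformaticians building or filtering binder–peptide design
pipelines — in particular for phosphotyrosine (pTyr / PDB component `PTR`)
peptide targets.

## What it computes

**Interface annotation.** A target residue is a *hotspot* iff its
(virtual) Cβ lies within 7 Å of any binder Cβ **and** its solvent-accessible
surface area is at least 30 Å² (Shrake–Rupley, probe radius 2.8 Å). An
*anti-hotspot* is a target residue whose closest heavy atom is more than
10 Å from every binder atom. Hotspots optionally carry a continuous
*super-hotspot* weight

    v_i = min(n_i + ε, 12) / 12,   n_i = #{binder Cα within 10 Å of Cα_i},

with ε a seeded jitter in {−1, 0, +1}. Hotspot masks can be downsampled to
a coverage budget (speckle or spatial-region strategy), and the `ORI`
pseudoatom — the center of the starting noise cloud that steers binder
placement — is placed at the geometric center of the hotspot Cβs.

**Packing quality.** Each residue gets a side-chain-neighbor count

    SCN_i = Σ_{j≠i} w_dist(d_ij) · w_ang(θ_ij),
    w_dist = 1/(1 + e^{d_ij − 9}),
    w_ang  = ((cos θ_ij + 0.5)/1.5)²  for cos θ_ij > −0.5, else 0,

where d_ij is the Cα–Cα distance and θ_ij the angle between the Cβ
direction of residue i and the vector to Cα_j. Complexes are rejected if
`binder_FBSCN` (fraction of binder residues with SCN > 4.0) < 0.12,
`interface_FBSCN` (same fraction over binder interface residues) < 0.13,
no hotspots exist, or the binder exceeds 170 residues. Disordered binder
termini are trimmed with a sliding 9-residue window (a residue is "folded"
iff SCN > 1.0; terminal residues are removed while the window holds ≤0/1/2
folded residues for window lengths ≤4/≤8/>8), and the target is radially
cropped to 25 Å around a seeded hotspot (binder residues always retained).
Targets are never packing-scored or trimmed.

**Conditioning features.** A per-token 1D tensor with fixed channel blocks —
amino-acid one-hot (20 + unknown), secondary-structure token (H/E/C from a
self-contained φ/ψ-window rule), motif flag, hotspot/anti-hotspot masks,
hotspot value, RASA (probe 1.4 Å, Tien-style max-ASA normalization) —
29 channels total, broadcastable from residues to atom slots.

**Design filters.** Heavy-atom hydrogen-bond detection (donor–acceptor
≤ 3.5 Å, acceptor-antecedent angle ≥ 90°, D–H…A ≥ 120° when hydrogens are
present) feeds the accept/reject gates for designed pTyr binders: at least
2 hydrogen bonds from the binder to the phosphate group, at most 12 total
hydrogen bonds to the peptide, phosphotyrosine RMSD < 5 Å between designed
and predicted complexes after Kabsch superposition on the binder Cαs,
binder length < 160, plus optional pLDDT/iPAE/iPTM/PTM confidence gates
(explicit thresholds only — no silent defaults).

**Synthetic fixtures.** A deterministic generator builds idealized
binder–phosphopeptide complexes (helix bundle / single helix / sheet
binders; helical, strand or extended peptides with full-geometry PTR;
controllable contact counts, phosphate-donor distances and disordered
tails), so everything above is testable without downloading structures.

## Worked example

```r
library(binderprep)

spec <- fixture_spec(disorder_tail_len = 6)   # bundle binder + pTyr peptide
cs <- assemble_complex(spec)
cs
#> ComplexStructure: 67 residues, 348 atoms
#>   chain A (binder): 60 residues
#>   chain B (target): 7 residues

hs <- detect_hotspots(cs)
names(hs)[hs]
#> [1] "B:1" "B:3" "B:4"

report <- curation_verdict(cs, scn_per_residue(cs), hs)
report
#> PackingReport: accept (binder_FBSCN 0.200, interface_FBSCN 0.143, 60 binder residues)

cmd_filter(cs, predicted = cs)
#> FilterReport: pass (phosphate H-bonds 2, peptide H-bonds 2, pTyr RMSD 0.00 A)
```

Three of the four peptide contact residues clear both hotspot gates (the
fourth sits in the binding groove and falls below the 30 Å² exposure gate);
a fifth of binder residues count as packed, which clears both FBSCN gates,
so the complex is accepted for curation. The same complex, treated as a
design with itself as the "predicted" structure, passes the filter gates
with its two phosphate-coordinating donors and a 0 Å pTyr RMSD.

The same pipelines are scriptable from a shell:

```sh
Rscript exec/binderprep fixture --out fix.pdb --seed 1
Rscript exec/binderprep curate --input fix.pdb --binder-chains A --out-dir out
# exit code 0 = accepted, 3 = rejected by gates, 1 = error
```

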