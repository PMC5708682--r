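---
title: "Methods: metrics, scores and event calls for hinge-protein trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metrics, scores and event calls for hinge-protein trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flytrap)
```

## The model

A Periplasmic Binding Protein (PBP) is treated as two quasi-rigid domains
connected by a short hinge. The canonical partition (HisJ numbering, shared
by the LAO/HisJ family) is domain 1 = residues 1–86 and 197–238, domain 2 =
90–192, with linkers 87–89 and 193–196. Opening and closure are rigid-body
rotations of one domain relative to the other about the hinge; everything
the package measures is a function of that geometry plus small-amplitude
thermal noise.

The analysis makes three assumptions worth stating explicitly:

1. **Shared numbering.** Frames and references pair residues and atoms by
   `(residue_index, atom_name)`; no sequence alignment is performed. This is
   correct for trajectories of a single protein against its own
   crystallographic/NMR references.
2. **Intact fold.** Q(NC) is used to *verify* this assumption per frame
   rather than to detect events; values staying near 1 (empirically
   0.8–0.95 on noisy but folded frames) mean the contact network is intact.
3. **Two-state geometry.** Event calls are crossovers between similarity to
   an open and a closed reference. Genuine intermediates would show as
   prolonged near-equality of the two curves and are not assigned a state.

## The two similarity scores

Both scores compare Cα–Cα distances of a frame against a reference, pair by
pair, through Gaussians of width σ~ij~ = |i−j|^0.15^ (residue-index units —
distant-in-sequence pairs are judged more leniently):

* **Q(NC)** sums over the *native contact set* of the reference: all Cα
  pairs with sequence separation ≥ 2 within 8.0 Å (boundary inclusive) in
  the reference, with exponent −Δ²/(2σ²).
* **q(similarity)** sums over *all* pairs with separation ≥ 2, no distance
  cutoff, with exponent −Δ²/σ².

The exponent denominators are deliberately asymmetric (2σ² vs σ²); they are
kept as published usage of these scores and both are explicit in the code.

**Normalization.** The historical prefactors 1/((NC−1)(NC−2)) and
1/((n−1)(n−2)) do not evaluate to 1 for a frame identical to the reference
(the q(similarity) sum has (n−1)(n−2)/2 terms, so identity scores ½; the
Q(NC) sum has NC terms). Reported trajectory values of 0.8–0.9 are only
consistent with a per-term normalization, so the package default,
`"unit_identity"`, divides by the number of summed terms and scores exactly
1 at identity. The literal prefactors remain available as
`normalization = "printed"` for comparability with legacy outputs. This dual
mode exists because the convention used by the original analysis tooling
cannot be determined from its description.

## Geometry metrics

* **Distance**: Euclidean distance between the heavy-atom, mass-weighted
  centers of mass (COM) of the two domains.
* **Angle**: at the COM of the whole hinge (both linkers pooled — the hinge
  is one named region), subtended by the two domain COMs; range (0, 180]°.
* **Dihedral**: torsion over COM(domain 1)–COM(linker 1)–COM(linker 2)–
  COM(domain 2), signed, (−180, 180]°. The original description never
  prints its four-center construction; these are the only four natural
  centers the partition defines, and this choice is flagged as a design
  decision. The dihedral is excluded from event concurrency scoring — it
  shows little sensitivity to opening/closure.
* **RMSD**: Kabsch superposition (SVD with reflection correction) on heavy
  atoms (or Cα), RMSD measured over Cα. For the open-vs-closed reference
  comparison the convention is fit *and* measure on Cα of residues 1–238
  (`cmd_compare_refs()`); both conventions are exposed.
* **R~g~, SASA**: heavy-atom, mass-weighted R~g~; Shrake–Rupley SASA with
  van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80 Å (P 1.80, Se 1.90,
  H 1.20 if present) and probe 1.4 Å. Radii are a config argument — the
  source analysis names no radii set, so these conventional values are
  explicit and overridable.

## Event detection

All thresholds are configuration keys; the defaults below were chosen once,
before benchmarking, so that the constructed step signal in the unit tests
is detected and pure-noise series stay silent; they are not tuned to any
outcome.

| parameter | default | units | role |
|---|---|---|---|
| `smooth_window_frames` | 25 (0.5 ns at 20 ps) | frames | centered moving average on q~closed~ − q~open~ |
| `min_sustain_frames` | 50 (1 ns) | frames | a sign change must persist this long to be a crossover |
| `window_frames` | 50 | frames | half-width of the concurrency search window |
| `prominence_mads` | 3 | run-MADs | extremum prominence needed to support a call |
| `min_metrics` | 3 | count | supporting metrics required for `sustained = TRUE` |

A crossover's direction comes from the new dominant reference (open
dominant ⇒ opening). Concurrency then asks, for distance, angle, RMSD,
R~g~ and SASA, whether the window around the crossover contains a peak
(opening: all five; closure: RMSD only) or a valley (closure: distance,
angle, R~g~, SASA) whose prominence over the run median exceeds
`prominence_mads` × the run's median absolute deviation. Runs are processed
independently; no smoothing window, sustain count or event call ever spans
a junction between concatenated runs.

Note a consequence of median/MAD prominence: a *permanent* mid-run state
change (half the run in each state) inflates the MAD and is deliberately
not scored as "concurrent" — the pattern being formalized is a transient
excursion against a stable baseline, which is how such events present in
practice.

The quantitative criterion for "concurrent" is this package's explicit
formalization of what was originally a by-eye judgment; it is an auditable
procedure, not a claim about the original authors' exact practice.

## Endpoint summaries

For each run, the first and last `window_ns` (default 5 ns) are sampled
every `sample_every_ps` (default 20 ps) and pooled across runs; each pool is
summarized by linear-interpolation quartiles (R `quantile` type 7 — Tukey
hinges were rejected so box values are reproducible bit for bit) and min/max
whiskers. Ten 50-ns runs at these defaults give exactly 2,500 values per
box, which the acceptance suite checks as an exact integer.

## The synthetic generator: what it emulates, and what it does not

`generate_trajectory()` emulates what production MD supplies to this
analysis — and only that:

* a 238-residue pseudo-Cα chain (3.8 Å spacing) folded into two compact
  guided-random-walk domains ~22 Å from the hinge, linkers near the hinge;
* an explicit N/CA/C peptide fragment at residues 15–16 carrying the
  configured ω isomer (cis = 0°, trans = 180°);
* scheduled transitions: the hinge angle follows logistic steps (10–90%
  width 0.5 ns) between θ~open~ = 120° and θ~closed~ = 80° — a 40° closure,
  the magnitude of a large PBP flytrap motion;
* isotropic Gaussian noise of σ = 0.3 Å applied **per residue** (one
  displacement per residue per frame, residues 15–16 sharing one), so
  residues jitter as rigid units and stiff internal geometry — notably ω —
  is preserved, as it is in real MD at these timescales;
* full reproducibility from a single seed, and a ground-truth event list.

It does **not** emulate: force-field physics, solvent, secondary structure,
chain continuity across the rotated hinge (domain 2 is rotated rigidly, so
linker bond lengths stretch non-physically during transitions), spontaneous
(unscheduled) transitions, partial unfolding, or ligand dynamics (a "holo"
fixture is one tagged pseudo-atom in the cleft, excluded from metrics by
default). Consequently a green synthetic benchmark establishes that the
*analysis* recovers known rigid-body events at realistic noise — it says
nothing about whether any particular force field produces such events.

The canonical benchmark (`synthetic_benchmark_config()`) fixes the stated
world: 10 runs × 50 ns at 20 ps, starting closed with trans Pro16, with 4
opening events at 25 ns in runs 2, 5, 7 and 9. The cis/trans behavioral
difference (trans opens, cis does not) is encoded in `benchmark_suite()` as
a fixture property — trans conditions carry scheduled events, cis carry
none — mirroring the finding it stands in for rather than simulating its
physics.

## Numerical choices

* **Kabsch**: covariance SVD with determinant correction, so reflections are
  never returned; < 3 paired atoms is an error.
* **SASA points**: a deterministic golden-spiral set (default 960 for
  single structures, 240 per frame in trajectory pipelines — a documented
  speed/precision trade-off; at 240 points the total for a 238-atom
  structure is stable to well under the 2% used in tests). Results are
  bitwise reproducible for a fixed point count.
* **Torsions**: atan2 formulation, IUPAC sign convention (cis = 0°),
  degenerate (collinear) geometry is an explicit error.
* **ω classification bands**: |ω| ≤ 30° cis, ≥ 150° trans, otherwise
  "twisted"; configurable, odd-symmetric by construction.
* **Contact cutoff boundary**: 8.0 Å inclusive.
* **Density maps**: 100 × 100 bins over [0.4, 1]², log10(1 + count);
  out-of-range points are dropped and counted, never clamped.
* **PDB I/O**: altloc "A"/blank kept, hydrogens and waters dropped on read;
  read∘write is the identity on coordinates to the format's 3 decimals.
  NMR ensembles default to model 1.

## Known limitations

* The two real reference-pair RMSD targets (5.3 Å and 9.8 Å for the LAO and
  HisJ open/closed pairs over residues 1–238) require PDB entries that are
  not redistributable with the package and cannot be fetched in an offline
  environment; the corresponding acceptance test fails with an explanatory
  message unless the files are supplied locally. Side chains missing from
  one deposited closed structure were rebuilt in the original preparation;
  a heavy-atom superposition against the raw deposition may therefore
  differ slightly, though Cα-only comparisons are unaffected.
* Event counts from the original concatenated MD figures cannot be
  reproduced — those trajectories were never deposited. The synthetic
  benchmark with ground truth is the package's substitute validation
  surface, and its recall/spurious-call/frame-error checks are the
  corresponding acceptance tests.
* q(similarity) crossovers assume the two references are geometrically well
  separated; when the two curves nearly overlap (as happens for some
  homologs at high temperature), crossovers become ill-defined and calls
  should be read with the concurrency support, not alone.
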