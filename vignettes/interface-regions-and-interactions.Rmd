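---
title: "Interface regions, non-bonded interactions, and pair statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface regions, non-bonded interactions, and pair statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiface)
```

This vignette documents the models, geometric criteria and numerical
choices behind `ppiface`, in the spirit of a methods section: what is
computed, under which assumptions, and where the design was genuinely open.

## 1. Solvent accessibility and the region model

Solvent-accessible surface area is computed with the Shrake–Rupley
algorithm: each heavy atom is inflated by the probe radius (default
1.4 Å, a water molecule) and sampled with a deterministic golden-spiral
quadrature (default 960 points per atom); a point is accessible when it
lies outside every neighboring inflated sphere. Van der Waals radii are
Bondi's (C 1.70, N 1.55, O 1.52, S 1.80, Se 1.90 Å), overridable through
the `radii` argument. Hydrogens are ignored by default — the convention
for X-ray structures deposited without them — and the quadrature is
deterministic, so identical inputs give identical areas. At 960
points/atom the per-sphere error against the analytic one- and two-sphere
closed forms is below 0.2% (the test suite and the acceptance script both
measure this); doubling the point count changes per-residue areas by well
under 1 Å².

Relative accessibility is `rASA = ASA / MaxASA`, with MaxASA a per-residue
normalization constant. Because published MaxASA scales differ, the region
classification is run once per scale — by default the theoretical and the
empirical scale of Tien et al. (2013) and the empirical scale of Miller et
al. (1987) — and the most frequently assigned label is kept. The tie-break
is a fixed priority in which the more-buried label wins (core > support >
rim-interacting > rim-NIS > surface > interior); some fixed rule is
required for reproducibility, and preferring burial is conservative for
interface membership. rASA values above 1 occur for extended conformations
and chain termini; they are kept unclamped, since clamping would silently
bias the burial signal ΔrASA.

The free monomers are the chains extracted from the complex with their
coordinates untouched — no re-minimization. The region rules use strict
inequalities at the 25% cut: a residue sitting exactly at 25% on both
sides falls into the rim branch, and the interface test `ΔrASA > 0` is
evaluated against a tolerance of 1e-9 to absorb quadrature noise. The
ΔrASA ≤ 5% sub-split of the rim separates the non-interacting surface
from the genuinely interacting rim.

Buried surface area is accounted per residue as
`max(ASA_monomer − ASA_complex, 0)` and partitioned by consensus region,
so the per-region values sum exactly to the total; the total also equals
the independent identity `ASA_A + ASA_B − ASA_complex`, which the test
suite checks on generated dimers.

## 2. Interaction detectors

Candidate residue pairs are those with a Cα–Cα distance of at most 14 Å
(inclusive); intra-chain candidates additionally require a sequence
separation of at least 2 to exclude trivially bonded neighbors. Every
detector then works from internal distances and angles only, which makes
the output rigid-motion invariant by construction (and tested under random
rotations).

All thresholds live in `geometry_config()` with these defaults (distances
in Å, angles in degrees, `≤` semantics for distances, inclusive windows
for angles — a contact built exactly at a cutoff fires):

| criterion | default | used by |
|---|---|---|
| Cα–Cα candidate cutoff | 14 | all |
| H-bond donor–acceptor distance / angle | 3.5 / ≥ 90 | hbond, salt bridge |
| S/Se H-bond distance | 4.2 | sse_hbond |
| H–π centroid distance / normal cone | 4.5 / 40 | h_pi |
| n→π* O⋯C distance / approach window | 3.6 / 95–125 | n_pi_star |
| C-bond C⋯O distance / σ-hole angle | 3.6 / ≥ 140 | c_bond |
| chalcogen S/Se⋯X distance / σ-hole angle | 4.0 / ≥ 140 | chalcogen |
| aromatic–S/Se centroid distance / face cone | 5.5 / 40 | aromatic_sse |
| ring–ring centroid distance; stacked / T-shaped split | 7.0; ≤ 30 / ≥ 60 | aromatic_aromatic |
| amino–π distance / cone | 5.5 / 45 | amino_pi |
| aromatic–charge centroid distance | 6.0 | aromatic_cation/anion |
| salt-bridge N⋯O distance | 4.0 | salt_bridge |
| vdW slack over radius sum | 0.5 | vdw |
| hydrophobic side-chain C–C distance | 5.0 | hydrophobic |
| guanidinium centroid distance / plane angle | 5.0 / 30 | arg_arg_stacking |
| backbone / side-chain proximity | 8.0 / 5.0 | clash, repulsion |

**Hydrogen handling.** Deposited X-ray structures rarely carry hydrogens,
so hydrogen-mediated criteria are evaluated on heavy atoms: the angle at
the donor between its covalent antecedent and the acceptor must be at
least 90°. For rotatable donors (hydroxyls, lysine ammonium) an ideally
placed hydrogen would orient toward the acceptor, making the heavy-atom
angle test equivalent to the donor–H⋯acceptor test; for rigid donors it
is a mild relaxation. Acceptor-side geometry is not restricted.

**Disjointness conventions.** A van der Waals record is emitted per
heavy-atom pair within the inflated radius sum, *except* for atom pairs
that already explain a directional interaction (H-bond, salt bridge,
chalcogen, n→π*, C-bond) — per-type counts are disjoint at the atom-pair
level. Stacked ARG–ARG pairs are removed from the charge-clash and
charge-repulsion categories. Clash vs repulsion is decided by minimum
atom distances (backbone close + side chains close = clash; backbone
close + side chains far = repulsion); minimum-atom distance was chosen
over centroid distance because it is well-defined for side chains of any
size. HIS is treated as cation-capable by default (configurable), as in
the residue-class table.

A pair of residues engaged in at least one detected interaction forms an
*interacting pair*; pair records carry the interaction set, the unordered
residue-name pair type, and the consensus regions of both residues.

## 3. Region-resolved statistics

Composition and partitioning use the IMGT physicochemical classes
(charge, polarity, hydropathy, aromatic/aliphatic flags, side-chain
H-bond capability); note tyrosine is polar with neutral hydropathy.
Stickiness compares the fractional contribution of each amino-acid type
to interface area against its contribution to the exposed surface area,
as `ln(f_interface / f_surface)` with a pseudo-share of 1e-6 on both
sides; a type absent from both is reported missing, never 0.

The *mean count per capable pair* averages the per-pair count of one
interaction type over all candidate pairs that are chemically capable of
forming it (an explicit capability table ships with the package: e.g.,
only ARG–ARG can arginine-stack, salt bridges need opposite formal
charges, aromatic types need a ring). Candidate pairs — not all residue
pairs — form the denominator, so a capable pair that forms nothing counts
as a zero. Binary types get a 95% Wilson score interval; count-valued
types (vdW, hydrogen bonds) a Student-t interval.

Pair-count-vs-BSA scaling counts same-region pairs twice — such a pair
crosses the region's buried surface once per chain — and merges rim with
rim-NIS; the OLS fit reports slope, intercept, R² and p.

## 4. Pair-class diversity and co-occurrence

Interacting pairs are simplified to four classes (positive, negative,
polar, apolar: charged residues keep their sign, the rest split by
polarity), giving 10 unordered pair classes. Shannon entropy is computed
in bits over the pair-class frequencies and evenness divides by
`log2 k`. `k` defaults to the 10 *possible* classes rather than the
number observed (configurable), so evenness is comparable across regions
with different observed repertoires; the degenerate single-class case is
defined as J = 1.

Pair types confined to few structures are screened with tf-idf: raw total
count as tf, `ln(N/df)` as idf, threshold 1. The natural-log idf makes a
type present in *every* structure score exactly 0 and drop out — a
documented side effect shared by any idf variant that vanishes at
df = N.

PMI compares a pair class's frequency with its independence baseline,
which carries a factor 2 for heterogeneous pairs (two orderings):
`log2(f_pair/(f1 f2))` or `log2(f_pair/(2 f1 f2))`. Frequencies entering
the PMI are per-complex frequencies averaged over complexes
(mean-of-frequencies, not pooled counts), so large complexes do not
dominate a group; a pooled mode exists for sensitivity checks. Unobserved
or filtered cells are reported missing rather than −∞, and downstream
tables keep the missingness explicit. The core and support are analyzed
together for statistical robustness, and interior values pool the whole
dataset regardless of stability group.

Complexes are classified by binding affinity (`log10` of a molar KD,
IC50 or Ki — manifest units are converted; whether IC50/Ki should be
transformed before mixing with KD is left to the data provider, values
are used as given): above −6 transient, below −9 stable, between — and
exactly at the boundaries — intermediate.

## 5. The synthetic generators, and what passing means

The package tests itself entirely on generated inputs:

* *SASA toys* (≤ 3 spheres) have closed-form expected areas
  (isolated sphere, two-sphere cap); configurations avoid triple
  overlaps, the regime where the closed forms hold.
* *Burial dimers* surround single-atom probes with blocker shells so
  each probe's rASA falls in a prescribed band before/after "binding";
  the construction is verified internally by running the full SASA
  pipeline. These exercise the classifier, not protein realism.
* *Interaction geometries* place idealized residue templates (standard
  bond lengths, regular polygon rings) so that one detector's criteria
  are satisfied with a chosen margin, or violated in exactly one
  criterion. Positive fixtures sit `margin` inside the cutoff, negatives
  `margin` outside.
* *Frequency fixtures* draw pair classes from a mixture whose weight is
  solved numerically so the coupled pair's asymptotic PMI equals
  `log2 c` under the post-mixture marginals. A naive "multiply one cell
  by c" construction would miss the target through renormalization and
  marginal shift; the solved mixture does not. For large marginals some
  targets are unattainable by mixing and the generator refuses them.

Passing on these fixtures demonstrates that the geometry, the
bookkeeping and the statistics are implemented correctly; it does not
demonstrate biological conclusions about real interfaces, which would
require curated experimental structures with measured affinities. The
idealized templates are scaffolds, not conformers: they have no
hydrogens, no alternate rotamers, and regular ring geometry.

## 6. Numerical choices and problem sizes

* SASA quadrature: 960 points/atom for reported numbers; tests that only
  need band membership use 240–480 points. Either is far inside the
  bands the burial dimers are built with.
* Threshold sharpness is guaranteed for `≤` comparisons; fixtures built
  *exactly* at a cutoff are checked at a margin of 1e-6 Å because
  coordinates synthesized through unit-vector arithmetic carry ~1e-16
  relative error — an exactly-at-cutoff distance is not floating-point
  stable under rotation either.
* Altloc handling keeps the highest-occupancy conformer, ties broken by
  altloc letter; NMR ensembles use model 1 with the model count recorded.
  MSE/SEC map to MET/CYS templates retaining selenium; other nonstandard
  residues are excluded with a warning.
* Determinism: the only stochastic components (frequency draws,
  bootstrap) take explicit seeds; the pipeline itself is seed-free and
  byte-reproducible.
* Test-suite scale: the candidate-filter oracle uses a 50-residue toy;
  the PMI recovery uses 1e5 draws; the OLS-recovery ensemble uses 400
  synthetic complexes with Gaussian affinity noise (sd 1.5 log units,
  a realistic spread for measured affinities); bootstrap calibration
  uses 120 replications of n = 60 at 300 resamples.

## 7. Known limitations

* No structure repair, hydrogen placement, or assembly generation from
  symmetry operators; the manifest must state the chain grouping.
* Water-mediated and ligand-mediated interactions are out of scope.
* The detectors are geometric classifiers, not energy models; a detected
  clash is a geometric statement whose energetic effect depends on
  context.
* The heavy-atom hydrogen-bond criterion slightly over-accepts rigid
  donors with unfavorable proton positions.
* Closed-form SASA validation covers up to three spheres; larger systems
  are validated only through convergence and conservation identities.
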