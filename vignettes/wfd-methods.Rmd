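---
title: "Distance-weighted residue descriptors for interface prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-weighted residue descriptors for interface prediction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiwfd)
```

# The problem and the model

Interface residues — the residues a protein uses to touch its partner in a
complex — are defined here operationally, from buried surface area. The
package computes per-residue solvent-accessible surface area (ASA) twice:
with the partner chains present (CASA, the *complex* state) and with each
chain isolated (MASA, the *monomer* state). A residue is

* a **surface residue** when its unbound relative accessibility
  (total RASA) is at least 16 % — interfaces form from residues that are
  solvent-exposed once the partner is removed, so only surface residues are
  candidates for prediction; and
* an **interface residue** when, additionally, |MASA − CASA| ≥ 1 Å² — any
  non-trivial burial on binding counts as interfacial contact.

Both thresholds are boundary-inclusive ("at least"). The prediction task is
binary classification of surface residues into interface / non-interface.

Each residue carries a 50-dimensional descriptor: 25 sequence-profile
features (20 substitution probabilities, entropy, relative entropy,
conservation weight, sequence variability, and NOCC, the number of aligned
sequences), 12 structure features (five ASA components, five RASA
components, average depth index DPX, average protrusion index CX), and 13
physicochemical constants per amino-acid type (eight HQI8 cluster indices
and the five Atchley factors). The **weighted feature descriptor (WFD)** of
a query residue Q concatenates the descriptors of an 11-residue sequence
window, each neighbour's block divided by its Cα–Cα Euclidean distance to
Q (the self-distance is defined as 1), so that spatially close neighbours
dominate. With window 11 this yields 50 × 11 = 550 features.

Classification is by **bagging**: m bootstrap samples drawn uniformly with
replacement (for n′ = n a sample contains on average 1 − 1/e ≈ 63.2 %
unique examples), one CART tree fitted per sample, majority vote with the
positive-vote fraction as a continuous score.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `surface_threshold` | 0.16 | fraction of max-ASA | the standard exposure cut-off for surface residues |
| `interface_delta` | 1.0 | Å² | minimal burial counting as contact; compared on total ASA |
| `window` | 11 | residues | the descriptor window; must be odd |
| `m` | 10 | learners | common bagging default; the method's source does not fix m |
| `probe_radius` | 1.4 | Å | water probe |
| `n_points` | 960 | points/atom | Shrake–Rupley quadrature resolution (≈1 % area error) |
| `sphere_radius` (CX) | 10.0 | Å | protrusion sphere |
| `mean_atom_volume` (CX) | 20.1 | Å³ | mean heavy-atom volume from the CX literature |
| `folds` | 5 | — | fivefold cross-validation |

The burial threshold's unit is not fully specified in the field's usage
(1 Å² vs 1 % RASA); this package compares **total ASA in Å²** and exposes
the threshold as configuration.

# Numerical choices

**SASA quadrature.** ASA is computed by the Shrake–Rupley method with a
deterministic Fibonacci-spiral point set rather than by external DSSP/PSAIA
executables, for self-contained reproducibility; a DSSP `ACC`-column reader
is provided as an optional bypass. Radii are per element (C 1.70, N 1.55,
O 1.52, S 1.80 Å). A fixed global point set would make areas depend on the
structure's orientation on disk, so the quadrature sphere is oriented along
the structure's principal axes (eigenvectors of the coordinate covariance,
signs fixed by the third moment of the projections): the point set then
co-rotates with the structure and areas are invariant under rigid
transforms to numerical precision. Bound and unbound computations share the
complex-wide frame, which guarantees CASA ≤ MASA exactly (occlusion can
only remove accessible test points).

**RASA denominators.** Total RASA uses the Tien et al. (2013) theoretical
maximum ASA per amino acid. All five RASA components are divided by the
*same* total reference, a deliberate deviation from deriving per-component
references from an extended Gly-X-Gly construction: it keeps the
additivity identities (backbone + side-chain = total; polar + non-polar =
total) exact in relative as well as absolute terms, introduces no hidden
numeric construction at load time, and is inconsequential downstream —
only total RASA enters a decision rule (the 16 % gate); the component RASA
values are classifier features whose scaling a tree-based learner absorbs.
Unknown residues (`X`) use the mean reference, flagged.

**DPX / CX.** Depth is the distance to the nearest solvent-accessible atom
(SASA > 0), zero for accessible atoms, averaged per residue; it is
computed in the bound complex (the natural default for complex analysis;
the source is silent on bound vs unbound). CX approximates occupied volume
as atom count × 20.1 Å³ in a 10 Å sphere; at physical interior packing
(~208 atoms fill the sphere) the free volume reaches zero, so the free
volume is clamped at 0 and CX ≥ 0 (a strict cx > 0 is not attainable from
the formula itself). Only the residue-average depth and protrusion indices
are provided — the six-variant breakdowns of structure-analysis suites are
not used by the method.

**Entropy.** Profile entropy is −Σ p ln p in natural log units with
0·ln 0 ≡ 0, and relative entropy is scaled by 100/ln 20 so the uniform
20-letter distribution maps to 100. The "25th" profile feature is NOCC:
the canonical enumeration (20 + 4 named statistics) yields only 24, and
NOCC is the HSSP-native per-residue count that completes the 25.

**WFD ordering.** The stated rule — blocks in ascending distance order —
conflicts with the worked sequence-order example usually quoted for it, and
the two cannot both hold. The package sorts blocks by ascending ED with the
self block first (ED ≡ 1 is smaller than any real Cα–Cα distance, which is
≥ ~2.9 Å for non-pathological structures), ties broken by sequence
position; `order_by = "sequence"` switches to plain window order. Padding
slots at chain termini are zero blocks appended after all real blocks, so
the fixed 550-width and the sorted prefix are both preserved. A residue
without a Cα uses its heavy-atom centroid (flagged) so window distances
stay defined; coincident coordinates fall back to distance 1.

**Trees and votes.** The CART base learner uses Gini impurity, exhaustive
axis-aligned splits, no depth limit, minimum leaf size 2, and deterministic
tie-breaks (lowest feature index, then smallest threshold). A greedy tree
with min-leaf 2 can stall on interleaved four-point configurations where no
split reduces impurity (the XOR corner case); with min-leaf 1 the tree
carves such patterns exactly. Vote ties (score exactly 0.5) are called
non-interface — the conservative choice for site calling. ROC curves use
the strict rule "positive when score > threshold", matching the tie-break;
metrics with zero denominators are reported as `NA` with a reason, never
silently as 0. Cross-validation folds are stratified, or grouped by chain
when chain ids are supplied — residue-level splits would leak windowed
features between train and test.

**Class balance.** No rebalancing is applied: nothing in the method's
description prescribes resampling, so the training distribution is used as
given. Heavily imbalanced inputs will shift the vote threshold's operating
point; the vote-fraction score and ROC/AUC remain informative in that case.

# What the synthetic generator emulates — and what it does not

`make_toy_complex()` builds two chains of pseudo-residues (backbone N, CA,
C, O plus one side-chain bead; glycine gets none) along smooth paths with
the idealized 3.8 Å Cα spacing. The first `contact_patch_size` residues of
each chain face each other across `inter_chain_gap`; the rest of chain B
turns away. This produces real occlusion geometry: the ΔASA labeling rule
recovers the designated patch (edge residues may bury marginally less than
1 Å², hence tests tolerate ~2 of 10 edge misses), and 100 Å separation
yields zero interface labels. `make_synthetic_profiles()` gives interface
rows lower entropy by mixing a one-hot component with weight
0.2 × effect size (capped at 0.9) into a flat-Dirichlet row — at effect 0
the classes are exchangeable, at effect 2 the entropy shift is detectable
at p < 10⁻³ with n = 200. `make_labeled_dataset()` bypasses structure
entirely: standard-normal features with `n_informative` columns shifted by
`effect_size` pooled SDs for positives.

A green end-to-end test on these fixtures establishes that the plumbing is
correct — labels follow the stated rules, the encoding has the stated
geometry-dependence, the ensemble recovers a known planted signal (held-out
AUC ≥ 0.95 at effect 2; AUC ≈ 0.5 at effect 0). It does **not** establish
performance on real complexes: pseudo-residues have no rotamers, packing
or secondary-structure context; synthetic profiles are not evolutionary
alignments; and the planted-signal geometry is far cleaner than real
interface signals. The headline numbers reported for this method family on
curated PDB benchmark sets (accuracies near 93 %) are properties of those
datasets and are not reproducible from synthetic fixtures; this package
makes no such claim and its tests compute no such number.

# Known limitations

* PDB ATOM-record input only (first model, heavy atoms); no mmCIF.
* The 25 % sequence-identity redundancy filter of dataset curation is out
  of scope (it needs all-vs-all alignment and is external to the per-chain
  method); chain-level curation implements the length (≥ 100) and
  interface-count (≥ 20 hetero / ≥ 30 homo) filters only.
* Shrake–Rupley areas approximate, but do not bit-match, DSSP or PSAIA
  output; the DSSP reader exists precisely so users can substitute DSSP
  totals when fidelity to that toolchain matters.
* The HQI8 / Atchley tables are embedded published constants; the pipeline
  treats them as opaque encodings and no result in this package depends on
  an individual entry.
* Training is in-memory; the package targets desk-scale datasets
  (hundreds of chains), not proteome-scale scans.
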