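---
title: "Methods: residue descriptors and statistics for early folding residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue descriptors and statistics for early folding residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(earlyfold)
```

# Scope and model

`earlyfold` characterizes individual residues of globular proteins with a
view to separating three roles: early folding residues (EFR, the
folding-initiation sites identified by pulse-labeling hydrogen–deuterium
exchange or predicted from sequence), late folding residues (LFR), and
functional residues (catalytic and ligand-binding positions). The package
computes structural descriptors per residue, compares them between groups
with burial-stratified nonparametric tests, and quantifies the
co-occurrence of two binary label sets with an observed-versus-expected
overlap shift.

The underlying structural model is deliberately coarse. A protein is an
ordered set of chains of residues with heavy-atom coordinates; hydrogens
are never used. All sequence arithmetic (local/tertiary classification,
loop windows, terminus distance) uses a consecutive 0-based index per
chain, not author numbering, so insertion codes and numbering gaps cannot
corrupt sequence-separation logic. Author numbers are preserved for label
attachment and reporting.

# Descriptors

## Contact graph and topology

Two residues are in contact when their Cα atoms are strictly closer than
8 Å; covalently adjacent residues are connected regardless of distance,
since both bonds and spatial contacts stabilize the fold. An edge is
*local* when the sequence separation is at most 5 and *tertiary*
otherwise; contacts across chains are tertiary because no sequence
separation is defined between chains. On this graph we compute:

* **Betweenness** — the sum over node pairs of the fraction of shortest
  paths passing through the residue, divided by `(n−1)(n−2)/2`. Multiple
  shortest paths are counted fractionally (Brandes-style pair
  dependencies); integer counting would make the statistic depend on
  arbitrary tie-breaking in dense helical neighborhoods.
* **Closeness** — `(m−1) / Σ d(v,·)` within the residue's connected
  component of size `m`; isolated nodes score 0. Protein graphs at 8 Å are
  effectively always connected, so the harmonic variant buys nothing and
  was rejected.
* **Clustering coefficient** — realized edges among the `n_k` neighbors
  over `n_k (n_k − 1)/2`, and 0 when `n_k < 2`.
* **Distinct neighborhood count** — the neighbors of a residue are
  partitioned into connected components of the subgraph induced on the
  neighbor set *using only local edges among its members*; the count is
  the number of components. Paths through non-neighbors do not merge
  neighborhoods: the statistic asks how many sequence-separated regions
  the residue itself stitches together, which is exactly what makes a
  folding nucleus a hub.

## Solvent accessibility and burial

ASA uses the Shrake–Rupley construction: each atom's sphere is inflated by
the probe radius (1.4 Å) and sampled with a deterministic golden-spiral
lattice of 960 points; a point survives if it lies outside every other
inflated sphere. A deterministic lattice (rather than random sampling)
makes ASA bit-for-bit reproducible; refining from 240 to 960 points moves
single-atom ASA by well under 1%. Van der Waals radii are C 1.70, N 1.55,
O 1.52, S 1.80 Å, with 1.70 Å and a warning for unknown elements.
Coincident atom centers do not occlude one another (the occlusion test
excludes distance ≈ 0), so degenerate inputs fail soft.

Residue ASA is divided by a fixed per-amino-acid maximum (the theoretical
Gly-X-Gly scale of Tien et al. 2013) to give RASA; values above 1 are
legitimate for distorted termini and are not clipped. A residue is
*buried* when RASA < 0.16, strictly; this single burial definition is
reused everywhere (energy table derivation, stratified testing), so there
is exactly one notion of "core" in the pipeline. Which maximum-ASA scale
the burial threshold was originally calibrated against is not fully
determined; the scale is therefore a documented, swappable argument
(`rasa(..., scale = )`), and no test pins absolute RASA values — only
threshold behavior and orderings.

## Energy profile

The pseudo-energy of amino acid `a` is
`e(a) = −ln((n_buried(a) + 1) / (n_exposed(a) + 1))`, an inverse-Boltzmann
conversion of burial propensity with add-one pseudocounts and kT folded
into the unit. The profile value of a residue is the sum of `e` over its
Cβ-contact partners (Cβ–Cβ < 8 Å, Cα for glycine). Whether the original
energy summed only partner energies or pair energies `e(i)+e(j)` is not
decidable from the description we follow; the partner-only reading is the
default and a `mode = "pair"` switch exposes the alternative for
sensitivity analysis — for group *comparisons* the two move together.
Residues without contacts have energy 0; unknown residue types are
excluded as centers and partners and yield `NA`.

## Non-covalent contact detectors

The cited interaction profilers place hydrogens and check angles; this
package deliberately does not. Hydrogen bonds are heavy-atom
donor–acceptor pairs (donors: nitrogens plus Ser/Thr/Tyr hydroxyls;
acceptors: oxygens plus His ring nitrogens) within 3.5 Å, excluding
sequential backbone–backbone pairs, counted per atom pair. Hydrophobic
interactions are apolar side-chain carbon pairs within 4.0 Å, at most one
per residue pair. Absolute counts will therefore deviate from
full-profiler output, and nothing downstream depends on their absolute
scale — the statistics consume group contrasts, and the test suite asserts
properties (symmetry, rigid invariance, polar-chain zeros, brute-force
pair equality), not reference counts.

# Statistics

Group comparisons report means and standard deviations over *all*
residues but take their p-value from the *buried subset*: EFR concentrate
in the core and functional residues at the surface, so unstratified tests
mostly measure burial. Continuous features use the two-sided Mann–Whitney
U test (exact enumeration when both samples have ≤ 8 observations and no
ties; otherwise the normal approximation with mid-ranks, tie-corrected
variance and continuity correction), significant below 0.05. Count-valued
features (contact, bond and neighborhood counts) use Dunn's rank z-test
with Bonferroni correction, significant below 0.025. No correction is
applied *across* features — each feature is reported on its own, and the
Bonferroni family is only Dunn's pairwise set; consumers scanning many
features should apply their own FDR control.

The overlap shift for two label sets over `N` positions is
`100·(n_obs/N − (n_A/N)(n_B/N))` — observed joint probability minus the
product of marginals, in percentage points. It is reported to 2 decimals,
marginal percentages to 1 decimal. Notched-box summaries use the McGill
convention `median ± 1.57·IQR/√n`, the standard reading of a "95%
confidence interval around the median".

# The synthetic generator

Every stage is exercised end-to-end on synthetic structures, so the
generator is first-class code. It emulates small single-chain globular
proteins in the 56–164 residue range typical of experimental folding
datasets (default 80–100 residues): a layout of helix/strand/coil
segments, ideal-geometry backbones (bond lengths and angles fixed,
per-segment φ/ψ: −57/−47 helical, −139/135 extended, broad coil sampling),
and side chains reduced to Cβ plus at most two ideal pseudo-atoms — enough
for every consumer in the package (contact atoms, apolar carbons,
hydroxyl donors). Helices built this way have the canonical ~2.3 Å Cα
radius, ~1.5 Å rise and 100° twist, and their i, i+4 amide–carbonyl pairs
fall inside the hydrogen-bond detector's cutoff, as they should.

Segments are rigidly placed around a common center — hydrophobic-rich
segments inward — then compacted: first pulled radially until contact,
then annealed with small rigid perturbations accepted only when they
shrink the radius of gyration without atom clashes (< 2.5 Å). The
resulting ~100-residue globules have realistic radii of gyration (~11–12 Å)
and 20–30% buried residues.

Because the reduced side chains bias RASA upward relative to full-atom
structures, amino-acid identity is assigned *after* assembly, conditioned
on measured burial: buried positions become hydrophobic with probability
0.97, exposed ones with probability 0.03, iterated a few times because
rebuilding side chains shifts accessibility. This plants the
buried/exposed occupancy contrast that an inverse-Boltzmann potential must
recover — hydrophobics come out majority-buried with negative
pseudo-energies, polars positive — at the cost of a lower hydrophobic
sequence fraction (~25%) than real proteins (~45%). The generator is
seed-deterministic down to the written PDB bytes, and all RNG use is
isolated from the caller's RNG state.

Label sets with controlled joint probability use exact-count sampling:
`round(p_J·N)` positions get both labels, the marginals are filled to
`round(p_A·N)` and `round(p_B·N)`, and positions are shuffled by seed.
Exact counts make the planted overlap shift an identity rather than an
estimate, which is what sharp recovery tests need; a Bernoulli variant is
used in the tests to confirm recovery under sampling noise as well.

What the generator does *not* emulate: real rotamers and Ramachandran
statistics, chain continuity between rigidly placed segments (covalent
adjacency is handled at the graph level, not the coordinate level),
realistic amino-acid composition, disulfides, ligands, and any actual
folding kinetics. Passing tests on synthetic data therefore demonstrate
correctness of the computations and the internal consistency of the
planted statistical structure — not biological validity of any particular
threshold on real proteins.

# Numerical and design choices

* Distance tests at cutoffs are strict (`<`) for the 8 Å contact rules
  and the 0.16 burial rule, matching their stated definitions; detector
  cutoffs (3.5/4.0 Å) are inclusive.
* The EFR score threshold classifies `score > 0.163` as EARLY — strictly
  greater, the boundary value itself is LATE.
* Alternate locations resolve to the highest occupancy (ties toward the
  alphabetically first altloc); only the first model of multi-model files
  is read; waters, ligands and hydrogens are dropped; non-standard
  residues map to their parent amino acid (e.g. MSE→MET) or to UNK.
* Prolines are ordinary residues here; when EFR labels come from
  hydrogen-deuterium exchange, prolines lack the exchangeable amide and
  are structurally LATE, which is how such datasets encode them. Callers
  who want them excluded can filter the feature table.
* Loop-fraction windows truncate at chain termini with the number of
  existing positions as denominator, rather than padding with fabricated
  annotation.
* Residue and structure centroids are unweighted means over heavy atoms.
* Start2Fold-style JSON ingestion verifies that a declared EFR count
  equals the parsed set size and fails loudly on mismatch; label
  attachment tolerates up to 10% unmatched residue numbers (reported),
  beyond which it raises a mapping error, since that level of mismatch
  indicates a numbering-scheme inconsistency rather than missing density.
  This guard threshold is this package's choice; how residue numbering
  reconciliations were handled originally is not specified anywhere we
  could follow.

# Problem sizes in the test suite

The suite validates against independent oracles at sizes where exhaustive
computation is cheap and behavior is already generic: 100 random graphs of
up to 30 nodes against Floyd–Warshall/path-enumeration oracles (tolerance
1e−9); Mann–Whitney exact p-values against full enumeration for all group
sizes up to 6; type-I calibration with 1000 null replicates of 200
residues; overlap recovery with 200 Bernoulli replicates at N = 1000;
energy profiles against a brute-force double loop on 40-residue folds; and
three cached 100-residue globules for all pipeline-level assertions. These
sizes are the package's validation design: each doubles as a regression
fixture, and all are regenerated from seeds at test time.

# Known limitations

Absolute hydrogen-bond and hydrophobic counts are not comparable to
full interaction profilers (no hydrogens, no geometry terms). RASA from
reduced-side-chain synthetic structures is systematically higher than
full-atom RASA, which is why the generator conditions composition on
measured burial instead of composition driving burial. The energy profile
is a burial potential, not a physical energy; only contrasts between
groups are meaningful. Temperature-dependent accessibility refinements
are out of scope.
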